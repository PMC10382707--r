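# Synthetic cell maps: homogeneous spatial Poisson centroids within a
# cortical region bounded by pial and white-matter polylines.

#' Default cortical section geometry
#'
#' A gently curved pia-to-white-matter band: the pial surface along the top,
#' the white-matter boundary along the bottom, and the region polygon formed
#' by joining them. Coordinates in um.
#'
#' @param width_um mediolateral extent of the region.
#' @param depth_um mean pia-to-white-matter distance.
#' @param curvature_um amplitude of the sinusoidal bowing of both surfaces.
#' @param n_vertices vertices per boundary polyline.
#' @return A `section_geometry` list with `region`, `pia`, `wm`.
#' @export
cortex_geometry <- function(width_um = 1200, depth_um = 900,
                            curvature_um = 30, n_vertices = 9) {
  x <- seq(0, width_um, length.out = n_vertices)
  bow <- curvature_um * sin(pi * x / width_um)
  pia <- cbind(x, bow)
  wm <- cbind(x, depth_um + bow * 0.5)
  section_geometry(region = rbind(pia, wm[nrow(wm):1, ]), pia = pia, wm = wm)
}

#' Construct and validate section geometry
#'
#' @param region simple polygon (n x 2 matrix, um) outlining the area of
#'   interest.
#' @param pia,wm polylines (um) bounding the region at the pial surface and
#'   the white matter; they must not cross each other.
#' @param section_thickness_um slice thickness recorded as metadata (no
#'   stereological correction is applied).
#' @return A `section_geometry` list.
#' @export
section_geometry <- function(region, pia, wm, section_thickness_um = 50) {
  region <- as.matrix(region); pia <- as.matrix(pia); wm <- as.matrix(wm)
  if (abs(polygon_area(region)) <= 0)
    abort2("degenerate region polygon (area <= 0)", "audiogain_bad_geometry")
  if (polylines_cross(pia, wm))
    abort2("pia and white-matter polylines cross", "audiogain_bad_geometry")
  structure(list(region = region, pia = pia, wm = wm,
                 section_thickness_um = section_thickness_um),
            class = "section_geometry")
}

# Uniform points inside a polygon by bounding-box rejection sampling.
runif_in_polygon <- function(n, poly) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_polygon(px, py, poly)
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Synthesize a cell map for one hemisphere section
#'
#' Places PV+ and NeuN+ centroids by independent homogeneous spatial Poisson
#' processes at the given true densities within the region polygon, so the
#' expected marker count is `density x polygon area`.
#'
#' @param pv_density,neun_density true densities, cells/mm^2.
#' @param geometry a [section_geometry()] (default [cortex_geometry()]).
#' @param seed integer seed for the placement stream.
#' @param meta metadata list (animal_id, hemisphere, area, ...).
#' @return Object of class `cellmap`: `cells` data frame (`x_um`, `y_um`,
#'   `marker`) plus the geometry.
#' @export
synth_cellmap <- function(pv_density, neun_density = 0,
                          geometry = cortex_geometry(), seed = 1L,
                          meta = list()) {
  stopifnot(inherits(geometry, "section_geometry"))
  if (pv_density < 0 || neun_density < 0)
    abort2("densities must be >= 0", "audiogain_bad_config")
  area_mm2 <- abs(polygon_area(geometry$region)) / 1e6
  cells <- with_seed(seed, {
    out <- list()
    for (marker in c("PV", "NeuN")) {
      dens <- if (marker == "PV") pv_density else neun_density
      n <- stats::rpois(1, dens * area_mm2)
      pts <- runif_in_polygon(n, geometry$region)
      out[[marker]] <- data.frame(x_um = pts[, 1], y_um = pts[, 2],
                                  marker = rep(marker, n),
                                  stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  rownames(cells) <- NULL
  cellmap(cells, geometry, meta)
}

#' Construct a cell map from centroids and geometry
#'
#' @param cells data frame with `x_um`, `y_um`, `marker`.
#' @param geometry a [section_geometry()].
#' @param meta metadata list.
#' @return Object of class `cellmap`.
#' @export
cellmap <- function(cells, geometry, meta = list()) {
  stopifnot(inherits(geometry, "section_geometry"),
            all(c("x_um", "y_um", "marker") %in% names(cells)))
  structure(list(cells = cells, region = geometry$region,
                 pia = geometry$pia, wm = geometry$wm,
                 section_thickness_um = geometry$section_thickness_um,
                 meta = meta),
            class = "cellmap")
}

#' @export
print.cellmap <- function(x, ...) {
  cat(sprintf("cellmap: %d cells (%s) over %.3f mm^2\n",
              nrow(x$cells),
              paste(sprintf("%s=%d", names(table(x$cells$marker)),
                            as.integer(table(x$cells$marker))),
                    collapse = ", "),
              abs(polygon_area(x$region)) / 1e6))
  invisible(x)
}
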