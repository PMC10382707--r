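# Cell-density estimation and laminar depth analysis.

#' Marker density over the full region of interest
#'
#' Counts centroids of the given marker inside the region polygon (even-odd
#' rule, on-boundary points counted inside) and divides by the polygon area
#' (shoelace formula, um^2 converted to mm^2).
#'
#' @param cm a [cellmap()].
#' @param marker marker label to count (default "PV").
#' @return Object of class `density_estimate`: `marker`, `count`, `area_mm2`,
#'   `density_cells_mm2`, `frame`.
#' @export
density_full_region <- function(cm, marker = "PV") {
  stopifnot(inherits(cm, "cellmap"))
  cells <- cm$cells[cm$cells$marker == marker, ]
  count <- if (nrow(cells) == 0) 0L else
    sum(point_in_polygon(cells$x_um, cells$y_um, cm$region))
  area <- abs(polygon_area(cm$region)) / 1e6
  if (area <= 0) abort2("region area <= 0", "audiogain_bad_geometry")
  structure(list(marker = marker, count = as.integer(count),
                 area_mm2 = area, density_cells_mm2 = count / area,
                 frame = "full region"), class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("%s: %d cells / %.4f mm^2 = %.1f cells/mm^2 (%s)\n",
              x$marker, x$count, x$area_mm2, x$density_cells_mm2, x$frame))
  invisible(x)
}

# Build the strip rectangle (width w, long axis u through the region
# centroid) and return its intersection with the region polygon.
strip_polygon <- function(cm, w) {
  ctr <- polygon_centroid(cm$region)
  np <- nearest_on_polyline(ctr[1], ctr[2], cm$pia)
  u <- polyline_normal_at(cm$pia, np$segment, np$t)
  nw <- nearest_on_polyline(ctr[1], ctr[2], cm$wm)
  to_wm <- c(nw$x - np$x, nw$y - np$y)
  if (sum(u * to_wm) < 0) u <- -u            # orient pia -> white matter
  v <- c(-u[2], u[1])
  # rectangle long enough to span the whole region along u
  s_along <- (cm$region[, 1] - ctr[1]) * u[1] + (cm$region[, 2] - ctr[2]) * u[2]
  lo <- min(s_along) - 1; hi <- max(s_along) + 1
  corners <- rbind(ctr + lo * u - (w / 2) * v, ctr + hi * u - (w / 2) * v,
                   ctr + hi * u + (w / 2) * v, ctr + lo * u + (w / 2) * v)
  clip_polygon_convex(cm$region, corners)
}

#' Marker density within a central pia-to-white-matter strip
#'
#' The sampling frame is a rectangle through the region centroid, oriented
#' along the local pia-to-white-matter axis and spanning the full depth of
#' the region; its width is solved numerically so that the strip-region
#' intersection covers `strip_fraction` of the region area (relative
#' tolerance 1e-3).
#'
#' @param cm a [cellmap()].
#' @param marker marker label to count (default "NeuN").
#' @param strip_fraction target fraction of the region area (default 0.05).
#' @return A `density_estimate` over the strip intersection; the strip
#'   polygon is attached as attribute `strip`.
#' @export
density_central_strip <- function(cm, marker = "NeuN",
                                  strip_fraction = 0.05) {
  stopifnot(inherits(cm, "cellmap"),
            strip_fraction > 0, strip_fraction <= 1)
  area_reg <- abs(polygon_area(cm$region))
  target <- strip_fraction * area_reg
  area_of <- function(w) {
    p <- strip_polygon(cm, w)
    if (nrow(p) < 3) 0 else abs(polygon_area(p))
  }
  wmax <- max(stats::dist(cm$region)) * 1.05
  if (area_of(wmax) <= target * (1 + 1e-9)) {
    w <- wmax                                # fraction ~ 1: whole region
  } else {
    w <- stats::uniroot(function(w) area_of(w) - target,
                        lower = 1e-6 * wmax, upper = wmax,
                        tol = 1e-4 * wmax)$root
  }
  strip <- strip_polygon(cm, w)
  if (nrow(strip) < 3)
    abort2("strip cannot be placed inside the region",
           "audiogain_bad_geometry")
  # strip must reach both boundaries (pia and white matter)
  dp <- min(nearest_on_polyline(strip[, 1], strip[, 2], cm$pia)$dist)
  dw <- min(nearest_on_polyline(strip[, 1], strip[, 2], cm$wm)$dist)
  if (dp > 1e-3 * sqrt(area_reg) || dw > 1e-3 * sqrt(area_reg))
    abort2("strip does not reach both the pia and the white matter",
           "audiogain_bad_geometry")
  cells <- cm$cells[cm$cells$marker == marker, ]
  count <- if (nrow(cells) == 0) 0L else
    sum(point_in_polygon(cells$x_um, cells$y_um, strip))
  area <- abs(polygon_area(strip)) / 1e6
  out <- structure(list(marker = marker, count = as.integer(count),
                        area_mm2 = area, density_cells_mm2 = count / area,
                        frame = "central strip"), class = "density_estimate")
  attr(out, "strip") <- strip
  out
}

#' Normalized laminar depth of centroids
#'
#' For each centroid, `p` is its nearest point on the pial surface; the depth
#' line runs from `p` along the local inward pia normal (segment normals,
#' averaged at vertices) to its first intersection `w` with the white-matter
#' boundary. Depth is the centroid's projection onto that line divided by
#' `|w - p|`, clipped to `[0, 1]`. When the normal fails to hit the white
#' matter, the nearest-distance ratio `d_pia / (d_pia + d_wm)` is used and
#' flagged.
#'
#' @param x_um,y_um centroid coordinates.
#' @param pia,wm boundary polylines (n x 2 matrices, um).
#' @return Data frame `depth` in `[0, 1]`, `method` ("normal" or
#'   "nearest_ratio"), `clipped`.
#' @export
normalized_depth <- function(x_um, y_um, pia, wm) {
  pia <- as.matrix(pia); wm <- as.matrix(wm)
  n <- length(x_um)
  if (n == 0)
    return(data.frame(depth = numeric(0), method = character(0),
                      clipped = logical(0), stringsAsFactors = FALSE))
  np <- nearest_on_polyline(x_um, y_um, pia)

  # per-cell inward pia normal: segment normals, averaged at vertices
  ns <- nrow(pia) - 1L
  d_seg <- pia[-1, , drop = FALSE] - pia[-nrow(pia), , drop = FALSE]
  N <- cbind(-d_seg[, 2], d_seg[, 1])
  N <- N / sqrt(rowSums(N^2))
  nrm <- N[np$segment, , drop = FALSE]
  tol <- 1e-9
  at_start <- np$t <= tol & np$segment > 1
  at_end <- np$t >= 1 - tol & np$segment < ns
  if (any(at_start))
    nrm[at_start, ] <- nrm[at_start, , drop = FALSE] +
      N[np$segment[at_start] - 1L, , drop = FALSE]
  if (any(at_end))
    nrm[at_end, ] <- nrm[at_end, , drop = FALSE] +
      N[np$segment[at_end] + 1L, , drop = FALSE]
  nrm <- nrm / sqrt(rowSums(nrm^2))

  # orient toward the white matter
  nw0 <- nearest_on_polyline(np$x, np$y, wm)
  flip <- nrm[, 1] * (nw0$x - np$x) + nrm[, 2] * (nw0$y - np$y) < 0
  nrm[flip, ] <- -nrm[flip, , drop = FALSE]

  # first ray-polyline intersection with wm, vectorized per wm segment
  span <- rep(Inf, n)
  for (s in seq_len(nrow(wm) - 1L)) {
    p <- wm[s, ]; r <- wm[s + 1, ] - p
    den <- nrm[, 1] * r[2] - nrm[, 2] * r[1]
    dx <- p[1] - np$x; dy <- p[2] - np$y
    t_ray <- (dx * r[2] - dy * r[1]) / den
    u <- (dx * nrm[, 2] - dy * nrm[, 1]) / den
    ok <- abs(den) > 1e-15 & t_ray > 1e-9 & u >= -1e-9 & u <= 1 + 1e-9 &
      t_ray < span
    span[ok] <- t_ray[ok]
  }
  hit <- is.finite(span)
  proj <- (x_um - np$x) * nrm[, 1] + (y_um - np$y) * nrm[, 2]
  d <- proj / span
  if (any(!hit)) {                        # fallback: nearest-distance ratio
    dw <- nearest_on_polyline(x_um[!hit], y_um[!hit], wm)$dist
    d[!hit] <- np$dist[!hit] / (np$dist[!hit] + dw)
  }
  data.frame(depth = pmin(1, pmax(0, d)),
             method = ifelse(hit, "normal", "nearest_ratio"),
             clipped = d < 0 | d > 1, stringsAsFactors = FALSE)
}

#' Laminar profile: equal-depth binning
#'
#' Counts normalized depths into `n_bins` equal-width bins on `[0, 1]`,
#' half-open `[lo, hi)` except the final bin, which includes 1.
#'
#' @param depths normalized depths in `[0, 1]`.
#' @param n_bins 5, 10 or 20.
#' @return Object of class `laminar_profile`: per-bin `counts` and
#'   `fractions` (fractions are NA when there are no cells).
#' @export
laminar_profile <- function(depths, n_bins = 5L) {
  if (!n_bins %in% c(5L, 10L, 20L))
    abort2("n_bins must be 5, 10 or 20", "audiogain_bad_bins")
  if (length(depths) && (min(depths) < 0 || max(depths) > 1))
    abort2("depths must lie in [0, 1]", "audiogain_bad_depth")
  idx <- pmin(floor(depths * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    n_bins = as.integer(n_bins), counts = counts,
    fractions = if (length(depths)) counts / length(depths)
                else rep(NA_real_, n_bins),
    bin_lo = (seq_len(n_bins) - 1) / n_bins,
    bin_hi = seq_len(n_bins) / n_bins), class = "laminar_profile")
}

#' @export
print.laminar_profile <- function(x, ...) {
  cat(sprintf("laminar profile, %d bins: %s\n", x$n_bins,
              paste(x$counts, collapse = " ")))
  invisible(x)
}
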