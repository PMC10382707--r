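# Plain-text interchange: sweep sets as long CSV + JSON sidecar, cell maps as
# CSV + JSON geometry, cohort manifests as JSON.

#' Write / read a sweep set (long CSV + JSON sidecar)
#'
#' The CSV holds `trial`, `sample_index`, `voltage_uV`; the sidecar records
#' `fs_hz`, `t0_index`, and the recording metadata.
#'
#' @param ss a [sweepset()].
#' @param csv_path,json_path output paths.
#' @return `write_sweepset` returns the paths invisibly; `read_sweepset`
#'   returns a [sweepset()].
#' @export
write_sweepset <- function(ss, csv_path, json_path = sub("\\.csv$", ".json",
                                                         csv_path)) {
  stopifnot(inherits(ss, "sweepset"))
  nt <- nrow(ss$voltages); nsamp <- ncol(ss$voltages)
  df <- data.frame(trial = rep(seq_len(nt), each = nsamp),
                   sample_index = rep(seq_len(nsamp), nt),
                   voltage_uV = as.vector(t(ss$voltages)))
  utils::write.csv(df, csv_path, row.names = FALSE)
  side <- c(list(fs_hz = ss$fs, t0_index = ss$t0_index,
                 n_trials = nt, n_samples = nsamp), ss$meta)
  jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_sweepset
#' @export
read_sweepset <- function(csv_path, json_path = sub("\\.csv$", ".json",
                                                    csv_path)) {
  df <- utils::read.csv(csv_path)
  side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  v <- matrix(df$voltage_uV[order(df$trial, df$sample_index)],
              nrow = side$n_trials, ncol = side$n_samples, byrow = TRUE)
  meta <- side[setdiff(names(side),
                       c("fs_hz", "t0_index", "n_trials", "n_samples"))]
  sweepset(v, side$fs_hz, side$t0_index, meta = meta)
}

#' Write / read a cell map (centroid CSV + JSON geometry)
#'
#' @param cm a [cellmap()].
#' @param csv_path,json_path output paths.
#' @return `write_cellmap` returns the paths invisibly; `read_cellmap`
#'   returns a [cellmap()].
#' @export
write_cellmap <- function(cm, csv_path, json_path = sub("\\.csv$", ".json",
                                                        csv_path)) {
  stopifnot(inherits(cm, "cellmap"))
  utils::write.csv(cm$cells, csv_path, row.names = FALSE)
  geo <- c(list(region = unname(apply(cm$region, 1, c, simplify = FALSE)),
                pia = unname(apply(cm$pia, 1, c, simplify = FALSE)),
                wm = unname(apply(cm$wm, 1, c, simplify = FALSE)),
                units = "um",
                section_thickness_um = cm$section_thickness_um),
           cm$meta)
  jsonlite::write_json(geo, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname write_cellmap
#' @export
read_cellmap <- function(csv_path, json_path = sub("\\.csv$", ".json",
                                                   csv_path)) {
  cells <- utils::read.csv(csv_path)
  geo <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  as_mat <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, x)
  }
  g <- section_geometry(as_mat(geo$region), as_mat(geo$pia), as_mat(geo$wm),
                        geo$section_thickness_um %||% 50)
  meta <- geo[setdiff(names(geo), c("region", "pia", "wm", "units",
                                    "section_thickness_um"))]
  cellmap(cells, g, meta)
}

#' Write / read a cohort manifest as JSON
#'
#' @param manifest a [generate_cohort()] result.
#' @param path output path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the manifest (config restored as `cohort_config`).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  jsonlite::write_json(
    list(config = unclass(manifest$config),
         animals = manifest$animals, ears = manifest$ears,
         hemispheres = manifest$hemispheres),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(cohort_config, raw$config[setdiff(names(raw$config), NULL)])
  structure(list(config = cfg, animals = raw$animals, ears = raw$ears,
                 hemispheres = raw$hemispheres),
            class = "cohort_manifest")
}
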