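# ABR threshold detection and hearing-impairment classification.

#' Bundle a level series of averaged ABR waveforms
#'
#' @param levels tested stimulus levels, dB SPL (will be validated as sorted
#'   and duplicate-free by [detect_threshold()]).
#' @param waveforms list of trial-averaged `waveform` objects, one per level.
#' @param meta metadata (animal_id, ear, stimulus, age_weeks, ...).
#' @return Object of class `abr_series`.
#' @export
abr_series <- function(levels, waveforms, meta = list()) {
  stopifnot(length(levels) == length(waveforms),
            all(vapply(waveforms, inherits, TRUE, "waveform")))
  structure(list(levels = levels, waveforms = waveforms, meta = meta),
            class = "abr_series")
}

#' Detect the ABR threshold from a level series
#'
#' A level is response-positive when the post-stimulus peak-to-peak amplitude
#' in `window_ms` exceeds `k` times the prestimulus noise SD, with the SD
#' pooled across all levels of the series (the noise floor is common to the
#' series, and the pooled estimate keeps the false-alarm rate of the
#' peak-to-peak statistic below ~1% per series at the default `k = 6.5`; see
#' the package vignette for the calibration). The threshold is the lowest
#' level that is response-positive together with *all* higher tested levels;
#' if no such level exists the ear is flagged "above max tested".
#'
#' @param series an [abr_series()] with at least 3 levels.
#' @param k noise-SD multiple of the detection criterion.
#' @param window_ms post-stimulus analysis window, ms.
#' @return Object of class `ear_audiogram`: `threshold_db_spl` (NA when above
#'   max tested), `above_max`, `noise_sd_uv`, and a per-level `detail` data
#'   frame.
#' @export
detect_threshold <- function(series, k = 6.5, window_ms = c(1, 10)) {
  stopifnot(inherits(series, "abr_series"))
  lev <- series$levels
  if (length(lev) < 3)
    abort2("need >= 3 levels spanning sub- to supra-threshold",
           "audiogain_bad_series")
  if (is.unsorted(lev, strictly = TRUE))
    abort2("levels must be sorted and duplicate-free", "audiogain_bad_series")
  pre <- unlist(lapply(series$waveforms, function(w) w$v[w$t_ms < 0]))
  if (length(pre) < 2)
    abort2("missing pre-stimulus baseline samples", "audiogain_bad_series")
  sd_pool <- stats::sd(pre)
  p2p <- vapply(series$waveforms, function(w) {
    v <- w$v[w$t_ms >= window_ms[1] & w$t_ms <= window_ms[2]]
    max(v) - min(v)
  }, 0)
  positive <- p2p > k * sd_pool
  # lowest level from which all higher levels are also positive
  all_above <- rev(cumprod(rev(positive))) > 0
  thr <- if (any(all_above)) lev[which(all_above)[1]] else NA_real_
  structure(list(
    threshold_db_spl = thr, above_max = !any(all_above),
    noise_sd_uv = sd_pool, k = k,
    detail = data.frame(level_db_spl = lev, p2p_uv = p2p,
                        positive = positive),
    meta = series$meta), class = "ear_audiogram")
}

# Canonical audiogram table row used across the audiometry functions.
audiogram_row <- function(animal_id, genotype, ear, threshold_db_spl,
                          above_max = FALSE, stimulus = "click",
                          age_weeks = NA_real_, sex = NA_character_) {
  data.frame(animal_id = animal_id, genotype = genotype, ear = ear,
             stimulus = stimulus, age_weeks = age_weeks, sex = sex,
             threshold_db_spl = threshold_db_spl, above_max = above_max,
             stringsAsFactors = FALSE)
}

#' Classify ears and animals by hearing status
#'
#' The normal-hearing cutoff is `mean + cutoff_sd x SD` over all wild-type
#' ear thresholds (ears pooled across animals and sexes; sample SD). An ear
#' is impaired iff its threshold strictly exceeds the cutoff; ears above the
#' maximum tested level count as impaired. Animals are "normal",
#' "monaural HI" or "binaural HI" from their ear flags; animals with a single
#' measured ear are classified on that ear and flagged `partial`.
#'
#' @param audiograms data frame with one row per ear: `animal_id`,
#'   `genotype` ("WT"/...), `ear`, `threshold_db_spl`, `above_max`.
#' @param cutoff_sd SD multiple defining the upper bound of normal hearing.
#' @return Object of class `hearing_status`: `cutoff_db`, per-ear flags
#'   (`ears`), and per-animal categories with dB HL (`animals`).
#' @export
classify_hearing <- function(audiograms, cutoff_sd = 2.5) {
  need <- c("animal_id", "genotype", "ear", "threshold_db_spl", "above_max")
  stopifnot(all(need %in% names(audiograms)))
  if (anyDuplicated(audiograms[, c("animal_id", "ear")]))
    abort2("one row per animal x ear required (summarize sessions first)",
           "audiogain_bad_audiogram")
  wt <- audiograms$genotype == "WT" & !audiograms$above_max &
    !is.na(audiograms$threshold_db_spl)
  if (sum(wt) < 2)
    abort2("need >= 2 WT ears with numeric thresholds",
           "audiogain_bad_audiogram")
  cutoff <- mean(audiograms$threshold_db_spl[wt]) +
    cutoff_sd * stats::sd(audiograms$threshold_db_spl[wt])
  ears <- audiograms
  ears$impaired <- ears$above_max |
    (!is.na(ears$threshold_db_spl) & ears$threshold_db_spl > cutoff)

  per_animal <- split(ears, ears$animal_id)
  animals <- do.call(rbind, lapply(per_animal, function(d) {
    n_imp <- sum(d$impaired)
    cat_ <- if (nrow(d) == 1) {
      if (d$impaired) "monaural HI" else "normal"
    } else if (n_imp == 2) "binaural HI"
      else if (n_imp == 1) "monaural HI" else "normal"
    data.frame(animal_id = d$animal_id[1], genotype = d$genotype[1],
               n_ears_measured = nrow(d), n_ears_impaired = n_imp,
               category = cat_, hi = n_imp > 0, partial = nrow(d) < 2,
               stringsAsFactors = FALSE)
  }))
  rownames(animals) <- NULL
  hl <- compute_hl_db(audiograms)
  animals <- merge(animals, hl[, c("animal_id", "max_threshold_db", "hl_db")],
                   by = "animal_id", sort = FALSE)
  structure(list(cutoff_db = cutoff, cutoff_sd = cutoff_sd,
                 ears = ears, animals = animals),
            class = "hearing_status")
}

#' @export
print.hearing_status <- function(x, ...) {
  cat(sprintf("hearing status: cutoff %.2f dB SPL (mean + %.1f SD, WT ears)\n",
              x$cutoff_db, x$cutoff_sd))
  print(table(x$animals$genotype, x$animals$category))
  invisible(x)
}

#' Animal-level hearing loss in dB HL
#'
#' `hl_db = max threshold across the animal's measured ears - mean over WT
#' animals of that same per-animal maximum`. Ears above the maximum tested
#' level are excluded from the maximum (counted in the `n_sentinel_excluded`
#' attribute); an animal with only sentinel ears gets NA.
#'
#' @param audiograms per-ear audiogram data frame (see [classify_hearing()]).
#' @return Data frame `animal_id`, `genotype`, `max_threshold_db`, `hl_db`.
#' @export
compute_hl_db <- function(audiograms) {
  stopifnot(all(c("animal_id", "genotype", "threshold_db_spl") %in%
                  names(audiograms)))
  num <- !audiograms$above_max & !is.na(audiograms$threshold_db_spl)
  n_sent <- sum(!num)
  per <- split(audiograms[num, ], audiograms$animal_id[num], drop = FALSE)
  ids <- unique(audiograms$animal_id)
  mx <- vapply(ids, function(id) {
    d <- per[[id]]
    if (is.null(d) || nrow(d) == 0) NA_real_ else max(d$threshold_db_spl)
  }, 0)
  gt <- audiograms$genotype[match(ids, audiograms$animal_id)]
  wt_ref <- mean(mx[gt == "WT"], na.rm = TRUE)
  if (!is.finite(wt_ref))
    abort2("empty WT reference set", "audiogain_bad_audiogram")
  out <- data.frame(animal_id = ids, genotype = gt,
                    max_threshold_db = mx, hl_db = mx - wt_ref,
                    stringsAsFactors = FALSE)
  attr(out, "n_sentinel_excluded") <- n_sent
  rownames(out) <- NULL
  out
}

#' Average repeated audiograms within age windows
#'
#' Per-ear arithmetic mean of numeric thresholds within each age window
#' (default `[3, 6)` weeks and `[6, 14]` weeks). Sentinel ("above max
#' tested") sessions are excluded and counted; ears with sessions in both
#' windows are flagged `longitudinal`.
#'
#' @param audiograms session-level audiogram rows (one per ear x session).
#' @param windows named list of `c(lo, hi)` age windows in weeks; the first
#'   window is half-open `[lo, hi)`, subsequent ones are `[lo, hi]`.
#' @return Data frame with one row per ear x window present in the data;
#'   attribute `n_sentinel_excluded` counts dropped sentinel sessions.
#' @export
summarize_by_age_window <- function(audiograms,
                                    windows = list(young = c(3, 6),
                                                   adult = c(6, 14))) {
  stopifnot(all(c("animal_id", "ear", "age_weeks", "threshold_db_spl",
                  "above_max") %in% names(audiograms)))
  num <- audiograms[!audiograms$above_max &
                      !is.na(audiograms$threshold_db_spl), ]
  n_sent <- nrow(audiograms) - nrow(num)
  rows <- list()
  for (wi in seq_along(windows)) {
    wname <- names(windows)[wi]
    w <- windows[[wi]]
    sel <- if (wi == 1) num$age_weeks >= w[1] & num$age_weeks < w[2]
           else num$age_weeks >= w[1] & num$age_weeks <= w[2]
    d <- num[sel, ]
    if (nrow(d) == 0) next
    agg <- stats::aggregate(threshold_db_spl ~ animal_id + genotype + ear,
                            data = d, FUN = mean)
    agg$window <- wname
    agg$n_sessions <- stats::aggregate(
      threshold_db_spl ~ animal_id + genotype + ear, data = d,
      FUN = length)$threshold_db_spl
    rows[[wname]] <- agg
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(0), genotype = character(0),
               ear = character(0), threshold_db_spl = numeric(0),
               window = character(0), n_sessions = integer(0))
  key <- paste(out$animal_id, out$ear)
  out$longitudinal <- key %in% key[duplicated(key)]
  rownames(out) <- NULL
  attr(out, "n_sentinel_excluded") <- n_sent
  out
}

#' Ear- and animal-level impairment prevalence
#'
#' @param status a [classify_hearing()] result.
#' @return Data frame with one row per genotype x unit (`ear`, `animal`):
#'   impaired count, measured count, and `percent = 100 x impaired /
#'   measured`.
#' @export
summarize_prevalence <- function(status) {
  stopifnot(inherits(status, "hearing_status"))
  if (nrow(status$ears) == 0)
    abort2("empty cohort", "audiogain_bad_audiogram")
  rows <- list()
  for (gt in unique(status$ears$genotype)) {
    e <- status$ears[status$ears$genotype == gt, ]
    a <- status$animals[status$animals$genotype == gt, ]
    rows[[paste0(gt, "_ear")]] <- data.frame(
      genotype = gt, unit = "ear", impaired = sum(e$impaired),
      measured = nrow(e), percent = 100 * sum(e$impaired) / nrow(e),
      stringsAsFactors = FALSE)
    rows[[paste0(gt, "_animal")]] <- data.frame(
      genotype = gt, unit = "animal", impaired = sum(a$hi),
      measured = nrow(a), percent = 100 * sum(a$hi) / nrow(a),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
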