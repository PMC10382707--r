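# Sweep-set preprocessing and ABR/AEP feature extraction.
#
# ABR sweeps are bandpass filtered (100-3000 Hz Butterworth, zero-phase by
# default) before trial averaging; AEP sweeps are analyzed as recorded.
# Wave I amplitude is baseline(onset)-to-first-peak; AEP components are the
# window extrema P1 [15,30] ms (max), N1 [25,60] ms (min), P2 [60,110] ms
# (max), with complex amplitudes P1-N1 and P2-N1. Central auditory gain is
# the AEP complex amplitude divided by ABR wave I amplitude.

new_waveform <- function(v, fs, t_ms, meta = list()) {
  structure(list(v = as.numeric(v), fs = fs, t_ms = t_ms, meta = meta),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz, t in [%.1f, %.1f] ms\n",
              length(x$v), x$fs, min(x$t_ms), max(x$t_ms)))
  invisible(x)
}

#' Band-pass filter an ABR sweep set
#'
#' Applies the 100-3000 Hz 5th-order Butterworth filter to every trial.
#' The default mode filters forward then time-reversed (zero net phase
#' shift; the effective order doubles). AEP sweep sets are rejected: they
#' are analyzed with only their hardware filtering.
#'
#' @param sweeps a [sweepset()]; `meta$modality` must not be "AEP".
#' @param lo,hi band edges, Hz.
#' @param order designed filter order.
#' @param mode "zero_phase" (forward-backward) or "causal" (single pass).
#' @return The filtered [sweepset()].
#' @export
bandpass_abr <- function(sweeps, lo = 100, hi = 3000, order = 5L,
                         mode = c("zero_phase", "causal")) {
  stopifnot(inherits(sweeps, "sweepset"))
  mode <- match.arg(mode)
  if (identical(sweeps$meta$modality, "AEP"))
    abort2("AEP sweeps must not be software-filtered", "audiogain_aep_filter")
  if (sweeps$fs < 6500)
    abort2("fs too low for a 3 kHz band edge (need >= 6.5 kHz)",
           "audiogain_bad_fs")
  sos <- butter_bandpass_sos(order, lo, hi, sweeps$fs)
  x <- t(sweeps$voltages)                     # samples x trials
  y <- if (mode == "zero_phase") sosfiltfilt(sos, x)
       else sosfilt_causal(sos, x)
  out <- sweeps
  out$voltages <- t(y)
  out$meta$filtered <- mode
  out
}

#' Average trials of a sweep set
#'
#' @param sweeps a [sweepset()] with at least one trial.
#' @return A `waveform` (pointwise mean, time axis re-referenced so stimulus
#'   onset is 0 ms).
#' @export
average_trials <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweepset"))
  if (nrow(sweeps$voltages) < 1)
    abort2("empty sweep set", "audiogain_empty_sweepset")
  new_waveform(colMeans(sweeps$voltages), sweeps$fs, sweep_time_ms(sweeps),
               meta = sweeps$meta)
}

# Prestimulus noise SD of a waveform (0 when there is no prestim segment).
prestim_sd <- function(w) {
  pre <- w$v[w$t_ms < 0]
  if (length(pre) < 2) 0 else stats::sd(pre)
}

#' Extract ABR wave I
#'
#' Wave I amplitude is the difference between the signal at the moment of
#' sound onset (t = 0) and the first qualifying peak: the earliest local
#' maximum inside `search_ms` rising at least `prominence_mult` prestimulus
#' noise SDs above baseline. If no peak qualifies the feature is flagged
#' absent (distinct from amplitude 0).
#'
#' @param w trial-averaged `waveform` covering at least `[0, 10]` ms.
#' @param search_ms first-peak search window, ms.
#' @param prominence_mult prominence floor as a multiple of the prestimulus
#'   noise SD.
#' @param rel_height additional floor as a fraction of the window's maximum
#'   rise above baseline; rejects small filter-ringing ripples riding ahead
#'   of a much larger wave I (set 0 to disable).
#' @param baseline "onset" (single sample at t = 0, the default) or
#'   "prestim_mean".
#' @return List of class `abr_features`: `wave1_amplitude_uv`,
#'   `wave1_latency_ms`, `absent`, `baseline_uv`.
#' @export
extract_abr_wave1 <- function(w, search_ms = c(0.5, 3),
                              prominence_mult = 2, rel_height = 0.5,
                              baseline = c("onset", "prestim_mean")) {
  stopifnot(inherits(w, "waveform"))
  baseline <- match.arg(baseline)
  if (max(w$t_ms) < 10)
    abort2("waveform must cover [0, >=10] ms post onset",
           "audiogain_short_record")
  base <- if (baseline == "onset") {
    w$v[which.min(abs(w$t_ms))]
  } else mean(w$v[w$t_ms < 0])
  floor_uv <- prominence_mult * prestim_sd(w)
  n <- length(w$v)
  i <- 2:(n - 1)
  is_max <- w$v[i] > w$v[i - 1] & w$v[i] >= w$v[i + 1]
  cand <- i[is_max & w$t_ms[i] >= search_ms[1] & w$t_ms[i] <= search_ms[2]]
  in_win <- w$t_ms >= search_ms[1] & w$t_ms <= search_ms[2]
  floor_rel <- rel_height * max(max(w$v[in_win]) - base, 0)
  cand <- cand[w$v[cand] - base >= max(floor_uv, floor_rel)]
  if (length(cand) == 0) {
    return(structure(list(wave1_amplitude_uv = NA_real_,
                          wave1_latency_ms = NA_real_,
                          absent = TRUE, baseline_uv = base),
                     class = "abr_features"))
  }
  k <- cand[1]                              # earliest qualifying peak wins
  structure(list(wave1_amplitude_uv = w$v[k] - base,
                 wave1_latency_ms = w$t_ms[k],
                 absent = FALSE, baseline_uv = base),
            class = "abr_features")
}

#' Extract AEP P1/N1/P2 components
#'
#' P1 is the maximum on `[15, 30]` ms, N1 the minimum on `[25, 60]` ms, P2
#' the maximum on `[60, 110]` ms (window edges inclusive; ties broken by the
#' earliest sample). Complex amplitudes are `P1 - N1` and `P2 - N1`.
#'
#' @param w trial-averaged `waveform` covering at least `[0, 110]` ms.
#' @return List of class `aep_features` with latencies (ms) and amplitudes
#'   (uV).
#' @export
extract_aep_components <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (max(w$t_ms) < 110)
    abort2("waveform must cover [0, >=110] ms post onset",
           "audiogain_short_record")
  pick <- function(win, fun) {
    idx <- which(w$t_ms >= win[1] & w$t_ms <= win[2])
    k <- idx[fun(w$v[idx])]                 # which.max/min take the earliest
    c(v = w$v[k], t = w$t_ms[k])
  }
  p1 <- pick(c(15, 30), which.max)
  n1 <- pick(c(25, 60), which.min)
  p2 <- pick(c(60, 110), which.max)
  structure(list(p1_latency_ms = p1["t"], n1_latency_ms = n1["t"],
                 p2_latency_ms = p2["t"],
                 p1_uv = unname(p1["v"]), n1_uv = unname(n1["v"]),
                 p2_uv = unname(p2["v"]),
                 p1n1_amplitude_uv = unname(p1["v"] - n1["v"]),
                 n1p2_amplitude_uv = unname(p2["v"] - n1["v"])),
            class = "aep_features")
}

#' Central auditory gain ratios
#'
#' `p1n1_gain = p1n1_amplitude / wave1_amplitude` and likewise for N1-P2,
#' from an ABR/AEP pair recorded for the same stimulated ear at the same
#' level. Undefined when wave I is absent or non-positive.
#'
#' @param abr an `abr_features` object.
#' @param aep an `aep_features` object.
#' @param on_invalid "error" raises a classed error; "na" returns NA gains
#'   with an `exclusion_reason` (for pipeline accounting).
#' @return List of class `gain_measures`.
#' @export
compute_gain <- function(abr, aep, on_invalid = c("error", "na")) {
  stopifnot(inherits(abr, "abr_features"), inherits(aep, "aep_features"))
  on_invalid <- match.arg(on_invalid)
  reason <- if (abr$absent) "wave I absent"
            else if (abr$wave1_amplitude_uv <= 0) "wave I amplitude <= 0"
            else NA_character_
  if (!is.na(reason)) {
    if (on_invalid == "error")
      abort2(paste("gain undefined:", reason), "audiogain_undefined_gain")
    return(structure(list(p1n1_gain = NA_real_, n1p2_gain = NA_real_,
                          exclusion_reason = reason),
                     class = "gain_measures"))
  }
  structure(list(
    p1n1_gain = aep$p1n1_amplitude_uv / abr$wave1_amplitude_uv,
    n1p2_gain = aep$n1p2_amplitude_uv / abr$wave1_amplitude_uv,
    exclusion_reason = NA_character_), class = "gain_measures")
}
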