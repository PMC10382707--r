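# Synthetic evoked-potential sweep sets.

#' Construct a sweep set
#'
#' @param voltages trials x samples matrix, uV.
#' @param fs sampling rate, samples/s.
#' @param t0_index 1-based sample index of stimulus onset (t = 0).
#' @param meta named list of recording metadata (modality, level_db_spl,
#'   ear, animal_id, age_weeks, stimulus, ...).
#' @return Object of class `sweepset`.
#' @export
sweepset <- function(voltages, fs, t0_index, meta = list()) {
  voltages <- as.matrix(voltages)
  if (fs <= 0) abort2("fs must be positive", "audiogain_bad_sweepset")
  if (t0_index < 1 || t0_index > ncol(voltages))
    abort2("t0_index outside record", "audiogain_bad_sweepset")
  structure(list(voltages = voltages, fs = fs,
                 t0_index = as.integer(t0_index), meta = meta),
            class = "sweepset")
}

#' @export
print.sweepset <- function(x, ...) {
  cat(sprintf("sweepset: %d trials x %d samples @ %g Hz (%s, %s dB SPL)\n",
              nrow(x$voltages), ncol(x$voltages), x$fs,
              x$meta$modality %||% "?", x$meta$level_db_spl %||% "?"))
  invisible(x)
}

# Time axis in ms relative to stimulus onset.
sweep_time_ms <- function(x) {
  (seq_len(ncol(x$voltages)) - x$t0_index) / x$fs * 1000
}

waveform_time_grid <- function(params) {
  npre <- round(params$pre_ms * params$fs / 1000)
  npost <- round(params$post_ms * params$fs / 1000)
  n <- npre + npost + 1L
  list(t_ms = (seq_len(n) - (npre + 1L)) / params$fs * 1000,
       t0_index = npre + 1L, n = n)
}

# Trial noise: white, or Gaussian-kernel-smoothed and rescaled to sd, drawn
# columnwise (one column per trial/trace).
draw_noise <- function(n_samples, n_draws, sd, fs, kernel_ms) {
  if (sd == 0) return(matrix(0, n_samples, n_draws))
  if (kernel_ms <= 0)
    return(matrix(stats::rnorm(n_samples * n_draws, sd = sd),
                  n_samples, n_draws))
  k <- stats::dnorm(seq(-3 * kernel_ms, 3 * kernel_ms, by = 1000 / fs),
                    sd = kernel_ms)
  k <- k / sqrt(sum(k^2))                  # unit output variance
  pad <- length(k)
  x <- matrix(stats::rnorm((n_samples + 2 * pad) * n_draws),
              n_samples + 2 * pad, n_draws)
  y <- stats::filter(x, k, sides = 2)
  sd * matrix(y[(pad + 1):(pad + n_samples), ], n_samples, n_draws)
}

#' Deterministic evoked template
#'
#' Sum of Gaussian bumps scaled by the level-dependent amplitude
#' `growth_uv_per_db * (level - threshold + threshold_step_db) * gain` for
#' `level >= threshold`, identically zero below threshold.
#'
#' @param params a [waveform_params()].
#' @param level stimulus level, dB SPL.
#' @param threshold the ear's true threshold, dB SPL.
#' @param gain multiplicative amplitude factor (central gain for AEP).
#' @param t_ms time axis, ms re onset; defaults to the params record grid.
#' @return Numeric vector of template voltages, uV.
#' @export
evoked_template <- function(params, level, threshold, gain = 1, t_ms = NULL) {
  stopifnot(inherits(params, "waveform_params"))
  if (is.null(t_ms)) t_ms <- waveform_time_grid(params)$t_ms
  if (level < threshold) return(numeric(length(t_ms)))
  s <- params$growth_uv_per_db *
    (level - threshold + params$threshold_step_db) * gain
  v <- numeric(length(t_ms))
  for (i in seq_len(nrow(params$components))) {
    cm <- params$components$center_ms[i]
    w <- params$components$width_ms[i]
    v <- v + params$components$rel_amp[i] * exp(-0.5 * ((t_ms - cm) / w)^2)
  }
  s * v
}

#' Synthesize a sweep set for one ear, level and modality
#'
#' @param threshold_true the ear's true threshold, dB SPL.
#' @param level stimulus level in `[0, 90]` dB SPL.
#' @param modality "ABR" or "AEP".
#' @param params a [waveform_params()] of the matching modality; defaults to
#'   `waveform_params(modality)`.
#' @param gain AEP amplitude multiplier (central gain); must stay 1 for ABR.
#' @param seed integer seed for the trial noise stream.
#' @param meta extra metadata carried on the sweep set.
#' @return A [sweepset()]. Trials are independent noise realizations around
#'   the same deterministic template.
#' @export
synth_sweepset <- function(threshold_true, level,
                           modality = c("ABR", "AEP"),
                           params = NULL, gain = 1, seed = 1L,
                           meta = list()) {
  modality <- match.arg(modality)
  if (level < 0 || level > 90)
    abort2("level outside the tested 0-90 dB SPL range",
           "audiogain_bad_level")
  params <- params %||% waveform_params(modality)
  stopifnot(params$modality == modality)
  if (modality == "ABR" && gain != 1)
    abort2("central gain applies to AEP amplitudes only",
           "audiogain_bad_config")
  grid <- waveform_time_grid(params)
  tmpl <- evoked_template(params, level, threshold_true, gain, grid$t_ms)
  v <- with_seed(seed, {
    t(draw_noise(grid$n, params$n_trials, params$noise_sd, params$fs,
                 params$noise_kernel_ms %||% 0))
  })
  v <- sweep(v, 2, tmpl, `+`)
  sweepset(v, params$fs, grid$t0_index,
           meta = c(list(modality = modality, level_db_spl = level,
                         stimulus = "click", noise_sd = params$noise_sd,
                         n_trials = params$n_trials), meta))
}

#' Synthesize a trial-averaged waveform directly
#'
#' Statistically identical to averaging `params$n_trials` sweeps of
#' [synth_sweepset()] (the residual noise SD is `noise_sd / sqrt(n_trials)`),
#' at a fraction of the cost; used by the pipeline's `average_only` mode for
#' large simulations.
#'
#' @inheritParams synth_sweepset
#' @return A `waveform` object (see [average_trials()]).
#' @export
synth_avg_waveform <- function(threshold_true, level,
                               modality = c("ABR", "AEP"),
                               params = NULL, gain = 1, seed = 1L,
                               meta = list()) {
  modality <- match.arg(modality)
  if (level < 0 || level > 90)
    abort2("level outside the tested 0-90 dB SPL range",
           "audiogain_bad_level")
  params <- params %||% waveform_params(modality)
  stopifnot(params$modality == modality)
  grid <- waveform_time_grid(params)
  tmpl <- evoked_template(params, level, threshold_true, gain, grid$t_ms)
  sd_avg <- params$noise_sd / sqrt(params$n_trials)
  v <- tmpl + with_seed(seed, {
    drop(draw_noise(grid$n, 1L, sd_avg, params$fs,
                    params$noise_kernel_ms %||% 0))
  })
  new_waveform(v, params$fs, grid$t_ms,
               meta = c(list(modality = modality, level_db_spl = level,
                             stimulus = "click", noise_sd = params$noise_sd,
                             n_trials = params$n_trials), meta))
}
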