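# Configuration objects for the synthetic-cohort generator.

#' Cohort generator configuration
#'
#' Describes the generative structure the analysis assumes: a two-genotype
#' cohort in which mutant ears are impaired independently with probability
#' `p_ear_impaired_mut` (with a left-ear bias among monaural cases),
#' unimpaired ear thresholds are normal around `wt_threshold_mean`, impaired
#' ears add a positive truncated-normal shift, cortical AEP amplitudes of
#' impaired animals are scaled by `gain_factor_hi`, and auditory-cortex PV+
#' density declines linearly with the animal's hearing loss in dB HL.
#'
#' Defaults are calibrated once to the study structure being emulated:
#' WT ear thresholds N(30, 4.35) dB SPL, so that mean + 2.5 SD = 40.88 dB SPL;
#' impaired shift N(30, 10) truncated at 0; 46% per-ear impairment
#' probability; left bias 0.7 among monaural cases; AEP gain factor 2 in
#' hearing-impaired animals; PV+ density 150 cells/mm^2 in wild types with a
#' slope of -2 cells/mm^2 per dB HL in mutants; NeuN+ density 2500 cells/mm^2
#' in all groups.
#'
#' @param n_wt,n_mut number of wild-type and mutant animals.
#' @param p_ear_impaired_mut per-ear impairment probability in mutants.
#' @param left_bias probability that a monaurally impaired mutant's affected
#'   ear is the left one.
#' @param wt_threshold_mean,wt_threshold_sd dB SPL; unimpaired-ear true
#'   threshold distribution (truncated at `instrument_floor_db`).
#' @param impaired_shift_mean,impaired_shift_sd dB SPL; positive threshold
#'   shift of impaired ears.
#' @param impaired_shift_floor dB SPL; lower truncation of the impaired
#'   shift. The default (15) keeps every flagged-impaired ear above the
#'   wild-type-referenced cutoff, matching the emulated study in which
#'   impairment is *defined* by a supra-cutoff threshold (set 0 for an
#'   unconstrained positive shift).
#' @param gain_factor_hi dimensionless multiplier applied to AEP component
#'   amplitudes of impaired-animal hemispheres.
#' @param pv_density_wt cells/mm^2, wild-type PV+ density.
#' @param pv_density_slope_hl cells/mm^2 per dB HL (negative), applied to
#'   mutant animals' auditory-cortex PV+ density.
#' @param neun_density cells/mm^2, genotype-independent NeuN+ density.
#' @param ages_weeks measurement ages for the longitudinal audiograms.
#' @param seed integer master seed; identical seeds give bit-identical
#'   cohorts.
#' @param instrument_floor_db,instrument_max_db tested stimulus level range,
#'   dB SPL.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_wt = 25L, n_mut = 25L,
                          p_ear_impaired_mut = 0.46,
                          left_bias = 0.7,
                          wt_threshold_mean = 30, wt_threshold_sd = 4.35,
                          impaired_shift_mean = 30, impaired_shift_sd = 10,
                          impaired_shift_floor = 15,
                          gain_factor_hi = 2,
                          pv_density_wt = 150, pv_density_slope_hl = -2,
                          neun_density = 2500,
                          ages_weeks = c(4, 5, 8, 10),
                          seed = 1L,
                          instrument_floor_db = 0,
                          instrument_max_db = 90) {
  if (n_wt < 1 || n_mut < 1)
    abort2("cohort sizes must be positive", "audiogain_bad_config")
  for (p in c(p_ear_impaired_mut, left_bias))
    if (is.na(p) || p < 0 || p > 1)
      abort2("probabilities must lie in [0, 1]", "audiogain_bad_config")
  if (wt_threshold_sd < 0 || impaired_shift_sd < 0)
    abort2("standard deviations must be >= 0", "audiogain_bad_config")
  if (impaired_shift_floor < 0)
    abort2("impaired_shift_floor must be >= 0", "audiogain_bad_config")
  if (pv_density_wt < 0 || neun_density < 0)
    abort2("densities must be >= 0", "audiogain_bad_config")
  if (instrument_max_db <= instrument_floor_db)
    abort2("instrument_max_db must exceed instrument_floor_db",
           "audiogain_bad_config")
  structure(list(
    n_wt = as.integer(n_wt), n_mut = as.integer(n_mut),
    p_ear_impaired_mut = p_ear_impaired_mut, left_bias = left_bias,
    wt_threshold_mean = wt_threshold_mean, wt_threshold_sd = wt_threshold_sd,
    impaired_shift_mean = impaired_shift_mean,
    impaired_shift_sd = impaired_shift_sd,
    impaired_shift_floor = impaired_shift_floor,
    gain_factor_hi = gain_factor_hi,
    pv_density_wt = pv_density_wt,
    pv_density_slope_hl = pv_density_slope_hl,
    neun_density = neun_density,
    ages_weeks = ages_weeks,
    seed = as.integer(seed),
    instrument_floor_db = instrument_floor_db,
    instrument_max_db = instrument_max_db
  ), class = "cohort_config")
}

# Validates component bumps against the extraction windows they must land in.
validate_components <- function(comp, modality) {
  stopifnot(is.data.frame(comp),
            all(c("center_ms", "width_ms", "rel_amp") %in% names(comp)))
  if (any(comp$width_ms <= 0))
    abort2("component widths must be > 0", "audiogain_bad_config")
  if (modality == "AEP") {
    win <- list(c(15, 30), c(25, 60), c(60, 110))
    if (nrow(comp) != 3)
      abort2("AEP model needs exactly P1, N1, P2 components",
             "audiogain_bad_config")
    for (i in 1:3) {
      if (comp$center_ms[i] < win[[i]][1] || comp$center_ms[i] > win[[i]][2])
        abort2(sprintf("AEP component %d center outside its window", i),
               "audiogain_bad_config")
    }
    if (comp$rel_amp[2] >= 0)
      abort2("N1 must be a negative deflection", "audiogain_bad_config")
  }
  invisible(comp)
}

#' Waveform model parameters
#'
#' Evoked responses are modelled as sums of Gaussian bumps whose common
#' amplitude scale grows linearly with stimulus level above the ear's true
#' threshold: `scale = growth_uv_per_db * (level - threshold +
#' threshold_step_db)` for `level >= threshold`, and exactly 0 below
#' threshold. The `threshold_step_db` offset (default one 10-dB level step)
#' makes the response non-zero *at* threshold, i.e. the true threshold is the
#' lowest level with a detectable response. Trials are independent Gaussian
#' noise realizations around the deterministic template.
#'
#' @param modality "ABR" (waves I-V plus troughs, short latency) or "AEP"
#'   (P1/N1/P2, cortical latencies).
#' @param fs sampling rate, samples/s. The ABR default (25 kHz) keeps the
#'   100-3000 Hz analysis band well below Nyquist.
#' @param pre_ms,post_ms record extent around stimulus onset, ms.
#' @param components data.frame with `center_ms`, `width_ms`, `rel_amp`
#'   (dimensionless, relative to wave I / P1 = 1).
#' @param growth_uv_per_db amplitude growth slope above threshold, uV/dB.
#' @param threshold_step_db level offset at threshold, dB (see above).
#' @param noise_sd single-trial additive noise SD, uV.
#' @param noise_kernel_ms temporal smoothness of the trial noise: SD (ms) of
#'   the Gaussian kernel applied to white noise before rescaling to
#'   `noise_sd`. 0 gives white noise. The ABR default is 0 (broadband noise,
#'   subsequently band-pass filtered by the analysis); the AEP default is 8
#'   ms, emulating the low-frequency-dominated residual of averaged cortical
#'   EEG — with residual noise smooth at the analysis-window scale, the
#'   window-extremum component amplitudes are unbiased, as in real
#'   recordings.
#' @param n_trials trials per sweep set.
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(modality = c("ABR", "AEP"),
                            fs = NULL, pre_ms = NULL, post_ms = NULL,
                            components = NULL,
                            growth_uv_per_db = NULL,
                            threshold_step_db = 10,
                            noise_sd = NULL, noise_kernel_ms = NULL,
                            n_trials = 100L) {
  modality <- match.arg(modality)
  if (modality == "ABR") {
    fs <- fs %||% 25000
    pre_ms <- pre_ms %||% 5
    post_ms <- post_ms %||% 15
    components <- components %||% data.frame(
      center_ms = c(1.5, 2.1, 2.8, 3.5, 4.2, 5.0, 6.0),
      width_ms  = c(0.25, 0.25, 0.30, 0.30, 0.35, 0.40, 0.50),
      rel_amp   = c(1.00, -0.60, 0.85, -0.50, 0.65, -0.35, 0.40))
    growth_uv_per_db <- growth_uv_per_db %||% 0.1
    noise_sd <- noise_sd %||% 2.5
    noise_kernel_ms <- noise_kernel_ms %||% 0
  } else {
    fs <- fs %||% 8000
    pre_ms <- pre_ms %||% 20
    post_ms <- post_ms %||% 140
    components <- components %||% data.frame(
      center_ms = c(22, 42, 85),
      width_ms  = c(4, 8, 12),
      rel_amp   = c(1.0, -1.5, 0.75))
    growth_uv_per_db <- growth_uv_per_db %||% 0.25
    noise_sd <- noise_sd %||% 15
    noise_kernel_ms <- noise_kernel_ms %||% 8
  }
  if (fs <= 2 * 3000)
    abort2("fs must exceed twice the 3 kHz analysis band",
           "audiogain_bad_config")
  if (n_trials < 1)
    abort2("n_trials must be >= 1", "audiogain_bad_config")
  if (noise_sd < 0 || noise_kernel_ms < 0)
    abort2("noise_sd and noise_kernel_ms must be >= 0",
           "audiogain_bad_config")
  validate_components(components, modality)
  structure(list(modality = modality, fs = fs, pre_ms = pre_ms,
                 post_ms = post_ms, components = components,
                 growth_uv_per_db = growth_uv_per_db,
                 threshold_step_db = threshold_step_db,
                 noise_sd = noise_sd, noise_kernel_ms = noise_kernel_ms,
                 n_trials = as.integer(n_trials)),
            class = "waveform_params")
}
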