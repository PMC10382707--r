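# Trial averaging and ABR/AEP feature extraction.

test_that("average_trials: identity, symmetry, and CLT scaling", {
  v <- sin(seq(0, 4 * pi, length.out = 400))
  ss1 <- sweepset(matrix(v, 1), fs = 20000, t0_index = 100)
  expect_equal(average_trials(ss1)$v, v)

  ss2 <- sweepset(rbind(v, -v), fs = 20000, t0_index = 100)
  expect_equal(average_trials(ss2)$v, numeric(400))

  expect_error(average_trials(sweepset(matrix(numeric(0), 0, 10), 20000, 5)),
               class = "audiogain_empty_sweepset")

  # 100 noise trials with SD sigma: residual SD ~ sigma/10
  sigma <- 3
  set.seed(8)
  ss3 <- sweepset(matrix(rnorm(100 * 2000, sd = sigma), 100), 20000, 100)
  res_sd <- sd(average_trials(ss3)$v)
  se <- (sigma / 10) / sqrt(2 * (2000 - 1))
  expect_lt(abs(res_sd - sigma / 10), 3 * se)
})

test_that("wave I extraction: construction, tie-break, absence", {
  t <- time_axis()
  w <- make_waveform(gauss_bump(t, 1.5, 0.25, 5))
  f <- extract_abr_wave1(w)
  expect_false(f$absent)
  expect_equal(f$wave1_amplitude_uv, 5, tolerance = 1e-6)
  expect_equal(f$wave1_latency_ms, 1.5, tolerance = 1e-9)

  # two prominent bumps: the earliest qualifying peak wins
  w2 <- make_waveform(gauss_bump(t, 1.5, 0.15, 4) +
                        gauss_bump(t, 2.5, 0.15, 6))
  expect_equal(extract_abr_wave1(w2)$wave1_latency_ms, 1.5,
               tolerance = 1e-9)

  # flat trace: no qualifying peak -> flagged absent, not amplitude 0
  f3 <- extract_abr_wave1(make_waveform(numeric(length(t))))
  expect_true(f3$absent)
  expect_true(is.na(f3$wave1_amplitude_uv))

  expect_error(extract_abr_wave1(make_waveform(numeric(100))),
               class = "audiogain_short_record")
})

test_that("wave I equals a brute-force scan over window maxima", {
  t <- time_axis()
  set.seed(11)
  for (rep in 1:50) {
    n_b <- sample(2:5, 1)
    v <- rowSums(vapply(seq_len(n_b), function(b)
      gauss_bump(t, runif(1, 0.6, 6), runif(1, 0.1, 0.5),
                 runif(1, 0.5, 6)), numeric(length(t))))
    v <- v + 0.01 * sin(t)                  # break exact plateaus
    w <- make_waveform(v)
    f <- extract_abr_wave1(w, prominence_mult = 0, rel_height = 0)
    # oracle: scan all interior samples for local maxima in [0.5, 3] ms
    base <- v[which.min(abs(t))]
    best <- NA
    for (i in 2:(length(v) - 1)) {
      if (t[i] >= 0.5 && t[i] <= 3 && v[i] > v[i - 1] && v[i] >= v[i + 1] &&
          v[i] - base >= 0) { best <- i; break }
    }
    if (is.na(best)) {
      expect_true(f$absent)
    } else {
      expect_equal(f$wave1_amplitude_uv, v[best] - base, tolerance = 1e-12)
      expect_equal(f$wave1_latency_ms, t[best], tolerance = 1e-12)
    }
  }
})

test_that("AEP components: construction, degenerate, exhaustive oracle", {
  t <- time_axis(fs = 2000, pre_ms = 20, post_ms = 140)
  v <- gauss_bump(t, 20, 2, 4) + gauss_bump(t, 40, 3, -6) +
    gauss_bump(t, 80, 4, 3)
  f <- extract_aep_components(make_waveform(v, fs = 2000, pre_ms = 20))
  expect_equal(f$p1n1_amplitude_uv, 10, tolerance = 1e-3)
  expect_equal(f$n1p2_amplitude_uv, 9, tolerance = 1e-3)
  expect_equal(unname(f$p1_latency_ms), 20, tolerance = 1e-9)
  expect_equal(unname(f$n1_latency_ms), 40, tolerance = 1e-9)
  expect_equal(unname(f$p2_latency_ms), 80, tolerance = 1e-9)

  # constant waveform: zero amplitudes, latencies at window starts
  fc <- extract_aep_components(make_waveform(rep(2, length(t)), fs = 2000,
                                             pre_ms = 20))
  expect_equal(fc$p1n1_amplitude_uv, 0)
  expect_equal(fc$n1p2_amplitude_uv, 0)
  expect_equal(unname(fc$p1_latency_ms), 15)
  expect_equal(unname(fc$n1_latency_ms), 25)
  expect_equal(unname(fc$p2_latency_ms), 60)

  expect_error(extract_aep_components(make_waveform(numeric(100), fs = 2000,
                                                    pre_ms = 20)),
               class = "audiogain_short_record")

  # 50 random smooth waveforms vs per-sample extremum search
  set.seed(13)
  for (rep in 1:50) {
    v <- as.numeric(filter(rnorm(length(t)), rep(1 / 25, 25), sides = 2))
    v[is.na(v)] <- 0
    f <- extract_aep_components(make_waveform(v, fs = 2000, pre_ms = 20))
    oracle <- function(win, fun) {
      idx <- which(t >= win[1] & t <= win[2])
      idx[fun(v[idx])]
    }
    i1 <- oracle(c(15, 30), which.max)
    i2 <- oracle(c(25, 60), which.min)
    i3 <- oracle(c(60, 110), which.max)
    expect_equal(f$p1n1_amplitude_uv, v[i1] - v[i2], tolerance = 1e-12)
    expect_equal(f$n1p2_amplitude_uv, v[i3] - v[i2], tolerance = 1e-12)
    # latencies always inside their defining windows
    expect_true(f$p1_latency_ms >= 15 && f$p1_latency_ms <= 30)
    expect_true(f$n1_latency_ms >= 25 && f$n1_latency_ms <= 60)
    expect_true(f$p2_latency_ms >= 60 && f$p2_latency_ms <= 110)
  }
})

test_that("zero-noise features equal generator template features", {
  # AEP (unfiltered): extraction reproduces the analytic template exactly
  params <- waveform_params("AEP", noise_sd = 0, n_trials = 2L)
  w <- average_trials(synth_sweepset(30, 80, "AEP", params, seed = 4))
  f <- extract_aep_components(w)
  tmpl <- evoked_template(params, 80, 30, t_ms = w$t_ms)
  win <- function(lo, hi, fun) {
    idx <- which(w$t_ms >= lo & w$t_ms <= hi); idx[fun(tmpl[idx])]
  }
  expect_equal(f$p1n1_amplitude_uv,
               tmpl[win(15, 30, which.max)] - tmpl[win(25, 60, which.min)],
               tolerance = 1e-6)

  # ABR: unfiltered extraction matches the template; the two-pass filter
  # keeps the amplitude within the pass-band attenuation of the oracle
  pa <- waveform_params("ABR", noise_sd = 0, n_trials = 2L)
  ss <- synth_sweepset(30, 80, "ABR", pa, seed = 4)
  f_raw <- extract_abr_wave1(average_trials(ss))
  tmpl_a <- evoked_template(pa, 80, 30)
  expect_equal(f_raw$wave1_amplitude_uv, max(tmpl_a[1:which.max(tmpl_a)]),
               tolerance = 1e-6)
  f_flt <- extract_abr_wave1(average_trials(bandpass_abr(ss)))
  ratio <- f_flt$wave1_amplitude_uv / f_raw$wave1_amplitude_uv
  expect_gt(ratio, 0.80)
  expect_lt(ratio, 1.02)
})

test_that("gain: arithmetic, guard, and exact ground-truth recovery", {
  abr <- structure(list(wave1_amplitude_uv = 1, wave1_latency_ms = 1.5,
                        absent = FALSE, baseline_uv = 0),
                   class = "abr_features")
  aep <- structure(list(p1n1_amplitude_uv = 2, n1p2_amplitude_uv = 3),
                   class = "aep_features")
  g <- compute_gain(abr, aep)
  expect_equal(g$p1n1_gain, 2)
  expect_equal(g$n1p2_gain, 3)

  abr0 <- abr; abr0$wave1_amplitude_uv <- 0
  expect_error(compute_gain(abr0, aep), class = "audiogain_undefined_gain")
  gna <- compute_gain(abr0, aep, on_invalid = "na")
  expect_true(is.na(gna$p1n1_gain))
  expect_match(gna$exclusion_reason, "<= 0")

  # zero-noise HI (gain 2, threshold 60) vs NHI (gain 1, threshold 30):
  # the gain ratio equals gain_factor_hi exactly, independent of thresholds
  pa <- waveform_params("ABR", noise_sd = 0, n_trials = 1L)
  pe <- waveform_params("AEP", noise_sd = 0, n_trials = 1L)
  gain_of <- function(thr, g) {
    wa <- average_trials(bandpass_abr(synth_sweepset(thr, 80, "ABR", pa,
                                                     seed = 1)))
    we <- average_trials(synth_sweepset(thr, 80, "AEP", pe, gain = g,
                                        seed = 1))
    compute_gain(extract_abr_wave1(wa), extract_aep_components(we))$p1n1_gain
  }
  expect_equal(gain_of(60, 2) / gain_of(30, 1), 2, tolerance = 1e-9)
})
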