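# Threshold detection, classification, dB HL, age windows, prevalence.

test_that("zero-noise threshold detection is exact; pure noise is sentinel", {
  pa0 <- waveform_params("ABR", noise_sd = 0)
  ser <- synth_ear_series(40, seq(0, 90, 10), pa0, seed = 1)
  det <- detect_threshold(ser)
  expect_false(det$above_max)
  expect_equal(det$threshold_db_spl, 40)

  # no evoked component at any tested level -> "above max tested"
  pa <- waveform_params("ABR")
  ser_noise <- synth_ear_series(1000, seq(0, 90, 10), pa, seed = 2)
  det_n <- detect_threshold(ser_noise)
  expect_true(det_n$above_max)
  expect_true(is.na(det_n$threshold_db_spl))
})

test_that("series contracts: sorting, size, baseline", {
  pa0 <- waveform_params("ABR", noise_sd = 0)
  ser <- synth_ear_series(40, seq(0, 90, 10), pa0, seed = 1)
  bad <- ser; bad$levels <- rev(bad$levels)
  expect_error(detect_threshold(bad), class = "audiogain_bad_series")
  short <- abr_series(ser$levels[1:2], ser$waveforms[1:2])
  expect_error(detect_threshold(short), class = "audiogain_bad_series")
  nopre <- ser
  nopre$waveforms <- lapply(nopre$waveforms, function(w) {
    keep <- w$t_ms >= 0
    audiogain:::new_waveform(w$v[keep], w$fs, w$t_ms[keep])
  })
  expect_error(detect_threshold(nopre), class = "audiogain_bad_series")
})

test_that("detected threshold is non-decreasing in k", {
  ser <- synth_ear_series(40, seq(0, 90, 10),
                          waveform_params("ABR"), seed = 9)
  thr <- vapply(c(3, 5, 6.5, 9, 15, 40), function(k) {
    d <- detect_threshold(ser, k = k)
    if (d$above_max) Inf else d$threshold_db_spl
  }, 0)
  expect_true(all(diff(thr) >= 0))
})

test_that("classification reproduces the printed cutoff rule", {
  wt <- wt_pair_for_cutoff(40.88, s = 4.3)
  aud <- rbind(
    aud_table("WT01", "WT", c("left", "right"), wt),
    aud_table("MUT01", "MUT", c("left", "right"), c(40, 45)))
  st <- classify_hearing(aud)
  expect_equal(st$cutoff_db, 40.88, tolerance = 1e-9)
  expect_false(st$ears$impaired[st$ears$threshold_db_spl == 40])
  expect_true(st$ears$impaired[st$ears$threshold_db_spl == 45])
  # quadrant rule: ears (40, 45) -> monaural HI
  expect_equal(st$animals$category[st$animals$animal_id == "MUT01"],
               "monaural HI")
})

test_that("quadrant rule and degenerate WT SD", {
  wt <- wt_pair_for_cutoff(40.88)
  aud <- rbind(
    aud_table("WT01", "WT", c("left", "right"), wt),
    aud_table("M1", "MUT", c("left", "right"), c(30, 70)),
    aud_table("M2", "MUT", c("left", "right"), c(70, 75)),
    aud_table("M3", "MUT", c("left", "right"), c(30, 35)))
  st <- classify_hearing(aud)
  cats <- setNames(st$animals$category, st$animals$animal_id)
  expect_equal(unname(cats[c("M1", "M2", "M3")]),
               c("monaural HI", "binaural HI", "normal"))

  # all WT ears equal: SD 0, cutoff = that value, strictly higher impaired
  aud2 <- rbind(aud_table("WT01", "WT", c("left", "right"), c(30, 30)),
                aud_table("M1", "MUT", c("left", "right"), c(30, 30.1)))
  st2 <- classify_hearing(aud2)
  expect_equal(st2$cutoff_db, 30)
  expect_equal(sum(st2$ears$impaired), 1L)

  # sentinel ears count as impaired
  aud3 <- rbind(aud_table("WT01", "WT", c("left", "right"), wt),
                aud_table("M1", "MUT", c("left", "right"),
                          c(NA, 35), above_max = c(TRUE, FALSE)))
  st3 <- classify_hearing(aud3)
  expect_equal(st3$animals$category[st3$animals$animal_id == "M1"],
               "monaural HI")

  # single measured ear: classified on it, flagged partial
  aud4 <- rbind(aud_table("WT01", "WT", c("left", "right"), wt),
                aud_table("WT02", "WT", "left", 35))
  st4 <- classify_hearing(aud4)
  expect_true(st4$animals$partial[st4$animals$animal_id == "WT02"])
  expect_equal(st4$animals$category[st4$animals$animal_id == "WT02"],
               "normal")
})

test_that("classification is invariant to row order and monotone", {
  set.seed(5)
  aud <- do.call(rbind, lapply(1:12, function(i) {
    gt <- if (i <= 6) "WT" else "MUT"
    aud_table(sprintf("%s%02d", gt, i), gt, c("left", "right"),
              round(runif(2, 25, 70)))
  }))
  st1 <- classify_hearing(aud)
  perm <- sample(nrow(aud))
  st2 <- classify_hearing(aud[perm, ])
  expect_equal(st1$cutoff_db, st2$cutoff_db)
  m <- merge(st1$animals, st2$animals, by = "animal_id")
  expect_equal(m$category.x, m$category.y)

  # raising an impaired ear never makes it unimpaired (fixed WT cutoff)
  base <- aud
  i_mut <- which(base$genotype == "MUT")[1]
  for (bump in c(0, 5, 10, 20, 40)) {
    aud_b <- base
    aud_b$threshold_db_spl[i_mut] <- base$threshold_db_spl[i_mut] + bump
    st_b <- classify_hearing(aud_b)
    if (bump == 0) was <- st_b$ears$impaired[i_mut]
    if (was) expect_true(st_b$ears$impaired[i_mut])
  }
})

test_that("dB HL arithmetic and brute-force recomputation", {
  # WT animals with per-animal max thresholds averaging 32
  aud <- rbind(aud_table("WT01", "WT", c("left", "right"), c(28, 30)),
               aud_table("WT02", "WT", c("left", "right"), c(30, 34)),
               aud_table("M1", "MUT", c("left", "right"), c(30, 40)))
  hl <- compute_hl_db(aud)
  expect_equal(hl$hl_db[hl$animal_id == "M1"], 40 - 32)   # max - WT mean
  expect_equal(hl$hl_db[hl$animal_id == "WT02"], 34 - 32)

  set.seed(17)
  aud_r <- do.call(rbind, lapply(1:15, function(i) {
    gt <- if (i <= 7) "WT" else "MUT"
    aud_table(sprintf("A%02d", i), gt, c("left", "right"),
              runif(2, 20, 80))
  }))
  hl_r <- compute_hl_db(aud_r)
  # independent re-implementation
  mx <- tapply(aud_r$threshold_db_spl, aud_r$animal_id, max)
  gt <- tapply(aud_r$genotype, aud_r$animal_id, `[`, 1)
  ref <- mean(mx[gt == "WT"])
  expect_equal(hl_r$hl_db, as.numeric(mx[hl_r$animal_id] - ref),
               tolerance = 1e-12)
})

test_that("age-window summaries average sessions correctly", {
  ses <- rbind(
    aud_table("M1", "MUT", "left", 30), aud_table("M1", "MUT", "left", 40),
    aud_table("M2", "MUT", "left", 55))
  ses$age_weeks <- c(4, 5, 8)
  out <- summarize_by_age_window(ses)
  young <- out[out$window == "young", ]
  expect_equal(young$threshold_db_spl[young$animal_id == "M1"], 35)
  expect_false("M2" %in% young$animal_id)    # only measured at 8 weeks
  adult <- out[out$window == "adult", ]
  expect_equal(adult$threshold_db_spl[adult$animal_id == "M2"], 55)

  # sentinels excluded and counted; window edges [3,6) and [6,14]
  ses2 <- rbind(aud_table("M3", "MUT", "left", NA, above_max = TRUE),
                aud_table("M4", "MUT", "left", 42))
  ses2$age_weeks <- c(4, 6)
  out2 <- summarize_by_age_window(ses2)
  expect_equal(attr(out2, "n_sentinel_excluded"), 1L)
  expect_equal(out2$window[out2$animal_id == "M4"], "adult")
})

test_that("longitudinal persistence is recovered on synthetic cohorts", {
  # persistent true thresholds: paired young vs adult ear means differ by
  # less than measurement noise (one detection level step)
  cfg <- run_config(cohort_config(n_wt = 4, n_mut = 8,
                                  ages_weeks = c(4, 5, 8, 10), seed = 33))
  run <- run_full_analysis(cfg)
  aw <- run$age_windows
  wide <- merge(aw[aw$window == "young", c("animal_id", "ear",
                                           "threshold_db_spl")],
                aw[aw$window == "adult", c("animal_id", "ear",
                                           "threshold_db_spl")],
                by = c("animal_id", "ear"))
  expect_gt(nrow(wide), 10)
  expect_true(all(abs(wide$threshold_db_spl.x - wide$threshold_db_spl.y)
                  <= 10))
})

test_that("prevalence percentages and empty-cohort guard", {
  wt <- wt_pair_for_cutoff(40.88)
  aud <- rbind(aud_table("WT01", "WT", c("left", "right"), wt),
               aud_table("M1", "MUT", c("left", "right"), c(50, 60)),
               aud_table("M2", "MUT", c("left", "right"), c(30, 50)),
               aud_table("M3", "MUT", c("left", "right"), c(30, 30)))
  prev <- summarize_prevalence(classify_hearing(aud))
  mut_ear <- prev[prev$genotype == "MUT" & prev$unit == "ear", ]
  expect_equal(mut_ear$percent, 100 * 3 / 6)
  mut_an <- prev[prev$genotype == "MUT" & prev$unit == "animal", ]
  expect_equal(mut_an$percent, 100 * 2 / 3)
})
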