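# End-to-end orchestration: generation -> features -> classification ->
# histology -> statistics, with result tables mirroring the study's figures.

#' Full-analysis run configuration
#'
#' @param cohort a [cohort_config()].
#' @param abr_params,aep_params [waveform_params()] for the two modalities.
#' @param levels_db audiogram level series, dB SPL (sorted, common step).
#' @param feature_level_db click level for the ABR/AEP feature comparisons.
#' @param cutoff_sd SD multiple for the hearing-impairment cutoff.
#' @param threshold_k noise multiple for threshold detection.
#' @param n_bins laminar bins (5, 10 or 20).
#' @param strip_fraction NeuN strip area fraction.
#' @param filter_mode "zero_phase" or "causal" ABR filtering.
#' @param trial_mode "average_only" synthesizes trial-averaged traces
#'   directly (identical in distribution, much faster); "full" synthesizes
#'   and averages every trial.
#' @param markers histology markers to simulate and analyze.
#' @param areas cortical areas to simulate and analyze.
#' @param out_dir optional output directory for CSV/JSON tables.
#' @param seed master seed; defaults to the cohort seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       abr_params = waveform_params("ABR"),
                       aep_params = waveform_params("AEP"),
                       levels_db = seq(0, 90, by = 10),
                       feature_level_db = 80,
                       cutoff_sd = 2.5,
                       threshold_k = 6.5,
                       n_bins = 5L,
                       strip_fraction = 0.05,
                       filter_mode = c("zero_phase", "causal"),
                       trial_mode = c("average_only", "full"),
                       markers = c("PV", "NeuN"),
                       areas = c("A1", "M2"),
                       out_dir = NULL,
                       seed = NULL) {
  structure(list(cohort = cohort, abr_params = abr_params,
                 aep_params = aep_params, levels_db = levels_db,
                 feature_level_db = feature_level_db, cutoff_sd = cutoff_sd,
                 threshold_k = threshold_k, n_bins = as.integer(n_bins),
                 strip_fraction = strip_fraction,
                 filter_mode = match.arg(filter_mode),
                 trial_mode = match.arg(trial_mode),
                 markers = markers, areas = areas, out_dir = out_dir,
                 seed = as.integer(seed %||% cohort$seed)),
            class = "run_config")
}

#' Synthesize and preprocess one ear's ABR level series
#'
#' Generates the trial-averaged ABR trace at every level and applies the
#' 100-3000 Hz filter (in `average_only` mode the average is filtered
#' directly, which equals averaging filtered trials by linearity).
#'
#' @param threshold_true the ear's true threshold, dB SPL.
#' @param levels_db level series.
#' @param abr_params ABR [waveform_params()].
#' @param seed stream seed for this series.
#' @param filter_mode,trial_mode see [run_config()].
#' @param meta metadata for the series.
#' @return An [abr_series()] of filtered averaged waveforms.
#' @export
synth_ear_series <- function(threshold_true, levels_db = seq(0, 90, 10),
                             abr_params = waveform_params("ABR"),
                             seed = 1L,
                             filter_mode = c("zero_phase", "causal"),
                             trial_mode = c("average_only", "full"),
                             meta = list()) {
  filter_mode <- match.arg(filter_mode)
  trial_mode <- match.arg(trial_mode)
  grid <- waveform_time_grid(abr_params)
  if (trial_mode == "average_only") {
    traces <- vapply(levels_db, function(lv) {
      synth_avg_waveform(threshold_true, lv, "ABR", abr_params,
                         seed = derive_seed(seed, "level", lv))$v
    }, numeric(grid$n))
    sos <- butter_bandpass_sos(5, 100, 3000, abr_params$fs)
    filt <- if (filter_mode == "zero_phase") sosfiltfilt(sos, traces)
            else sosfilt_causal(sos, traces)
    wfs <- lapply(seq_along(levels_db), function(i) {
      new_waveform(filt[, i], abr_params$fs, grid$t_ms,
                   meta = c(list(modality = "ABR",
                                 level_db_spl = levels_db[i]), meta))
    })
  } else {
    wfs <- lapply(levels_db, function(lv) {
      ss <- synth_sweepset(threshold_true, lv, "ABR", abr_params,
                           seed = derive_seed(seed, "level", lv), meta = meta)
      average_trials(bandpass_abr(ss, mode = filter_mode))
    })
  }
  abr_series(levels_db, wfs, meta)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort2(sprintf("[stage %s] %s", name, conditionMessage(e)),
           "audiogain_stage_error")
  })
}

group_label <- function(genotype, hi) {
  ifelse(genotype == "WT", "WT", ifelse(hi, "MUT-HI", "MUT-NHI"))
}

#' Run the full synthetic-cohort analysis
#'
#' Orchestrates cohort generation, per-ear threshold detection at every age,
#' age-window summaries, hearing classification, 80-dB click ABR/AEP feature
#' extraction and central-gain computation, histology (PV full-region and
#' NeuN central-strip densities, PV laminar profiles), and the statistical
#' battery. Group labels in all downstream tables derive from the
#' classification stage.
#'
#' @param config a [run_config()].
#' @return Object of class `audiogain_run`: a list of result tables (see
#'   Details) plus the config.
#' @details Components: `manifest`, `audiograms` (session level), `age_windows`,
#'   `status` (classification), `prevalence`, `features` (one row per
#'   recording), `waveform_summaries`, `feature_stats`, `densities`,
#'   `laminar`, `density_stats`, `laminar_stats`, `density_hl_correlation`,
#'   `accounting`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cc <- config$cohort
  seed <- config$seed

  manifest <- stage("generate", generate_cohort(cc))
  ears <- manifest$ears
  animals <- manifest$animals

  # --- audiometry: level series per ear x age ------------------------------
  audiograms <- stage("threshold", {
    keys <- expand.grid(ear_row = seq_len(nrow(ears)), age = cc$ages_weeks)
    lev <- config$levels_db
    nlev <- length(lev)
    if (config$trial_mode == "average_only") {
      # one batched zero-phase filter call over every ear x age x level trace
      grid <- waveform_time_grid(config$abr_params)
      traces <- matrix(0, grid$n, nrow(keys) * nlev)
      for (j in seq_len(nrow(keys))) {
        i <- keys$ear_row[j]
        sser <- derive_seed(seed, "abr", ears$animal_id[i], ears$ear[i],
                            keys$age[j])
        for (l in seq_len(nlev)) {
          traces[, (j - 1L) * nlev + l] <- synth_avg_waveform(
            ears$threshold_true_db[i], lev[l], "ABR", config$abr_params,
            seed = derive_seed(sser, "level", lev[l]))$v
        }
      }
      sos <- butter_bandpass_sos(5, 100, 3000, config$abr_params$fs)
      filt <- if (config$filter_mode == "zero_phase")
        sosfiltfilt(sos, traces) else sosfilt_causal(sos, traces)
      series_list <- lapply(seq_len(nrow(keys)), function(j) {
        wfs <- lapply(seq_len(nlev), function(l) {
          new_waveform(filt[, (j - 1L) * nlev + l], config$abr_params$fs,
                       grid$t_ms, meta = list(modality = "ABR",
                                              level_db_spl = lev[l]))
        })
        abr_series(lev, wfs)
      })
    } else {
      series_list <- lapply(seq_len(nrow(keys)), function(j) {
        i <- keys$ear_row[j]
        synth_ear_series(
          ears$threshold_true_db[i], lev, config$abr_params,
          seed = derive_seed(seed, "abr", ears$animal_id[i], ears$ear[i],
                             keys$age[j]),
          filter_mode = config$filter_mode, trial_mode = "full")
      })
    }
    rows <- lapply(seq_len(nrow(keys)), function(j) {
      i <- keys$ear_row[j]
      det <- detect_threshold(series_list[[j]], k = config$threshold_k)
      audiogram_row(
        ears$animal_id[i], ears$genotype[i], ears$ear[i],
        det$threshold_db_spl, det$above_max, "click", keys$age[j],
        animals$sex[match(ears$animal_id[i], animals$animal_id)])
    })
    do.call(rbind, rows)
  })

  age_windows <- stage("age_windows", summarize_by_age_window(audiograms))

  # classification on the latest session per ear
  latest_aud <- do.call(rbind, lapply(
    split(audiograms, paste(audiograms$animal_id, audiograms$ear)),
    function(d) d[which.max(d$age_weeks), ]))
  status <- stage("classify",
                  classify_hearing(latest_aud, cutoff_sd = config$cutoff_sd))
  prevalence <- stage("prevalence", summarize_prevalence(status))
  hi_by_animal <- stats::setNames(status$animals$hi, status$animals$animal_id)

  # --- 80-dB click features ------------------------------------------------
  feats <- stage("features", {
    rows <- list()
    abr_traces <- list(); aep_traces <- list()
    filt_batch <- NULL
    if (config$trial_mode == "average_only") {
      grid <- waveform_time_grid(config$abr_params)
      raw <- vapply(seq_len(nrow(ears)), function(i) {
        synth_avg_waveform(ears$threshold_true_db[i],
                           config$feature_level_db, "ABR",
                           config$abr_params,
                           seed = derive_seed(seed, "feat_abr",
                                              ears$animal_id[i],
                                              ears$ear[i]))$v
      }, numeric(grid$n))
      sos <- butter_bandpass_sos(5, 100, 3000, config$abr_params$fs)
      filt_batch <- if (config$filter_mode == "zero_phase")
        sosfiltfilt(sos, raw) else sosfilt_causal(sos, raw)
    }
    for (i in seq_len(nrow(ears))) {
      id <- ears$animal_id[i]
      gain_true <- animals$gain_factor_true[match(id, animals$animal_id)]
      sd_abr <- derive_seed(seed, "feat_abr", id, ears$ear[i])
      sd_aep <- derive_seed(seed, "feat_aep", id, ears$ear[i])
      if (config$trial_mode == "average_only") {
        grid <- waveform_time_grid(config$abr_params)
        wa <- new_waveform(filt_batch[, i], config$abr_params$fs, grid$t_ms,
                           meta = list(modality = "ABR",
                                       level_db_spl = config$feature_level_db))
        we <- synth_avg_waveform(ears$threshold_true_db[i],
                                 config$feature_level_db, "AEP",
                                 config$aep_params, gain = gain_true,
                                 seed = sd_aep)
      } else {
        ssa <- synth_sweepset(ears$threshold_true_db[i],
                              config$feature_level_db, "ABR",
                              config$abr_params, seed = sd_abr)
        wa <- average_trials(bandpass_abr(ssa, mode = config$filter_mode))
        we <- average_trials(synth_sweepset(
          ears$threshold_true_db[i], config$feature_level_db, "AEP",
          config$aep_params, gain = gain_true, seed = sd_aep))
      }
      fa <- extract_abr_wave1(wa)
      fe <- extract_aep_components(we)
      g <- compute_gain(fa, fe, on_invalid = "na")
      # a recording stimulated at or below the ear's detected threshold has
      # no valid wave I; exclude its gain with an accounting reason
      det <- latest_aud[latest_aud$animal_id == id &
                          latest_aud$ear == ears$ear[i], ]
      if (nrow(det) == 1 &&
          (det$above_max ||
             (!is.na(det$threshold_db_spl) &&
                det$threshold_db_spl > config$feature_level_db))) {
        g$p1n1_gain <- NA_real_
        g$n1p2_gain <- NA_real_
        g$exclusion_reason <- "no suprathreshold ABR at feature level"
      }
      rows[[i]] <- data.frame(
        animal_id = id, genotype = ears$genotype[i], ear = ears$ear[i],
        group = group_label(ears$genotype[i], hi_by_animal[[id]]),
        wave1_uv = fa$wave1_amplitude_uv,
        wave1_latency_ms = fa$wave1_latency_ms,
        wave1_absent = fa$absent,
        p1_latency_ms = fe$p1_latency_ms, n1_latency_ms = fe$n1_latency_ms,
        p2_latency_ms = fe$p2_latency_ms,
        p1n1_uv = fe$p1n1_amplitude_uv, n1p2_uv = fe$n1p2_amplitude_uv,
        p1n1_gain = g$p1n1_gain, n1p2_gain = g$n1p2_gain,
        exclusion_reason = g$exclusion_reason,
        stringsAsFactors = FALSE)
      abr_traces[[i]] <- wa$v
      aep_traces[[i]] <- we$v
    }
    list(table = do.call(rbind, rows),
         abr = do.call(rbind, abr_traces), aep = do.call(rbind, aep_traces),
         abr_t_ms = waveform_time_grid(config$abr_params)$t_ms,
         aep_t_ms = waveform_time_grid(config$aep_params)$t_ms)
  })
  features <- feats$table
  rownames(features) <- NULL

  waveform_summaries <- stage("waveform_means", {
    summarize_traces <- function(tr, t_ms) {
      do.call(rbind, lapply(unique(features$group), function(g) {
        m <- tr[features$group == g, , drop = FALSE]
        data.frame(group = g, t_ms = t_ms, mean_uv = colMeans(m),
                   sem_uv = apply(m, 2, stats::sd) / sqrt(nrow(m)),
                   n_recordings = nrow(m), stringsAsFactors = FALSE)
      }))
    }
    list(abr = summarize_traces(feats$abr, feats$abr_t_ms),
         aep = summarize_traces(feats$aep, feats$aep_t_ms))
  })

  feature_stats <- stage("feature_stats", {
    measures <- c("wave1_uv", "p1n1_uv", "n1p2_uv", "p1n1_gain", "n1p2_gain")
    out <- list()
    for (m in measures) {
      v <- features[[m]]
      ok <- !is.na(v)
      out[[m]] <- list(
        t_wt_vs_mut = t_tests(v[ok & features$genotype == "WT"],
                              v[ok & features$genotype == "MUT"]),
        anova_groups = anova_lsd(v[ok], features$group[ok]))
    }
    out
  })

  # --- histology -----------------------------------------------------------
  hemi <- manifest$hemispheres
  hemi <- hemi[hemi$area %in% config$areas, ]
  histo <- stage("histology", {
    dens <- list(); lam <- list()
    for (i in seq_len(nrow(hemi))) {
      id <- hemi$animal_id[i]
      cm <- synth_cellmap(
        pv_density = if ("PV" %in% config$markers) hemi$pv_density_true[i] else 0,
        neun_density = if ("NeuN" %in% config$markers)
          hemi$neun_density_true[i] else 0,
        seed = derive_seed(seed, "cells", id, hemi$hemisphere[i],
                           hemi$area[i]),
        meta = list(animal_id = id, hemisphere = hemi$hemisphere[i],
                    area = hemi$area[i]))
      grp <- group_label(hemi$genotype[i], hi_by_animal[[id]])
      if ("PV" %in% config$markers) {
        d <- density_full_region(cm, "PV")
        dens[[length(dens) + 1L]] <- data.frame(
          animal_id = id, genotype = hemi$genotype[i], group = grp,
          hemisphere = hemi$hemisphere[i], area = hemi$area[i],
          marker = "PV", frame = d$frame, count = d$count,
          area_mm2 = d$area_mm2, density = d$density_cells_mm2,
          stringsAsFactors = FALSE)
        pv <- cm$cells[cm$cells$marker == "PV", ]
        dep <- normalized_depth(pv$x_um, pv$y_um, cm$pia, cm$wm)
        prof <- laminar_profile(dep$depth, config$n_bins)
        lam[[length(lam) + 1L]] <- data.frame(
          animal_id = id, genotype = hemi$genotype[i], group = grp,
          hemisphere = hemi$hemisphere[i], area = hemi$area[i],
          marker = "PV", n_bins = prof$n_bins,
          bin_index = seq_len(prof$n_bins),
          count = prof$counts, fraction = prof$fractions,
          stringsAsFactors = FALSE)
      }
      if ("NeuN" %in% config$markers) {
        d <- density_central_strip(cm, "NeuN", config$strip_fraction)
        dens[[length(dens) + 1L]] <- data.frame(
          animal_id = id, genotype = hemi$genotype[i], group = grp,
          hemisphere = hemi$hemisphere[i], area = hemi$area[i],
          marker = "NeuN", frame = d$frame, count = d$count,
          area_mm2 = d$area_mm2, density = d$density_cells_mm2,
          stringsAsFactors = FALSE)
      }
    }
    list(densities = do.call(rbind, dens),
         laminar = if (length(lam)) do.call(rbind, lam) else NULL)
  })
  densities <- histo$densities
  laminar <- histo$laminar

  density_stats <- stage("density_stats", {
    out <- list()
    for (ar in unique(densities$area)) {
      for (mk in unique(densities$marker)) {
        d <- densities[densities$area == ar & densities$marker == mk, ]
        key <- paste(ar, mk, sep = "_")
        out[[key]] <- list(
          t_wt_vs_mut = t_tests(d$density[d$genotype == "WT"],
                                d$density[d$genotype == "MUT"]),
          anova_groups = anova_lsd(d$density, d$group))
      }
    }
    out
  })

  laminar_stats <- stage("laminar_stats", {
    if (is.null(laminar)) NULL else {
      out <- list()
      for (ar in unique(laminar$area)) {
        d <- laminar[laminar$area == ar, ]
        out[[ar]] <- do.call(rbind, lapply(
          sort(unique(d$bin_index)), function(b) {
            db <- d[d$bin_index == b & !is.na(d$fraction), ]
            res <- anova_lsd(db$fraction, db$group)
            data.frame(area = ar, bin_index = b, F = res$statistic,
                       df1 = res$df[["df1"]], df2 = res$df[["df2"]],
                       p_value = res$p_value,
                       significant = res$significant)
          }))
      }
      out
    }
  })

  # --- density vs hearing-loss correlation (mutant hemispheres) ------------
  density_hl <- stage("density_hl", {
    latest <- do.call(rbind, lapply(
      split(audiograms, paste(audiograms$animal_id, audiograms$ear)),
      function(d) d[which.max(d$age_weeks), ]))
    hl <- compute_hl_db(latest)
    d <- densities[densities$marker == "PV" & densities$area == "A1", ]
    d <- merge(d, hl[, c("animal_id", "hl_db")], by = "animal_id")
    mut <- d[d$genotype == "MUT" & !is.na(d$hl_db), ]
    sp <- tryCatch(spearman(mut$hl_db, mut$density),
                   audiogain_bad_sample = function(e) NULL)
    list(table = d, spearman_mut = sp,
         note = if (is.null(sp)) "correlation undefined (degenerate sample)")
  })

  out <- structure(list(
    config = config, manifest = manifest, audiograms = audiograms,
    age_windows = age_windows, status = status, prevalence = prevalence,
    features = features, waveform_summaries = waveform_summaries,
    feature_stats = feature_stats, densities = densities, laminar = laminar,
    density_stats = density_stats, laminar_stats = laminar_stats,
    density_hl_correlation = density_hl),
    class = "audiogain_run")
  out$accounting <- sample_accounting(out)
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' @export
print.audiogain_run <- function(x, ...) {
  cat("audiogain run (seed", x$config$seed, ")\n")
  cat("cutoff:", sprintf("%.2f dB SPL", x$status$cutoff_db), "\n")
  print(x$prevalence)
  invisible(x)
}

#' Sample accounting per comparison
#'
#' Numbers of mice and sample units (recordings, ears, hemispheres) entering
#' each analysis, with exclusion counts (undefined gains, sentinel
#' thresholds).
#'
#' @param run an `audiogain_run`.
#' @return Data frame with one row per comparison x group.
#' @export
sample_accounting <- function(run) {
  stopifnot(inherits(run, "audiogain_run"))
  rows <- list()
  add <- function(comparison, group, unit, n_units, n_mice, excluded = 0L,
                  reason = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      comparison = comparison, group = group, unit = unit,
      n_units = n_units, n_mice = n_mice, n_excluded = excluded,
      exclusion_reason = reason, stringsAsFactors = FALSE)
  }
  aud <- run$audiograms
  for (gt in unique(aud$genotype)) {
    d <- aud[aud$genotype == gt, ]
    add("audiometry", gt, "ear x session", nrow(d),
        length(unique(d$animal_id)),
        sum(d$above_max), "above max tested")
  }
  fe <- run$features
  for (g in unique(fe$group)) {
    d <- fe[fe$group == g, ]
    add("evoked features", g, "recording", nrow(d),
        length(unique(d$animal_id)))
    add("central gain", g, "recording", sum(!is.na(d$p1n1_gain)),
        length(unique(d$animal_id[!is.na(d$p1n1_gain)])),
        sum(is.na(d$p1n1_gain)), "gain undefined (wave I)")
  }
  de <- run$densities
  for (key in unique(paste(de$area, de$marker))) {
    d <- de[paste(de$area, de$marker) == key, ]
    for (g in unique(d$group)) {
      dg <- d[d$group == g, ]
      add(paste("histology", key), g, "hemisphere", nrow(dg),
          length(unique(dg$animal_id)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Serialize the result bundle as CSV/JSON tables.
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE)
  wcsv(run$audiograms, "audiograms.csv")
  wcsv(run$age_windows, "age_windows.csv")
  wcsv(run$status$ears, "ear_status.csv")
  wcsv(run$status$animals, "animal_status.csv")
  wcsv(run$prevalence, "prevalence.csv")
  wcsv(run$features, "features.csv")
  wcsv(run$densities, "densities.csv")
  if (!is.null(run$laminar)) wcsv(run$laminar, "laminar.csv")
  wcsv(run$accounting, "accounting.csv")
  wcsv(run$waveform_summaries$abr, "waveform_means_abr.csv")
  wcsv(run$waveform_summaries$aep, "waveform_means_aep.csv")
  write_manifest(run$manifest, file.path(dir, "manifest.json"))
  flat <- function(sr) list(test = sr$test, statistic = sr$statistic,
                            df = sr$df, p_value = sr$p_value, n = sr$n,
                            lsd = sr$lsd)
  stats_out <- list(
    cutoff_db = run$status$cutoff_db,
    features = lapply(run$feature_stats, function(x) lapply(x, flat)),
    densities = lapply(run$density_stats, function(x) lapply(x, flat)),
    density_hl_spearman = if (!is.null(run$density_hl_correlation$spearman_mut))
      flat(run$density_hl_correlation$spearman_mut))
  jsonlite::write_json(stats_out, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
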