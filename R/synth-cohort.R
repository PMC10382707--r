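# Cohort manifest generation: per-animal ground truth for recovery tests.

rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (1 - plo), mean, sd)
}

#' Generate a synthetic cohort manifest
#'
#' Draws per-animal ground truth: sex, per-ear impairment flags and true ABR
#' thresholds, the animal's AEP gain factor (elevated in animals with at
#' least one impaired ear), its true hearing loss in dB HL, and true PV+ and
#' NeuN+ densities per hemisphere and cortical area. Each animal's draws come
#' from a child random stream derived from the master seed and the animal id,
#' so enlarging the cohort does not perturb existing animals.
#'
#' @param config a [cohort_config()].
#' @return An object of class `cohort_manifest`: a list with `config`,
#'   `animals`, `ears` and `hemispheres` data frames.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- c(sprintf("WT%03d", seq_len(config$n_wt)),
           sprintf("MUT%03d", seq_len(config$n_mut)))
  genotype <- rep(c("WT", "MUT"), c(config$n_wt, config$n_mut))

  ears <- vector("list", length(ids))
  animals <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    gt <- genotype[i]
    res <- with_seed(derive_seed(config$seed, "animal", id), {
      sex <- sample(c("M", "F"), 1L)
      imp <- if (gt == "MUT") {
        flags <- stats::runif(2) < config$p_ear_impaired_mut
        if (sum(flags) == 1L) {
          # left bias reweights which ear of a monaural case is affected
          left <- stats::runif(1) < config$left_bias
          c(left, !left)
        } else flags
      } else c(FALSE, FALSE)
      base <- rtrunc_norm(2, config$wt_threshold_mean, config$wt_threshold_sd,
                          config$instrument_floor_db)
      shift <- rtrunc_norm(2, config$impaired_shift_mean,
                           config$impaired_shift_sd,
                           config$impaired_shift_floor %||% 0)
      thr <- base + ifelse(imp, shift, 0)
      list(sex = sex, imp = imp, thr = thr)
    })
    ears[[i]] <- data.frame(
      animal_id = id, genotype = gt, ear = c("left", "right"),
      impaired_true = res$imp, threshold_true_db = res$thr,
      stringsAsFactors = FALSE)
    animals[[i]] <- data.frame(
      animal_id = id, genotype = gt, sex = res$sex,
      hi_true = any(res$imp),
      max_threshold_true_db = max(res$thr),
      stringsAsFactors = FALSE)
  }
  ears <- do.call(rbind, ears)
  animals <- do.call(rbind, animals)

  wt_ref <- mean(animals$max_threshold_true_db[animals$genotype == "WT"])
  animals$hl_db_true <- animals$max_threshold_true_db - wt_ref
  animals$gain_factor_true <- ifelse(animals$hi_true,
                                     config$gain_factor_hi, 1)

  hemi <- expand.grid(animal_id = animals$animal_id,
                      hemisphere = c("left", "right"),
                      area = c("A1", "M2"),
                      stringsAsFactors = FALSE)
  hemi <- merge(hemi, animals[, c("animal_id", "genotype", "hl_db_true")],
                by = "animal_id", sort = FALSE)
  hemi$pv_density_true <- ifelse(
    hemi$genotype == "MUT" & hemi$area == "A1",
    pmax(0, config$pv_density_wt +
           config$pv_density_slope_hl * hemi$hl_db_true),
    config$pv_density_wt)
  hemi$neun_density_true <- config$neun_density
  hemi <- hemi[order(hemi$animal_id, hemi$area, hemi$hemisphere), ]
  rownames(hemi) <- NULL

  structure(list(config = config, animals = animals, ears = ears,
                 hemispheres = hemi),
            class = "cohort_manifest")
}

#' @export
print.cohort_manifest <- function(x, ...) {
  n_imp <- sum(x$ears$impaired_true[x$ears$genotype == "MUT"])
  cat(sprintf(
    "Synthetic cohort: %d WT + %d MUT animals (seed %d)\n",
    x$config$n_wt, x$config$n_mut, x$config$seed))
  cat(sprintf("  impaired mutant ears: %d of %d; HI animals: %d of %d\n",
              n_imp, 2L * x$config$n_mut,
              sum(x$animals$hi_true), x$config$n_mut))
  invisible(x)
}
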