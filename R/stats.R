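# The study's statistical battery with explicit exact/approximate contracts.
# All tests are two-tailed with alpha = 0.05 by default.

new_stat_result <- function(test, statistic, df, p, n, estimate = NULL,
                            groups = NULL, method = NULL, alpha = 0.05,
                            extra = list()) {
  p <- min(1, max(0, p))
  structure(c(list(test = test, statistic = statistic, df = df,
                   p_value = p, n = n, estimate = estimate, groups = groups,
                   method = method, alpha = alpha,
                   significant = p < alpha), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- if (is.null(x$df) || all(is.na(x$df))) "" else
    paste0(" (df ", paste(format(x$df), collapse = ", "), ")")
  cat(sprintf("%s: statistic %.4g%s, two-tailed p = %.4g%s [%s]\n",
              x$test, x$statistic, dfs, x$p_value,
              if (x$significant) " *" else "", x$method %||% ""))
  invisible(x)
}

two_sided_exact_p <- function(dist_vals, dist_prob, observed, tol = 1e-9) {
  lo <- sum(dist_prob[dist_vals <= observed + tol])
  hi <- sum(dist_prob[dist_vals >= observed - tol])
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon rank-sum test
#'
#' Midranks are used for ties. With `min(n_a, n_b) <= 8` and no ties the
#' two-tailed p value comes from full enumeration of the `choose(N, n_a)`
#' rank assignments (doubling the smaller tail); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b numeric samples (each n >= 1).
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default picks
#'   per the rule above.
#' @return A `stat_result` with the rank-sum statistic `W` of sample `a`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1 || length(b) < 1)
    abort2("empty sample", "audiogain_bad_sample")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- exact %||% (min(na, nb) <= 8 && !ties)
  if (use_exact) {
    combos <- utils::combn(N, na)
    sums <- colSums(matrix(r[combos], nrow = na))
    vals <- sort(unique(sums))
    prob <- as.numeric(table(factor(sums, levels = vals))) / ncol(combos)
    p <- two_sided_exact_p(vals, prob, W)
    method <- "exact enumeration"
  } else {
    mu <- na * (N + 1) / 2
    tie_tab <- table(c(a, b))
    tie_corr <- sum(tie_tab^3 - tie_tab) / ((N) * (N - 1))
    v <- na * nb / 12 * ((N + 1) - tie_corr)
    cc <- sign(W - mu) * 0.5
    z <- if (v > 0) (W - mu - cc) / sqrt(v) else 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie and continuity corrected"
  }
  new_stat_result(
    "Wilcoxon rank-sum", W, NA_real_, p, c(n_a = na, n_b = nb),
    estimate = c(median_a = stats::median(a), median_b = stats::median(b)),
    method = method, alpha = alpha)
}

# Exact signed-rank distribution over 2^n sign patterns by convolution over
# doubled (hence integer) midranks.
signed_rank_exact_dist <- function(r2) {
  probs <- 1
  offset <- 0L
  for (ri in r2) {
    new <- numeric(length(probs) + ri)
    new[seq_along(probs)] <- probs / 2
    new[seq_along(probs) + ri] <- new[seq_along(probs) + ri] + probs / 2
    probs <- new
  }
  list(vals = (seq_along(probs) - 1) / 2, prob = probs)
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped by default (Wilcoxon's original treatment;
#' `zero_method = "pratt"` keeps them in the ranking). Midranks are used on
#' the absolute differences. With n <= 12 nonzero differences the two-tailed
#' p value comes from exact enumeration of the 2^n sign assignments,
#' otherwise from a tie- and continuity-corrected normal approximation.
#'
#' @param x paired differences, or the first sample if `y` is given.
#' @param y optional second paired sample (`d = x - y`).
#' @param zero_method "drop" or "pratt".
#' @param exact force or forbid enumeration.
#' @return A `stat_result` with `V`, the positive-rank sum.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, zero_method = c("drop", "pratt"),
                                 exact = NULL, alpha = 0.05) {
  zero_method <- match.arg(zero_method)
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  nz <- d != 0
  if (!any(nz)) {
    warning("all differences are zero; p = 1")
    return(new_stat_result("Wilcoxon signed-rank", 0, NA_real_, 1,
                           c(n = length(d)), method = "degenerate",
                           alpha = alpha))
  }
  if (zero_method == "drop") d <- d[nz]
  r <- rank(abs(d))
  use <- d != 0                      # pratt: zeros ranked but not summed
  V <- sum(r[use & d > 0])
  n_eff <- sum(use)
  use_exact <- exact %||% (n_eff <= 12)
  if (use_exact) {
    dist <- signed_rank_exact_dist(as.integer(round(2 * r[use])))
    p <- two_sided_exact_p(dist$vals, dist$prob, V)
    method <- "exact sign enumeration"
  } else {
    mu <- sum(r[use]) / 2
    tie_tab <- table(abs(d[use]))
    v <- sum(r[use]^2) / 4
    cc <- sign(V - mu) * 0.5
    z <- if (v > 0) (V - mu - cc) / sqrt(v) else 0
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation, tie and continuity corrected"
  }
  new_stat_result("Wilcoxon signed-rank", V, NA_real_, p,
                  c(n = length(d), n_nonzero = n_eff),
                  estimate = c(median_diff = stats::median(d)),
                  method = method, alpha = alpha,
                  extra = list(zero_method = zero_method))
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of midranks. For n <= 10 the two-tailed
#' p value is exact: the full n! permutation null of the rank cross-product
#' (enumerated in chunks for n = 10). For larger n the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` with n - 2 df is used.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param exact force or forbid enumeration.
#' @return A `stat_result` with `rho`.
#' @export
spearman <- function(x, y, exact = NULL, alpha = 0.05) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort2("need n >= 3 pairs", "audiogain_bad_sample")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort2("rho undefined for a constant sample", "audiogain_bad_sample")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  use_exact <- exact %||% (n <= 10)
  if (use_exact) {
    s_obs <- sum(rx * ry)
    center <- n * mean(rx) * mean(ry)
    # |rho| is monotone in |sum(rx * ry_perm) - center|
    if (n <= 9) {
      perms <- permutations_all(n)
      s <- as.vector(matrix(ry[perms], nrow(perms), n) %*% rx)
      extreme <- sum(abs(s - center) >= abs(s_obs - center) - 1e-9)
      total <- nrow(perms)
    } else {
      extreme <- 0; total <- 0
      sub <- permutations_all(n - 1L)
      for (i in seq_len(n)) {
        rest <- seq_len(n)[-i]
        s <- ry[i] * rx[1] +
          as.vector(matrix(ry[rest[sub]], nrow(sub), n - 1L) %*% rx[-1])
        extreme <- extreme + sum(abs(s - center) >= abs(s_obs - center) - 1e-9)
        total <- total + nrow(sub)
      }
    }
    p <- extreme / total
    df <- NA_real_
    method <- "exact permutation enumeration"
  } else {
    df <- n - 2
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t_stat <- rho * sqrt(df / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t_stat), df)
    }
    method <- "t approximation"
  }
  new_stat_result("Spearman rank correlation", rho, df, p, c(n = n),
                  estimate = c(rho = rho), method = method, alpha = alpha)
}

#' Student t tests (pooled-variance unpaired, or paired)
#'
#' The unpaired form uses the pooled variance (consistent with the classical
#' one-way ANOVA / LSD machinery). The paired form is a one-sample t test on
#' the differences. Zero pooled variance with equal means yields p = 1 (with
#' a warning); zero variance with unequal means yields p = 0.
#'
#' @param a,b samples (paired: equal length).
#' @param paired logical.
#' @return A `stat_result` with `t` and its df.
#' @export
t_tests <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]
  if (!paired) b <- b[!is.na(b)]
  if (paired) {
    if (length(a) != length(b))
      abort2("paired samples must have equal length", "audiogain_bad_sample")
    d <- a - b
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2) abort2("need >= 2 pairs", "audiogain_bad_sample")
    se <- stats::sd(d) / sqrt(n)
    df <- n - 1
    est <- mean(d)
    nrec <- c(n_pairs = n)
    label <- "paired t test"
  } else {
    na <- length(a); nb <- length(b)
    if (na < 2 || nb < 2)
      abort2("need >= 2 observations per group", "audiogain_bad_sample")
    df <- na + nb - 2
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    est <- mean(a) - mean(b)
    nrec <- c(n_a = na, n_b = nb)
    label <- "unpaired t test (pooled variance)"
  }
  if (se == 0) {
    if (est == 0) {
      warning("zero variance with equal means; p = 1 by convention")
      return(new_stat_result(label, 0, df, 1, nrec, estimate = est,
                             method = "degenerate", alpha = alpha))
    }
    return(new_stat_result(label, sign(est) * Inf, df, 0, nrec,
                           estimate = est, method = "degenerate",
                           alpha = alpha))
  }
  t_stat <- est / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  new_stat_result(label, t_stat, df, p, nrec, estimate = est,
                  method = "Student t", alpha = alpha)
}

#' One-way ANOVA with Fisher's LSD post hoc tests
#'
#' Ordinary (equal-variance) one-way ANOVA; when the omnibus test is
#' significant at `alpha` (or `run_lsd = "always"`), all pairwise Fisher LSD
#' comparisons are computed: `t_ij = (mean_i - mean_j) /
#' sqrt(MSW (1/n_i + 1/n_j))` with `N - k` df, two-tailed, with no
#' multiplicity adjustment.
#'
#' @param values numeric response.
#' @param groups group labels (>= 2 groups with >= 2 observations each).
#' @param run_lsd "auto" (gatekept on the omnibus p), "always", or "never".
#' @return A `stat_result` with `F`, df `(k - 1, N - k)`, and an `lsd` data
#'   frame (NULL when gatekept out).
#' @export
anova_lsd <- function(values, groups, alpha = 0.05,
                      run_lsd = c("auto", "always", "never")) {
  run_lsd <- match.arg(run_lsd)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  k <- nlevels(groups)
  ni <- tabulate(groups)
  if (k < 2 || any(ni < 2))
    abort2("need >= 2 groups with >= 2 observations each",
           "audiogain_bad_sample")
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1; df2 <- N - k
  msw <- ssw / df2
  if (msw == 0)
    abort2("zero within-group mean square (degenerate)",
           "audiogain_degenerate")
  f <- (ssb / df1) / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  lsd <- NULL
  if (run_lsd == "always" || (run_lsd == "auto" && p < alpha)) {
    pairs <- utils::combn(levels(groups), 2)
    lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      n1 <- ni[match(g1, levels(groups))]; n2 <- ni[match(g2, levels(groups))]
      tij <- (means[[g1]] - means[[g2]]) / sqrt(msw * (1 / n1 + 1 / n2))
      data.frame(group1 = g1, group2 = g2,
                 mean_diff = means[[g1]] - means[[g2]],
                 t = tij, df = df2,
                 p_value = 2 * stats::pt(-abs(tij), df2),
                 stringsAsFactors = FALSE)
    }))
    lsd$significant <- lsd$p_value < alpha
  }
  grp <- data.frame(group = levels(groups), n = ni,
                    mean = as.numeric(means),
                    sd = as.numeric(tapply(values, groups, stats::sd)),
                    stringsAsFactors = FALSE)
  new_stat_result("one-way ANOVA", f, c(df1 = df1, df2 = df2), p,
                  c(N = N, k = k), groups = grp,
                  method = if (is.null(lsd)) "omnibus only"
                           else "omnibus + Fisher LSD",
                  alpha = alpha, extra = list(lsd = lsd, msw = msw))
}
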