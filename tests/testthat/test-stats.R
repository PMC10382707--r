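# Statistical battery: exact enumeration contracts and closed-form oracles.

test_that("rank-sum: worked examples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(3)
  a <- rnorm(50); b <- rnorm(50, mean = 2)
  expect_lt(wilcoxon_rank_sum(a, b)$p_value, 0.001)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3),
               class = "audiogain_bad_sample")
})

test_that("rank-sum matches base R exact and approximate branches", {
  set.seed(21)
  for (i in 1:10) {
    a <- sample(1000, sample(3:8, 1))
    b <- sample(2000, sample(3:12, 1)) + 0.5
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  for (i in 1:10) {                         # ties/large n: normal approx
    a <- sample(8, 15, replace = TRUE)
    b <- sample(8, 18, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("signed-rank: worked examples and enumeration oracle", {
  expect_equal(wilcoxon_signed_rank(1:6)$p_value, 2 / 64)
  expect_equal(wilcoxon_signed_rank(c(2, -2))$p_value, 1)
  expect_warning(res <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(res$p_value, 1)

  set.seed(31)
  for (i in 1:10) {   # distinct magnitudes: base R exact oracle applies
    d <- sample(1:80, 11) * sample(c(-1, 1), 11, replace = TRUE)
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # midrank ties: independent brute-force 2^n sign enumeration
  for (i in 1:5) {
    d <- sample(c(-4:-1, 1:4), 9, replace = TRUE)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    vs <- as.vector(signs %*% r)
    p_oracle <- min(1, 2 * min(mean(vs <= v_obs + 1e-9),
                               mean(vs >= v_obs - 1e-9)))
    expect_equal(wilcoxon_signed_rank(d)$p_value, p_oracle,
                 tolerance = 1e-12)
  }
})

test_that("spearman: monotone extremes, exact enumeration, approximation", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman(x, 2 * x + 1)$statistic, 1)
  expect_equal(spearman(x, -x)$statistic, -1)
  expect_error(spearman(rep(1, 5), 1:5), class = "audiogain_bad_sample")
  expect_error(spearman(1:2, 1:2), class = "audiogain_bad_sample")

  set.seed(41)
  for (n in c(7, 8, 9)) {                   # exact vs base R (exact <= 9)
    x <- sample(100, n); y <- sample(100, n)
    expect_equal(spearman(x, y)$p_value,
                 suppressWarnings(cor.test(x, y, method = "spearman",
                                           exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
  # n = 10 chunked enumeration: base R switches to the AS89 approximation
  # there, so agreement is only to the approximation's accuracy (absolute)
  x <- sample(100, 10); y <- sample(100, 10)
  expect_lt(abs(spearman(x, y)$p_value -
                  suppressWarnings(cor.test(x, y, method = "spearman",
                                            exact = TRUE)$p.value)), 5e-3)
  # n > 10: t approximation against the closed form
  x <- rnorm(25); y <- x + rnorm(25)
  r <- cor(rank(x), rank(y))
  tt <- r * sqrt(23 / (1 - r^2))
  expect_equal(spearman(x, y)$p_value, 2 * pt(-abs(tt), 23),
               tolerance = 1e-12)
})

test_that("t tests match the closed form and handle degeneracies", {
  expect_equal(t_tests(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(sample(4:12, 1)); b <- rnorm(sample(4:12, 1), mean = 0.5)
    res <- t_tests(a, b)
    or <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$p_value, or$p.value, tolerance = 1e-12)
    expect_equal(unname(res$statistic), unname(or$statistic),
                 tolerance = 1e-12)
  }
  for (i in 1:5) {
    a <- rnorm(8); b <- a + rnorm(8, 0.3)
    expect_equal(t_tests(a, b, paired = TRUE)$p_value,
                 t.test(a, b, paired = TRUE)$p.value, tolerance = 1e-12)
  }
  # paired, constant difference with shrinking jitter: p -> small
  base <- rnorm(8)
  p_big <- t_tests(base + 1 + rnorm(8, sd = 0.5), base, paired = TRUE)$p_value
  p_small <- t_tests(base + 1 + rnorm(8, sd = 0.01), base,
                     paired = TRUE)$p_value
  expect_lt(p_small, p_big)
  expect_lt(p_small, 1e-6)
  expect_warning(t_tests(c(2, 2, 2), c(2, 2, 2)), "zero variance")
})

test_that("ANOVA + LSD: degenerate, hand-computed, base-R oracle, gating", {
  expect_error(anova_lsd(c(5, 5, 5, 5), c("a", "a", "b", "b")),
               class = "audiogain_degenerate")

  vals <- c(0, 0, 10, 10, 0, 0, 10, 10)
  grp <- rep(c("g1", "g2", "g3"), c(2, 2, 4))
  res <- anova_lsd(vals, grp, run_lsd = "always")
  expect_equal(unname(res$statistic), 2.5)       # SSB 100/2, MSW 100/5
  expect_equal(unname(res$df), c(2, 5))
  # pairwise LSD t for g1 vs g2: -10 / sqrt(20 * (1/2 + 1/2)) = -2.2360680
  lsd12 <- res$lsd[res$lsd$group1 == "g1" & res$lsd$group2 == "g2", ]
  expect_equal(lsd12$t, -10 / sqrt(20), tolerance = 1e-12)

  set.seed(61)
  for (i in 1:5) {
    v <- rnorm(30); g <- sample(c("a", "b", "c"), 30, replace = TRUE)
    res <- anova_lsd(v, g)
    or <- anova(lm(v ~ g))
    expect_equal(unname(res$statistic), or$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_value, or$`Pr(>F)`[1], tolerance = 1e-10)
  }

  # identical groups: F = 0, p = 1, no LSD emitted under gating
  v <- rep(c(1, 2, 3, 4), 3); g <- rep(c("a", "b", "c"), each = 4)
  res_id <- anova_lsd(rep(c(1, 2, 3, 4), 3), g)
  expect_equal(unname(res_id$statistic), 0)
  expect_equal(res_id$p_value, 1)
  expect_null(res_id$lsd)
  expect_false(is.null(anova_lsd(rep(c(1, 2, 3, 4), 3), g,
                                 run_lsd = "always")$lsd))
})

test_that("ANOVA with two groups satisfies F = t^2", {
  set.seed(71)
  a <- rnorm(12); b <- rnorm(15, 0.4)
  f <- anova_lsd(c(a, b), rep(c("a", "b"), c(12, 15)))$statistic
  t2 <- t_tests(a, b)$statistic^2
  expect_equal(unname(f), unname(t2), tolerance = 1e-10)
})

test_that("exact and approximate branches agree near their handover", {
  set.seed(81)
  for (i in 1:15) {
    a <- rnorm(8); b <- rnorm(8, 0.3)
    pe <- wilcoxon_rank_sum(a, b, exact = TRUE)$p_value
    pa <- wilcoxon_rank_sum(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
    d <- rnorm(12, 0.2)
    pe <- wilcoxon_signed_rank(d, exact = TRUE)$p_value
    pa <- wilcoxon_signed_rank(d, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
    x <- rnorm(10); y <- x + rnorm(10, sd = 2)
    pe <- spearman(x, y, exact = TRUE)$p_value
    pa <- spearman(x, y, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})
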