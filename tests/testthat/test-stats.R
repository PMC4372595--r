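test_that("the omnibus normality statistic matches its reference values", {
  # frozen reference values computed with an independent implementation of
  # the D'Agostino-Pearson K2 (skew + kurtosis z) on fixed vectors
  x1 <- c(10.691168, 11.643236, 10.660874, 7.393686, 11.810712, 10.892749,
          8.926094, 11.162236, 10.729145, 10.588265, 10.056844, 11.093426,
          8.527092, 9.67418, 9.035761, 11.197692, 10.079444, 9.415086,
          8.436183, 9.485616)
  r1 <- dagostino_test(x1)
  expect_equal(r1$statistic, 1.3687308591, tolerance = 1e-9)
  expect_equal(r1$p.value, 0.5044102119, tolerance = 1e-9)
  expect_equal(r1$z_skew, -1.1624883795, tolerance = 1e-9)
  expect_equal(r1$z_kurt, -0.1317255736, tolerance = 1e-9)

  x3 <- c(15, 7, 132, 58, 157, 64, 21, 12, 7, 4, 30, 11)
  r3 <- dagostino_test(x3)
  expect_equal(r3$statistic, 6.8394533912, tolerance = 1e-9)
  expect_equal(r3$p.value, 0.0327213766, tolerance = 1e-9)
  expect_error(dagostino_test(rnorm(5)), "n >= 8")
})

test_that("the normality gate selects the branch and enforces the n-floor", {
  set.seed(101)
  expect_identical(normality_gate(list(rnorm(100), rnorm(100))), "parametric")
  expect_identical(normality_gate(list(rlnorm(50, 0, 1))), "nonparametric")
  expect_identical(normality_gate(list(rnorm(5))), "nonparametric")
  expect_identical(normality_gate(list(rnorm(100), rnorm(5))),
                   "nonparametric")
  expect_error(normality_gate(list(numeric())), "empty")
})

test_that("compare_groups picks the right test and detects known shifts", {
  # identical groups: no signal
  same <- compare_groups(list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5)))
  expect_gt(same$p, 0.9)
  expect_false(same$significant)
  expect_null(same$posthoc)

  # two Gaussians 132 vs 82, sd 30, n 11: power above 0.9
  set.seed(7)
  hits <- replicate(300, {
    compare_groups(list(a = rnorm(11, 132, 30),
                        b = rnorm(11, 82, 30)))$significant
  })
  expect_gte(mean(hits), 0.9)

  # three substrate groups at study scale: the large contrast is found
  set.seed(8)
  res <- compare_groups(list(pyr_pro = rnorm(11, 132, 58),
                             g3p = rnorm(9, 68, 28),
                             pc_mal = pmax(rnorm(8, 6, 2), 0)))
  expect_true(res$test_name %in% c("one-way ANOVA + Tukey",
                                   "Kruskal-Wallis + Dunn"))
  expect_true(res$significant)
  expect_s3_class(res$posthoc, "data.frame")
  big <- grepl("pyr_pro", res$posthoc$pair) & grepl("pc_mal", res$posthoc$pair)
  expect_lt(res$posthoc$p[big], 0.05)

  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("the parametric and rank branches agree in direction", {
  set.seed(55)
  for (i in 1:10) {
    a <- rnorm(12, 10, 2); b <- rnorm(12, 13, 2)
    t_p <- stats::t.test(a, b, var.equal = TRUE)$p.value
    w_p <- suppressWarnings(stats::wilcox.test(a, b))$p.value
    if (t_p < 0.01) expect_lt(w_p, 0.1)
  }
})

test_that("Grubbs screening removes the planted outlier and nothing else", {
  g <- grubbs_exclude(c(9, 10, 10, 11, 50))
  expect_equal(g$excluded, 50)
  expect_equal(sort(g$sample), c(9, 10, 10, 11))
  # the statistic and critical value behind the removal
  x <- c(9, 10, 10, 11, 50)
  G <- max(abs(x - mean(x))) / sd(x)
  expect_equal(G, 1.7874, tolerance = 1e-4)
  expect_equal(suitflux:::grubbs_critical(5, 0.05), 1.715, tolerance = 1e-3)
  # tight sample: nothing removed
  expect_length(grubbs_exclude(c(9, 10, 11))$excluded, 0)
  # affirmatively non-Gaussian input is returned unchanged
  set.seed(3)
  skew <- rlnorm(50, 0, 1.5)
  gb <- grubbs_exclude(skew)
  expect_identical(gb$note, "gate_blocked")
  expect_length(gb$excluded, 0)
  expect_error(grubbs_exclude(c(1, 2)), "n >= 3")
})

test_that("Grubbs screening is capped at 20% and idempotent", {
  set.seed(12)
  x <- c(rnorm(16, 10, 0.5), 50, 60, 70, 80)   # 4 planted outliers in n = 20
  g <- grubbs_exclude(x)
  expect_lte(length(g$excluded), ceiling(0.2 * length(x)))
  g2 <- grubbs_exclude(g$sample)
  expect_length(g2$excluded, 0)
  expect_identical(sort(g2$sample), sort(g$sample))
})

test_that("ANCOVA slope homogeneity is calibrated and detects distinct slopes", {
  set.seed(23)
  # type-I: identical slopes
  p_null <- replicate(300, {
    x1 <- rnorm(13, 290, 50); x2 <- rnorm(13, 290, 50)
    g <- list(a = list(x = x1, y = 0.7 * x1 + rnorm(13, 0, 20)),
              b = list(x = x2, y = 0.7 * x2 + rnorm(13, 0, 20)))
    ancova_slopes(g)$p_interaction
  })
  expect_gt(mean(p_null < 0.05), 0.02)
  expect_lt(mean(p_null < 0.05), 0.10)
  # power on well-separated slopes
  p_alt <- replicate(200, {
    x1 <- rnorm(13, 290, 50); x2 <- rnorm(13, 290, 50)
    g <- list(a = list(x = x1, y = 0.9 * x1 + rnorm(13, 0, 15)),
              b = list(x = x2, y = 0.3 * x2 + rnorm(13, 0, 15)))
    ancova_slopes(g)$p_interaction
  })
  expect_gt(mean(p_alt < 0.05), 0.95)
  # per-group slopes are reported
  g <- list(a = list(x = 1:10, y = 0.7 * (1:10)),
            b = list(x = 1:10, y = 0.4 * (1:10)))
  a <- ancova_slopes(g)
  expect_equal(unname(a$slopes), c(0.7, 0.4), tolerance = 1e-10)
  expect_error(ancova_slopes(list(a = list(x = 1:10, y = 1:10))),
               "at least 2")
  expect_error(ancova_slopes(list(a = list(x = rep(1, 5), y = 1:5),
                                  b = list(x = 1:5, y = 1:5))),
               "degenerate")
})

test_that("mass scaling finds a proportional relationship and not a null one", {
  set.seed(61)
  mass <- runif(24, 1.5, 3.5)                 # mg per insect, both sexes
  rate <- 120 * mass * (1 + rnorm(24, 0, 0.1))
  ms <- mass_scaling(rate, mass)
  expect_gt(ms$slope, 0)
  expect_lt(ms$slope_p, 0.05)
  expect_true(ms$corr_type %in% c("pearson", "spearman"))
  # mass-independent rates: slope CI covers zero most of the time
  cover <- replicate(100, {
    r0 <- rnorm(24, 300, 50)
    m0 <- runif(24, 1.5, 3.5)
    ms0 <- mass_scaling(r0, m0)
    abs(ms0$slope) < 2 * ms0$slope_se
  })
  expect_gt(mean(cover), 0.85)
  expect_error(mass_scaling(1:5, rep(2, 5)), "degenerate")
  expect_error(mass_scaling(1:5, 1:4), "paired")
})
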