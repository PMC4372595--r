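## --- normality-gated comparison scheme, outliers, slopes -------------------

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness z and the Anscombe-Glynn kurtosis z
#' into the omnibus statistic `K2 = Zs^2 + Zk^2`, referred to a chi-squared
#' distribution with 2 df. The small-sample transformations require n of at
#' least 8.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K2), `p.value`, `z_skew`, `z_kurt`.
#' @examples
#' dagostino_test(rnorm(50))$p.value
#' @export
dagostino_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("dagostino_test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance sample")

  ## skewness z (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  ## kurtosis z (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  z_kurt <- ((1 - 2 / (9 * A)) -
               ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- z_skew^2 + z_kurt^2
  list(statistic = k2, p.value = stats::pchisq(k2, 2, lower.tail = FALSE),
       z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Normality gate for test selection
#'
#' Parametric tests are used only when every group passes the
#' D'Agostino-Pearson test at `alpha`; any group below the test's validity
#' floor (n < 8) forces the nonparametric branch outright, since normality
#' cannot be assessed there.
#'
#' @param samples list of numeric vectors (each n >= 3).
#' @param alpha gate significance level (default 0.05).
#' @return `"parametric"` or `"nonparametric"`.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  if (!is.list(samples)) samples <- list(samples)
  if (any(vapply(samples, length, 0L) == 0)) stop("empty group")
  ns <- vapply(samples, function(s) sum(is.finite(s)), 0L)
  if (any(ns < 8)) return("nonparametric")
  ps <- vapply(samples, function(s) dagostino_test(s)$p.value, 0)
  if (all(ps > alpha)) "parametric" else "nonparametric"
}

## Dunn's post-hoc test after Kruskal-Wallis (rank sums, ties-corrected z,
## Bonferroni-adjusted p per pair)
dunn_posthoc <- function(values, groups, p_adjust = "bonferroni") {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(pair = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             z = z, p = pmin(stats::p.adjust(p, method = p_adjust), 1),
             stringsAsFactors = FALSE)
}

#' Normality-gated group comparison
#'
#' Implements the comparison scheme: two groups are compared by an unpaired
#' Student's t test (parametric branch) or Mann-Whitney test
#' (nonparametric); three or more groups by one-way ANOVA with Tukey HSD
#' post-hoc, or Kruskal-Wallis with Dunn's Bonferroni-adjusted post-hoc.
#' The branch is chosen by [normality_gate()].
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param alpha significance threshold (default 0.05, also used by the
#'   gate).
#' @return object of class `comparison_result`: `test_name`, `statistic`,
#'   `p`, `gate`, `groups`, `posthoc` (data frame, only for > 2 groups),
#'   `significant`.
#' @examples
#' set.seed(1)
#' compare_groups(list(a = rnorm(10, 0), b = rnorm(10, 3)))$p < 0.05
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs n >= 2")
  gate <- normality_gate(groups, alpha = alpha)
  values <- unlist(groups, use.names = FALSE)
  glab <- factor(rep(names(groups), vapply(groups, length, 0L)),
                 levels = names(groups))
  posthoc <- NULL
  if (length(groups) == 2) {
    if (gate == "parametric") {
      ht <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      test_name <- "Student t"
    } else {
      ht <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]]))
      test_name <- "Mann-Whitney"
    }
    statistic <- unname(ht$statistic); p <- ht$p.value
  } else {
    if (gate == "parametric") {
      fit <- stats::aov(values ~ glab)
      an <- summary(fit)[[1]]
      statistic <- an[["F value"]][1]; p <- an[["Pr(>F)"]][1]
      test_name <- "one-way ANOVA"
      tk <- stats::TukeyHSD(fit)$glab
      posthoc <- data.frame(pair = sub("-", " vs ", rownames(tk),
                                       fixed = TRUE),
                            diff = tk[, "diff"], p = tk[, "p adj"],
                            row.names = NULL, stringsAsFactors = FALSE)
    } else {
      ht <- stats::kruskal.test(values, glab)
      statistic <- unname(ht$statistic); p <- ht$p.value
      test_name <- "Kruskal-Wallis"
      posthoc <- dunn_posthoc(values, glab)
      test_name <- paste(test_name, "+ Dunn")
    }
    if (test_name == "one-way ANOVA") test_name <- "one-way ANOVA + Tukey"
  }
  structure(list(test_name = test_name, statistic = statistic, p = p,
                 gate = gate, groups = names(groups), posthoc = posthoc,
                 alpha = alpha, significant = is.finite(p) && p < alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s (%s branch): statistic = %.4g, p = %.4g%s\n",
              x$test_name, x$gate, x$statistic, x$p,
              if (x$significant) " *" else ""))
  if (!is.null(x$posthoc)) {
    ph <- x$posthoc
    ph[-1] <- lapply(ph[-1], signif, digits)
    print(ph, row.names = FALSE)
  }
  invisible(x)
}

## two-sided Grubbs critical value at level alpha
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Grubbs outlier screening
#'
#' Iteratively removes the single most extreme value while the Grubbs
#' statistic `G = max|x - mean| / sd` exceeds its two-sided critical value
#' at `alpha`. Removal is capped at 20% of the original sample (hard
#' guard). Samples large enough to be tested (n >= 8) that affirmatively
#' fail the D'Agostino-Pearson normality check are returned unchanged with
#' a `"gate_blocked"` note, since Grubbs assumes Gaussian data; smaller
#' samples cannot be tested and are screened as-is.
#'
#' @param sample numeric vector, n >= 3.
#' @param alpha significance level (default 0.05).
#' @param iterative if `FALSE`, at most one value is removed.
#' @return list with `sample` (cleaned), `excluded` (values removed, in
#'   removal order) and `note` (`"gate_blocked"` or `""`).
#' @examples
#' grubbs_exclude(c(9, 10, 10, 11, 50))$excluded   # 50
#' @export
grubbs_exclude <- function(sample, alpha = 0.05, iterative = TRUE) {
  x <- sample[is.finite(sample)]
  if (length(x) < 3) stop("Grubbs screening requires n >= 3")
  if (length(x) >= 8 && dagostino_test(x)$p.value < alpha)
    return(list(sample = x, excluded = numeric(), note = "gate_blocked"))
  max_remove <- ceiling(0.2 * length(x))
  excluded <- numeric()
  repeat {
    n <- length(x)
    if (n < 3 || length(excluded) >= max_remove) break
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    if (G > grubbs_critical(n, alpha)) {
      excluded <- c(excluded, x[i])
      x <- x[-i]
    } else break
    if (!iterative) break
  }
  list(sample = x, excluded = excluded, note = "")
}

#' ANCOVA test of slope homogeneity
#'
#' Tests whether linear-regression slopes differ among groups via the
#' group-by-covariate interaction term of an analysis of covariance.
#'
#' @param groups named list, each element a data frame or list with
#'   components `x` and `y` (>= 4 pairs per group).
#' @return list with `p_interaction`, `slopes` (named per-group slopes),
#'   `f_statistic` and the fitted `model`.
#' @examples
#' g <- list(a = list(x = 1:10, y = 1:10 * 0.7 + rnorm(10, 0, .1)),
#'           b = list(x = 1:10, y = 1:10 * 0.4 + rnorm(10, 0, .1)))
#' ancova_slopes(g)$p_interaction
#' @export
ancova_slopes <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 2) stop("at least 2 groups are required")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  dfs <- lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    if (length(g$x) != length(g$y)) stop("x and y lengths differ in ", nm)
    if (length(g$x) < 4) stop("group ", nm, " has fewer than 4 pairs")
    if (stats::var(g$x) == 0) stop("degenerate covariate in group ", nm)
    data.frame(x = g$x, y = g$y, g = nm, stringsAsFactors = FALSE)
  })
  dat <- do.call(rbind, dfs)
  dat$g <- factor(dat$g, levels = names(groups))
  full <- stats::lm(y ~ x * g, data = dat)
  an <- suppressWarnings(stats::anova(full))
  slopes <- vapply(names(groups), function(nm) {
    gd <- dat[dat$g == nm, ]
    unname(stats::coef(stats::lm(y ~ x, data = gd))[2])
  }, 0)
  list(p_interaction = an["x:g", "Pr(>F)"],
       f_statistic = an["x:g", "F value"],
       slopes = slopes, model = full)
}

#' Body-mass scaling of respiration
#'
#' Linear regression of per-individual respiration (typically the maximal
#' uncoupled rate of a permeabilized-muscle run) on body mass, with a
#' normality-gated correlation coefficient, to test whether respiration
#' varies in direct proportion with animal size.
#'
#' @param respiration per-individual rates.
#' @param body_mass per-individual mass (mg), same length.
#' @param alpha significance level for the correlation gate.
#' @return list with `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `corr_coeff`, `corr_type`, `n`, `model`.
#' @export
mass_scaling <- function(respiration, body_mass, alpha = 0.05) {
  if (length(respiration) != length(body_mass))
    stop("respiration and body_mass must be paired")
  n <- length(respiration)
  if (n < 4) stop("at least 4 individuals are required")
  if (stats::var(body_mass) == 0) stop("degenerate covariate: constant mass")
  fit <- stats::lm(respiration ~ body_mass)
  sm <- summary(fit)$coefficients
  corr_type <- if (normality_gate(list(respiration, body_mass),
                                  alpha = alpha) == "parametric")
    "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(body_mass, respiration,
                                         method = corr_type))
  list(slope = unname(sm["body_mass", "Estimate"]),
       slope_se = unname(sm["body_mass", "Std. Error"]),
       slope_p = unname(sm["body_mass", "Pr(>|t|)"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       corr_coeff = unname(ct$estimate), corr_type = corr_type,
       n = n, model = fit)
}
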