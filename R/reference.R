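#' Reference cohort summaries for Aedes aegypti flight muscle
#'
#' Published group means and standard deviations for *Aedes aegypti* flight
#' muscle mitochondria, bundled as the package's default generative
#' parameters for [simulate_cohort()] and as the desk inputs for the
#' decomposition examples. `reference_state_rates()` covers oxygraph state
#' rates of female preparations (isolated mitochondria in
#' nmol O2/min/mg protein; permeabilized muscle in pmol O2/s/mL/thorax);
#' `reference_h2o2_rates()` covers Amplex-red H2O2 production of both sexes
#' (pmol H2O2/min/mg protein); `reference_enzyme_activities()` covers
#' spectrophotometric enzyme activities (nmol product/min/mg protein);
#' `reference_efficiency()` covers the bioenergetic efficiency (slope of
#' OXPHOS capacity on maximal uncoupled respiration) and capacity summaries
#' of female preparations. Male oxygraph tables were published only as
#' supplementary material and are not bundled.
#'
#' @return a data frame; one row per group x metabolic state (or per assay).
#' @examples
#' subset(reference_state_rates(), regime == "PYR_PRO")
#' @export
reference_state_rates <- function() {
  iso <- expand.grid(state = c("LEAK", "OXPHOS_ADP", "ETS_FCCP",
                               "ROTENONE", "ANTIMYCIN"),
                     regime = c("PYR_PRO", "G3P", "PC_MAL"),
                     stringsAsFactors = FALSE)
  iso$mean <- c(15, 132, 157, 21, 7,
                30,  68, 100, NA, 8,
                 2,   6,   8,  1, 1)
  iso$sd   <- c( 7,  58,  64, 12, 4,
                11,  28,  42, NA, 4,
                 1,   2,   2,  1, 1)
  iso$n    <- c(11, 11, 10, 11, 10,
                 9,  9,  9, NA,  9,
                 8,  8,  8,  8,  8)
  iso$preparation <- "ISOLATED_MITO"
  iso$units <- "nmol_O2_per_min_per_mg"

  pm <- expand.grid(state = c("LEAK", "OXPHOS_ADP", "ETS_FCCP",
                              "ROTENONE", "ANTIMYCIN"),
                    regime = c("PYR_PRO", "G3P"),
                    stringsAsFactors = FALSE)
  pm$mean <- c(42, 265, 300, 34, 10,
               81, 140, 169, NA, 12)
  pm$sd   <- c(10,  45,  50, 10,  6,
               20,  43,  55, NA,  4)
  pm$n    <- c(13, 13, 13, 13, 13,
               12, 12, 12, NA, 12)
  pm$preparation <- "PERMEABILIZED_MUSCLE"
  pm$units <- "pmol_O2_per_s_per_mL_per_thorax"

  out <- rbind(iso, pm)
  out <- out[!is.na(out$mean), ]
  out$sex <- "FEMALE"
  rownames(out) <- NULL
  out[, c("sex", "preparation", "regime", "state", "mean", "sd", "n", "units")]
}

#' @rdname reference_state_rates
#' @export
reference_h2o2_rates <- function() {
  grid <- expand.grid(state = c("OLIGOMYCIN", "ETS_FCCP", "ROTENONE",
                                "ANTIMYCIN"),
                      regime = c("PYR_PRO", "G3P", "PC_MAL"),
                      sex = c("FEMALE", "MALE"),
                      stringsAsFactors = FALSE)
  ## G3P runs are rotenone-pretreated: their FCCP rate is already the
  ## rotenone-present baseline and no separate ROTENONE state exists.
  grid$mean <- c(371, 207, 260, 685,   369, 235, NA, 538,   112,  66, 104, 155,
                 419, 271, 310, 855,   473, 396, NA, 770,   128,  98, 110, 192)
  grid$sd   <- c(112, 104,  94, 236,    82,  42, NA,  99,    28,  23,  31,  45,
                  94, 111,  75, 159,    62,  61, NA, 186,    19,  19,  13,  53)
  grid$n    <- c(  5,   5,   5,   5,     9,   9, NA,   9,     5,   5,   5,   5,
                   5,   5,   5,   5,     9,   9, NA,   9,     5,   5,   5,   5)
  grid <- grid[!is.na(grid$mean), ]
  grid$preparation <- "ISOLATED_MITO"
  grid$units <- "pmol_H2O2_per_min_per_mg"
  rownames(grid) <- NULL
  grid[, c("sex", "preparation", "regime", "state", "mean", "sd", "n",
           "units")]
}

#' @rdname reference_state_rates
#' @export
reference_enzyme_activities <- function() {
  out <- data.frame(
    assay = rep(c("NADH_CYTC", "PROLINE_CYTC", "G3P_CYTC", "CYTC_OXIDASE",
                  "CITRATE_SYNTHASE"), times = 2),
    sex = rep(c("FEMALE", "MALE"), each = 5),
    mean = c(58, 3, 79, 164, 2177,
             51, 3, 91, 189, 1966),
    sd = c(16, 1, 18, 51, 1118,
           23, 1, 24, 65, 1148),
    n = c(9, 3, 6, 16, 16,
          8, 3, 6, 14, 14),
    units = "nmol_product_per_min_per_mg",
    stringsAsFactors = FALSE)
  out
}

#' @rdname reference_state_rates
#' @export
reference_efficiency <- function() {
  data.frame(
    preparation = c(rep("ISOLATED_MITO", 3), rep("PERMEABILIZED_MUSCLE", 2)),
    regime = c("PYR_PRO", "G3P", "PC_MAL", "PYR_PRO", "G3P"),
    slope = c(0.67, 0.55, 0.72, 0.74, 0.46),
    slope_sd = c(0.17, 0.08, 0.23, 0.14, 0.06),
    corr = c(0.78, 0.77, 0.79, 0.83, 0.84),
    corr_type = c("pearson", "spearman", "pearson", "pearson", "pearson"),
    oxphos_mean = c(118, 39, 4, 223, 59),
    oxphos_sd = c(57, 25, 1, 45, 27),
    n = c(11, 9, 8, 13, 12),
    sex = "FEMALE",
    stringsAsFactors = FALSE)
}
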