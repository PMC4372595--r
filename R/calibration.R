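## --- Amplex-red calibration and spectrophotometric enzymology --------------

#' Amplex-red standard curve for one modulator condition
#'
#' Standard curves are fitted per pharmacological condition because the
#' OXPHOS modulators themselves perturb the fluorophore response; a pooled
#' curve is deliberately not supported. `fit_calibration()` fits an ordinary
#' least-squares line of fluorescence on known H2O2 amount and refuses
#' degenerate or negative-slope input.
#'
#' @param standards data frame with columns `pmol` (known H2O2) and
#'   `fluorescence` (AU); at least 3 standards with distinct `pmol`.
#' @param condition modulator condition label (e.g. `"oligomycin"`,
#'   `"fccp"`, `"rotenone"`, `"antimycin"`).
#' @return an object of class `calibration_curve` with `slope` (AU/pmol),
#'   `intercept`, `r2`, `n_standards`, `condition`.
#' @examples
#' std <- data.frame(pmol = c(0, 100, 200), fluorescence = c(5, 25, 45))
#' fit_calibration(std, "fccp")$slope   # 0.2 AU/pmol
#' @export
fit_calibration <- function(standards, condition) {
  stopifnot(is.data.frame(standards),
            all(c("pmol", "fluorescence") %in% names(standards)))
  if (nrow(standards) < 3)
    stop("at least 3 standards are required")
  if (length(unique(standards$pmol)) < 2)
    stop("standards have degenerate (identical) H2O2 amounts")
  fit <- stats::lm(fluorescence ~ pmol, data = standards)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive; got ", format(slope))
  ss_tot <- sum((standards$fluorescence - mean(standards$fluorescence))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(condition = condition, slope = slope,
                 intercept = unname(stats::coef(fit)[1]), r2 = r2,
                 n_standards = nrow(standards)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Amplex-red calibration [%s]: %.4g AU/pmol (intercept %.3g, r2 %.4f, n = %d)\n",
              x$condition, x$slope, x$intercept, x$r2, x$n_standards))
  invisible(x)
}

#' Convert a fluorescence slope to a H2O2 production rate
#'
#' `rate = fluorescence slope / calibration slope / protein`, yielding
#' pmol H2O2/min/mg protein. The calibration curve must have been fitted
#' under the same modulator condition as the state being converted.
#'
#' @param fluor_slope fluorescence accrual rate (AU/min).
#' @param curve a [fit_calibration()] curve.
#' @param protein_mg mitochondrial protein in the cuvette (mg).
#' @param condition optional condition label of the state being converted;
#'   if given it must match `curve$condition`.
#' @return rate in pmol H2O2/min/mg.
#' @examples
#' cu <- fit_calibration(data.frame(pmol = c(0, 100, 200),
#'                                  fluorescence = c(5, 25, 45)), "oligomycin")
#' h2o2_rate(12, cu, 0.17)   # 352.94 pmol/min/mg
#' @export
h2o2_rate <- function(fluor_slope, curve, protein_mg, condition = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (protein_mg <= 0) stop("protein_mg must be > 0")
  if (!is.null(condition) && !identical(condition, curve$condition))
    stop("condition mismatch: state measured under '", condition,
         "' but curve fitted under '", curve$condition, "'")
  fluor_slope / curve$slope / protein_mg
}

#' Convert all states of a fluorimeter fit to H2O2 rates
#'
#' Applies [h2o2_rate()] state by state, picking for each metabolic state
#' the calibration curve of its modulator condition (see
#' [state_condition()]). Errors if any state lacks a matching curve.
#'
#' @param fit a [suit_fit()] of a fluorescence trace (rates in AU/min).
#' @param calibration named list of [fit_calibration()] curves keyed by
#'   condition.
#' @param protein_mg protein in the cuvette; defaults to the fit's
#'   metadata.
#' @return data frame `state`, `rate`, `units` (pmol H2O2/min/mg),
#'   `condition`.
#' @export
h2o2_rates <- function(fit, calibration, protein_mg = NULL) {
  stopifnot(inherits(fit, "suit_fit"))
  if (attr(fit$trace, "channel") != "fluorescence")
    stop("h2o2_rates() expects a fluorescence-channel fit")
  if (is.null(protein_mg)) protein_mg <- fit$meta$protein_mg
  conds <- state_condition(fit$rates$state)
  missing <- fit$rates$state[!conds %in% names(calibration)]
  if (length(missing))
    stop("no calibration curve for state(s): ",
         paste(missing, collapse = ", "))
  rate <- vapply(seq_len(nrow(fit$rates)), function(i)
    h2o2_rate(fit$rates$rate[i], calibration[[conds[i]]], protein_mg,
              condition = conds[i]), 0)
  data.frame(state = fit$rates$state, rate = rate,
             units = "pmol_H2O2_per_min_per_mg", condition = conds,
             stringsAsFactors = FALSE)
}

.assay_table <- function() {
  data.frame(
    name = c("NADH_CYTC", "PROLINE_CYTC", "G3P_CYTC", "PC_CYTC",
             "CYTC_OXIDASE", "CITRATE_SYNTHASE"),
    wavelength_nm = c(550, 550, 550, 550, 550, 412),
    epsilon_mM_cm = c(18.7, 18.7, 18.7, 18.7, 18.7, 13.6),
    direction = c("increase", "increase", "increase", "increase",
                  "decrease", "increase"),
    inhibitor = c("rotenone", "antimycin A", "antimycin A", "antimycin A",
                  "KCN", NA),
    stringsAsFactors = FALSE)
}

#' Spectrophotometric assay definitions
#'
#' The cytochrome-c oxidoreductase assays follow ferricytochrome c
#' reduction (rising A550, epsilon 18.7 per mM per cm), cytochrome c
#' oxidase follows ferrocytochrome c oxidation (falling A550, same
#' epsilon), and citrate synthase follows TNB formation from DTNB (rising
#' A412, epsilon 13.6 per mM per cm). Each assay names the inhibitor whose
#' insensitive remainder defines the specific (sensitive) activity.
#'
#' @param name one of `"NADH_CYTC"`, `"PROLINE_CYTC"`, `"G3P_CYTC"`,
#'   `"PC_CYTC"`, `"CYTC_OXIDASE"`, `"CITRATE_SYNTHASE"`.
#' @param epsilon_mM_cm optional extinction-coefficient override.
#' @return an object of class `assay_definition`.
#' @export
assay_definition <- function(name, epsilon_mM_cm = NULL) {
  tab <- .assay_table()
  name <- match.arg(name, tab$name)
  row <- tab[tab$name == name, ]
  if (!is.null(epsilon_mM_cm)) {
    stopifnot(epsilon_mM_cm > 0)
    row$epsilon_mM_cm <- epsilon_mM_cm
  }
  structure(as.list(row), class = "assay_definition")
}

as_assay_definition <- function(x) {
  if (inherits(x, "assay_definition")) return(x)
  if (is.character(x) && length(x) == 1L) return(assay_definition(x))
  stop("unknown assay: supply an assay_definition or one of ",
       paste(.assay_table()$name, collapse = ", "))
}

#' Enzyme activity from an absorbance slope
#'
#' Beer-Lambert conversion:
#' `rate = |dA/dt| / (epsilon x path) x volume x 1000 / protein`, i.e. the
#' mM/min concentration change scaled to nmol product/min/mg protein. A
#' slope whose sign contradicts the assay direction is flagged
#' (`"wrong_sign"` attribute) but its magnitude is still returned.
#'
#' @param dA_dt absorbance change per minute (signed).
#' @param assay an [assay_definition()] or assay name.
#' @param cuvette_volume_mL reaction volume (mL).
#' @param path_cm optical path length (cm).
#' @param protein_mg protein in the cuvette (mg).
#' @return activity in nmol product/min/mg, with attribute `wrong_sign` if
#'   the slope direction contradicted the assay.
#' @examples
#' enzyme_activity(0.0187, "NADH_CYTC", 1, 1, 0.08)   # 12.5 nmol/min/mg
#' @export
enzyme_activity <- function(dA_dt, assay, cuvette_volume_mL = 1, path_cm = 1,
                            protein_mg = 0.08) {
  assay <- as_assay_definition(assay)
  if (path_cm <= 0) stop("path_cm must be > 0")
  if (protein_mg <= 0) stop("protein_mg must be > 0")
  expected_sign <- if (assay$direction == "increase") 1 else -1
  rate <- abs(dA_dt) / (assay$epsilon_mM_cm * path_cm) *
    cuvette_volume_mL * 1000 / protein_mg
  if (dA_dt != 0 && sign(dA_dt) != expected_sign) {
    warning("absorbance slope sign contradicts the ", assay$name,
            " assay direction; magnitude returned, flagged wrong_sign")
    attr(rate, "wrong_sign") <- TRUE
  }
  rate
}

#' Inhibitor-sensitive activity
#'
#' The diagnostic activity of each assay is the total rate minus the rate
#' remaining after the assay's inhibitor (rotenone-sensitive cytochrome c
#' reduction, cyanide-sensitive oxidation, ...). Negative results indicate
#' an inhibitor paradox (stimulation on inhibition) and are flagged, not
#' clamped, so that cohort means stay unbiased.
#'
#' @param total,insensitive total and inhibitor-insensitive rates, same
#'   units.
#' @return sensitive rate; attribute `flag = "inhibitor_paradox"` when
#'   negative.
#' @examples
#' inhibitor_sensitive_activity(60, 2)   # 58
#' @export
inhibitor_sensitive_activity <- function(total, insensitive) {
  out <- total - insensitive
  if (out < 0) attr(out, "flag") <- "inhibitor_paradox"
  out
}

#' Citrate-synthase normalization
#'
#' Activities are divided by the same sample's citrate synthase activity (a
#' mitochondrial-content proxy). For cohorts the summary must be the mean
#' +/- SD of per-sample ratios, not the ratio of group means; this function
#' is vectorized over samples for that purpose.
#'
#' @param activity enzyme activity (same units as `cs_activity`).
#' @param cs_activity citrate synthase activity, > 0.
#' @return unitless ratio(s).
#' @examples
#' cs_normalize(58, 2177)   # 0.0266
#' @export
cs_normalize <- function(activity, cs_activity) {
  if (any(!is.finite(cs_activity)) || any(cs_activity <= 0))
    stop("cs_activity must be > 0")
  activity / cs_activity
}

#' Extract activities from a spectrophotometric trace
#'
#' Fits the pre- and post-inhibitor absorbance slopes by least squares
#' (with a settling margin around the inhibitor addition), converts both
#' through [enzyme_activity()], and returns the inhibitor-sensitive
#' activity.
#'
#' @param trace an absorbance [instrument_trace()] (e.g. from
#'   [simulate_spectro_trace()]).
#' @param assay an [assay_definition()] or assay name.
#' @param inhibitor_time inhibitor addition time (s); defaults to the value
#'   recorded on the trace.
#' @param settle_s margin excluded on both sides of the addition (s).
#' @param cuvette_volume_mL,path_cm,protein_mg cuvette geometry and
#'   loading, as in [enzyme_activity()].
#' @return list with `total`, `insensitive`, `sensitive` (nmol/min/mg) and
#'   the fitted `dA_dt` slopes.
#' @export
fit_enzyme_assay <- function(trace, assay, inhibitor_time = NULL,
                             settle_s = 15, cuvette_volume_mL = 1,
                             path_cm = 1, protein_mg = 0.08) {
  stopifnot(inherits(trace, "instrument_trace"))
  assay <- as_assay_definition(assay)
  if (is.null(inhibitor_time)) inhibitor_time <- attr(trace, "inhibitor_time")
  if (is.null(inhibitor_time))
    stop("inhibitor_time not given and not recorded on the trace")
  pre <- trace$time_s < inhibitor_time - settle_s
  post <- trace$time_s > inhibitor_time + settle_s
  if (sum(pre) < 5 || sum(post) < 5)
    stop("too few samples on one side of the inhibitor addition")
  slope_of <- function(sel)
    unname(stats::coef(stats::lm(trace$signal[sel] ~ trace$time_s[sel]))[2]) * 60
  dA_pre <- slope_of(pre)
  dA_post <- slope_of(post)
  total <- enzyme_activity(dA_pre, assay, cuvette_volume_mL, path_cm,
                           protein_mg)
  insens <- enzyme_activity(dA_post, assay, cuvette_volume_mL, path_cm,
                            protein_mg)
  list(total = as.numeric(total), insensitive = as.numeric(insens),
       sensitive = inhibitor_sensitive_activity(as.numeric(total),
                                                as.numeric(insens)),
       dA_dt_pre = dA_pre, dA_dt_post = dA_post)
}
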