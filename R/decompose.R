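## --- inhibitor-subtraction decomposition of respiration and ROS ------------

## accept a named numeric vector, a named list of state_rate objects, or a
## suit_fit; return named numeric (+ units attr when known)
rate_values <- function(rates) {
  if (inherits(rates, "suit_fit"))
    return(structure(coef(rates), units = rates$rates$units[1]))
  if (is.list(rates) && length(rates) &&
      all(vapply(rates, inherits, TRUE, "state_rate"))) {
    un <- unique(vapply(rates, `[[`, "", "units"))
    if (length(un) > 1)
      stop("state rates carry mixed units: ", paste(un, collapse = ", "))
    return(structure(vapply(rates, `[[`, 0, "value"), units = un))
  }
  if (is.numeric(rates) && !is.null(names(rates))) return(rates)
  stop("rates must be a named numeric vector, a named list of state_rate ",
       "objects, or a suit_fit")
}

need_states <- function(r, states, what) {
  missing <- setdiff(states, names(r))
  if (length(missing))
    stop(what, " requires state(s): ", paste(missing, collapse = ", "))
}

contribution_df <- function(site, value, units) {
  data.frame(site = site, value = value,
             units = if (is.null(units)) NA_character_ else units,
             flag = ifelse(value < 0, "negative_contribution", ""),
             stringsAsFactors = FALSE)
}

#' Decompose respiration into electron-entry site contributions
#'
#' Assigns maximal (FCCP-uncoupled) respiration to electron-transport-system
#' entry sites by sequential inhibitor subtraction. With pyruvate + proline:
#' complex I = FCCP minus rotenone-insensitive rate, proline dehydrogenase
#' (ProDH) = rotenone-insensitive minus antimycin-resistant rate. With G3P
#' (rotenone-pretreated): G3P dehydrogenase = FCCP minus
#' antimycin-insensitive rate. With palmitoylcarnitine + malate: complex I =
#' FCCP minus rotenone, ETF:QOR = rotenone minus antimycin. The identity
#' `sum(contributions) + antimycin residual = FCCP` holds by construction
#' and is asserted on every call. Negative contributions are flagged, never
#' clamped.
#'
#' @param rates named rates (vector, list of `state_rate`, or a
#'   [suit_fit()]) covering the regime's required states, identical units.
#' @param regime a [suit_regime()] or regime name.
#' @return data frame `site`, `value`, `units`, `flag`, with attribute
#'   `conservation_residual`.
#' @examples
#' respiration_contributions(
#'   c(ETS_FCCP = 157, ROTENONE = 21, ANTIMYCIN = 7), "PYR_PRO")
#' @export
respiration_contributions <- function(rates, regime) {
  regime <- as_suit_regime(regime)
  r <- rate_values(rates)
  need_states(r, required_states(regime), "respiration decomposition")
  fccp <- r[["ETS_FCCP"]]; aa <- r[["ANTIMYCIN"]]
  out <- switch(regime$name,
    PYR_PRO = contribution_df(c("CI_PYRPRO", "PRODH"),
                              c(fccp - r[["ROTENONE"]],
                                r[["ROTENONE"]] - aa), attr(r, "units")),
    G3P = contribution_df("G3PDH", fccp - aa, attr(r, "units")),
    PC_MAL = contribution_df(c("CI_PCMAL", "ETFQOR"),
                             c(fccp - r[["ROTENONE"]],
                               r[["ROTENONE"]] - aa), attr(r, "units")))
  residual <- fccp - sum(out$value) - aa
  stopifnot(abs(residual) <= 1e-8 * max(1, abs(fccp)))
  attr(out, "conservation_residual") <- residual
  out
}

#' Assign H2O2 production to electron-leak sites
#'
#' Superoxide/H2O2 topology by the same sequential-inhibition logic, with
#' the opposite arithmetic orientation: blocking electron flow downstream of
#' a leak site raises its superoxide output, so each site's contribution is
#' the later (more inhibited) rate minus the earlier one. With pyruvate +
#' proline: site IF of complex I = rotenone minus FCCP, ProDH + other
#' dehydrogenases = antimycin minus rotenone. With G3P (rotenone present
#' throughout, so the FCCP state is the rotenone baseline): G3PDH + others =
#' antimycin minus FCCP. With palmitoylcarnitine + malate: site IF =
#' rotenone minus FCCP, ETF:QOR + others = antimycin minus rotenone.
#'
#' @param rates named H2O2 rates (pmol/min/mg) covering the regime's
#'   required states.
#' @param regime a [suit_regime()] or regime name.
#' @return data frame as in [respiration_contributions()].
#' @examples
#' ros_site_contributions(
#'   c(ETS_FCCP = 207, ROTENONE = 260, ANTIMYCIN = 685), "PYR_PRO")
#' @export
ros_site_contributions <- function(rates, regime) {
  regime <- as_suit_regime(regime)
  r <- rate_values(rates)
  need_states(r, required_states(regime), "ROS site decomposition")
  fccp <- r[["ETS_FCCP"]]; aa <- r[["ANTIMYCIN"]]
  switch(regime$name,
    PYR_PRO = contribution_df(c("IF_PYRPRO", "PRODH_OTHER"),
                              c(r[["ROTENONE"]] - fccp,
                                aa - r[["ROTENONE"]]), attr(r, "units")),
    G3P = contribution_df("G3PDH_OTHER", aa - fccp, attr(r, "units")),
    PC_MAL = contribution_df(c("IF_PCMAL", "ETFQOR_OTHER"),
                             c(r[["ROTENONE"]] - fccp,
                               aa - r[["ROTENONE"]]), attr(r, "units")))
}

#' OXPHOS and ETS capacity
#'
#' `oxphos_capacity()` is the ADP-stimulated respiration net of the leak
#' rate (the flux available to ATP synthesis); `ets_capacity()` is the
#' maximal uncoupled respiration net of the antimycin-resistant residual
#' (the electron-transport-system ceiling). Computed within run; negative
#' ETS capacity is returned with a flag, not clamped.
#'
#' @param rates named rates covering `LEAK`/`OXPHOS_ADP` (OXPHOS) or
#'   `ETS_FCCP`/`ANTIMYCIN` (ETS).
#' @return capacity in the input units.
#' @examples
#' oxphos_capacity(c(LEAK = 42, OXPHOS_ADP = 265))   # 223
#' ets_capacity(c(ETS_FCCP = 300, ANTIMYCIN = 10))   # 290
#' @export
oxphos_capacity <- function(rates) {
  r <- rate_values(rates)
  need_states(r, c("LEAK", "OXPHOS_ADP"), "OXPHOS capacity")
  unname(r[["OXPHOS_ADP"]] - r[["LEAK"]])
}

#' @rdname oxphos_capacity
#' @export
ets_capacity <- function(rates) {
  r <- rate_values(rates)
  need_states(r, c("ETS_FCCP", "ANTIMYCIN"), "ETS capacity")
  out <- unname(r[["ETS_FCCP"]] - r[["ANTIMYCIN"]])
  if (out < 0) attr(out, "flag") <- "negative_capacity"
  out
}

#' Bioenergetic efficiency analysis
#'
#' Regresses per-run OXPHOS capacity on per-run ETS capacity. The slope is
#' the bioenergetic efficiency (how much of each unit of
#' electron-transport ceiling is actually harnessed for phosphorylating
#' respiration); the correlation coefficient is Pearson when both margins
#' pass the normality gate, Spearman otherwise.
#'
#' @param oxphos,ets paired per-run capacities (same length, >= 4), or a
#'   two-column data frame/matrix as `oxphos`.
#' @param alpha significance level of the normality gate.
#' @return object of class `bioenergetic_summary`: `oxphos_capacity`,
#'   `ets_capacity` (means), `efficiency_slope`, `slope_se`, `slope_p`,
#'   `corr_coeff`, `corr_type`, `n`.
#' @examples
#' set.seed(1)
#' ets <- rnorm(13, 290, 50)
#' ox <- 0.74 * ets + rnorm(13, 10, 15)
#' efficiency_analysis(ox, ets)
#' @export
efficiency_analysis <- function(oxphos, ets = NULL, alpha = 0.05) {
  if (is.null(ets)) {
    stopifnot(ncol(oxphos) >= 2)
    ets <- oxphos[[2]]; oxphos <- oxphos[[1]]
  }
  if (length(oxphos) != length(ets)) stop("oxphos and ets must be paired")
  n <- length(oxphos)
  if (n < 4) stop("at least 4 (OXPHOS, ETS) pairs are required")
  if (stats::var(ets) == 0) stop("ETS capacities have zero variance")
  fit <- stats::lm(oxphos ~ ets)
  sm <- suppressWarnings(summary(fit))$coefficients
  gate <- normality_gate(list(oxphos, ets), alpha = alpha)
  corr_type <- if (gate == "parametric") "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(ets, oxphos, method = corr_type))
  structure(list(oxphos_capacity = mean(oxphos), ets_capacity = mean(ets),
                 efficiency_slope = unname(sm["ets", "Estimate"]),
                 slope_se = unname(sm["ets", "Std. Error"]),
                 slope_p = unname(sm["ets", "Pr(>|t|)"]),
                 corr_coeff = unname(ct$estimate), corr_type = corr_type,
                 n = n, lm = fit),
            class = "bioenergetic_summary")
}

#' @export
print.bioenergetic_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Bioenergetic summary (n = %d runs)\n", x$n))
  cat(sprintf("  OXPHOS capacity (mean): %.4g\n  ETS capacity (mean):    %.4g\n",
              x$oxphos_capacity, x$ets_capacity))
  cat(sprintf("  efficiency slope: %.3f +/- %.3f (p = %.3g)\n",
              x$efficiency_slope, x$slope_se, x$slope_p))
  cat(sprintf("  correlation: %s r = %.3f\n", x$corr_type, x$corr_coeff))
  invisible(x)
}

#' Relative respiratory metrics
#'
#' Percent-of-maximum metrics used to characterize coupling and electron
#' routing: ADP-stimulated respiration as a percentage of the uncoupled
#' maximum, rotenone- and antimycin-insensitive percentages, and the
#' complex-I channelling percentage `(1 - rotenone/FCCP) x 100` (the share
#' of uncoupled electron flow that passes complex I). Rotenone metrics are
#' omitted for rotenone-pretreated (G3P) runs.
#'
#' @param rates named rates including `ETS_FCCP` (> 0) plus whichever of
#'   `OXPHOS_ADP`, `ROTENONE`, `ANTIMYCIN` are present.
#' @param regime a [suit_regime()] or regime name.
#' @return named numeric vector of percentages.
#' @examples
#' relative_metrics(c(OXPHOS_ADP = 265, ETS_FCCP = 300, ROTENONE = 34,
#'                    ANTIMYCIN = 10), "PYR_PRO")
#' @export
relative_metrics <- function(rates, regime) {
  regime <- as_suit_regime(regime)
  r <- rate_values(rates)
  need_states(r, "ETS_FCCP", "relative metrics")
  fccp <- r[["ETS_FCCP"]]
  if (fccp <= 0) stop("ETS_FCCP rate must be > 0")
  out <- c()
  if ("OXPHOS_ADP" %in% names(r))
    out <- c(out, adp_over_fccp = 100 * r[["OXPHOS_ADP"]] / fccp)
  if ("ROTENONE" %in% names(r) && !regime$rotenone_pretreated)
    out <- c(out,
             rot_insensitive_pct = 100 * r[["ROTENONE"]] / fccp,
             complexI_channel_pct = 100 * (1 - r[["ROTENONE"]] / fccp))
  if ("ANTIMYCIN" %in% names(r))
    out <- c(out, aa_insensitive_pct = 100 * r[["ANTIMYCIN"]] / fccp)
  out
}

#' Decompose a tidy per-run rate table
#'
#' Convenience wrapper applying the site decomposition and capacities run
#' by run to a tidy table of extracted rates (as produced by the pipeline
#' or [simulate_cohort()] truth), returning tidy per-run results ready for
#' group statistics.
#'
#' @param rate_table data frame with columns `run_id`, `sex`,
#'   `preparation`, `regime`, `state` and a rate column.
#' @param assay `"respirometry"` (sites + OXPHOS/ETS capacity) or `"ros"`
#'   (leak-site contributions).
#' @param value column holding the rates.
#' @return list of data frames: `contributions` (per run x site) and, for
#'   respirometry, `capacities` (per run: `oxphos`, `ets`).
#' @export
decompose_rate_table <- function(rate_table,
                                 assay = c("respirometry", "ros"),
                                 value = "rate") {
  assay <- match.arg(assay)
  stopifnot(all(c("run_id", "regime", "state", value) %in% names(rate_table)))
  keys <- intersect(c("run_id", "sex", "preparation", "regime"),
                    names(rate_table))
  contribs <- list(); caps <- list()
  for (id in unique(rate_table$run_id)) {
    rr <- rate_table[rate_table$run_id == id, ]
    r <- stats::setNames(rr[[value]], rr$state)
    regime <- rr$regime[1]
    cc <- if (assay == "respirometry") respiration_contributions(r, regime)
          else ros_site_contributions(r, regime)
    cc <- cbind(rr[1, keys, drop = FALSE], cc, row.names = NULL)
    contribs[[id]] <- cc
    if (assay == "respirometry" &&
        all(c("LEAK", "OXPHOS_ADP", "ETS_FCCP", "ANTIMYCIN") %in% names(r)))
      caps[[id]] <- cbind(rr[1, keys, drop = FALSE],
                          data.frame(oxphos = oxphos_capacity(r),
                                     ets = as.numeric(ets_capacity(r))),
                          row.names = NULL)
  }
  out <- list(contributions = do.call(rbind, c(contribs,
                                               make.row.names = FALSE)))
  if (length(caps))
    out$capacities <- do.call(rbind, c(caps, make.row.names = FALSE))
  out
}
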