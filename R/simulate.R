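## --- synthetic instrument data with known ground truth ---------------------

#' Instrument trace container
#'
#' A thin wrapper around a two-column data frame (`time_s`, `signal`) with
#' channel metadata. Oxygraph traces carry oxygen concentration in nmol/mL,
#' fluorimeter traces arbitrary fluorescence units, spectrophotometer traces
#' absorbance.
#'
#' @param time_s sampling times in seconds, strictly increasing.
#' @param signal signal values, same length as `time_s`.
#' @param channel `"O2"`, `"fluorescence"` or `"absorbance"`.
#' @param units signal units label.
#' @param injections times (s) of instantaneous reoxygenation/injection
#'   steps contained in the trace, if any.
#' @return a data frame of class `instrument_trace`.
#' @export
instrument_trace <- function(time_s, signal, channel = c("O2", "fluorescence",
                                                         "absorbance"),
                             units = NULL, injections = numeric()) {
  channel <- match.arg(channel)
  if (length(time_s) != length(signal))
    stop("time_s and signal must have the same length")
  if (any(diff(time_s) <= 0))
    stop("time_s must be strictly increasing")
  if (is.null(units))
    units <- switch(channel, O2 = "nmol_per_mL", fluorescence = "AU",
                    absorbance = "A")
  structure(data.frame(time_s = time_s, signal = signal),
            channel = channel, units = units, injections = injections,
            class = c("instrument_trace", "data.frame"))
}

#' Ground truth for a simulated run
#'
#' @param state_rates named numeric vector: true steady rate per metabolic
#'   state, in the preparation's units.
#' @param noise_sd additive Gaussian noise SD on the signal.
#' @param drift linear signal drift per minute.
#' @param settle_tau exponential time constant (s) of the transition between
#'   consecutive states after a titration event.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(state_rates, noise_sd = 0, drift = 0,
                         settle_tau = 15) {
  stopifnot(is.numeric(state_rates), !is.null(names(state_rates)))
  if (any(!is.finite(state_rates)) || any(state_rates < 0))
    stop("all true rates must be finite and >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (all(c("ANTIMYCIN", "ETS_FCCP") %in% names(state_rates)) &&
      state_rates["ANTIMYCIN"] > state_rates["ETS_FCCP"])
    stop("ANTIMYCIN rate must not exceed ETS_FCCP rate")
  if (all(c("LEAK", "OXPHOS_ADP") %in% names(state_rates)) &&
      state_rates["LEAK"] > state_rates["OXPHOS_ADP"])
    stop("LEAK rate must not exceed OXPHOS_ADP rate")
  structure(list(state_rates = state_rates, noise_sd = noise_sd,
                 drift = drift, settle_tau = settle_tau),
            class = "ground_truth")
}

## run expr under a temporary RNG state seeded with `seed` (NULL = use the
## current stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

## cumulative integral (in signal units) at each sample time of a
## piecewise-constant slope (signal units per MINUTE, one per state) with
## exponential settling of time constant tau (s) after each event. Closed
## form, so integration is exact.
settle_cumulative <- function(event_times, slopes, time_s, tau) {
  K <- length(event_times)
  f_ev <- numeric(K)
  f_ev[1] <- slopes[1]                 # first state starts settled
  if (K > 1) for (k in 2:K) {
    dtk <- event_times[k] - event_times[k - 1]
    f_ev[k] <- slopes[k - 1] + (f_ev[k - 1] - slopes[k - 1]) *
      (if (tau > 0) exp(-dtk / tau) else 0)
  }
  seg_int <- function(k, t) {          # state k's integral from its event to t
    d <- f_ev[k] - slopes[k]
    dt <- t - event_times[k]
    base <- slopes[k] * dt
    if (tau > 0) base <- base + d * tau * (1 - exp(-dt / tau))
    base / 60
  }
  cum_ev <- numeric(K)
  if (K > 1) for (k in 2:K)
    cum_ev[k] <- cum_ev[k - 1] + seg_int(k - 1, event_times[k])
  st <- findInterval(time_s, event_times)
  cum_ev[st] + vapply(seq_along(time_s),
                      function(i) seg_int(st[i], time_s[i]), 0)
}

## concentration decline slope (signal units per minute) for one state rate
conc_slope_per_min <- function(rate, meta) {
  if (meta$preparation == "ISOLATED_MITO")
    rate * meta$protein_mg / meta$chamber_volume_mL      # nmol O2/min/mg -> nmol/mL/min
  else
    rate * meta$thorax_count * 60 / 1000                 # pmol O2/s/mL -> nmol/mL/min
}

#' Simulate an oxygraph trace for a SUIT run
#'
#' Oxygen concentration starts at 240 nmol/mL (isolated mitochondria) or
#' 500 nmol/mL (permeabilized muscle) and declines within each metabolic
#' state at the slope implied by the true rate, with an exponential settling
#' transition after each titration event, additive Gaussian noise, and
#' automatic reoxygenation steps back to the starting concentration whenever
#' the working floor (100 or 400 nmol/mL) is reached. The deterministic part
#' of the trace is integrated analytically, so on noiseless traces the
#' concentration drop over any interval equals the integrated flux exactly.
#'
#' @param protocol a [suit_protocol()].
#' @param truth a [ground_truth()] whose `state_rates` cover every protocol
#'   state, in the preparation's units.
#' @param meta a [run_meta()].
#' @param sampling_dt sampling interval in seconds (0.5-10).
#' @param seed integer seed; identical seed gives a bit-identical trace.
#' @return a list with elements `trace` ([instrument_trace()]) and `events`
#'   (data frame of titration events including any reoxygenation steps).
#' @examples
#' p <- suit_protocol("PYR_PRO", "ISOLATED_MITO")
#' tr <- ground_truth(c(LEAK = 15, OXPHOS_ADP = 132, CYTC_TEST = 134,
#'                      ETS_FCCP = 157, ROTENONE = 21, ANTIMYCIN = 7))
#' run <- simulate_oxygraph_trace(p, tr, run_meta("ISOLATED_MITO"), seed = 1)
#' @export
simulate_oxygraph_trace <- function(protocol, truth, meta, sampling_dt = 2,
                                    seed = NULL) {
  stopifnot(inherits(protocol, "suit_protocol"), inherits(truth, "ground_truth"),
            inherits(meta, "run_meta"))
  if (sampling_dt < 0.5 || sampling_dt > 10)
    stop("sampling_dt must be in [0.5, 10] seconds")
  missing_states <- setdiff(protocol$states, names(truth$state_rates))
  if (length(missing_states))
    stop("truth lacks rates for state(s): ",
         paste(missing_states, collapse = ", "))

  start <- if (meta$preparation == "ISOLATED_MITO") 240 else 500
  floor_c <- if (meta$preparation == "ISOLATED_MITO") 100 else 400
  ev <- protocol$events
  t_end <- max(ev$time_s) + protocol$state_duration_s
  time_s <- seq(0, t_end, by = sampling_dt)
  n <- length(time_s)

  slopes <- vapply(protocol$states, function(s)
    conc_slope_per_min(truth$state_rates[[s]], meta), 0)
  consumed <- settle_cumulative(ev$time_s, slopes, time_s, truth$settle_tau)
  conc <- start - consumed
  ## reoxygenation: instantaneous steps back to the start level
  inj_times <- numeric()
  offset <- 0
  for (i in seq_len(n)) {
    if (conc[i] + offset <= floor_c) {
      offset <- offset + (start - (conc[i] + offset))
      inj_times <- c(inj_times, time_s[i])
    }
    conc[i] <- conc[i] + offset
  }

  sig <- with_seed(seed, {
    out <- conc + truth$drift * time_s / 60
    if (truth$noise_sd > 0) out <- out + stats::rnorm(n, 0, truth$noise_sd)
    out
  })

  events <- ev
  if (length(inj_times)) {
    reox <- data.frame(time_s = inj_times, reagent = "reoxygenation",
                       final_concentration = NA_character_,
                       state = NA_character_, stringsAsFactors = FALSE)
    events <- rbind(events, reox)
    events <- events[order(events$time_s), ]
    rownames(events) <- NULL
  }
  list(trace = instrument_trace(time_s, sig, "O2", injections = inj_times),
       events = events)
}

#' Modulator condition in effect during a metabolic state
#'
#' Maps metabolic-state labels to the pharmacological condition under which
#' the chamber operates, which is the key used to select the matching
#' Amplex-red calibration curve (standard curves are fitted separately in
#' the presence of each OXPHOS modulator).
#'
#' @param state character vector of state labels.
#' @return character vector of condition labels.
#' @examples
#' state_condition(c("OLIGOMYCIN", "ETS_FCCP"))
#' @export
state_condition <- function(state) {
  cond <- c(LEAK = "substrate", OXPHOS_ADP = "adp", CYTC_TEST = "cytc",
            OLIGOMYCIN = "oligomycin", ETS_FCCP = "fccp",
            ROTENONE = "rotenone", ANTIMYCIN = "antimycin")
  unname(cond[state])
}

#' Simulate an Amplex-red fluorimeter trace
#'
#' Fluorescence accrues piecewise-linearly: within each metabolic state the
#' slope is `true rate x protein_mg x condition calibration slope` (AU/min),
#' with the same exponential settling, linear drift and Gaussian noise model
#' as the oxygraph simulator. With non-negative rates and zero noise the
#' trace is monotonically non-decreasing.
#'
#' @param protocol a [suit_protocol()] (normally `assay = "ros"`).
#' @param true_h2o2_rates named vector of true rates (pmol H2O2/min/mg) per
#'   protocol state.
#' @param calibration named list of [calibration_curve()] objects keyed by
#'   modulator condition (see [state_condition()] mapping); every protocol
#'   state must have one.
#' @param meta a [run_meta()].
#' @param sampling_dt sampling interval (s).
#' @param noise_sd,drift,settle_tau noise SD (AU), drift (AU/min) and
#'   settling constant (s).
#' @param seed integer seed.
#' @return list with `trace` and `events`, as for
#'   [simulate_oxygraph_trace()].
#' @export
simulate_fluorimeter_trace <- function(protocol, true_h2o2_rates, calibration,
                                       meta, sampling_dt = 2, noise_sd = 0,
                                       drift = 0, settle_tau = 15,
                                       seed = NULL) {
  stopifnot(inherits(protocol, "suit_protocol"), inherits(meta, "run_meta"))
  missing_states <- setdiff(protocol$states, names(true_h2o2_rates))
  if (length(missing_states))
    stop("true_h2o2_rates lacks state(s): ",
         paste(missing_states, collapse = ", "))
  conds <- state_condition(protocol$states)
  missing_cal <- protocol$states[!conds %in% names(calibration)]
  if (length(missing_cal))
    stop("missing calibration curve for state(s): ",
         paste(missing_cal, collapse = ", "),
         " (condition ", paste(unique(conds[!conds %in% names(calibration)]),
                               collapse = ", "), ")")

  slopes <- vapply(seq_along(protocol$states), function(i)
    true_h2o2_rates[[protocol$states[i]]] * meta$protein_mg *
      calibration[[conds[i]]]$slope, 0)   # AU per min

  ev <- protocol$events
  t_end <- max(ev$time_s) + protocol$state_duration_s
  time_s <- seq(0, t_end, by = sampling_dt)
  fl <- 10 + settle_cumulative(ev$time_s, slopes, time_s, settle_tau)

  sig <- with_seed(seed, {
    out <- fl + drift * time_s / 60
    if (noise_sd > 0) out <- out + stats::rnorm(length(fl), 0, noise_sd)
    out
  })
  list(trace = instrument_trace(time_s, sig, "fluorescence"),
       events = ev)
}

#' Simulate a spectrophotometric enzyme-assay trace
#'
#' Absorbance changes linearly at
#' `dA/dt = sign x epsilon x path x (activity x protein_mg / volume_mL) / 1000`
#' per minute (Beer-Lambert; activity in nmol/min/mg so the bracket is in
#' micromolar per minute). After `inhibitor_time` the slope is multiplied by
#' `residual_fraction`, emulating addition of the assay's diagnostic
#' inhibitor. `direction = "decrease"` assays (cytochrome c oxidase) have a
#' falling absorbance.
#'
#' @param assay an [assay_definition()] or assay name.
#' @param true_activity true specific activity (nmol product/min/mg).
#' @param inhibitor_time time (s) at which the inhibitor is added.
#' @param residual_fraction fraction of activity remaining after the
#'   inhibitor, in `[0, 1]`.
#' @param protein_mg,volume_mL,path_cm cuvette loading, volume and light
#'   path.
#' @param duration_s,sampling_dt trace length and sampling interval (s).
#' @param A0 starting absorbance.
#' @param noise_sd additive Gaussian noise SD (absorbance units).
#' @param seed integer seed.
#' @return an [instrument_trace()] with attribute `inhibitor_time`.
#' @export
simulate_spectro_trace <- function(assay, true_activity, inhibitor_time = 300,
                                   residual_fraction = 0, protein_mg = 0.08,
                                   volume_mL = 1, path_cm = 1,
                                   duration_s = 600, sampling_dt = 1,
                                   A0 = 0.2, noise_sd = 0, seed = NULL) {
  assay <- as_assay_definition(assay)
  if (residual_fraction < 0 || residual_fraction > 1)
    stop("residual_fraction must be in [0, 1]")
  stopifnot(true_activity >= 0, protein_mg > 0, volume_mL > 0, path_cm > 0)
  sgn <- if (assay$direction == "increase") 1 else -1
  slope <- sgn * assay$epsilon_mM_cm * path_cm *
    (true_activity * protein_mg / volume_mL) / 1000     # A per minute
  time_s <- seq(0, duration_s, by = sampling_dt)
  pre <- pmin(time_s, inhibitor_time)
  post <- pmax(time_s - inhibitor_time, 0)
  a <- A0 + slope * pre / 60 + slope * residual_fraction * post / 60
  sig <- with_seed(seed, {
    if (noise_sd > 0) a + stats::rnorm(length(a), 0, noise_sd) else a
  })
  out <- instrument_trace(time_s, sig, "absorbance")
  attr(out, "inhibitor_time") <- inhibitor_time
  attr(out, "assay") <- assay$name
  out
}

#' Cohort specification for the synthetic-data generator
#'
#' Defines the groups, per-group generative means/SDs and noise model of a
#' simulated cohort. Defaults reproduce the reference study conditions: the
#' bundled group summaries ([reference_state_rates()] for oxygraph cohorts,
#' [reference_h2o2_rates()] for fluorimetric cohorts), instrument-grade
#' signal noise of 0.1 nmol/mL (oxygraph) or 0.2 AU (fluorimeter), a 15 s
#' settling constant and 2 s sampling.
#'
#' @param groups data frame with columns `sex`, `preparation`, `regime`
#'   selecting which groups to simulate; default: every group present in
#'   `group_stats`.
#' @param n_per_group runs per group (>= 3).
#' @param assay `"respirometry"` or `"ros"`.
#' @param group_stats data frame of generative parameters with columns
#'   `sex`, `preparation`, `regime`, `state`, `mean`, `sd` (shape of
#'   [reference_state_rates()]).
#' @param efficiency_slope optional true OXPHOS-on-ETS regression slope; by
#'   default the slope implied by the group means,
#'   `(mean ADP - mean LEAK) / (mean FCCP - mean antimycin)`.
#' @param noise_sd,settle_tau,sampling_dt instrument noise SD, settling
#'   constant (s) and sampling interval (s).
#' @param state_duration_s spacing of titration events (s).
#' @param seed integer seed for the whole cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = NULL, n_per_group = 10,
                        assay = c("respirometry", "ros"),
                        group_stats = NULL, efficiency_slope = NULL,
                        noise_sd = NULL, settle_tau = 15, sampling_dt = 2,
                        state_duration_s = 240, seed = 1) {
  assay <- match.arg(assay)
  if (is.null(group_stats))
    group_stats <- if (assay == "respirometry") reference_state_rates()
                   else reference_h2o2_rates()
  if (is.null(groups))
    groups <- unique(group_stats[, c("sex", "preparation", "regime")])
  rownames(groups) <- NULL
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  if (any(group_stats$sd < 0)) stop("group SDs must be >= 0")
  for (i in seq_len(nrow(groups))) {
    sel <- group_stats$sex == groups$sex[i] &
      group_stats$preparation == groups$preparation[i] &
      group_stats$regime == groups$regime[i]
    if (!any(sel))
      stop("group_stats has no rows for group ",
           paste(groups[i, ], collapse = "/"))
  }
  if (is.null(noise_sd)) noise_sd <- if (assay == "respirometry") 0.1 else 0.2
  structure(list(groups = groups, n_per_group = as.integer(n_per_group),
                 assay = assay, group_stats = group_stats,
                 efficiency_slope = efficiency_slope, noise_sd = noise_sd,
                 settle_tau = settle_tau, sampling_dt = sampling_dt,
                 state_duration_s = state_duration_s, seed = as.integer(seed)),
            class = "cohort_spec")
}

## draw per-run true state rates for one group. Between-animal variation is
## a shared multiplicative factor (scaled to the FCCP coefficient of
## variation) plus state-level Gaussian noise; the OXPHOS capacity is
## generated around the target regression line on ETS capacity so that
## efficiency-slope analyses have a defined truth. Truncation keeps all
## rates non-negative.
draw_respirometry_rates <- function(stats_df, n, efficiency_slope = NULL) {
  m <- stats::setNames(stats_df$mean, stats_df$state)
  s <- stats::setNames(stats_df$sd, stats_df$state)
  has_rot <- "ROTENONE" %in% names(m)
  cv <- if (m[["ETS_FCCP"]] > 0) s[["ETS_FCCP"]] / m[["ETS_FCCP"]] else 0
  a <- pmax(stats::rnorm(n, 1, cv), 0.05)
  fccp <- m[["ETS_FCCP"]] * a
  leak <- pmax(stats::rnorm(n, m[["LEAK"]], s[["LEAK"]]), 0)
  aa <- pmax(stats::rnorm(n, m[["ANTIMYCIN"]], s[["ANTIMYCIN"]]), 0)
  aa <- pmin(aa, fccp)
  rot <- if (has_rot) {
    r <- pmax(stats::rnorm(n, m[["ROTENONE"]], s[["ROTENONE"]]), 0)
    pmin(pmax(r, aa), fccp)
  } else NULL
  m_ox <- m[["OXPHOS_ADP"]] - m[["LEAK"]]
  m_ets <- m[["ETS_FCCP"]] - m[["ANTIMYCIN"]]
  beta <- if (is.null(efficiency_slope)) m_ox / m_ets else efficiency_slope
  res_var <- s[["OXPHOS_ADP"]]^2 -
    beta^2 * (s[["ETS_FCCP"]]^2 + s[["ANTIMYCIN"]]^2) - s[["LEAK"]]^2
  sd_res <- sqrt(max(res_var, 0))
  ets <- fccp - aa
  oxphos <- pmax(m_ox + beta * (ets - m_ets) + stats::rnorm(n, 0, sd_res), 0)
  adp <- oxphos + leak
  out <- data.frame(run = seq_len(n), LEAK = leak, OXPHOS_ADP = adp,
                    ETS_FCCP = fccp, ANTIMYCIN = aa)
  if (has_rot) out$ROTENONE <- rot
  if ("CYTC_TEST" %in% names(m))
    out$CYTC_TEST <- pmax(stats::rnorm(n, m[["CYTC_TEST"]], s[["CYTC_TEST"]]), 0)
  attr(out, "true_slope") <- beta
  out
}

draw_ros_rates <- function(stats_df, n, shared_fraction = 0.5) {
  m <- stats::setNames(stats_df$mean, stats_df$state)
  s <- stats::setNames(stats_df$sd, stats_df$state)
  cvs <- ifelse(m > 0, s / m, 0)
  sigma_a <- sqrt(shared_fraction) * stats::median(cvs)
  a <- pmax(stats::rnorm(n, 1, sigma_a), 0.05)
  out <- data.frame(run = seq_len(n))
  for (st in names(m)) {
    resid_sd <- sqrt(max(s[[st]]^2 - (m[[st]] * sigma_a)^2, 0))
    out[[st]] <- pmax(m[[st]] * a + stats::rnorm(n, 0, resid_sd), 0)
  }
  out
}

#' Draw per-run true state rates for a group
#'
#' The rate-level generator behind [simulate_cohort()], exposed for
#' tests and for capacity/efficiency simulations that do not need traces.
#' Rates are drawn from truncated-at-zero Gaussians with the group's
#' mean/SD, tied together by a shared animal-level factor; for oxygraph
#' groups the OXPHOS capacity is generated around a true regression line on
#' ETS capacity (slope `efficiency_slope`, default implied by the means).
#'
#' @param stats_df rows of a group-statistics table for one single group
#'   (columns `state`, `mean`, `sd`).
#' @param n number of runs.
#' @param assay `"respirometry"` or `"ros"`.
#' @param efficiency_slope optional true slope (oxygraph assay only).
#' @param seed optional integer seed.
#' @return data frame, one row per run, one column per state; for the
#'   oxygraph assay the attribute `"true_slope"` records the generative
#'   slope.
#' @export
simulate_state_rates <- function(stats_df, n,
                                 assay = c("respirometry", "ros"),
                                 efficiency_slope = NULL, seed = NULL) {
  assay <- match.arg(assay)
  if (anyDuplicated(stats_df$state))
    stop("stats_df must describe a single group (duplicated states found)")
  with_seed(seed, {
    if (assay == "respirometry")
      draw_respirometry_rates(stats_df, n, efficiency_slope)
    else
      draw_ros_rates(stats_df, n)
  })
}

## default calibration-curve set used by simulated ROS cohorts: one curve
## per modulator condition, fitted from simulated standards
default_cohort_calibration <- function(conditions, standards_noise_sd = 0.5) {
  slopes <- c(substrate = 0.20, adp = 0.21, cytc = 0.20, oligomycin = 0.19,
              fccp = 0.22, rotenone = 0.20, antimycin = 0.18)
  pmol <- c(0, 100, 200, 400)
  out <- list()
  for (cond in conditions) {
    true_slope <- slopes[[cond]]
    fl <- 5 + true_slope * pmol +
      stats::rnorm(length(pmol), 0, standards_noise_sd)
    curve <- fit_calibration(data.frame(pmol = pmol, fluorescence = fl),
                             condition = cond)
    curve$true_slope <- true_slope
    out[[cond]] <- curve
  }
  out
}

#' Simulate a whole cohort with known ground truth
#'
#' Generates one instrument trace + event log per run for every group in the
#' specification, together with the true per-run state rates that produced
#' them. Respirometry cohorts produce oxygraph traces; ROS cohorts produce
#' Amplex-red fluorimeter traces plus the per-condition calibration curves
#' (fitted from simulated standards) needed to convert them back.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `suit_cohort` with elements `runs` (list of
#'   per-run lists: `run_id`, `group`, `meta`, `trace`, `events`, `truth`),
#'   `truth` (tidy data frame of true rates), `calibration` (ROS cohorts
#'   only) and `spec`.
#' @examples
#' spec <- cohort_spec(groups = data.frame(sex = "FEMALE",
#'                                         preparation = "ISOLATED_MITO",
#'                                         regime = "PYR_PRO"),
#'                     n_per_group = 3, seed = 7)
#' coh <- simulate_cohort(spec)
#' length(coh$runs)
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    runs <- list()
    truth_rows <- list()
    calibration <- NULL
    if (spec$assay == "ros")
      calibration <- default_cohort_calibration(
        unique(state_condition(.suit_states)))
    rid <- 0L
    for (g in seq_len(nrow(spec$groups))) {
      grp <- spec$groups[g, ]
      stats_df <- spec$group_stats[
        spec$group_stats$sex == grp$sex &
          spec$group_stats$preparation == grp$preparation &
          spec$group_stats$regime == grp$regime, ]
      protocol <- suit_protocol(grp$regime, grp$preparation,
                                assay = spec$assay,
                                state_duration_s = spec$state_duration_s)
      ## only states with generative parameters are simulated; drop template
      ## states that the group table does not cover (e.g. CYTC_TEST)
      keep <- protocol$states %in% stats_df$state
      protocol$events <- protocol$events[keep, , drop = FALSE]
      protocol$states <- protocol$states[keep]
      protocol$events$time_s <- spec$state_duration_s *
        (seq_len(nrow(protocol$events)) - 1L)

      rates <- simulate_state_rates(
        stats_df[match(protocol$states, stats_df$state), ],
        spec$n_per_group, assay = spec$assay,
        efficiency_slope = spec$efficiency_slope)
      meta <- if (grp$preparation == "ISOLATED_MITO")
        run_meta("ISOLATED_MITO", grp$sex,
                 protein_mg = if (spec$assay == "ros") 0.17 else 0.2)
      else run_meta("PERMEABILIZED_MUSCLE", grp$sex)

      for (i in seq_len(spec$n_per_group)) {
        rid <- rid + 1L
        true_rates <- stats::setNames(
          as.numeric(rates[i, protocol$states]), protocol$states)
        if (spec$assay == "respirometry") {
          tr <- ground_truth(true_rates, noise_sd = spec$noise_sd,
                             settle_tau = spec$settle_tau)
          sim <- simulate_oxygraph_trace(protocol, tr, meta,
                                         sampling_dt = spec$sampling_dt)
        } else {
          true_cal <- lapply(calibration, function(cu)
            list(slope = cu$true_slope))
          sim <- simulate_fluorimeter_trace(
            protocol, true_rates, true_cal, meta,
            sampling_dt = spec$sampling_dt, noise_sd = spec$noise_sd,
            settle_tau = spec$settle_tau)
        }
        run_id <- sprintf("run%03d", rid)
        runs[[run_id]] <- list(run_id = run_id, group = grp, meta = meta,
                               protocol = protocol, trace = sim$trace,
                               events = sim$events, truth = true_rates)
        truth_rows[[run_id]] <- data.frame(
          run_id = run_id, sex = grp$sex, preparation = grp$preparation,
          regime = grp$regime, state = names(true_rates),
          true_rate = as.numeric(true_rates), stringsAsFactors = FALSE)
      }
    }
    structure(list(runs = runs,
                   truth = do.call(rbind, c(truth_rows,
                                            make.row.names = FALSE)),
                   calibration = calibration, spec = spec),
              class = "suit_cohort")
  })
}

#' @export
print.suit_cohort <- function(x, ...) {
  cat(sprintf("Simulated %s cohort: %d runs in %d group(s)\n",
              x$spec$assay, length(x$runs), nrow(x$spec$groups)))
  invisible(x)
}
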