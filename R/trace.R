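## --- raw traces -> one steady-state rate per metabolic state ---------------

#' Compute a flux series from an instrument trace
#'
#' Differentiates the signal with a centred sliding-window least-squares
#' slope and converts to the preparation's flux units. For oxygen traces the
#' sign convention is consumption-positive:
#' isolated mitochondria report `slope(nmol/mL/min) x chamber_volume_mL /
#' protein_mg` (nmol O2/min/mg), permeabilized muscle
#' `slope(nmol/mL/min) x 1000 / 60 / thorax_count` (pmol O2/s/mL per
#' thorax). Fluorescence traces report the raw slope in AU/min
#' (accrual-positive). Windows spanning a reoxygenation injection are
#' masked (`NA`).
#'
#' @param trace an [instrument_trace()] (`O2` or `fluorescence` channel).
#' @param meta a [run_meta()]; required for oxygen unit conversion.
#' @param window_points width of the sliding window (odd, >= 5).
#' @param mask_times times (s) of instantaneous steps to mask; defaults to
#'   the injection times recorded on the trace.
#' @return a data frame of class `flux_series` (`time_s`, `flux`) with unit
#'   metadata in attributes.
#' @examples
#' p <- suit_protocol("PYR_PRO", "ISOLATED_MITO")
#' m <- run_meta("ISOLATED_MITO")
#' tr <- ground_truth(c(LEAK = 0, OXPHOS_ADP = 0, CYTC_TEST = 0,
#'                      ETS_FCCP = 0, ROTENONE = 0, ANTIMYCIN = 0))
#' run <- simulate_oxygraph_trace(p, tr, m, seed = 1)
#' fx <- compute_flux(run$trace, m)
#' range(fx$flux, na.rm = TRUE)   # zero flux
#' @export
compute_flux <- function(trace, meta, window_points = 9, mask_times = NULL) {
  stopifnot(inherits(trace, "instrument_trace"))
  if (window_points < 5 || window_points %% 2 == 0)
    stop("window_points must be odd and >= 5")
  t <- trace$time_s
  y <- trace$signal
  n <- length(t)
  if (any(diff(t) <= 0)) stop("trace time must be strictly increasing")
  if (n < window_points) stop("trace shorter than the sliding window")
  if (is.null(mask_times)) mask_times <- attr(trace, "injections")
  channel <- attr(trace, "channel")
  if (channel == "O2" && !inherits(meta, "run_meta"))
    stop("run_meta required to convert an O2 trace to flux units")

  ## rolling least-squares slope via cumulative sums (exact for irregular
  ## sampling)
  h <- (window_points - 1L) %/% 2L
  w <- window_points
  cx <- c(0, cumsum(t)); cy <- c(0, cumsum(y))
  cxx <- c(0, cumsum(t * t)); cxy <- c(0, cumsum(t * y))
  idx <- (h + 1L):(n - h)
  lo <- idx - h; hi <- idx + h
  S <- function(cs) cs[hi + 1L] - cs[lo]
  Sx <- S(cx); Sy <- S(cy); Sxx <- S(cxx); Sxy <- S(cxy)
  slope_s <- (w * Sxy - Sx * Sy) / (w * Sxx - Sx^2)   # signal units per second
  slope_min <- slope_s * 60

  flux <- rep(NA_real_, n)
  flux[idx] <- if (channel == "O2") {
    if (meta$preparation == "ISOLATED_MITO")
      -slope_min * meta$chamber_volume_mL / meta$protein_mg
    else
      -slope_min * 1000 / 60 / meta$thorax_count
  } else {
    slope_min
  }
  ## mask windows that straddle an instantaneous step
  for (tm in mask_times) {
    bad <- idx[t[lo] < tm & tm <= t[hi]]
    flux[bad] <- NA_real_
  }
  units <- if (channel != "O2") "AU_per_min"
           else if (meta$preparation == "ISOLATED_MITO") "nmol_O2_per_min_per_mg"
           else "pmol_O2_per_s_per_mL_per_thorax"
  structure(data.frame(time_s = t, flux = flux),
            units = units, channel = channel,
            window_points = window_points,
            guard_s = h * max(diff(t)),
            class = c("flux_series", "data.frame"))
}

#' Segment a flux series into per-state windows
#'
#' One window per metabolic state, opening `settle_s` seconds after the
#' state's titration event (to let the chamber mix and the signal settle)
#' and closing at the next state event or at the end of the trace.
#' Reoxygenation injections do not open windows. The event log must contain
#' the protocol's states in protocol order; any missing or out-of-order
#' state is an error.
#'
#' @param flux a `flux_series` from [compute_flux()].
#' @param events event data frame (`time_s`, `reagent`, `state`, ...);
#'   rows with `NA` state are ignored.
#' @param protocol the [suit_protocol()] the run followed.
#' @param settle_s settling time excluded at the head of each state (s).
#' @return data frame of class `state_windows`: `state`, `t_start`, `t_end`.
#' @export
segment_states <- function(flux, events, protocol, settle_s = 60) {
  stopifnot(inherits(protocol, "suit_protocol"))
  sev <- events[!is.na(events$state), , drop = FALSE]
  sev <- sev[order(sev$time_s), , drop = FALSE]
  if (!identical(sev$state, protocol$states)) {
    missing <- setdiff(protocol$states, sev$state)
    extra <- setdiff(sev$state, protocol$states)
    msg <- "event log does not match the protocol state sequence"
    if (length(missing)) msg <- paste0(msg, "; missing: ",
                                       paste(missing, collapse = ", "))
    if (length(extra)) msg <- paste0(msg, "; unexpected: ",
                                     paste(extra, collapse = ", "))
    if (!length(missing) && !length(extra))
      msg <- paste0(msg, "; found order ", paste(sev$state, collapse = " -> "),
                    " but expected ", paste(protocol$states, collapse = " -> "))
    stop(msg)
  }
  t_next <- c(sev$time_s[-1], max(flux$time_s))
  out <- data.frame(state = sev$state,
                    t_start = sev$time_s + settle_s,
                    t_end = t_next,
                    stringsAsFactors = FALSE)
  if (any(out$t_start >= out$t_end))
    stop("settle_s leaves no analysable window for state(s): ",
         paste(out$state[out$t_start >= out$t_end], collapse = ", "))
  class(out) <- c("state_windows", "data.frame")
  out
}

#' Extract the steady-state rate of one metabolic state
#'
#' Robust location estimate of the flux over the last `tail_s` seconds of
#' the state window (the plateau the instrument operator would read). Flux
#' samples whose sliding window reaches past the end of the state are
#' excluded, as are masked samples. A `"no_plateau"` QC flag is raised when
#' the flux still drifts by more than `plateau_threshold` (relative) across
#' the rate window.
#'
#' @param flux a `flux_series`.
#' @param window one row of [segment_states()] output (or a list with
#'   `state`, `t_start`, `t_end`).
#' @param estimator `"median"` (default) or `"trimmed_mean"` (10% trim).
#' @param tail_s length of the rate window at the end of the state (s).
#' @param plateau_threshold relative drift across the rate window above
#'   which the `"no_plateau"` flag is set.
#' @return an object of class `state_rate`: `state`, `value`, `units`,
#'   `n_points`, `window`, `qc_flags`.
#' @export
extract_state_rate <- function(flux, window,
                               estimator = c("median", "trimmed_mean"),
                               tail_s = 60, plateau_threshold = 0.10) {
  estimator <- match.arg(estimator)
  guard <- attr(flux, "guard_s")
  if (is.null(guard)) guard <- 0
  t_hi <- window$t_end - guard
  t_lo <- max(window$t_start, t_hi - tail_s)
  sel <- flux$time_s >= t_lo & flux$time_s <= t_hi & !is.na(flux$flux)
  n_pts <- sum(sel)
  if (n_pts < 5)
    stop("fewer than 5 clean flux samples in the rate window of state ",
         window$state)
  v <- flux$flux[sel]
  tt <- flux$time_s[sel]
  value <- if (estimator == "median") stats::median(v) else mean(v, trim = 0.1)
  qc <- character()
  dr <- stats::coef(stats::lm(v ~ tt))[2] * 60          # flux units per min
  rel_drift <- abs(dr * (t_hi - t_lo) / 60) / max(abs(value), 1e-12)
  if (is.finite(rel_drift) && rel_drift > plateau_threshold)
    qc <- c(qc, "no_plateau")
  structure(list(state = window$state, value = value,
                 units = attr(flux, "units"), n_points = n_pts,
                 window = c(t_start = t_lo, t_end = t_hi), qc_flags = qc),
            class = "state_rate")
}

#' @export
print.state_rate <- function(x, ...) {
  cat(sprintf("%s: %.4g %s (n = %d%s)\n", x$state, x$value, x$units,
              x$n_points,
              if (length(x$qc_flags)) paste0("; QC: ",
                                             paste(x$qc_flags, collapse = ","))
              else ""))
  invisible(x)
}

#' Cytochrome-c outer-membrane integrity check
#'
#' Exogenous cytochrome c stimulates respiration only when the outer
#' mitochondrial membrane is damaged; the absence of a sizeable stimulation
#' is the standard quality-control test for preparation integrity. The
#' verdict is `PASS` when `(after - before) / before` does not exceed
#' `threshold_fraction`, `FAIL` otherwise, and `INDETERMINATE` when the
#' pre-cytochrome-c rate is not positive.
#'
#' @param rate_before,rate_after_cytc rates before and after the cytochrome
#'   c addition ([extract_state_rate()] objects or plain numbers in
#'   identical units).
#' @param threshold_fraction maximal tolerated relative stimulation
#'   (default 0.15).
#' @return list with `verdict` (`"PASS"`, `"FAIL"` or `"INDETERMINATE"`)
#'   and `stimulation_fraction`.
#' @examples
#' cytc_integrity_check(130, 134)$verdict   # "PASS"
#' @export
cytc_integrity_check <- function(rate_before, rate_after_cytc,
                                 threshold_fraction = 0.15) {
  if (inherits(rate_before, "state_rate") &&
      inherits(rate_after_cytc, "state_rate") &&
      !identical(rate_before$units, rate_after_cytc$units))
    stop("rates have different units: ", rate_before$units, " vs ",
         rate_after_cytc$units)
  b <- if (inherits(rate_before, "state_rate")) rate_before$value else rate_before
  a <- if (inherits(rate_after_cytc, "state_rate")) rate_after_cytc$value
       else rate_after_cytc
  if (!is.finite(b) || b <= 0)
    return(list(verdict = "INDETERMINATE", stimulation_fraction = NA_real_))
  frac <- (a - b) / b
  list(verdict = if (frac <= threshold_fraction) "PASS" else "FAIL",
       stimulation_fraction = frac)
}
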