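p_iso <- suit_protocol("PYR_PRO", "ISOLATED_MITO")
m_iso <- run_meta("ISOLATED_MITO")

linear_trace <- function(decline_per_min, t_end = 600, dt = 2, start = 240) {
  t <- seq(0, t_end, by = dt)
  instrument_trace(t, start - decline_per_min * t / 60, "O2")
}

test_that("flux unit conversions invert the simulator's forward model", {
  # 1.2 nmol/mL/min decline, 2.2 mL, 0.2 mg -> 13.2 nmol O2/min/mg
  fx <- compute_flux(linear_trace(1.2), m_iso)
  expect_lt(max(abs(fx$flux - 13.2), na.rm = TRUE), 1e-6)
  expect_identical(attr(fx, "units"), "nmol_O2_per_min_per_mg")
  # 0.6 nmol/mL/min, permeabilized -> 0.6 x 1000/60 = 10 pmol O2/s/mL
  m_pm <- run_meta("PERMEABILIZED_MUSCLE")
  fx2 <- compute_flux(linear_trace(0.6, start = 500), m_pm)
  expect_lt(max(abs(fx2$flux - 10), na.rm = TRUE), 1e-6)
  expect_identical(attr(fx2, "units"), "pmol_O2_per_s_per_mL_per_thorax")
  # flat trace -> zero flux
  fx3 <- compute_flux(linear_trace(0), m_iso)
  expect_equal(max(abs(fx3$flux), na.rm = TRUE), 0)
})

test_that("compute_flux validates its inputs", {
  expect_error(compute_flux(linear_trace(1), m_iso, window_points = 4),
               "odd")
  expect_error(compute_flux(linear_trace(1), m_iso, window_points = 3),
               "odd|>= 5")
  expect_error(instrument_trace(c(0, 2, 2), c(1, 2, 3)),
               "strictly increasing")
  expect_error(compute_flux(linear_trace(1), meta = NULL), "run_meta")
})

test_that("states are segmented in protocol order with settle exclusion", {
  sim <- simulate_oxygraph_trace(p_iso, pyrpro_truth(), m_iso, seed = 1)
  fx <- compute_flux(sim$trace, m_iso)
  w <- segment_states(fx, sim$events, p_iso, settle_s = 60)
  expect_identical(w$state, p_iso$states)
  expect_equal(nrow(w), 6)
  expect_equal(w$t_start, p_iso$events$time_s + 60)
  expect_true(all(w$t_end[-6] == p_iso$events$time_s[-1]))

  g3p <- suit_protocol("G3P", "ISOLATED_MITO")
  tr_g <- ground_truth(c(LEAK = 30, OXPHOS_ADP = 68, CYTC_TEST = 69,
                         ETS_FCCP = 100, ANTIMYCIN = 8))
  sim_g <- simulate_oxygraph_trace(g3p, tr_g, m_iso, seed = 2)
  wg <- segment_states(compute_flux(sim_g$trace, m_iso), sim_g$events, g3p)
  expect_false("ROTENONE" %in% wg$state)

  # antimycin before FCCP: order violation
  ev_bad <- sim$events
  i_aa <- which(ev_bad$state %in% "ANTIMYCIN")
  i_fccp <- which(ev_bad$state %in% "ETS_FCCP")
  ev_bad$state[c(i_aa, i_fccp)] <- ev_bad$state[c(i_fccp, i_aa)]
  expect_error(segment_states(fx, ev_bad, p_iso), "order|sequence")
  # missing state
  ev_missing <- sim$events[!(sim$events$state %in% "ROTENONE"), ]
  expect_error(segment_states(fx, ev_missing, p_iso), "missing: ROTENONE")
})

test_that("rate extraction is exact on constant flux and robust to noise", {
  t <- seq(0, 300, 2)
  fx <- structure(data.frame(time_s = t, flux = rep(132, length(t))),
                  units = "nmol_O2_per_min_per_mg", guard_s = 8,
                  class = c("flux_series", "data.frame"))
  w <- list(state = "OXPHOS_ADP", t_start = 0, t_end = 300)
  r <- extract_state_rate(fx, w)
  expect_equal(r$value, 132)
  expect_gte(r$n_points, 5)
  expect_length(r$qc_flags, 0)

  set.seed(9)
  reps <- replicate(50, {
    fx$flux <- 132 + rnorm(length(t), 0, 5)
    extract_state_rate(fx, w)$value
  })
  expect_true(all(abs(reps - 132) < 2 + 3 * 5 / sqrt(30)))
  expect_lt(abs(mean(reps) - 132), 1)

  # linear drift with no plateau raises the QC flag
  fx$flux <- 100 + t
  r2 <- extract_state_rate(fx, w)
  expect_true("no_plateau" %in% r2$qc_flags)

  # too few clean points
  fx$flux[t > 250] <- NA
  fx$flux[t <= 250] <- NA
  expect_error(extract_state_rate(fx, w), "fewer than 5")
})

test_that("cytochrome-c integrity verdicts follow the stimulation fraction", {
  r <- cytc_integrity_check(130, 134)
  expect_identical(r$verdict, "PASS")
  expect_equal(r$stimulation_fraction, (134 - 130) / 130)
  expect_identical(cytc_integrity_check(100, 130)$verdict, "FAIL")
  expect_identical(cytc_integrity_check(0, 10)$verdict, "INDETERMINATE")
})

test_that("noiseless synthetic runs are recovered within 0.5% in all states", {
  for (prep in c("ISOLATED_MITO", "PERMEABILIZED_MUSCLE")) {
    for (rg in c("PYR_PRO", "G3P")) {
      p <- suit_protocol(rg, prep)
      rates <- if (rg == "PYR_PRO")
        c(LEAK = 42, OXPHOS_ADP = 265, CYTC_TEST = 268, ETS_FCCP = 300,
          ROTENONE = 34, ANTIMYCIN = 10)
      else
        c(LEAK = 81, OXPHOS_ADP = 140, CYTC_TEST = 141, ETS_FCCP = 169,
          ANTIMYCIN = 12)
      meta <- run_meta(prep)
      sim <- simulate_oxygraph_trace(p, ground_truth(rates), meta, seed = 3)
      fit <- suit_fit(sim$trace, sim$events, p, meta)
      expect_true(all(abs(coef(fit) - rates[names(coef(fit))]) /
                        rates[names(coef(fit))] < 0.005),
                  label = paste(prep, rg, "recovery within 0.5%"))
    }
  }
})

test_that("reoxygenation masking leaves noiseless rates unchanged", {
  # high rates force injections; recovery must still be exact
  high <- ground_truth(c(LEAK = 60, OXPHOS_ADP = 300, CYTC_TEST = 300,
                         ETS_FCCP = 350, ROTENONE = 30, ANTIMYCIN = 7))
  sim <- simulate_oxygraph_trace(p_iso, high, m_iso, seed = 1)
  expect_gt(length(attr(sim$trace, "injections")), 0)
  fit <- suit_fit(sim$trace, sim$events, p_iso, m_iso)
  expect_true(all(abs(coef(fit) - high$state_rates[names(coef(fit))]) /
                    high$state_rates[names(coef(fit))] < 0.005))
})
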