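p_iso <- suit_protocol("PYR_PRO", "ISOLATED_MITO")
m_iso <- run_meta("ISOLATED_MITO")

test_that("zero flux and zero noise give a flat trace at 240 nmol/mL", {
  tr <- ground_truth(setNames(rep(0, 6), p_iso$states))
  sim <- simulate_oxygraph_trace(p_iso, tr, m_iso, seed = 1)
  expect_equal(unique(sim$trace$signal), 240)
})

test_that("the OXPHOS segment declines at rate x protein / volume", {
  # 132 nmol O2/min/mg x 0.2 mg / 2.2 mL = 12.0 nmol/mL/min
  sim <- simulate_oxygraph_trace(p_iso, pyrpro_truth(), m_iso, seed = 1)
  tr <- sim$trace
  ev <- sim$events
  t_adp <- ev$time_s[ev$state %in% "OXPHOS_ADP"]
  t_next <- ev$time_s[ev$state %in% "CYTC_TEST"]
  sel <- tr$time_s >= t_adp + 120 & tr$time_s <= t_next  # settled part
  slope <- coef(lm(signal ~ time_s, data = tr[sel, ]))[2] * 60
  expect_equal(unname(slope), -12, tolerance = 1e-4)
})

test_that("identical seeds give bit-identical traces", {
  tr <- pyrpro_truth(noise_sd = 2)
  a <- simulate_oxygraph_trace(p_iso, tr, m_iso, seed = 42)
  b <- simulate_oxygraph_trace(p_iso, tr, m_iso, seed = 42)
  expect_identical(a$trace$signal, b$trace$signal)
  c <- simulate_oxygraph_trace(p_iso, tr, m_iso, seed = 43)
  expect_false(identical(a$trace$signal, c$trace$signal))
})

test_that("flux integrates exactly to the concentration drop (noise 0)", {
  # small protein load keeps the run above the reoxygenation floor
  m_small <- run_meta("ISOLATED_MITO", protein_mg = 0.05)
  tr0 <- pyrpro_truth(settle_tau = 0)   # instant transitions
  sim <- simulate_oxygraph_trace(p_iso, tr0, m_small, sampling_dt = 2,
                                 seed = 1)
  expect_length(attr(sim$trace, "injections"), 0)
  slopes <- tr0$state_rates[p_iso$states] * 0.05 / 2.2
  dur <- diff(c(p_iso$events$time_s, max(sim$trace$time_s)))
  expected_drop <- sum(slopes * dur / 60)
  expect_equal(sim$trace$signal[1] - tail(sim$trace$signal, 1),
               unname(expected_drop), tolerance = 1e-12)
  # exponential settling: drop over each settled sampling step still equals
  # the state slope x dt (within a state, far from its event)
  sim2 <- simulate_oxygraph_trace(p_iso, pyrpro_truth(), m_small, seed = 1)
  t_adp <- p_iso$events$time_s[p_iso$states == "OXPHOS_ADP"]
  i <- which(sim2$trace$time_s > t_adp + 150 & sim2$trace$time_s < t_adp + 200)
  step <- diff(sim2$trace$signal[i])
  expect_equal(step, rep(-132 * 0.05 / 2.2 * 2 / 60, length(step)),
               tolerance = 1e-4)
})

test_that("reoxygenation injections step back to the start level", {
  high <- ground_truth(c(LEAK = 60, OXPHOS_ADP = 300, CYTC_TEST = 300,
                         ETS_FCCP = 350, ROTENONE = 30, ANTIMYCIN = 7))
  sim <- simulate_oxygraph_trace(p_iso, high, m_iso, seed = 1)
  inj <- attr(sim$trace, "injections")
  expect_gt(length(inj), 0)
  expect_true(all(sim$trace$signal >= 100 - 1e-9))
  expect_equal(sim$trace$signal[match(inj, sim$trace$time_s)],
               rep(240, length(inj)))
  expect_true(all(inj %in% sim$events$time_s))
})

test_that("ground-truth invariants are enforced", {
  expect_error(ground_truth(c(LEAK = -1, OXPHOS_ADP = 5)), "finite and >= 0")
  expect_error(ground_truth(c(ETS_FCCP = 10, ANTIMYCIN = 20)), "ANTIMYCIN")
  expect_error(ground_truth(c(LEAK = 10, OXPHOS_ADP = 5)), "LEAK")
  expect_error(ground_truth(c(LEAK = 1), noise_sd = -1), "noise_sd")
})

test_that("fluorimeter traces are piecewise linear in rate x protein x slope", {
  p_ros <- suit_protocol("G3P", "ISOLATED_MITO", assay = "ros")
  cal <- exact_calibration()
  m <- run_meta("ISOLATED_MITO", protein_mg = 0.17)
  rates0 <- setNames(rep(0, length(p_ros$states)), p_ros$states)
  flat <- simulate_fluorimeter_trace(p_ros, rates0, cal, m, seed = 1)
  expect_equal(diff(range(flat$trace$signal)), 0)

  # 369 pmol/min/mg x 0.17 mg x 0.2 AU/pmol = 12.546 AU/min
  rates <- setNames(c(50, 100, 369, 235, 538), p_ros$states)
  sim <- simulate_fluorimeter_trace(p_ros, rates, cal, m, seed = 1)
  ev <- sim$events
  t0 <- ev$time_s[ev$state == "OLIGOMYCIN"]
  t1 <- ev$time_s[ev$state == "ETS_FCCP"]
  sel <- sim$trace$time_s >= t0 + 120 & sim$trace$time_s <= t1
  slope <- coef(lm(signal ~ time_s, data = sim$trace[sel, ]))[2] * 60
  expect_equal(unname(slope), 12.546, tolerance = 1e-4)
  # non-negative rates, no noise: monotone non-decreasing
  expect_true(all(diff(sim$trace$signal) >= -1e-12))
  # determinism
  sim2 <- simulate_fluorimeter_trace(p_ros, rates, cal, m, seed = 1)
  expect_identical(sim$trace$signal, sim2$trace$signal)
})

test_that("a missing condition calibration is rejected naming the state", {
  p_ros <- suit_protocol("PYR_PRO", "ISOLATED_MITO", assay = "ros")
  cal <- exact_calibration(conditions = c("substrate", "adp", "oligomycin",
                                          "fccp", "rotenone"))
  rates <- setNames(rep(10, length(p_ros$states)), p_ros$states)
  expect_error(
    simulate_fluorimeter_trace(p_ros, rates, cal, run_meta("ISOLATED_MITO")),
    "ANTIMYCIN")
})

test_that("spectrophotometer traces follow Beer-Lambert", {
  flat <- simulate_spectro_trace("NADH_CYTC", 0, seed = 1)
  expect_equal(diff(range(flat$signal)), 0)
  # activity 12.5 nmol/min/mg, 0.08 mg, 1 mL -> 1 uM/min -> dA/dt 0.0187
  tr <- simulate_spectro_trace("NADH_CYTC", 12.5, inhibitor_time = 300,
                               residual_fraction = 0, seed = 1)
  pre <- tr$time_s < 300
  dA <- coef(lm(tr$signal[pre] ~ tr$time_s[pre]))[2] * 60
  expect_equal(unname(dA), 0.0187, tolerance = 1e-9)
  # oxidase runs downhill
  ox <- simulate_spectro_trace("CYTC_OXIDASE", 12.5, seed = 1)
  expect_lt(tail(ox$signal, 1), ox$signal[1])
  # residual_fraction 1: inhibitor-insensitive == total, sensitive == 0
  full <- simulate_spectro_trace("NADH_CYTC", 12.5, residual_fraction = 1)
  fa <- fit_enzyme_assay(full, "NADH_CYTC")
  expect_equal(as.numeric(fa$sensitive), 0, tolerance = 1e-9)
  expect_error(simulate_spectro_trace("NADH_CYTC", 1, residual_fraction = 2),
               "residual_fraction")
})

test_that("cohorts with sd = 0 reproduce the group means exactly", {
  stats0 <- reference_state_rates()
  stats0$sd <- 0
  spec <- one_group_spec(n_per_group = 3, group_stats = stats0,
                         noise_sd = 0, seed = 5)
  coh <- simulate_cohort(spec)
  truth <- coh$truth
  ref <- reference_state_rates()
  for (st in unique(truth$state)) {
    expect_equal(unique(truth$true_rate[truth$state == st]),
                 ref$mean[ref$preparation == "ISOLATED_MITO" &
                            ref$regime == "PYR_PRO" & ref$state == st],
                 tolerance = 1e-12)
  }
})

test_that("cohort sampling recovers group means and never goes negative", {
  spec <- one_group_spec(n_per_group = 10, seed = 7)
  coh <- simulate_cohort(spec)
  truth <- coh$truth
  expect_true(all(truth$true_rate >= 0))
  adp <- truth$true_rate[truth$state == "OXPHOS_ADP"]
  expect_lt(abs(mean(adp) - 132), 2 * 58 / sqrt(10))
  # determinism of the whole dataset
  coh2 <- simulate_cohort(one_group_spec(n_per_group = 10, seed = 7))
  expect_identical(coh$truth, coh2$truth)
  expect_identical(coh$runs[[3]]$trace$signal, coh2$runs[[3]]$trace$signal)
})

test_that("cohorts honour a prescribed true efficiency slope", {
  tab <- reference_state_rates()
  g <- tab[tab$preparation == "PERMEABILIZED_MUSCLE" & tab$regime == "PYR_PRO", ]
  set.seed(31)
  slopes <- replicate(60, {
    r <- simulate_state_rates(g, 13, efficiency_slope = 0.74)
    efficiency_analysis(r$OXPHOS_ADP - r$LEAK,
                        r$ETS_FCCP - r$ANTIMYCIN)$efficiency_slope
  })
  expect_lt(abs(mean(slopes) - 0.74), 2 * sd(slopes) / sqrt(60))
})

test_that("cohort specs validate their inputs", {
  expect_error(cohort_spec(n_per_group = 2), "n_per_group")
  bad <- reference_state_rates()
  bad$sd[1] <- -1
  expect_error(cohort_spec(group_stats = bad), "SDs")
  expect_error(
    cohort_spec(groups = data.frame(sex = "FEMALE",
                                    preparation = "PERMEABILIZED_MUSCLE",
                                    regime = "PC_MAL")),
    "no rows")
})
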