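test_that("respiration decomposes by the inhibitor-subtraction formulas", {
  # female isolated mitochondria, pyruvate+proline group means
  cc <- respiration_contributions(
    c(ETS_FCCP = 157, ROTENONE = 21, ANTIMYCIN = 7), "PYR_PRO")
  expect_equal(cc$value[cc$site == "CI_PYRPRO"], 136)
  expect_equal(cc$value[cc$site == "PRODH"], 14)
  # palmitoylcarnitine+malate: ETF:QOR = rotenone - antimycin
  cp <- respiration_contributions(
    c(ETS_FCCP = 8, ROTENONE = 1, ANTIMYCIN = 1), "PC_MAL")
  expect_equal(cp$value[cp$site == "ETFQOR"], 0)
  expect_equal(cp$value[cp$site == "CI_PCMAL"], 7)
  # G3P: single G3PDH site
  cg <- respiration_contributions(c(ETS_FCCP = 100, ANTIMYCIN = 8), "G3P")
  expect_equal(cg$value, 92)
  expect_identical(cg$site, "G3PDH")
  # rotenone == FCCP: complex I contribution vanishes
  c0 <- respiration_contributions(
    c(ETS_FCCP = 50, ROTENONE = 50, ANTIMYCIN = 5), "PYR_PRO")
  expect_equal(c0$value[c0$site == "CI_PYRPRO"], 0)
  # missing states are errors
  expect_error(respiration_contributions(c(ETS_FCCP = 157), "PYR_PRO"),
               "ROTENONE")
})

test_that("the conservation identity holds exactly for any decomposition", {
  set.seed(13)
  for (i in 1:50) {
    rg <- sample(c("PYR_PRO", "G3P", "PC_MAL"), 1)
    r <- c(ETS_FCCP = runif(1, 0, 300), ROTENONE = runif(1, 0, 100),
           ANTIMYCIN = runif(1, 0, 50))
    cc <- respiration_contributions(r, rg)
    expect_equal(sum(cc$value) + r[["ANTIMYCIN"]], r[["ETS_FCCP"]],
                 tolerance = 1e-12)
    expect_equal(attr(cc, "conservation_residual"), 0, tolerance = 1e-12)
  }
})

test_that("negative contributions are flagged, never clamped", {
  cc <- respiration_contributions(
    c(ETS_FCCP = 10, ROTENONE = 15, ANTIMYCIN = 2), "PYR_PRO")
  expect_equal(cc$value[cc$site == "CI_PYRPRO"], -5)
  expect_identical(cc$flag[cc$site == "CI_PYRPRO"], "negative_contribution")
})

test_that("increasing FCCP strictly increases the complex-I share", {
  vals <- sapply(c(100, 150, 200, 250), function(f)
    respiration_contributions(
      c(ETS_FCCP = f, ROTENONE = 21, ANTIMYCIN = 7), "PYR_PRO")$value[1])
  expect_true(all(diff(vals) > 0))
})

test_that("ROS leak sites follow the inverted subtraction orientation", {
  # female pyruvate+proline group means
  rc <- ros_site_contributions(
    c(ETS_FCCP = 207, ROTENONE = 260, ANTIMYCIN = 685), "PYR_PRO")
  expect_equal(rc$value[rc$site == "IF_PYRPRO"], 53)
  expect_equal(rc$value[rc$site == "PRODH_OTHER"], 425)
  # female G3P: FCCP state is the rotenone-present baseline
  rg <- ros_site_contributions(c(ETS_FCCP = 235, ANTIMYCIN = 538), "G3P")
  expect_equal(rg$value, 303)
  expect_identical(rg$site, "G3PDH_OTHER")
  # rotenone == FCCP: no site-IF signal
  r0 <- ros_site_contributions(
    c(ETS_FCCP = 100, ROTENONE = 100, ANTIMYCIN = 150), "PC_MAL")
  expect_equal(r0$value[r0$site == "IF_PCMAL"], 0)
})

test_that("capacities reproduce the published derived values", {
  expect_equal(oxphos_capacity(c(LEAK = 42, OXPHOS_ADP = 265)), 223)
  expect_equal(oxphos_capacity(c(LEAK = 81, OXPHOS_ADP = 140)), 59)
  expect_equal(oxphos_capacity(c(LEAK = 2, OXPHOS_ADP = 6)), 4)
  expect_equal(ets_capacity(c(ETS_FCCP = 300, ANTIMYCIN = 10)), 290)
  expect_equal(ets_capacity(c(ETS_FCCP = 5, ANTIMYCIN = 5)), 0)
  neg <- ets_capacity(c(ETS_FCCP = 5, ANTIMYCIN = 8))
  expect_equal(as.numeric(neg), -3)
  expect_identical(attr(neg, "flag"), "negative_capacity")
  expect_error(oxphos_capacity(c(OXPHOS_ADP = 5)), "LEAK")
})

test_that("efficiency analysis returns slope, correlation and its type", {
  x <- c(100, 150, 200, 250, 300)
  e <- efficiency_analysis(x, x)
  expect_equal(e$efficiency_slope, 1)
  expect_equal(e$corr_coeff, 1)
  expect_identical(e$corr_type, "spearman")  # n < 8 forces the rank branch
  expect_error(efficiency_analysis(1:3, 1:3), "at least 4")
  expect_error(efficiency_analysis(c(1, 2, 3, 4), rep(5, 4)),
               "zero variance")
  # recovery of a known slope at study scale
  tab <- reference_state_rates()
  g <- tab[tab$preparation == "PERMEABILIZED_MUSCLE" & tab$regime == "PYR_PRO", ]
  r <- simulate_state_rates(g, 13, efficiency_slope = 0.74, seed = 17)
  e2 <- efficiency_analysis(r$OXPHOS_ADP - r$LEAK, r$ETS_FCCP - r$ANTIMYCIN)
  expect_lt(abs(e2$efficiency_slope - 0.74), 2 * e2$slope_se)
  expect_true(e2$corr_type %in% c("pearson", "spearman"))
})

test_that("relative metrics reproduce the published percentages", {
  rm <- relative_metrics(c(OXPHOS_ADP = 265, ETS_FCCP = 300, ROTENONE = 34,
                           ANTIMYCIN = 10), "PYR_PRO")
  expect_equal(rm[["adp_over_fccp"]], 88.33, tolerance = 1e-4)
  expect_equal(rm[["complexI_channel_pct"]], 100 * (1 - 34 / 300))
  expect_equal(rm[["rot_insensitive_pct"]], 100 * 34 / 300)
  expect_equal(rm[["aa_insensitive_pct"]], 100 * 10 / 300)
  expect_equal(relative_metrics(c(OXPHOS_ADP = 50, ETS_FCCP = 50),
                                "PYR_PRO")[["adp_over_fccp"]], 100)
  expect_error(relative_metrics(c(ETS_FCCP = 0), "PYR_PRO"), "> 0")
  # G3P runs report no rotenone metrics
  rg <- relative_metrics(c(OXPHOS_ADP = 140, ETS_FCCP = 169, ANTIMYCIN = 12),
                         "G3P")
  expect_false("rot_insensitive_pct" %in% names(rg))
})

test_that("tidy rate tables decompose run by run", {
  tab <- data.frame(run_id = rep(c("a", "b"), each = 5),
                    sex = "FEMALE", preparation = "ISOLATED_MITO",
                    regime = "PYR_PRO",
                    state = rep(c("LEAK", "OXPHOS_ADP", "ETS_FCCP",
                                  "ROTENONE", "ANTIMYCIN"), 2),
                    rate = c(15, 132, 157, 21, 7, 10, 100, 120, 18, 5),
                    stringsAsFactors = FALSE)
  d <- decompose_rate_table(tab)
  expect_equal(nrow(d$contributions), 4)
  expect_equal(d$contributions$value[d$contributions$run_id == "a" &
                                       d$contributions$site == "CI_PYRPRO"],
               136)
  expect_equal(d$capacities$oxphos, c(117, 90))
  expect_equal(d$capacities$ets, c(150, 115))
})
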