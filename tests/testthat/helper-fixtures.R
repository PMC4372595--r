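# shared fixture builders (everything generated in code; no data files)

# canonical female isolated-mitochondria PYR_PRO truth, group-mean rates
pyrpro_truth <- function(noise_sd = 0, ...) {
  ground_truth(c(LEAK = 15, OXPHOS_ADP = 132, CYTC_TEST = 134,
                 ETS_FCCP = 157, ROTENONE = 21, ANTIMYCIN = 7),
               noise_sd = noise_sd, ...)
}

# exact calibration curves (slope AU/pmol, intercept 5) for every condition
exact_calibration <- function(slope = 0.2,
                              conditions = c("substrate", "adp", "cytc",
                                             "oligomycin", "fccp",
                                             "rotenone", "antimycin")) {
  out <- lapply(conditions, function(cond) {
    cu <- fit_calibration(
      data.frame(pmol = c(0, 100, 200),
                 fluorescence = 5 + slope * c(0, 100, 200)),
      condition = cond)
    cu
  })
  names(out) <- conditions
  out
}

# one-group cohort spec shortcut
one_group_spec <- function(regime = "PYR_PRO",
                           preparation = "ISOLATED_MITO", ...) {
  cohort_spec(groups = data.frame(sex = "FEMALE", preparation = preparation,
                                  regime = regime, stringsAsFactors = FALSE),
              ...)
}
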