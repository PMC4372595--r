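# suitflux

Mitochondrial physiology from raw respirometry and fluorimetry traces:
an R pipeline for substrate–uncoupler–inhibitor titration (SUIT)
experiments on insect flight muscle.

## The problem

High-resolution respirometry of *Aedes aegypti* flight muscle — isolated
mitochondria or single permeabilized thoraxes — records oxygen
concentration while substrates and OXPHOS modulators are titrated in
sequence: substrates (leak state), ADP (OXPHOS state), cytochrome *c*
(outer-membrane integrity check), FCCP (maximal uncoupled flux), rotenone
(complex I blockade) and antimycin A (complex III blockade). A parallel
Amplex-red assay records H₂O₂ release under oligomycin, FCCP, rotenone and
antimycin A. The scientific quantities of interest are not the raw traces
but derived ones:

* **Steady-state fluxes** per metabolic state, *J*\_leak, *J*\_ADP,
  *J*\_FCCP, *J*\_Rot, *J*\_AA (nmol O₂·min⁻¹·mg⁻¹ for isolated
  mitochondria, pmol O₂·s⁻¹·mL⁻¹·thorax⁻¹ for permeabilized muscle).
* **Electron-entry site contributions** by inhibitor subtraction:
  with pyruvate + proline, complex I = *J*\_FCCP − *J*\_Rot and proline
  dehydrogenase (ProDH) = *J*\_Rot − *J*\_AA; with glycerol-3-phosphate
  (rotenone-pretreated), G3PDH = *J*\_FCCP − *J*\_AA; with
  palmitoylcarnitine + malate, ETF:QOR = *J*\_Rot − *J*\_AA. The identity
  Σ contributions + *J*\_AA = *J*\_FCCP holds exactly and is asserted on
  every decomposition.
* **Superoxide/H₂O₂ topology** with the opposite orientation (blocking
  downstream of a leak site raises its output): site I\_F of complex I =
  *J*\_Rot − *J*\_FCCP; ProDH/G3PDH/ETF:QOR "+ other dehydrogenases" =
  *J*\_AA minus the preceding state.
* **Bioenergetic capacity and efficiency**: OXPHOS capacity =
  *J*\_ADP − *J*\_leak, ETS capacity = *J*\_FCCP − *J*\_AA, and the
  efficiency is the slope of per-run OXPHOS capacity regressed on ETS
  capacity.
* **Enzyme activities** from spectrophotometric slopes via Beer–Lambert
  (ε = 18.7 mM⁻¹·cm⁻¹ for cytochrome-*c* assays at 550 nm, 13.6 for the
  citrate-synthase/DTNB assay at 412 nm), as inhibitor-sensitive rates,
  optionally normalized by citrate synthase.

Statistics follow a normality-gated scheme (D'Agostino–Pearson):
Student's *t* / ANOVA + Tukey on the parametric branch, Mann–Whitney /
Kruskal–Wallis + Dunn otherwise, Grubbs outlier screening, ANCOVA for
slope homogeneity and mass-scaling regressions.

Because no raw traces are deposited with the reference tables, the package
includes a first-class simulator (`simulate_oxygraph_trace()`,
`simulate_fluorimeter_trace()`, `simulate_spectro_trace()`,
`simulate_cohort()`) that generates instrument data with known ground
truth, so the entire pipeline is testable end to end by parameter
recovery.

## Worked example

Simulate one female isolated-mitochondria run at the reference group means
(leak 15, ADP 132, FCCP 157, rotenone 21, antimycin 7 nmol O₂/min/mg),
then fit it:

```r
library(suitflux)

p   <- suit_protocol("PYR_PRO", "ISOLATED_MITO")
m   <- run_meta("ISOLATED_MITO", sex = "FEMALE")      # 0.2 mg, 2.2 mL, 27.5 C
tru <- ground_truth(c(LEAK = 15, OXPHOS_ADP = 132, CYTC_TEST = 134,
                      ETS_FCCP = 157, ROTENONE = 21, ANTIMYCIN = 7),
                    noise_sd = 0.1)
run <- simulate_oxygraph_trace(p, tru, m, seed = 1)
fit <- suit_fit(run$trace, run$events, p, m)
summary(fit)
```

```
SUIT respirometry fit: PYR_PRO, ISOLATED_MITO (FEMALE)
      state    rate                  units         qc
       LEAK  15.580 nmol_O2_per_min_per_mg no_plateau
 OXPHOS_ADP 131.400 nmol_O2_per_min_per_mg
  CYTC_TEST 133.900 nmol_O2_per_min_per_mg
   ETS_FCCP 157.000 nmol_O2_per_min_per_mg
   ROTENONE  21.710 nmol_O2_per_min_per_mg no_plateau
  ANTIMYCIN   6.551 nmol_O2_per_min_per_mg
Cytochrome-c integrity: PASS (stimulation 1.9%)

Site contributions (inhibitor subtraction):
      site  value                  units flag
 CI_PYRPRO 135.30 nmol_O2_per_min_per_mg
     PRODH  15.16 nmol_O2_per_min_per_mg
```

Reading the output: the fitted state rates recover the generative truth to
within the instrument noise; cytochrome *c* stimulated respiration by only
1.9 % (< 15 %), so the outer membrane is intact; complex I carries
~135 of the 157 nmol O₂/min/mg uncoupled flux and ProDH ~15, with the
antimycin-resistant residual closing the balance exactly. `no_plateau`
flags mark states whose flux still drifted more than 10 % across the rate
window — expected for near-zero fluxes at this noise level, and advisory
only.

`suit_fit` objects support `coef()`, `predict()`, `residuals()`,
`plot()`, `simulate()` and `summary()`. Cohort-level work goes through
`simulate_cohort()` → `process_cohort()` → `decompose_rate_table()` /
`efficiency_analysis()` / `compare_groups()`.

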