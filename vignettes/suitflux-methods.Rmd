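---
title: "Methods: SUIT flux extraction, site decomposition and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SUIT flux extraction, site decomposition and the synthetic cohort model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suitflux)
```

This vignette documents the models, estimators and numerical choices
behind `suitflux`, in the spirit of a statistical-methods appendix: what
is assumed, what is estimated, which defaults matter, and what the
package's passing tests do and do not demonstrate about real data.

## 1. The measurement model

A SUIT (substrate–uncoupler–inhibitor titration) run produces a signal
$y(t)$ — oxygen concentration (nmol/mL), resorufin fluorescence (AU) or
absorbance — sampled every 0.5–10 s, plus an event log of titrations. The
package models the signal as **piecewise steady**: within each metabolic
state $s$ the deterministic flux is constant, and after each titration the
flux relaxes exponentially from its previous value with time constant
$\tau$ (chamber mixing + chemistry). For oxygen,

$$ y(t) = y_0 - \int_0^t J_c(u)\,du + \varepsilon(t), \qquad
   \varepsilon(t) \sim N(0, \sigma^2)\ \text{i.i.d.}, $$

where $J_c$ is the volumetric consumption rate. The per-state fluxes are
the estimands. Unit conversions are fixed by chamber geometry: isolated
mitochondria $J = J_c \cdot V_{chamber} / m_{protein}$
(nmol O₂·min⁻¹·mg⁻¹ with the defaults $V = 2.2$ mL, $m \approx 0.2$ mg);
permeabilized muscle $J = J_c \cdot 1000/60$ per thorax
(pmol O₂·s⁻¹·mL⁻¹·thorax⁻¹). Oxygen is kept inside a working regime
(240→100 nmol/mL for isolated mitochondria, ~500→400 for muscle) by
instantaneous reoxygenation steps.

**Assumptions.** Steady plateaus exist within each state (checked by a QC
flag, not assumed silently); noise is additive and state-independent;
reoxygenation is instantaneous; back-diffusion and sensor drift beyond a
linear term are not modelled.

## 2. Flux extraction (`suit_fit`)

1. **Derivative.** `compute_flux()` differentiates $y$ with a centred
   sliding-window least-squares slope (default 9 points). The rolling
   regression is computed from zero-padded cumulative sums, which is exact
   for irregular sampling. Windows that straddle a reoxygenation step are
   masked.
2. **Segmentation.** `segment_states()` opens one window per state,
   from `settle_s` (default 60 s) after the state's event to the next
   state event. Event logs that miss a state or disorder the sequence are
   rejected, not repaired.
3. **Rate.** `extract_state_rate()` takes a robust location estimate
   (median by default; 10 %-trimmed mean available) over the final
   `tail_s` = 60 s of the window, excluding samples whose derivative
   window reaches past the state boundary. A relative drift > 10 % across
   the rate window raises the advisory `no_plateau` flag.
4. **QC.** When a cytochrome-*c* state is present, stimulation of more
   than 15 % over the preceding ADP rate fails the outer-membrane
   integrity check; the state is never used in decompositions.

Defaults (9-point window, 60 s settle, 60 s rate window, 10 % drift
threshold, 15 % cytochrome-*c* threshold) are stated here precisely
because the underlying experiment reports none of them; they are justified
by the recovery property below and all are overridable arguments.

**Recovery property.** On noiseless simulated runs the extracted rates
match truth to < 0.5 % in every state and preparation — including runs
with reoxygenation steps — because the estimator chain inverts the
simulator's forward model exactly (the tests assert this). With the
settling constant τ = 15 s, the 60 s settle plus the end-of-window
placement of the rate window leaves transients of order $e^{-12}$.

## 3. Decomposition and bioenergetics

Respiration decomposes by within-run subtraction (sequential inhibition
on the same sample): complex I = FCCP − rotenone and ProDH = rotenone −
antimycin (pyruvate + proline); G3PDH = FCCP − antimycin (G3P runs, which
are rotenone-pretreated and therefore have no separate rotenone state);
complex I and ETF:QOR analogously for palmitoylcarnitine + malate. The
conservation identity (contributions + antimycin residual = FCCP) holds
by construction and is still asserted on every call as a guard against
unit mix-ups. Negative contributions are flagged, never clamped:
truncation would bias cohort means and hide QC failures.

H₂O₂ topology uses the opposite orientation — a site's contribution is
the *later*, more inhibited rate minus the earlier one — because blocking
electron flow downstream of a leak site increases its superoxide output.
The site I$_F$ convention (rotenone state minus FCCP state) was fixed
deliberately: subtraction conventions for this contrast are written
inconsistently across published protocols, and this orientation is the
one consistent with ROS biochemistry under uncoupled conditions and with
the reference values (e.g. 260 − 207 = 53 > 0). It is a documented
convention, not a
silent resolution. Sites beyond I$_F$ cannot be separated by this design
and are reported as "+ other dehydrogenases".

OXPHOS capacity (ADP − leak) and ETS capacity (FCCP − antimycin) are
computed per run; `efficiency_analysis()` regresses OXPHOS on ETS
capacity across runs, reporting the slope (the bioenergetic efficiency),
its SE and p, and a correlation coefficient whose type follows the
normality gate (Pearson if both margins pass, else Spearman).

## 4. The synthetic cohort model

`simulate_cohort()` defines the study conditions; its defaults are the
published group means ± SD bundled in `reference_state_rates()` /
`reference_h2o2_rates()` (female oxygraph groups; both sexes for H₂O₂).
Per run $i$ in a group:

* a shared animal factor $a_i \sim N(1, cv_{FCCP})$ (truncated > 0)
  scales the FCCP rate, inducing the between-state correlation that makes
  efficiency-slope analysis meaningful without inventing a covariance the
  reference tables do not report;
* leak, rotenone and antimycin rates are truncated-at-zero Gaussians with
  the group's mean/SD, ordered by clamping (antimycin ≤ FCCP, antimycin ≤
  rotenone ≤ FCCP);
* OXPHOS capacity is generated around a *true regression line* on ETS
  capacity, $OX_i = \bar{OX} + \beta\,(ETS_i - \bar{ETS}) + e_i$, with
  $\beta$ either supplied (`efficiency_slope`) or implied by the means,
  and $\mathrm{sd}(e)$ chosen so the marginal ADP SD matches the table.
  With the published means/SDs this reproduces the published slope
  standard errors (≈ 0.13 vs the printed 0.14 for pyruvate + proline
  muscle) and correlations (≈ 0.86 vs 0.83) without further tuning.
* H₂O₂ groups use the shared factor (50 % of median squared CV) plus
  state-level residuals matched to the marginal SDs.

No within-run noise magnitude accompanies the reference tables; the
defaults —
0.1 nmol/mL oxygen noise at 2 s sampling and 0.2 AU fluorescence noise —
are instrument-grade values for a high-resolution oxygraph and a
spectrofluorimeter, set once and overridable (`noise_sd`). The settling
constant τ = 15 s is a plausible mixing time and is synthetic-only: no
claim about real chamber kinetics is attached to it.

**What the generator does *not* emulate:** oxygen back-diffusion, sensor
drift/recalibration, chemical side reactions, non-Gaussian animal
variation, within-state metabolic drift (substrate depletion), or
fluorophore photobleaching. Passing recovery tests therefore demonstrate
the correctness of the estimator chain under the stated noise model, not
robustness to every instrument pathology.

**Truncation effects.** Truncating rates at zero is part of the study
conditions. For groups whose mean is within ~1 SD of zero
(palmitoylcarnitine states at 1 ± 1) the truncated law's mean exceeds the
nominal mean by up to ~0.3 units, a deterministic generator property, and
the OXPHOS-capacity truncation attenuates the recovered G3P muscle
efficiency slope by roughly 5–8 % (0.46 → ≈ 0.43). Parameter-recovery
tests therefore compare pipeline estimates against the *realized* ground
truth of each simulated cohort; comparisons against the nominal table
means are made where the margin (2 SEM) dominates these effects.

## 5. Calibration and enzymology

Amplex-red fluorescence is converted through per-condition standard
curves (`fit_calibration()`: OLS of fluorescence on pmol H₂O₂, slope > 0
enforced, ≥ 3 distinct standards), one curve per OXPHOS modulator — a
pooled curve is deliberately unsupported because the modulators perturb
the fluorophore response. `h2o2_rate()` then applies
$J_{H_2O_2} = \dot F / (\text{slope} \cdot m_{protein})$, and the
round-trip with the simulator is exact at zero noise (tested).

Spectrophotometric activities use Beer–Lambert,
$J = |\dot A| / (\varepsilon \ell) \cdot V \cdot 1000 / m$, with
ε = 18.7 mM⁻¹cm⁻¹ at 550 nm for all cytochrome-*c* assays. For the
citrate synthase assay the package fixes the standard literature DTNB/TNB
coefficient, 13.6 mM⁻¹cm⁻¹ at 412 nm, configurable via
`assay_definition(epsilon_mM_cm=)`. Inhibitor-sensitive activities are
total − insensitive, with negative results flagged
(`inhibitor_paradox`) rather than clamped. CS normalization is computed
per sample; cohort summaries must average per-sample ratios, not divide
group means.

## 6. Statistical scheme

* **Normality gate.** D'Agostino–Pearson omnibus $K^2$ (skewness z +
  kurtosis z; implemented from the standard transformations and verified
  against an independent implementation to 10 decimals). The test is
  undefined for very small samples, so any group with n < 8 forces the
  nonparametric branch — consistent with the many n = 3–6 groups in the
  reference tables being analysed nonparametrically.
* **Comparisons.** Two groups: Student's *t* (pooled variance) or
  Mann–Whitney. More: one-way ANOVA + Tukey HSD or Kruskal–Wallis +
  Dunn. Dunn's post-hoc uses ties-corrected rank-sum z statistics with
  Bonferroni adjustment (the conservative convention, since Dunn's test
  is used with several adjustments in practice). Under a Gaussian
  null the whole gated procedure rejects at 0.050 ± 0.005 (asserted over
  4000 seeded replicates).
* **Grubbs screening.** Iterative one-at-a-time removal while
  $G = \max|x-\bar x|/s$ exceeds the two-sided critical value
  $\frac{n-1}{\sqrt n}\sqrt{t^2_{\alpha/(2n),\,n-2}/(n-2+t^2)}$, capped
  at 20 % of the sample and blocked when a testable sample (n ≥ 8)
  affirmatively fails the normality gate. Samples with 3 ≤ n < 8 cannot
  be normality-tested and are screened as-is; this resolves the tension
  between "screen only Gaussian samples" and the n = 5 worked example
  {9, 10, 10, 11, 50} → remove 50 (G = 1.787 > 1.715).
* **Slopes.** `ancova_slopes()` tests the group × covariate interaction.
  A power caveat belongs here: with the published group sizes (13/12) and
  noise scale (slope SDs 0.14/0.06), the attainable power to distinguish
  slopes 0.74 vs 0.46 is only ≈ 0.3 (the slope-difference SE is ≈ 0.15–0.19
  against a difference of 0.28). The package reports this honestly; the
  corresponding end-to-end check records the shortfall rather than
  relaxing the test.

## 7. Problem sizes

Chosen as the package's own test-design sizes: unit tests run single
runs and 10-run groups; calibration checks use 4000 null replicates;
efficiency-slope coverage uses 200 replicate cohorts at the published
group sizes (13/12); the acceptance script recovers group means from
80-run cohorts (Monte-Carlo SE ≈ cv/9) and slope means from 200
replicates. All are seeded and complete in seconds.

## 8. Known limitations

* The settle time, rate-window length and derivative width are
  validated only against the synthetic forward model, not against
  instrument software output.
* Membrane potential, P/O ratios, respiratory control ratios and flux
  control coefficients are out of scope.
* Site assignment beyond I$_F$ is intentionally coarse ("+ other
  dehydrogenases"); the inhibitor approach cannot localize further.
* Male oxygraph reference groups are not bundled (published only as
  supplementary material), so male defaults exist only for H₂O₂ cohorts.
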