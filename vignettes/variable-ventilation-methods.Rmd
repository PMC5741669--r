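---
title: "Variable ventilation mechanics, morphometry and study statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable ventilation mechanics, morphometry and study statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varivent)
```

## The problem

In volume-controlled ventilation every breath is identical. In emphysema,
where lung units have widely different time constants, that monotony can
leave slow units under-inflated while overdistending fast ones, predisposing
to ventilator-induced injury and loading the right heart. Variable
ventilation (VV) instead delivers a Gaussian breath-to-breath tidal-volume
(V_T) sequence with a fixed mean and a prescribed coefficient of variation
(CV), the experimental dial of interest. This package implements the full
computational chain such an experiment needs — V_T sequence generation,
equation-of-motion mechanics, airspace-heterogeneity morphometry, 2^−ΔΔCt
expression analysis, and the statistical battery — plus a synthetic cohort
that emulates a five-group rat emphysema study (non-ventilated controls and
ventilated groups at CV 0, 15, 22.5, 30%; 7 animals per group).

## Tidal-volume generation

`generate_vt_sequence()` draws `n_breaths` values from
N(mean, (mean·CV/100)²) with mean = `mean_vt × body_mass`.

Defaults and why:

- `mean_vt = 6` mL/kg, `peep = 3` cmH2O, `n_breaths = 1200`: the protocol's
  set points (1200 breaths cover the 2-h ventilation period).
- `body_mass = 0.437` kg: the cohort's mean body mass.
- `resp_rate = 57` /min: the protocol adjusted rate to blood pH and reports
  only minute ventilation (≈150 mL/min); 150 / 2.622 mL ≈ 57.
- `ie_ratio = 0.5` (I:E = 1:2): conventional for rodent ventilation; the
  design lists I:E without a value.
- `truncation_sd = 3` and `vt_floor_frac = 0.1`: the source of the original
  generator's treatment of physically impossible draws is unknown. Clipping
  at ±3 SD plus a strictly positive floor guarantees deliverable volumes and
  attenuates the realized CV by < 2% relative even at CV 30% (a
  Monte-Carlo test asserts this). If the floor censors more than 1% of
  draws the result carries a `floor_warning` flag rather than failing.
  Both are configurable; `truncation_sd = Inf` disables clipping.

The realized CV uses the n−1 sample SD. At n = 1200 its sampling SD is
about CV/√(2n) ≈ 0.46 percentage points at CV 22.5, so a ±2-point agreement
band is a sampling statement, not a model claim.

`build_breath_waveform()` produces a volume-controlled breath: constant
inspiratory flow with a short linear rise (`rise_frac = 0.05` of the
inspiratory time — real ventilators have a rise time, and a strictly
constant inspiratory flow would be colinear with the intercept in an
inspiration-only mechanics fit), an optional end-inspiratory pause, and a
passive expiration (exponential, default time constant t_exp/8, or linear).
Flow samples are normalised so that the *trapezoid-integrated* volume peaks
at exactly V_T and returns to zero within 0.1% — the integration identity
the estimator relies on holds on the discrete grid, not just in continuous
time.

## Forward simulation and the mechanics estimator

The single-compartment linear model is

Paw(t) = E·V(t) + R·V̇(t) + P0 + ε(t),  ε ~ N(0, noise_sd²),

with E elastance (cmH2O/mL), R resistance (cmH2O/mL/s) and P0 the
end-expiratory offset (total PEEP). `simulate_breaths()` evaluates it
exactly on the waveform grid (volume is the cumulative trapezoid of flow,
so the equation of motion holds to machine precision with zero noise — a
tested invariant). Expiration is passive with time constant R/E, under
which the airway-opening pressure sits at P0 exactly: the resistive drop
cancels the elastic recoil. Optional 12-bit quantization of Paw over a
configurable range emulates the original analog-to-digital converter; it is
off by default.

The two-compartment variant places (E2, R2) in parallel with (E, R) behind
a shared airway node. Its steady-state volume split is fully determined by
the elastances (V2/V = E1/(E1+E2)), so the "volume fraction" is exposed as
a derived field rather than a free parameter. During an end-inspiratory
pause the compartments exchange gas (pendelluft) and the measured pressure
relaxes from peak to plateau as a single exponential with rate
(E1+E2)/(R1+R2); the test suite verifies the numerically integrated decay
against this closed form. The variant exists to probe estimator robustness
to time-constant inhomogeneity; it is never fitted.

`fit_equation_of_motion()` regresses Paw on {V, V̇, 1} by ordinary least
squares, per breath by default, with volume re-referenced to zero at each
breath start so the intercept is interpretable as total PEEP. Per-breath
estimates are aggregated by the median (robust to occasional corrupted
breaths) or the mean; a global single fit is available. Windowing
(whole-breath vs inspiration-only) is configurable because the original
analysis does not state it; on noise-free data both solve the same exact
linear system and the tests require them to agree to 1e−6. A rank-deficient
regressor matrix raises a degenerate-fit error naming the breath.

## Airspace morphometry

For a sample of airspace diameters (protocol convention: 20 per animal) with
sample mean μ, SD σ and skewness γ (biased 1/n moments by default — the
protocol fixes n, and only with 1/n moments does the closed form below
reproduce the raw-moment ratio exactly):

- mean linear intercept Lm = μ;
- D2 of Lm, default **moment form**:
  D2 = (μ³ + 3μσ² + γσ³) / (μ² + σ²) ≡ E[d³]/E[d²], the third-to-second
  raw moment ratio;
- homogeneity index 1/β = Lm / D2, equal to 1 for perfectly uniform
  airspaces and falling with heterogeneity.

A literal two-factor form μ·(1 + σ²/(μ²+σ²))·(2 + σγ/μ) appears typeset in
parts of the morphometry literature. It gives D2 = 2μ and 1/β = 0.5 for
perfectly uniform airspaces, which contradicts the semantics of a
homogeneity index that approaches 1 with uniformity; the moment form is
therefore the default and the literal form is retained behind
`form = "literal"` with an explicit discrepancy test. Negative-skew samples
are accepted; there D2 may fall below μ, which is documented rather than
clamped.

`generate_airspace_sample()` draws from a location-shifted gamma (skewness
set via the shape, 2/√k) or a lognormal (skewness implied by the CV). The
shifted gamma keeps its support positive only when skew ≥ 2·CV, which is
enforced with an informative error; the boundary case (pure gamma,
skew = 2·CV) has the convenient closed form E[d³]/E[d²] = μ(1 + 2CV²), i.e.
1/β = 1/(1 + 2CV²) in expectation. The cohort generator exploits this to
solve the within-animal diameter CV from each group's target homogeneity
index (e.g. 1/β = 0.85 → CV ≈ 0.30; 1/β = 0.66 → CV ≈ 0.51). Note the
distinction between this *within-animal* CV and the much smaller
*between-animal* CV of Lm (≈ 0.09 for the intermediate group): conflating
them would put 1/β near 0.98 instead of 0.85.

## 2^−ΔΔCt expression analysis

ΔCt = mean Ct(target) − mean Ct(housekeeping 36B4) per animal (triplicates
averaged first; optional rejection of replicates > 0.5 cycles from the
replicate median, off by default). The calibrator is the arithmetic mean
ΔCt of the non-ventilated group per gene — the standard Livak convention,
under which the calibrator group's geometric-mean fold is exactly 1 (an
exact test, not a tolerance). Fold = 2^−ΔΔCt. Primer-efficiency correction
and absolute quantification are out of scope.

## The statistical battery

- **Power / sample size**: exact noncentral-t power of the two-sided
  two-sample t-test (df = 2n−2, noncentrality d√(n/2)). A normal
  approximation misorders n = 6 vs 7 at d = 2.21; the exact computation
  returns n = 7 at α = 0.008 (the Bonferroni level 0.05/6) and power 0.8.
  The design's α was ambiguous between 0.05 and 0.008; only 0.008
  reproduces the published n = 7 (α = 0.05 gives n = 5), so that is the
  documented reading.
- **Holm-Šídák**: step-down, adjusted p for the i-th smallest raw p is the
  running maximum of 1 − (1 − p_(j))^(m−j+1), clipped at 1.
- **Two-way repeated-measures ANOVA**: balanced split-plot sums of squares
  computed directly from cell/marginal means (Type III = Type I on a
  balanced design); group is tested against subjects-within-groups, time
  and interaction against the within-subject residual. Unbalanced or
  incomplete data are rejected by design, naming the offending subject.
  Post hoc: pairwise group t contrasts within each timepoint, one
  Holm-Šídák family. The implementation is validated against `stats::aov`
  with an `Error(subject/time)` stratum as an independent oracle.
- **Kruskal–Wallis + Dunn**: H with the tie correction; Dunn z statistics
  on mean ranks with Holm-Šídák (default) or Bonferroni adjustment. An
  all-identical sample yields H = 0, p = 1 rather than an error.
- **Spearman**: Pearson correlation of midranks, two-sided p via the t
  approximation (matching `cor.test(..., exact = FALSE)`).
- **Percent change**: per animal 100·(END−BASELINE)/BASELINE, then the group
  mean. Mean-of-ratios ≠ ratio-of-means; the published percent-change table
  is consistent with per-animal averaging, which is why that convention is
  implemented and why the printed table values are not acceptance targets.

Null-calibration tests run the package's own implementations over 10,000
simulated null datasets (n = 7/group) and require type-I error within 3
binomial standard errors of nominal α for paired t, the RM-ANOVA group
test, and Kruskal–Wallis.

## The synthetic cohort: what it is and is not

`generate_cohort()` draws per-animal values from Gaussians with the
published group means and SDs for every variable and timepoint, truncated
at zero (these are positive physiological quantities and some echo SDs are
large relative to their means). BASELINE and END draws share a
within-animal correlation, default 0.7 — the paired dependence structure
was not reported, so this is a declared default chosen to make paired tests
behave realistically, not an inference. PAT/PET is derived per animal from
its PAT and PET draws. Non-ventilated animals contribute only morphometry
and expression data, mirroring the design.

In full-pipeline mode the tabulated E and R become ground truth for signal
simulation (CV 0 at BASELINE, the group CV at END) and are replaced by
estimator output. The default uses 50 breaths per recording rather than the
protocol's 1200 purely for runtime; the estimator is unbiased per breath,
so the scale-down affects only the variance of the estimates. A test
requires the estimated group trajectory to reproduce the sign of the
elastance change in high-variability groups across seeded cohorts.

Gene-expression shifts per group are *synthetic magnitudes*: the study
reports fold changes only graphically, so the generator encodes the
reported directions and contrasts (e.g. IL-6 and SP-D elevated at CV 30%,
CINC-1 elevated everywhere except CV 22.5%) with plausible ΔΔCt sizes.
Green expression tests therefore establish that the pipeline propagates
known shifts correctly — not that the study's effect sizes are reproduced.
The same caveat applies cohort-wide: a green end-to-end run establishes
self-consistency of generator + pipeline under the published summary
statistics and Gaussian within-group variation; it cannot validate the
animal-level results, whose raw data were never deposited.

## Numerical and degenerate-input choices

- Waveform normalisation solves the inspiratory and expiratory scale
  factors exactly on the trapezoid grid (peak volume = V_T to machine
  precision; end-expiratory residual equals the analytic exp(−t_exp/τ)).
- Breath periods shorter than 2 samples, pauses that swallow expiration,
  zero or negative tidal volumes, non-positive E/R, Ct outside (0, 45),
  fewer than 3 diameters, constant inputs to Spearman, zero-variance
  paired differences, and p-values outside [0, 1] all raise immediate,
  specific errors.
- `run_study()` derives per-stage seeds from the master seed, so a fixed
  seed makes the entire report bundle bit-identical across reruns (tested
  byte-for-byte on the written files).
- The two-compartment ODE is integrated with RK4 at 4 substeps per sample;
  the pause-decay test pins the integrated dynamics to the closed-form
  relaxation rate within 1%.

## Known limitations

- Linear mechanics only: no nonlinear pressure–volume curve, no
  viscoelasticity, no gas exchange; the estimator fits the
  single-compartment form even when the two-compartment simulator generated
  the data (deliberately, to study robustness).
- The cohort generator treats variables as independent Gaussians apart from
  the BASELINE–END pairing; cross-variable correlations (e.g. E with PAT)
  are not modelled except where a variable is derived (PAT/PET).
- Echocardiographic quantities are generated summary inputs, never computed
  from images.
- The morphometry generator fixes the within-animal CV per group; real
  animals vary in heterogeneity as well as in mean Lm.
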