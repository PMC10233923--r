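---
title: "Models and methods behind hmiol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hmiol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmiol)
```

## The clinical problem

Cataract surgery replaces the crystalline lens with an intraocular lens
(IOL) whose power determines the eye's postoperative refraction. In highly
myopic eyes (axial length AL >= 26 mm) the classical power formulas lose
accuracy: effective lens position (ELP) regressions were calibrated on
normal-length eyes, long eyes often need low or negative lens powers where
small ELP errors translate into large refractive surprises, and several
modern calculators refuse axial lengths above 35 mm altogether. `hmiol`
implements a machine-learning calculation pipeline aimed specifically at
this population: theoretical vergence formulas supply physically grounded
features, supervised learners model what the formulas miss, and an
exhaustive inverse search turns the fitted predictor into a power
calculator.

## Vergence optics

Both engines model the pseudophakic eye as two thin lenses (cornea, IOL) in
a medium of refractive index 1.336, with the refraction expressed at a
12 mm spectacle vertex. Keratometry converts to corneal radius through the
keratometer index 1.3375 (`r = 337.5 / K`), the convention of the optical
biometers this schema mirrors.

**SRK/T.** The implemented steps are the canonical published ones: a
corrected axial length `LCOR` (identity up to 24.2 mm, a quadratic beyond),
corneal width `Cw = -5.41 + 0.58412 LCOR + 0.098 K`, corneal height
`H = r - sqrt(r^2 - Cw^2/4)`, ELP `= H + (0.62467 A - 68.747) - 3.336`, a
retinal-thickness correction `0.65696 - 0.02029 AL`, and the two-surface
vergence expression with corneal index 1.333. When the corneal-height
square root would go negative (very long eyes with steep corneas) the
argument is clamped to zero with a warning — the original algorithm's
behavior — rather than failing, which keeps extreme but real biometry
usable.

**Haigis.** ELP is the three-constant regression
`d = a0 + a1 ACD + a2 AL`, corneal power comes from the radius with index
1.3315, and the same vergence chain applies. When a lens model publishes
only an A constant, the classical fallback `a0 = 0.62467 A - 72.434`,
`a1 = 0.4`, `a2 = 0.1` is derived automatically (with a notice).

Both expressions are linear-fractional in IOL power, so the power achieving
any target refraction has a closed form; the package uses it for
emmetropia/target inversion and the test suite verifies it against
bracketed root finding. Forward predictions are verified against an
independent stepwise vergence-propagation oracle to well below 0.01 D.

## Features and cohort handling

A cohort is a plain CSV, one row per eye. Inclusion requires AL >= 26 mm,
complete six-field biometry, an observed postoperative spherical
equivalent, and (when recorded) corrected acuity of at least 20/40;
refractions measured on a 5 m lane are standardized to 6 m by adding
-0.03 D. Two feature sets feed the learners: nine base features (the six
biometrics, implanted power, A constant, and the Haigis-predicted
refraction at that power) and a tenth, the SRK/T-predicted refraction, in
set 1 only. The implanted power and the A constant both enter as raw
numeric features; lens-model identity itself does not. Cohorts split 8:2
into training and test partitions by a seeded permutation with floor
rounding, so 1828 eyes give 1462/366. For comparisons against calculators
that cap AL at 35 mm, a closed-boundary filter (`AL <= 35.00` retained)
reports the excluded cases. AL subgroups use half-open bins [26, 28),
[28, 30), [30, Inf): the interior boundaries are ambiguous in the usual
range notation, so the package assigns them to the upper bin and makes the
cut points configurable.

## The assembled model

Four sub-models — gradient-boosted trees and RBF-kernel support vector
regression, each on both feature sets — are trained with the actual
postoperative spherical equivalent as target, then combined by a weighted
average. Published descriptions of such ensembles rarely state the weights;
`hmiol` defaults to weights proportional to inverse out-of-fold MAE from an
internal 5-fold scheme on the training cohort (each validation fold
disjoint from the folds that trained it), with equal weights selectable.
Hyperparameters are deliberately conservative and fixed in configuration:
trees of depth 4, 300 rounds at learning rate 0.05, single-threaded for
reproducibility; SVR with C = 10, epsilon = 0.1, internally standardized
features (trees are scale-invariant and use raw features). All seeds are
explicit; identical seeds reproduce identical models bit for bit, and the
saved artifact embeds a version tag and the feature schema so stale or
tampered files are rejected at load.

Because the theoretical features are recomputed at whatever power is
queried, the fitted ensemble answers both evaluation questions ("what
refraction did the implanted lens produce?") and planning questions ("what
would candidate power P give?"). Tree learners extrapolate poorly outside
the feature range seen in training, so planning queries are most reliable
when the training cohort's implanted powers span the candidate grid — a
caveat the planner tests make explicit.

## Power planning

`select_iol_power()` evaluates the ensemble on every candidate power (by
default -5 to 35 D in manufacturable 0.5 D steps) and picks the prediction
closest to the target. Two clinical conventions exist for ties and for
hyperopic surprises: the default takes the closest prediction with ties
broken toward the higher power (the more myopic outcome), and an
`avoid_hyperopic` mode restricts candidates to predictions at or below the
target. The selection is an exhaustive-grid argmin by construction and the
tests verify it against independent recomputation, plus against the
closed-form vergence inversion when the ensemble tracks a known truth
formula.

## Evaluation battery

The prediction error is `PE = actual - predicted` (negative PE = more
myopic than predicted). For each formula the package reports mean and SD of
PE, MAE +/- SD, MedAE, percentages within +/- 0.25/0.50/0.75/1.00 D (closed
thresholds, the universal convention), the cumulative absolute-error curve,
the Pearson correlation and least-squares slope of PE on AL, and a formula
performance index combining four components:
`FPI = 1 / (SD + MedAE + |slope| + 10 / pct_within_0.50)`. The four
components are exposed separately because published FPI scalings differ;
the composite should be compared only within one analysis. Comparisons use
the Friedman rank test on paired absolute errors with pairwise Wilcoxon
signed-rank post-hocs, Cochran's Q on the paired band indicators with
McNemar post-hocs, the two-group log-rank test on absolute error treated as
an uncensored event time, and Pearson correlation for PE-AL trends. All
pairwise families are Bonferroni-adjusted over every pair (the conservative
reading when the family is ambiguous). Omnibus and post-hoc p values are
asymptotic, as in standard statistical software; the test suite checks the
statistics exactly against permutation, dynamic-programming enumeration and
textbook log-rank oracles, and the p values against the oracle mid-p at
fixture sizes where the chi-square approximation is in its working range.
Degenerate inputs (identical columns, fully tied blocks, zero variance) are
reported as explicit no-difference results rather than NaN.

Comparator predictions from proprietary calculators cannot be reimplemented
and therefore enter as pre-computed columns in the predictions CSV.

## Synthetic cohorts

The generator draws six-variable biometry from a correlated normal with
marginal moments emulating a large highly myopic surgical cohort (AL
29.18 +/- 2.19 mm truncated to 26-37.5 mm, K 43.30/44.32 +/- 1.5/1.6 D,
ACD 3.42 +/- 0.34 mm, LT 4.44 +/- 0.39 mm, CD 11.75 +/- 0.42 mm). Because
published tables give only marginals, the correlation structure is a
package choice: rho(AL, ACD) = +0.3, rho(AL, K) = -0.2,
rho(K_flat, K_steep) = +0.9 — mild physiologic plausibility, fully
configurable. Two numerical details matter. First, truncating a normal at
26 mm would bias the AL mean upward by about 0.33 mm, so the generator
solves for parent parameters whose *truncated* distribution hits the
requested moments. Second, the two keratometry draws are sorted into
flat/steep order; with rho = 0.9 the swap probability is ~7% and shifts the
marginal means by ~0.02 D, negligible against sampling error.

Each eye is implanted with the truth-formula power for the configured
target (default -3.00 D, the usual choice for highly myopic patients who
value near vision; this reproduces an implanted-power distribution of
about 9 +/- 5 D), rounded to 0.5 D and clamped to [-10, 40] D, and the
observed refraction is the truth-formula output at that power plus
N(0, noise_sd) noise (default 0.3 D, a realistic manifest-refraction
repeatability). The generator emulates marginal moments and a plausible
dependence structure — not posterior staphyloma, biometry measurement
error, surgeon-specific constant optimization, or the true joint
distribution of myopic biometry — so passing tests demonstrate pipeline
correctness and recoverability, not clinical accuracy on real eyes.

Because the truth model is known, the ensemble has an analytic target: with
ground truth equal to the Haigis prediction plus N(0, 0.3) noise, the best
possible held-out MAE is the expected absolute value of the noise,
`0.3 * sqrt(2/pi) ~ 0.239 D`. On a generated 1828-eye cohort split 8:2 the
assembled model's held-out MAE lands within 0.05 D of this floor — the
pipeline's end-to-end parameter-recovery check, computed fresh by
`scripts/acceptance.R` on every run.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use cohorts of 120-1828 eyes —
the full published cohort size for the split/recovery checks, smaller
cohorts where a property does not depend on scale. Optics run in double
precision with no rounding before display; inversion tolerance is 1e-6 D
when root finding is used (the closed form is exact); moment matching for
the truncated AL marginal converges to ~1e-7. The sub-model interpolation
check deserves one note: the SVR's epsilon-insensitive loss makes training
residuals up to epsilon invisible to the optimizer, so at the default
epsilon = 0.1 a noise-free target is recovered only to MAE ~ 0.07 D; the
interpolation property is therefore exercised at epsilon = 0.01 via the
documented override, and the default configuration is checked against its
tube bound instead.

## Known limitations

- Printed accuracies of the original clinical study are not reproducible
  here: they depend on a private patient cohort and unpublished trained
  weights. The package reproduces the *method* and verifies it on synthetic
  data with known truth.
- Only SRK/T and Haigis are implemented as theoretical engines; other
  formulas (and toric/multifocal algebra, ray tracing) are out of scope.
- Tree sub-models extrapolate as constants outside the training feature
  range; planner grids far beyond the implanted powers seen in training
  will reflect that.
- The Haigis constant set per lens model is user-supplied; the shipped
  registry file is synthetic and illustrative, not optimized clinical
  constants.
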