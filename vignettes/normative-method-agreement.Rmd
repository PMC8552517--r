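---
title: "Normative brain volumetry and segmentation-method agreement: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative brain volumetry and segmentation-method agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normvol)
```

## The problem

Automated brain segmentation methods measure the same anatomical regions with
systematic differences: different atlases and boundary definitions produce
offsets and scalings of several hundred mm^3 between methods. In a
single-subject normative-modeling workflow — where a patient's regional volume
is converted to a z-score against an age-dependent reference distribution —
this raises two distinct questions:

1. **Scenario 1.** If the *same* method produces both the normative
   distribution and the patient's volume, are methods interchangeable? This
   requires the methods' volumes to correlate strongly (PCC-v) and the
   patients' z-scores to agree absolutely between methods (ICC-z).
2. **Scenario 2.** Can *different* methods produce the two? This additionally
   requires absolute agreement on the raw volumes (ICC-v), because any
   between-method offset or scaling propagates directly into the z-score.

`normvol` implements the complete analysis: normative fitting, z-scoring,
agreement statistics, and the diagnostic AUC of the z-score, together with a
synthetic cohort generator so that the whole pipeline is testable end to end
without access-restricted clinical data.

## The normative model

For one method and one region, let $y$ be the volume at age $t$ with sex $s$
(0 = female, 1 = male) and height $h$ in cm. The model assumes the
Yeo–Johnson-transformed volume is Gaussian with age-dependent location and
scale and an age-dependent transformation parameter:

$$
z \;=\; \frac{\psi_{L(t)}(y) - \mu(t) - \beta_s\, s - \beta_h\,(h - 170)}{\sigma(t)}
\;\sim\; \mathcal N(0, 1),
$$

where $\psi_\lambda$ is the Yeo–Johnson transformation. This is the classical
LMS construction: $L(t)$ carries the age-varying skewness, the median volume
is $M(t) = \psi^{-1}_{L(t)}(\mu(t))$ (plus covariate terms inside the
inverse), and the coefficient of variation is implied by $\sigma(t)$ at each
age. The model is fitted by maximizing the exact log-likelihood including the
Jacobian $\sum_i (L(t_i) - 1)\log(1 + y_i)$ of the transformation.

Design choices that were genuinely open, and how they were resolved:

* **Curve representation.** Each of $L$, $\mu$, $\log\sigma$ is a natural
  cubic regression spline in age with exactly $\delta$ degrees of freedom
  (default $\delta = 2$), plus an intercept. An unpenalized basis with the
  target df realizes the same smoothness control as a penalized spline tuned
  to an effective df, but deterministically and without a calibration loop —
  refits are bit-for-bit reproducible, which the pipeline's determinism
  guarantee relies on.
* **Covariate placement.** Sex and centered height act additively on the
  transformed-scale *location* only, not on $L$ or $\sigma$. This is the
  minimal covariate correction consistent with displaying reference curves
  for a single stratum (males of height 170 cm); modeling covariate effects
  in the scale or skewness would require far larger samples to identify.
* **Internal rescaling.** Volumes are divided by their sample median before
  transformation and the scale is stored in the model. The Yeo–Johnson family
  is not scale-equivariant, so this fixes the family at a well-conditioned
  operating point (transformed values of order 1) regardless of whether a
  region measures 1,700 or 13,000 mm^3; z-scores and curves are reported on
  the original mm^3 scale throughout.
* **Optimization.** BFGS on all coefficients jointly, initialized at the
  identity transform ($L \equiv 1$), the least-squares location fit and the
  log residual SD; convergence at relative log-likelihood change $10^{-8}$ or
  500 iterations, with non-convergence raised as an error carrying the
  diagnostics. $L(t)$ is kept in $(-3, 3)$ through a smooth $\tanh$ bound so
  extreme transformation parameters cannot blow up the likelihood.
* **Extrapolation.** Curves and z-scores are refused outside the fitted age
  range by default; the analysis only ever evaluates in-range, and reference
  curves extrapolate notoriously badly.

## Preprocessing rules

* Left/right hemisphere volumes are summed; a record with only one
  hemisphere present is an incomplete segmentation and becomes a failure.
* Caudate nucleus and accumbens are merged into one region, because some
  methods segment them jointly; for such pre-merged methods the combined
  value is used as-is.
* A failed segmentation is a missing *or zero* volume (aborting pipelines
  produce either).
* Gross outliers in the reference group are volumes more than 5 population
  SDs from the region mean, with mean and SD computed in a single pass over
  all values, candidates included, using the $n-1$ SD. The threshold of 5
  (rather than the conventional 3) keeps as much of the normal population as
  possible while rejecting unrealistic volumes. The removal is deliberately
  single-pass, not iterated to stability: iteration makes the excluded set
  depend on the iteration order and count, and at thresholds this extreme the
  second pass removes essentially nothing.
* A subject flagged by *any* method is excluded from that region for *all*
  methods (union rule), so every per-region analysis uses one shared subject
  set; exclusion is per-region, so a subject flagged for the amygdala still
  contributes to the thalamus.
* Patient (AD) records are never auto-excluded by z-score — their volumes are
  expected to be abnormal. Rejected patient segmentations enter the input as
  failures.

## Agreement statistics

With $X$ an $n \times k$ matrix of subjects by methods, the two-way mean
squares are

$$
\mathrm{MSR} = \tfrac{k}{n-1}\sum_i (\bar X_{i\cdot} - \bar X)^2,\quad
\mathrm{MSC} = \tfrac{n}{k-1}\sum_j (\bar X_{\cdot j} - \bar X)^2,\quad
\mathrm{MSE} = \tfrac{1}{(n-1)(k-1)}\sum_{ij} (X_{ij} - \bar X_{i\cdot} - \bar X_{\cdot j} + \bar X)^2,
$$

and the single-rater absolute-agreement intraclass correlation is

$$
\mathrm{ICC}(A,1) = \frac{\mathrm{MSR} - \mathrm{MSE}}
{\mathrm{MSR} + (k-1)\,\mathrm{MSE} + \tfrac{k}{n}(\mathrm{MSC} - \mathrm{MSE})}.
$$

It equals 1 exactly for identical columns and is driven down by offsets and
scalings: adding one population SD to one of two columns gives
$2s^2/(2s^2 + d^2) = 2/3$ in the large-$n$ limit, and scaling by $a$ with
population mean $m$ and variance $s^2$ gives
$2as^2 / ((1+a^2)s^2 + (1-a)^2 m^2)$ — about 0.70 for $a = 1.2$, $m = 5$,
$s = 1$. Both limits are verified by simulation in the test suite and
recomputed from scratch by `scripts/acceptance.R`.

Open conventions, fixed as follows:

* **Pairwise complete cases per cell.** Each method pair's statistic uses
  the subjects observed by both methods (not listwise across all five), with
  the n recorded per cell; this maximizes data use and matches the
  per-region shared subject set.
* **Rating bands are left-closed**: poor $<$ 0.5, fair $[0.5, 0.7)$, good
  $[0.7, 0.9)$, excellent $\ge 0.9$; a boundary value takes the upper label.
* **Undefined statistics** (constant inputs) propagate as `NA` with a
  warning, never as a number.
* ICC confidence intervals are not computed (point values only); other ICC
  variants (C,1), (A,k), (C,k) are out of scope.

Method-mean differences are tested with a fixed-effects one-way ANOVA and
Tukey's HSD post hoc, via `stats::aov()` and `stats::TukeyHSD()`.

## Diagnostic value of the z-score

The AUC is defined as the probability that a randomly chosen reference
subject has a *higher* z-score than a randomly chosen patient (patients are
expected below the norm), computed via midranks — exactly the Mann–Whitney
$U/(n_1 n_2)$ with ties counted $1/2$. Ties have probability zero for
continuous z-scores but the rule must still be fixed for implementation.
Because the patients span ages 71–91 while the reference cohort spans 45–95,
reference subjects are first restricted to the closed window $[71, 91]$;
otherwise the AUC would partly measure the age gap rather than the disease
effect. The 95% CI is a percentile bootstrap with 1,000 replicates, resampling
within each group independently (stratified, group sizes preserved) — the
simplest scheme consistent with comparing two fixed cohorts — and is seeded
deterministically per (method, region).

## The synthetic cohort generator

The generator exists because the motivating clinical cohort is
access-restricted: it reproduces the *statistical shape* of such data, not
its values. Its structure is latent-variable by design: each subject carries
one true volume per region, and each method observes
`scale * latent + offset + noise`. This is exactly the structure presupposed
by the offset/scaling sensitivity of ICC(A,1), and it yields closed-form
expected ICCs for testing. Skewness is generated through the inverse
Yeo–Johnson transform so that, in the identity-transform case, the fitter's
model family contains the generator's truth — enabling clean parameter
recovery tests with `true_z()` as oracle.

Defaults define the study conditions: 988 reference subjects uniform over
ages 45–95 (uniformity is chi-square-tested on deciles), 42 patients aged
71–91, male fractions 0.44 / 0.60, six regions with medians and CVs in the
published volumetric range (hippocampus 6,000 mm^3, amygdala 2,200,
caudate+accumbens 7,800, thalamus 12,400, putamen 8,250, globus pallidus
2,300; CV ≈ 0.13), mild negative age slopes, and additive sex/height effects
of a few percent. The five nominal methods carry scalings 0.92–1.12, offsets
−300 to +500 mm^3, noise SDs 100–200 mm^3 and small failure/outlier rates
(the largest failure rate 0.9%, matching the order observed for real
pipelines); disease atrophy is concentrated in hippocampus (factor 0.80) and
amygdala (0.83) with mild effects elsewhere (0.95–0.97). Where the emulated
study states a value (group sizes, age ranges, thresholds, bootstrap
replicates) the default *is* that value; the remaining magnitudes were chosen
once as field-typical and are not tuned.

Deliberately deterministic details: hemispheres split 48/52 (not random) so
merging is exactly testable; failures are missing volumes; gross outliers add
±8 population SDs (clamped at 1 mm^3 since volumes are non-negative); all
randomness flows from the single config seed.

What the generator does **not** emulate — and hence what passing tests do not
show about real data: spatially correlated segmentation errors (real methods
fail together on hard anatomy, the generator's failures are independent),
atlas-driven *shape* differences beyond affine volume distortion,
age-dependent method bias, scanner/protocol effects, and non-linear
volume–age trajectories. Agreement statistics on real cohorts can therefore
be substantially worse than on synthetic ones in ways these tests cannot
reveal.

## Problem sizes and numerical tolerances

The validation suite fits recovery cohorts of n = 2,000 over 20 seeds
(median-curve relative RMSE is required below 2% at interior ages, training
z-scores mean within ±0.05 and SD within [0.9, 1.1], tail calibration
|z| > 1.96 at 5% ± 2%), checks ICC(A,1) against an independent two-way ANOVA
oracle on 500 random matrices to 10⁻⁹ relative, verifies the offset and
scaling ICC limits at n = 10,000 within ±0.02, and runs the full default
cohort (988 + 42 subjects × 5 methods × 6 regions) end to end twice to
confirm hash-identical outputs. The analysis scripts use the same default
sizes; a full run takes well under a minute.

## Known limitations

* One cross-sectional measurement per subject; no longitudinal modeling.
* Location-only covariate correction; if sex or height truly modulates the
  variance or skewness of a region, that misspecification is absorbed by the
  fit.
* Regression splines with df = 2 cannot track sharply non-linear aging
  trajectories; raise `delta` if the data demand it, at the cost of wigglier
  reference curves.
* `cross_method_z()` (scoring one method's volumes against another's model)
  is a demonstration of the scenario-2 failure mode, not a recommended
  analysis — the agreement statistics are the decision tool.
* The pipeline starts at volume tables; no image I/O or segmentation.
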