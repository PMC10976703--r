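---
title: "Methods: simulated FDG-PET VOI analysis of MCI conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated FDG-PET VOI analysis of MCI conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdgvoi)
```

## The model in one page

A subject's FDG uptake in region $r$ is summarized as the pons-referenced
standard uptake value ratio
$$\mathrm{SUVr}(r) = \frac{\overline{A}(r)}{\overline{A}(\text{pons})},$$
which removes global scaling (dose, weight, scanner gain): multiplying
the raw activity by any constant leaves SUVr unchanged, and this
invariance is tested exactly. Against a normative database of
cognitively normal controls with per-region mean $\mu_r$ and SD
$\sigma_r$, the subject's standardized uptake is
$$Z(r) = \frac{\mathrm{SUVr}_{\text{subject}}(r) - \mu_r}{\sigma_r},$$
and $Z(r) < -2$ (strictly) calls region $r$ hypometabolic. Conversion
prediction rules are Boolean expressions over these calls (MTL alone,
PCC alone, conjunction, disjunction), evaluated against the observed
converter label with sensitivity, specificity, PPV, NPV and accuracy,
each with an exact Clopper–Pearson binomial CI (small-sample clinical
convention; Wald intervals misbehave at the proportions seen here).

On the sign convention: the clinical convention we implement makes low
uptake *negative* so that "$Z < -2$" means hypometabolism; formulations
that subtract the subject from the database mean flip the sign, and the
`orientation = "db_minus_subject"` flag reproduces that exactly (the
two outputs are negations of one another, which is tested).

## What the synthetic cohort emulates

No patient-level data of this kind are publicly deposited, so the
package generates cohorts whose *group-level* statistics match a
published clinical cohort:

* composition 40 CN / 38 MCI-NC / 44 MCI-C / 42 AD;
* per-(group, VOI) SUVr drawn $\mathcal N(\mu, \sigma)$ truncated at 0,
  with the 7 × 4 table of means/SDs as defaults
  (`default_regional_profile()`); e.g. MTL falls 1.10 → 1.06 → 0.91 →
  0.86 across CN → MCI-NC → MCI-C → AD while the occipital lobe is
  relatively spared;
* demographics (age, sex, education, APOE ε4 fraction) and baseline
  MMSE/CASI from the group means/SDs (`default_demographics()`);
* scan-to-conversion intervals for converters from
  $\mathcal N(3.70, 1.68^2)$ truncated to $[1, 8]$ years, and
  non-converter follow-up from $\mathcal N(4.34, 1.26^2)$ truncated to
  $[2, 7]$ years. A truncated normal is the one standard family that
  matches all three printed constraints (mean, SD, range) at once.
  Truncation shifts the converter mean upward to
  `r round(truncnorm_mean(3.70, 1.68, 1, 8), 3)` years — the acceptance
  checks compare against this analytic moment, not the untruncated one.

Regional values are independent across VOIs by default — the minimal
assumption. `severity_loading` $\in [0,1)$ optionally adds a common
subject-level severity factor loading negatively on every VOI and on
baseline cognition, producing co-hypometabolism and the positive
Z–cognition correlation seen clinically; independence is the default
because any particular correlation structure would be invented.

A consequence worth stating plainly: under independent normal draws at
these parameters, per-VOI hypometabolism prevalences and rule
sensitivities do **not** reproduce the percentages reported on the real
cohort (e.g. the single-MTL rule is more specific and less sensitive
here). The generator makes no attempt to force that agreement — the
real data presumably carry inter-regional correlation and
non-normality that the printed table does not determine. Passing tests
therefore validate the *pipeline* (recovery of configured truth), not
distributional realism of real FDG-PET.

## Longitudinal trajectories

Scores are generated from a marginal model with measurement number
categorical: expected score at visit $v$ equals a subject anchor plus a
group-specific visit offset (visit 1 ≡ 0; control offsets all 0). The
default offsets are the published GEE interaction coefficients — for
MMSE the converters decline −0.34, −0.89, −1.99, −2.73, −5.12 points at
visits 2–6 while non-converters transiently *improve* +0.56 at visit 3;
analogous CASI offsets scale roughly 3–4×. The subject anchor is the
cohort-drawn baseline plus education (+0.415 MMSE, +1.376 CASI points
per year) and male-sex (+1.198, +4.694) effects, centered within group
so that group means of the generated baseline remain the configured
ones; the realized visit-1 value is the subject's operative baseline
(with zero covariate effects and zero noise it equals the drawn
baseline exactly). Residuals are exchangeable within subject
(default correlation 0.5, matching the GEE working assumption
downstream), realized as a subject intercept plus visit noise with
total SD 1.5 MMSE points / 5 CASI points — typical test–retest noise
for these instruments; both are configurable. MMSE is rounded to an
integer then clipped to [0, 30]; CASI clipped to [0, 100]. Visits are
nominally annual with ±0.15 y jitter (visit 1 at 0). Conversion is
operationalized as MMSE dropping below 20.

Two deliberate consequences of instrument bounds: (i) baseline
dispersion slightly exceeds the configured SD because covariate
deviations and noise add to the drawn baseline; (ii) the MMSE ceiling
at 30 mildly compresses high scorers (mostly controls, mean 28.1), so
cross-sectional covariate coefficients recovered by regression are
attenuated by a few percent relative to the seeded values. The recovery
checks use robust standard errors at 20× cohort replication and the
seeded education coefficient is recovered within 3 SE despite this; at
much larger replication the shrinking SE would eventually expose the
ceiling bias, which is a property of bounded instruments, not an
estimation error.

## Estimation choices

**GEE.** The marginal trajectory model (outcome ~ sex + education +
group × visit, CN and visit 1 as reference) is estimated by solving the
Gaussian generalized estimating equations with an exchangeable working
correlation: iterate feasible GLS with the moment estimator of the
common correlation on Pearson residuals, then report cluster-robust
(sandwich) standard errors. Under working independence the point
estimates coincide with OLS, which the tests use as an independent
route. The estimator is implemented in the package (`gee_gaussian()`)
rather than delegated, and is deliberately limited to identity-link
Gaussian outcomes — all this pipeline needs.

**Rank tests.** Visit-wise group comparisons use the Mann–Whitney test,
paired two-scan VOI comparisons the Wilcoxon signed-rank test. Exact
null distributions are used for ≤ 10 observations without ties
(validated in tests against brute-force enumeration of all group
assignments / sign patterns); otherwise the tie-corrected normal
approximation without continuity correction. Zero paired differences
are dropped, and when *all* differences are zero the p-value is
reported `NA` rather than an arbitrary 1. Spearman correlations use
average ranks; constant vectors or n < 3 yield `NA` with a warning,
never a silent 0. No multiple-testing correction is applied across VOIs
by default, matching common practice for these descriptive panels.

## Phantom imaging and numerical choices

The atlas phantom partitions the grid into a 3 × 3 × 2 cell lattice and
fills one rectangular block per region (70% of the cell), the pons low
and medial and widened to ≥ 18 mm in-plane so a mid-pons 16 mm
reference box always fits; an 8³ grid correctly refuses. Rendering
inverts the SUVr definition — region voxels at
$\mathrm{SUVr} \times A_{\text{pons}}$, pons at $A_{\text{pons}}$,
background fixed at $0.25 \times A_{\text{pons}}$ so Z-map displays
have a nonzero surround — with optional multiplicative Gaussian voxel
noise truncated at 0. The default pipeline geometry is a 48³ grid of
2 mm voxels (36³ in tests), small enough that a 164-subject image-space
run takes seconds yet large enough for ~5000-voxel VOIs; phantoms are
born co-registered, so no spatial normalization is modeled.

Conventions fixed once: RAS+ diagonal affine, 1-based voxel indices in
R; boundary voxels belong to their stored label (no partial-volume
weighting); the reference "16 × 16 mm box" is completed symmetrically
to a 16 mm cube and clipped to the pons mask, with the plain
whole-label pons mean as the phantom default (both modes exposed and
equal on phantoms by construction). The normative SD is floored at
10⁻⁶ to keep degenerate synthetic inputs from dividing by zero;
thresholding is strictly `z < threshold`, so a boundary value of
exactly −2 is *normal*. Whether a VOI-level Z should be the Z of the
VOI mean or the mean of voxel Z values is not determined by the
clinical description; the package takes Z-of-VOI-mean as primary
(voxelwise maps are available separately via `z_volume()`).

## Problem sizes used in checks

Recovery checks run at the enrolled sizes where the claim is about the
enrolled cohort (group sizes; 40-control normative DB; 44-converter
baseline MMSE), at 10,000 draws for interval moments, at 20× cohort
replication for GEE coefficient recovery, and 2,000 replicates for the
5%-level null calibration of the visit-wise test. All complete in
seconds to a few minutes on one CPU.

## Known limitations

* Independent regional draws understate real inter-regional
  correlation; prevalences and rule operating points on synthetic data
  are not estimates of clinical ones.
* APOE ε4 status is carried as a covariate but does not influence
  conversion or trajectories (the observed carrier imbalance is left
  unmodeled on purpose).
* Age is drawn but inert in score generation by default.
* No partial-volume effects, scanner PSF, attenuation or registration
  error are simulated; the image path validates bookkeeping and
  normalization, not reconstruction physics.
* The GEE implementation covers Gaussian/identity with exchangeable or
  independence working correlation only.
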