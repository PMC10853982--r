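---
title: "Fixel-based white matter statistics: models, parameters and design choices"
author: "fixelstats"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fixelstats` re-implements, as reusable and tested components, the statistical
core of a fibre-specific (fixel-based) white-matter analysis for a
longitudinal multiple sclerosis cohort design: per-fixel metrics (FD, FC,
FDC), connectivity-enhanced fixel-wise inference with permutation FWE
correction, tract-of-interest group statistics, normative cognitive
phenotyping, and a nested cross-validated prediction framework. Everything
upstream of the fixel template — diffusion acquisition and preprocessing,
spherical deconvolution, template registration, tractography and streamline
filtering, lesion segmentation, volumetry — is out of scope; a synthetic
template and cohort generator stand in, with known ground truth, so that
every downstream stage can be verified.

# The fixel metrics

A *fixel* is a single fibre population within a voxel; crossing-fibre voxels
contain several. Three metrics are attached to each fixel:

* **FD (fibre density)** — microstructural, proportional to the intra-axonal
  volume of the fixel's fibre population. The package treats FD as an input
  (it is estimated upstream from the diffusion signal).
* **FC (fibre cross-section)** — macrostructural, the change in a bundle's
  cross-sectional area under the subject-to-template warp. The literature
  defines FC verbally; this package adopts the closed form

  $$\mathrm{FC}(J, v) \;=\; \frac{\det J}{\lVert J v\rVert}$$

  for the local warp Jacobian $J$ (with $\det J > 0$) and unit fibre
  direction $v$: the warp scales the bundle's volume by $\det J$ and its
  length along the fibre by $\lVert Jv\rVert$, so their ratio is exactly the
  area change of the cross-section perpendicular to the warped fibre. This
  is the module's normative definition; it is antipodally symmetric
  ($v$ and $-v$ are equivalent) and is validated in the tests against an
  independent Monte-Carlo oracle that maps a disc of template points through
  $J$, projects out the warped fibre direction, and measures the polygon
  area of the image.
* **FDC** — the product FD × FC, combining both effects.

Statistics on FC are computed on the natural-log scale (`log_fc`), the usual
recommendation for a ratio-scale quantity; percentage-difference displays
and FDC use raw FC. Whether tract averages should be taken over FC or logFC
is not settled usage; both are emitted and `mean_logfc` is the default
analysis column.

Tract aggregation is the arithmetic mean over the fixels carrying a tract's
label. Lesion masking is voxel-level — a lesioned voxel removes *all* its
fixels, including those of a second tract crossing through the voxel — since
lesions live in voxel space. A tract whose fixels are all masked is omitted
with a warning rather than silently dropped.

# The synthetic cohort generator

`simulation_config()` fixes the study conditions; `generate_cohort()` draws
from them. Defaults emulate the cohort structure of a longitudinal MS
study: 95 healthy controls (HC) and 327 patients (239 relapsing-remitting,
52 secondary progressive, 36 primary progressive); follow-up retention
233/327 patients and 61/95 controls (retention is deterministic in count —
`round(fraction * n)` per group — so the printed totals are reproduced
exactly); visit intervals 4.81 ± 0.85 y (patients) and 5.43 ± 1.07 y
(controls); ages 48.34 ± 10.95 / 45.70 ± 10.35 y; sex, education,
treatment-category and normalized-volume distributions matching the same
design. Per-tract healthy FD means default to 0.5 and FC to 1.0: **these are
order-of-magnitude choices**, since no per-tract reference values are
published; deficits are fractional, so conclusions in the tests never
depend on the absolute level.

The generative model, per subject $i$, tract $t$, group $g$:

* baseline FD $= \mu_t (1 - d^{FD}_{g,t}) \exp(\eta_i + \varepsilon_{it})$,
  with a per-subject global factor $\eta_i \sim N(0, \sigma_b^2)$ (damage and
  anatomy are correlated across tracts within a subject) and measurement
  noise $\varepsilon \sim N(0, \sigma_w^2)$ redrawn per visit;
* follow-up multiplies in $(1 + s_{g,t}\,\Delta_i)$ for the subject's
  interval $\Delta_i$ and annual fractional slope $s$;
* per-fixel values jitter the subject's tract value by
  $\exp(N(0, \sigma_f^2))$.

Default deficits are 5% (RRMS, PPMS) and 10% (SPMS) for FD, 2%/6% for FC;
default slopes 0 (HC), −0.002 to −0.008 per year — chosen once so that the
published qualitative pattern (SPMS worst, PPMS ≈ RRMS, all below HC,
decline concentrated in progressive disease) is built into the ground truth,
while between-subject noise ($\sigma_b = 0.06$, i.e. ~6%) keeps group
separation realistic rather than trivial. With all noise set to zero the
deficit estimate $1 - \bar{x}_g / \bar{x}_{HC}$ recovers the configured
value to numerical precision; this recovery property is tested on a
lesion-free configuration, because the lesion mechanism below deliberately
biases lesioned voxels.

**Warps.** Rather than simulating registration, each fixel's Jacobian is
constructed in closed form:
$J = vv^{\top} + s\cos\theta\,(I - vv^{\top}) + s\sin\theta\,(wu^{\top} - uw^{\top})$
with $\{v,u,w\}$ orthonormal, a small random in-plane rotation $\theta$, and
$s = \sqrt{\mathrm{FC}}$. This map fixes the fibre axis and scales the
perpendicular plane by $s$, so $\det J / \lVert Jv\rVert = s^2$ exactly and
the intended FC field is realized to machine precision — enabling exact
tests of the FC module against the generator.

**Lesions** are voxel sets drawn per patient by tract-weighted multinomial
sampling (Poisson count per phenotype). Inside a subject's lesion voxels the
apparent diffuse FD deficit is *attenuated* (default: halved). This is a
deliberate emulation choice: the study this design mirrors reported that
masking out lesions left results "similar with a slight increase in effect
sizes", i.e. the diffuse normal-appearing-white-matter deficit carried the
group differences. Encoding the attenuation makes that observable behaviour
emerge from the generator (masking removes the less-deficient voxels and
slightly increases measured effects); it is a phenomenological device, not a
biophysical claim about lesional tissue.

**Cognition.** Seven domain scores are generated as
`intercept + covariate effects (age, sex, education) + loading × z(FDC) + noise`,
where `z(FDC)` standardizes each subject's intended tract FDC against the
same-timepoint healthy controls. Each domain loads (0.35) on three
association pathways (cingulum, SLF and its temporal part, ILF, IFOF,
uncinate, forceps); with the default deficits this yields patient impairment
rates of the right order (~20% CI, ~20% MCI at baseline) and a mean patient
cognition Z near −0.8, without being tuned to reproduce any cohort's exact
frequencies. With noise and covariate effects zeroed, domain scores are an
exact affine function of tract FDC (tested). EDSS is a linear function of
mean damage plus noise, rounded to half points; volumes are drawn from
group-level normal distributions.

What the generator does **not** emulate: image-space anatomy (tracts are
axis-aligned voxel paths on a 20³ grid with deliberate 2–3-fixel crossings),
registration error, spatially correlated noise, lesion growth over time,
practice effects in cognition, or missing data. Passing tests therefore
demonstrate correctness of the statistical machinery under a known model,
not robustness to real-data artefacts.

# Fixel-wise inference (CFE)

Group contrasts are fitted per fixel by OLS on a shared design (group,
age, head-size scale as nuisance), giving
$t = c^{\top}\hat\beta / \sqrt{\hat\sigma^2 c^{\top}(X^{\top}X)^{-1}c}$.
Connectivity-based enhancement integrates threshold-exceedance extent,
weighted by streamline connectivity:

$$e_i \;=\; \sum_{h = dh,\,2dh,\,\dots \le t_i} dh\; h^{H} \Big( \sum_j c_{ij}^{\,C}\, \mathbf{1}[t_j \ge h] \Big)^{E}$$

with $c_{ij}$ = (streamlines through both $i$ and $j$) / (streamlines
through $i$), $c_{ii} = 1$. Exponents default to the enhancement method's
published values ($dh = 0.1$, $C = 0.5$, $E = 2$, $H = 3$) and are
configurable; the implementation is verified against a direct double-loop
summation and is monotone in $t$ by construction. Connectivity-weighted
pre-smoothing of the fixel data is available but off by default, since no
smoothing extent is part of this design.

Inference uses Freedman–Lane permutation: residuals from the nuisance-only
model are permuted and added back to the nuisance fit, respecting the
covariates; the maximum enhanced statistic per permutation forms the null,
and $p_i = (1 + \#\{\text{perm max} \ge e_i\})/(m + 1)$, which can never be
zero. If $n!$ is smaller than the requested number of permutations, all
distinct permutations are enumerated instead (and flagged). Contrasts are
one-sided by default (deficits in patients), two-sided optionally —
whether the original analyses were one- or two-sided is not documented, so
this is left as configuration rather than asserted.

# Tract-of-interest statistics

Baseline group comparisons are one-way ANCOVAs: group indicators plus
covariates (age, sex, head scale; education for cognitive-profile
comparisons; optionally treatment as binary or 5-level), with the group
partial F from nested residual sums of squares, covariate-adjusted means at
the observed covariate means, and all pairwise contrasts Bonferroni-corrected
within the tract (family = number of pairs). Across tracts, model p-values
are Bonferroni-corrected with family = number of tracts tested for that
metric; the family size is recorded in every output because the original
description ("multiple models' comparisons") does not fix it.

Longitudinal change uses a random-intercept linear mixed model
(`group * time + covariates`, REML via lme4), with baseline age and sex as
default covariates (the original covariate set is unstated; this is
configurable). Inference on fixed effects uses the large-sample normal
approximation — the simplest defensible contract, avoiding
degrees-of-freedom heuristics; per-phenotype slopes are reported as
`time + group:time` contrasts. With zero random-intercept variance the
estimates collapse to pooled OLS (tested), and simulated slopes are
recovered within 10% over 500 replicates.

# Cognitive phenotyping

Normative models are regression-based (the standard approach for this
battery): each domain is regressed on age, sex (1 = male) and binary
education in healthy controls only; Z-scores scale the residual by the HC
residual SD ($n - p$ denominator). Classification: **CI** if ≥ 2 of 7
domains have Z ≤ −2; else **MCI** if ≥ 2 have Z ≤ −1.5; else **CP**
(thresholds inclusive). Classification is monotone — lowering any domain
never moves a subject toward CP — verified exhaustively on a 7-dimensional
grid. Missing domains refuse classification by default; a lenient mode
classifies only when the observed domains already settle the class. Since
it is unstated whether follow-up scores were referenced to baseline or
follow-up controls, norms are fitted per timepoint by default (absorbing
learning effects), with a flag to reference baseline.

# Clinical association and prediction

The baseline association model is a three-block hierarchical regression:
demographics/clinical covariates forced; conventional MRI (volumes, lesion
load) added; candidate fixel metrics entered only after a univariate screen
(p < 0.05) and then pruned by backward elimination (p-to-remove 0.10, the
common software convention — the original threshold is unstated). The block
ΔR² quantifies the added value of fixel metrics beyond atrophy and lesion
load.

The prediction framework: 80/20 train/test split by seeded shuffle; 10-fold
outer CV on the training set; within each outer training set an inner
5-fold loop retains a feature only if univariately significant (p < 0.05,
configurable — no alpha is documented) in *all* inner training folds;
features retained in *all* outer loops form the consistent set (an
outer-majority variant is provided; strict is the default, matching "100%
consistency"). A bidirectional stepwise-AIC model over the consistent set is
then refitted on the full training set (not averaged across folds) and
applied frozen to the untouched test set. `AIC = n log(RSS/n) + 2k`
matches `stats::extractAIC`; ties break deterministically (drop before add,
then lexicographic). A fingerprint of the test rows taken before training
is re-verified at evaluation as a leakage guard. The inner univariate
screens are unadjusted for covariates by default (also unstated in the
original; partialling can be emulated by pre-residualizing features).

# Numerical choices and degenerate inputs

* Threshold comparisons in CFE use a 1e-12 slack so that `t = 1.0` counts
  as exceeding the `h = 1.0` threshold exactly.
* Zero residual variance in a fixel GLM yields a ±Inf t sentinel with a
  warning, never NaN; an all-zero contrast yields t = 0.
* A perfect fit (RSS within 1e-12 of zero relative to the outcome's total
  sum of squares) makes AIC undefined and raises an error.
* Rank-deficient designs fail with the offending columns named (QR pivots).
* FD < 0, FC ≤ 0, det(J) ≤ 0 and zero directions are validation errors.
* HC standardization SDs below 1e-12 fall back to 1 (relevant only in
  noise-free configurations).
* All randomness flows through one integer seed via named substreams
  (template, subjects, noise, dropout, lesions, cognition, ...), so stages
  are independently reproducible and identical configurations are
  byte-identical.

# Problem sizes used by the test suite

The suite runs at the sizes the checks were designed for: 1000 random warps
against the Monte-Carlo FC oracle; the full 7⁷ classification grid; 200
null replicates × 200 fixels × 500 permutations for family-wise error
calibration (and 1000 permutations for the one-tract sensitivity check at
n = 30 + 30, 0.8 SD); 1000 null ANCOVA replicates; 500 mixed-model recovery
replicates; 200 stepwise instances against exhaustive best-subset search;
100 + 100 nested-CV recovery and null runs at n = 320 with 20 candidate
features; and the full default cohort (95 + 327 subjects, two visits) for
the end-to-end ordering checks. The acceptance script reports the same
quantities at moderately reduced replicate counts.

# Known limitations

* FD is an input; nothing is inferred from diffusion signal.
* The FC closed form is exact for affine warps; real nonlinear warps are
  only locally affine.
* Mixed-model p-values are asymptotic; with very few subjects they are
  anticonservative.
* The stepwise-AIC rule retains a pure-noise covariate whenever its |t|
  exceeds √2 (~16% of null cases) — an inherent property of AIC, not a bug;
  the nested-CV consistency filter upstream is what controls false
  inclusion in the prediction framework.
* Synthetic lesion attenuation is phenomenological (see above); do not
  interpret it biologically.
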