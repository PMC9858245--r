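---
title: "CT body composition in 3D: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT body composition in 3D: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctanthro)
```

This vignette is the package's own account of its methods: the mass model
and its constants, the rule-based segmentation that stands in for a
learned classifier, what the synthetic data emulate (and what they do
not), the statistical layer, and the design decisions taken where the
problem was genuinely open.

## 1. The whole-body mass model

Given per-tissue voxel tallies from a segmented CT, whole-body masses are

$$\mathrm{MBM_{3D}} = N_{muscle}\, k_{muscle}\, V_{voxel}\, \rho_{muscle},$$

and analogously for subcutaneous and visceral fat with $\rho_{fat}$;
total fat mass is the sum of the two fat compartments, an identity the
code maintains to machine precision. The densities are fixed reference
values — muscle 1.06 g/mL, adipose tissue 0.923 g/mL — stored in
`mass_constants()` together with the voxel volume, so unit conversions
(g to kg, mm² to cm²) live in one place. All masses and L3 areas are
divided by squared body height; normalization commutes with the
extrapolation factors, so the order is immaterial.

**Extrapolation factors.** Clinical acquisitions rarely cover the whole
body. For a given acquisition field, each tissue's factor $k \ge 1$ is
the arithmetic mean over a CT atlas of (whole-body voxels) / (voxels in
the acquired area); a whole-body field has $k = 1$ exactly. We fix $k$
per field and per tissue — not per patient — since the atlas is the only
information available about unseen anatomy. Two consequences are worth
noting and are tested: with an atlas equal to the test subject itself the
reconstruction is exact, and for an abdomino-pelvic field the visceral
factor is exactly 1 because all visceral fat lies between the ischium
and the diaphragm.

## 2. Rule-based segmentation

The package deliberately uses a deterministic, fully inspectable
classifier rather than a learned one:

1. **Body mask** — threshold at −500 HU, keep the largest 3D connected
   component, fill holes slice-wise (recovering the lungs). The −500 HU
   choice separates air from all soft tissue including fat (−100 HU).
2. **HU windows** — fat [−190, −30] HU, muscle [−29, +150] HU, the
   literature-standard "wide" windows that work on injected and
   non-injected scans. These are configuration, not constants: they sit
   in `segmentation_params()`.
3. **Muscle wall rule** — organ parenchyma shares the muscle window, so
   windowing alone cannot isolate muscle. Per axial slice, muscle
   components in contact with the boundary-adjacent subcutaneous fat (or
   with the body boundary itself), completed by boundary-adjacent bone
   such as the skull, are taken as the body wall; after a morphological
   closing (8 mm disc) the region the wall encloses is the visceral
   cavity, and candidate components lying mostly (>50%) inside it are
   removed from the muscle mask.
4. **Fat split** — fat enclosed by the closed muscle wall is visceral;
   all other fat is subcutaneous, including fat on slices with no muscle
   wall at all (e.g. the scalp), for which a warning is emitted. The two
   compartments partition the fat mask exactly.
5. **Noise floor** — 3D components under 64 voxels are discarded.

The 8 mm closing radius is the smallest element that bridges the
inter-muscular gaps a real body wall exhibits without swallowing the
visceral-fat rim; it is exposed in the parameters. Slice indices are
1-based throughout (the R convention), with the axial index increasing
toward the head.

**L3 localization.** For phantoms the construction landmark is returned.
For volumes without landmarks a bone-profile heuristic is documented and
tested: the per-slice bone area (HU > 200) shows a low plateau between
the pelvic bones and the rib cage; L3 is the midpoint of the longest
interior plateau of at least 60 mm, flanked by at least 18 mm of high
bone area on both sides. Fields that lack such a plateau (e.g. a
thorax-only acquisition) are refused rather than guessed at.

## 3. What the synthetic data emulate

**Phantoms.** `generate_phantom()` builds a stylized whole-body anatomy
from stacked elliptical cylinders: a subcutaneous fat ring under the
skin, a muscle wall, and a visceral cavity holding organ tissue and a
contiguous visceral-fat rim (its share set by `visceral_fat_fraction`),
plus bone landmarks — femurs, pelvis, sacrum/spine, a rib shell, a skull.
Class HU values are Gaussian (air −1000, lung −750, fat −100, muscle +40,
organ +55, bone +700; SD 15 HU), chosen so the standard windows separate
classes but organ and muscle overlap — the morphological wall rule is
exercised, not bypassed. Ground truth is voxel-exact by construction,
which gives closed-form oracles: compartment tallies match analytic
shell volumes to within the voxel discretization (≤2% at the default
2 × 2 × 4 mm spacing).

The phantoms are *not* organ-realistic: no partial-volume mixing, no
contrast phases, no metal or beam-hardening artifacts, no pediatric or
severely atrophic anatomy, and the muscle wall is continuous rather than
interrupted. Passing the Dice suite (≥0.95 subcutaneous, ≥0.90 visceral
and muscle across seeds) therefore shows the rules are topologically
correct and self-consistent, not that they reach clinical accuracy on
real scans.

**Atlas population.** Nothing prescribes the diversity of the atlas
behind the extrapolation factors, so the package defines one:
`sample_phantom_spec()` jitters radii by ±5%, thicknesses by ±10%, draws
height from N(1.75 m, 0.09 m) and the visceral fraction from
U(0.25, 0.45). Held-out phantoms from this population recover whole-body
masses from abdomino-pelvic fields to within 10% (typically 5%).

**Cohort.** `generate_cohort()` reproduces the reference case mix
exactly — 526 patients; renal 204, colorectal 93, hepatocellular 72,
GIST 56, melanoma 42, breast 27, others 32; 377 men / 149 women — by
permuting fixed labels rather than drawing multinomials. Covariates are
lognormal with means/SDs matched to the reference descriptive table,
males shifted +20% in muscle and −15% in subcutaneous fat, and each 2D
measure correlated with its 3D counterpart on the log scale (0.96
visceral, 0.86 subcutaneous, 0.85 muscle). Event times are exponential
with hazard $\lambda_0 \exp(\sum \beta_j x_j)$; defaults take
$\lambda_0 = 0.10$/month and log hazard ratios from the reference
univariate estimates (VFM3D log 0.55, SFM3D log 0.98, MBM3D log 0.93,
line of treatment log 0.88), with exponential censoring at 0.01/month
and administrative censoring at 60 months. These defaults give ~64%
events and a median OS near 18 months — a plausibly heavy-event
metastatic cohort. Applying univariate reference coefficients jointly is
a simplification (they were not fitted jointly); the cohort is a test
substrate with known truth, not an epidemiological reconstruction.

## 4. The statistics layer

* **One-year landmark.** Dead = death within 12 months; alive = followed
  beyond 12 months; censored before 12 months is indeterminate and
  excluded (the exclusion count is reported). This censoring rule is a
  package decision; other conventions exist.
* **ROC/AUC.** Midrank Mann–Whitney AUC; two-sided p versus 0.5 from the
  tie-corrected normal approximation (`wilcox.test`). Orientation is
  fixed so AUC ≥ 0.5, with the direction recorded — `"less"` is the
  "low marker = risk" pattern.
* **Youden cutoff.** Candidates are midpoints between adjacent distinct
  observed values; ties in the Youden index resolve to the lowest
  candidate. Both the cutoff and the tie rule are property-tested
  against exhaustive enumeration.
* **KM / log-rank / Cox.** Product-limit estimates, the k-sample
  log-rank test, and univariate Cox models with Efron tie handling are
  delegated to the `survival` package; the tests validate them against
  independent hand-coded oracles (direct O/E/V tabulation; the analytic
  partial-likelihood score root on a 3-subject dataset). Monotone
  likelihood (complete separation) is flagged as non-converged instead
  of reporting a spurious hazard ratio.
* **Spearman** correlations use midranks with pairwise-complete
  observations; constant columns give `NA` with a warning.
* Tests are two-sided at the 5% level; no multiple-testing correction is
  applied, mirroring univariate reporting practice — a known limitation
  when nine markers are screened.

Calibration is verified by simulation in the test suite: Cox bias
≤ 0.05 with 92–98% interval coverage at $\beta \in \{-0.5, 0, 0.5\}$
(n = 5000, 400 replicates each), and the AUC test rejects between 3% and
7% of 2000 null datasets (n = 200) at the nominal 5% level.

## 5. Problem sizes and numerical choices

Default phantoms use 2 × 2 × 4 mm voxels (~9M voxels); the test suite
and the pipeline default run phantoms at 4 × 4 × 6 mm (~1.5M voxels),
which preserves every topological property while keeping a full
phantom-to-masses cycle around five seconds. The closed-form shell
oracle runs once at the default spacing. Connected components are
8-connected in-plane and merged across adjacent slices by voxel overlap;
morphology uses disc structuring elements sized in millimetres and
rounded to pixels. All randomness flows through explicit seeds;
generation, segmentation and the pipeline are bit-reproducible, and the
pipeline's report bundle embeds its configuration in a JSON manifest.

## 6. Known limitations

* Segmentation accuracy statements are phantom-relative; real CT noise,
  partial volume and anatomy variability are out of scope.
* Extrapolation factors assume the subject comes from the same
  population as the atlas; they fix axial proportions, so atypical body
  geometry biases the extrapolated masses.
* Intramuscular fat is not subclassified; bone and organs are segmented
  only as far as the landmarks require.
* The cohort simulator's hazard structure is exponential with
  time-constant effects; competing risks and time-varying covariates are
  not modelled.
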