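---
title: "Methods: synthetic cohorts and the multimodal signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic cohorts and the multimodal signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepsig)
```

`sleepsig` pairs a synthetic-cohort generator with the multi-stage
analysis pipeline that population neuroimaging studies use to relate
sleep, depression, and cognition phenotypes to task decoding, resting
connectivity, and cortical thickness. This vignette is the package's
account of the science: what each stage assumes, which knobs matter,
what the generator does and does not emulate, and where genuinely open
design choices were resolved.

## The cohort generator

### Phenotypes: a calibrated Gaussian copula

Five phenotypes are modelled jointly: duration of the longest sleep
bout (hours, accelerometer-style), insomnia frequency (ordinal 0–3),
daytime dozing frequency (ordinal 0–3), PHQ-2 depression score
(0–6), and a symbol-digit substitution cognition count. Printed
population correlations among such measures live on mixed
ordinal/continuous scales, so the generator draws latent standard
normals with correlation matrix $L$ and pushes them through marginal
transforms: an affine map for sleep hours (mean 6.8 h — the median
split point used by the stratified re-analysis — sd 1 h), threshold
discretization for the ordinals (PHQ-2 thresholds put roughly 3% of
subjects at the "depressed" cutoff of 3+, matching the order of
magnitude of a general-population imaging cohort), and a rounded
Gaussian count for cognition (mean 19, sd 5).

Discretization attenuates Pearson correlations, so $L$ cannot equal the
target matrix. `calibrate_latent_corr()` fixes this by simulation:
each sweep draws a large latent sample, measures the realized
observed-scale correlations, and moves each latent entry by the
remaining gap (projecting back to positive definite if needed). The
package defaults ship with a pre-calibrated $L$ (400,000 draws, 12
sweeps); the acceptance suite verifies that the realized partial
correlations recover the targets (0.15 insomnia–PHQ-2, −0.072
sleep–insomnia, −0.11 sleep–dozing, 0.081 insomnia–dozing, 0.036
sleep–cognition) within ±0.01 at n = 100,000 and ±0.015 at n = 30,000.

Covariates (age, sex, site, socioeconomic status, education, ethnicity,
accelerometry time offset, head motion, task performance statistics)
are drawn independently of the phenotypes by default;
`covariate_leakage` adds a linear age term to every latent score for
experiments that need confounded phenotypes. With leakage off, the
partial and marginal correlations coincide, which is what makes the
calibration targets interpretable.

### Task voxel data

For subject $s$ and region $g$ the generator emits a voxel-by-time
matrix: a baseline intensity of 100 (the percent-signal-change
reference), per-voxel AR(1) noise, a slow sinusoidal shift of at most
one cycle per run, and a planted category signal during stimulus
blocks. Each of the seven stimulus categories (three shapes, four
faces) has a region-specific pattern built from a shared class pattern
plus a category-specific deviation, so face and shape responses are
linearly separable and the seven categories have a non-trivial
representational geometry. The signal amplitude is

$$a_{sg} = \max\!\big(0,\; a_{0g} + w_g \textstyle\sum_k \tau_k z_k(s)\big),$$

where $z_k$ are standardized phenotypes, $\tau$ is `task_coupling`,
$a_{0g}$ varies ±30% around `task_a0`, and $w_g \in [0.5, 1.5]$ is a
region susceptibility profile. The floor at zero reflects that
separability cannot be negative. The susceptibility profile is shared
across phenotypes deliberately: it makes the planted second-level
coefficient maps of different phenotypes spatially proportional, so
signature correlations have a defined planted sign
($\mathrm{sign}(\tau_a \tau_b)$) rather than being driven by
estimation noise. The signal is inserted five volumes after block
onset, emulating the hemodynamic delay that the preprocessing shift
compensates.

Two noise defaults deserve comment.

* **Drift** (`drift_amplitude = 1`, 0.2–0.8 cycles per run): the drift
  is deliberately slow so that the per-voxel *linear* detrend has a
  real trend to remove. Faster oscillations would survive detrending
  and act as structured noise rather than drift.
* **AR(1) coefficient** (`ar1 = 0.1`): with three averaged samples per
  block and block = class, any temporal autocorrelation lets the
  cross-validated classifier exploit shared within-block noise when
  sibling samples fall in different folds, inflating null accuracy. At
  `ar1 = 0.3` the zero-signal pipeline decodes at ~54%; at the default
  0.1 it sits at 50–51%, which keeps the planted null honest. This is
  a genuine property of block designs with sample-level
  cross-validation, not an artifact of the implementation, and it is
  measured directly by the chance-calibration tests.

The default design has 10 blocks per class (20 blocks cycling the seven
categories), 6 task volumes per block averaged two-at-a-time into 3
samples, 4 rest volumes between blocks, TR 0.735 s — fixed so the
pipeline yields exactly 60 class-labelled samples, balanced 30/30. The
block count and averaging split are a design choice; only the 60-sample
total and the balance are treated as fixed constraints. The within-run
ordering of the seven categories is not prescribed anywhere, so the
generator alternates classes and cycles categories within class.

### Resting connectivity and thickness

Resting data are generated directly on the Fisher-z scale as
per-subject edge vectors over the $R(R-1)/2$ unique region pairs
(row-major lower triangle; 16,110 edges at $R = 180$): a fixed base
connectivity (higher within than between the seven networks), a
brain-wide shift $\sum_k g_k z_k(s)$ scaled by a per-edge
susceptibility in $[0.5, 1.5]$, optional per-edge couplings, and edge
noise (`rest_noise_sd = 0.1` z-units). `tanh` maps values back to
correlations, so they stay in (−1, 1). A 21-component edge set (210
edges) is generated by the same scheme for the IC-level models. Because
the sign of `rest_global_coupling` is configurable independently of
`task_coupling`, opposite directions can be planted for the same
phenotype pair — the task-hypoconnectivity / rest-hyperconnectivity
phenomenon the signature analysis is designed to expose. Cortical
thickness is a 2.5 mm baseline plus fixed region offsets, a coupled
phenotype term (mm per SD), and Gaussian noise.

Default couplings plant the direction pattern of interest: task
amplitude rises with sleep duration (+0.25) and cognition (+0.15) and
falls with insomnia (−0.1), dozing (−0.1), and PHQ-2 (−0.25), while
resting connectivity rises with sleep duration, insomnia, and PHQ-2
(+0.05 to +0.06) and falls with dozing (−0.08). Magnitudes were chosen
once as "moderate, clearly detectable at n ≈ 500" effects; the
sign-recovery suite measures that with these defaults the task
signature correlation of the sleep–depression pair is negative and the
resting one positive in ≥ 90% of 25 independent cohorts of 500
subjects.

## The analysis pipeline

**Partial correlations.** `partial_correlation()` residualizes both
variables on the covariates (QR-based, with a named error for collinear
columns) and correlates the residuals. The p-value uses the exact null
of the Pearson coefficient, $(1+r)/2 \sim
\mathrm{Beta}(n_\mathrm{eff}/2,\, n_\mathrm{eff}/2)$ with
$n_\mathrm{eff} = n - k - 2$, which the tests verify is identical to
the classical t-transform; intervals are Fisher-z at 99% (0.05
Bonferroni-corrected over five phenotypes). The accelerometry time
offset enters only pairs involving the accelerometer phenotype, since
it is a measurement-specific nuisance. Education is entered as an
ordinal score (a defensible alternative is one-hot coding; the ordinal
choice keeps one column and matches how the self-reports are handled).

**MVPA preprocessing** follows a fixed order: shift labels 5 volumes
later, per-voxel linear detrend (mean preserved), percent signal
change about the run mean, average within-block volume pairs, drop
rest, shuffle. Shifting labels instead of rotating data is equivalent
and avoids wrap-around artifacts. A voxel with zero run mean is a named
error rather than a silent Inf.

**Decoding** uses a soft-margin linear SVM (cost 1) under stratified,
seeded 6-fold cross-validation; each test fold holds 10 samples, 5 per
class. Fold assignment first puts samples in a canonical order (class,
then lexicographic values) so the result is exactly invariant to input
order, then shuffles within class. The default solver is a compact dual
coordinate-descent implementation of the linear SVM (the liblinear
algorithm, augmented-bias formulation, tolerance 0.1) compiled via
Rcpp; it makes cohort-scale decoding fast enough for the simulation
suites. `engine = "e1071"` runs the identical fold pipeline through
libsvm, and the test suite cross-checks the two engines (exact
agreement on separable data, mean accuracy difference below 0.03 on
hard problems; the small residual reflects the two formulations'
different handling of the bias term).

**Association maps** standardize the phenotype before fitting so betas
are comparable across phenotypes — a prerequisite for correlating
coefficient maps. Covariate sets are modality-specific: task models
include head motion and task performance statistics, resting models
include motion only, thickness models neither; imaging models carry a
sex-by-age interaction. Task coefficients are divided by the
classification error $1 - \mathrm{accuracy}$, floored at $1/120$ (half
a sample at 60 samples) so a perfectly decoding region cannot produce
an infinite normalized coefficient. FDR is Benjamini-Hochberg within
each phenotype's map, thresholded downstream at 0.05/5; edge models use
Bonferroni with an explicit test count, defaulting to 5 × (number of
edge models) — for the 21-component models that is 5 × 210, reading
"components" as the edge models actually fitted, with the count
overridable.

**RDMs** use 1 − Pearson between category mean patterns (the standard
choice for representational geometry; Euclidean is available), giving
symmetric 7×7 matrices with zero diagonal and 21 informative entries.

**Signature correlations** are Pearson correlations across units of two
coefficient maps, with the beta-distribution parametric p and, for
region-based maps, a spin test: each permutation draws one uniform 3D
rotation, applies it to left-hemisphere centroids and its x-mirrored
version to the right, reassigns every region the value of the region
whose rotated centroid lands nearest its original centroid (per
hemisphere, duplicates allowed, so no region is ever unassigned), and
averages the two hemispheres because regions are bilateral merges. The
spin p-value is the plain fraction of permutations with $|r_\mathrm{perm}|
\ge |r_\mathrm{obs}|$ — a "percentage" definition without the +1
correction, using ≥ at ties. Rotation is the default because it is the
cited test's standard construction; a geometry-free label permutation
is available behind `method = "label"`. Dual significance requires both
p-values below 0.05/5. The calibration suite shows the point of the
exercise: on spatially smoothed null map pairs the parametric test
rejects far above nominal level while the spin test stays at or below
it.

**Stratification** assigns PHQ-2 ≥ 3 to the depressed stratum and
sleep ≥ 6.8 h to the long sleepers (both boundaries inclusive, as the
group definitions state), refits all edge models per stratum, and
recomputes all pairwise signature correlations. With realistic PHQ-2
prevalence the depressed stratum needs cohorts of thousands; the
pipeline records and skips a stratum too small for its covariate model
rather than failing the whole run.

**Global and network means** average the unique off-diagonal pairs
(16,110 at R = 180) and the 7×7 network blocks; the tests verify
against brute-force enumeration and that pair-count-weighted block
means recompose the global mean exactly. Confidence intervals for the
global-mean models are reported at p = 0.01 (Bonferroni over five
phenotypes).

**CPM** residualizes edges on covariates over the full sample by
default — mirroring how the procedure is usually stated — with
within-fold residualization available (`residualize = "fold"`) and
recommended when leakage matters; the construction tests show both
recover a noiseless linear rule. Edge selection within each training
fold is strictly `p < 0.01`; selected edges are averaged into a single
signed summary feature by default, matching the averaged-values
formulation (`feature = "posneg"` gives the classic split into
positively and negatively correlated networks); performance is the Pearson
correlation of pooled out-of-fold predictions with truth. Folds that
select nothing predict their training mean and are recorded. Under the
null this fallback, plus selection overfitting, gives the pooled
performance a small negative bias (measured ≈ −0.03 at 200 candidate
edges and n = 200, inside the ±0.05 calibration band; with very few
candidate edges the empty-fold artifact dominates and the bias grows).

## Problem sizes used by the test and acceptance suites

The suites scale the study conditions to desk size while keeping the
statistical structure: null decoding calibration at 50 subjects × 20
regions; phenotype-structure recovery at 30,000 (and 100,000 for the
calibration property); opposing-signature sign recovery over 25 cohorts
of 500 subjects × 8 regions with 16-voxel regions; spin calibration
over 500 replicate map pairs on a 50-region atlas with 150
permutations each; CPM nulls over 100 cohorts of 200 subjects × 200
edges. The end-to-end pipeline example runs 200 subjects × 10–20
regions in well under a minute.

## Known limitations

* The generator emulates the *statistical* structure of a population
  imaging study — correlation structure, planted effect directions,
  block-design temporal structure — not the physics: no volumetric
  geometry, no physiological noise, no spatial voxel autocorrelation
  within regions, no site effects on the imaging measures, and no
  missing data. Passing tests therefore validate the estimators and
  their calibration, not robustness to real-data artifacts.
* Cross-validated accuracy is an optimistically biased activation proxy
  whenever samples within a block share noise; the default noise keeps
  this below half a percentage point, but analysts applying the
  pipeline to data with strong temporal autocorrelation should expect
  an inflated chance level (or use leave-block-out folds, which this
  implementation does not provide).
* The spin test treats bilateral regions by averaging the two
  hemispheres' reassignments; vertex-level spin tests and
  variogram-matching nulls are out of scope.
* Signature correlations across as few as 8–10 regions (the scaled-down
  suites) have wide sampling bands; the sign-recovery criterion is
  about direction, not magnitude.
* CPM's full-sample residualization leaks covariate information across
  folds; the effect is small here (covariates are independent of edges
  under the generator) but the within-fold option is the safer default
  on real data.
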