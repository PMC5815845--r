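---
title: "Decomposing working-memory activation into independent spatial networks"
author: "wmnica"
output: rmarkdown::html_vignette
---

## The problem and the model

Verbal n-back fMRI experiments contrast a high-load condition (2-back) with a
low-load attention control (0-back). At the group level the data form a
subjects-by-voxels matrix `X` of first-level 2-back − 0-back contrast
estimates. These contrasts are strongly non-Gaussian across both subjects and
voxels (heavy skew and kurtosis), which makes independent component analysis
a natural dimensionality reduction: `wmnica` models the standardized contrast
matrix as

```
X ≈ A S
```

where `S` is a k-by-voxels matrix of spatial sources ("voxel loadings",
statistically independent across voxels) and `A` is a subjects-by-k matrix of
mixing coefficients ("subject scores"). A subject with a high score on a
component coactivates the voxels loading on that component; components are
therefore interpreted as networks of coactivated regions within the
working-memory network (WMN). Behavior enters only after the decomposition:
components are annotated by regressing their scores on task performance, by
resampling stability, and by association with white-matter microstructure.

## Pipeline stages and the choices behind them

**Behavioral scoring.** Task schedules are generated under hard constraints:
six blocks of 14 stimuli per condition, exactly 3 targets per block, and a
configurable number of lure trials (default 15 of 84 2-back stimuli, 17.9%);
a lure is a nontarget matching the letter one or three positions back. Letter
assignment is sequential with rejection of accidental targets and lures, and
flags are re-verified against the final sequence. Sensitivity is the
signal-detection d′ = Φ⁻¹(H) − Φ⁻¹(F) computed over non-missing trials only.
Extreme proportions are corrected cell-wise, 0 → 0.5/N and 1 → (N−0.5)/N:
among the common conventions this is the one that reproduces the documented
performance ceiling of 4.34 for an 18-target/66-nontarget condition, which is
why it is the package default (alternatives such as the log-linear rule give
a different ceiling). Missing responses are removed from both numerator and
denominator of H and F. Subject exclusions follow five rules (overall
missingness > 30%; > 30% of targets missing in ≥ 3 blocks; the same for
nontargets; any cognitive measure beyond 4 SD of the sample mean; incomplete
data). The 4-SD screen is a single pass on the pre-exclusion sample — an
iterative screen would remove additional borderline subjects and is
deliberately not performed. The per-block target rule is interpreted
per block: with 3 targets per block, a single missing target already exceeds
30% of that block's targets.

**Mask construction.** Subjects whose missing-voxel count exceeds the mean by
4 SD are dropped, then every voxel with any remaining missing value, so all
later stages see complete data. The WMN mask is the set of voxels with
positive one-sample t and Benjamini–Hochberg FDR-adjusted p ≤ α (default
0.05). The t test is two-sided with the positivity restriction applied
afterwards; a one-sided variant would admit marginally more voxels, and the
two-sided-plus-restriction reading was chosen because the underlying t map is
a general-purpose product of the pipeline. BH was chosen among FDR variants
as the standard step-up procedure. Kurtosis is reported non-excess
(normal = 3) so diagnostic ranges are comparable with common reporting.

**ICA core.** Orientation matters: voxels are observations and subjects are
variables, so "centering and scaling the variables" standardizes each
subject's map, and scaling happens after batch residualization
(residualization produces standardized per-voxel residuals; the ICA then
re-standardizes per subject). The decomposition is fixed-point FastICA:
PCA whitening to k dimensions, symmetric (parallel) updates with the
log-cosh contrast (α = 1), convergence when the maximal change of any
unmixing direction falls below 1e-6, at most 1000 iterations, and up to 5
random restarts on non-convergence. These are the conventional defaults of
the fixed-point algorithm; k is never selected automatically — the scree of
the subject-correlation eigenvalues is provided and the analyst chooses.
Because the ICA sign is arbitrary, every component is recoded so that its
maximum-absolute-loading voxel is positive (scores negated along with the
source, leaving `A S` unchanged), and components are ordered by decreasing
score variance for determinism. Subject scores are computed as the
least-squares regression of each standardized subject map on the sources —
the same operation used to project the sources onto new subjects
(dual-regression-style scoring). Full least squares is used rather than the
orthonormal shortcut `S x / n` because estimated sources are decorrelated
only to numerical tolerance; the two agree for exactly orthonormal sources.
Thresholding for visualization and annotation pools the absolute loadings of
all k components and keeps the most extreme fraction (default 10%).

**Annotation.** Supra-threshold voxels are clustered by 26-connectivity by
default (corner neighbors count; 6 and 18 are available), positive and
negative loadings separately. Each voxel is assigned to its
maximum-probability atlas region when that probability is at least 25%, ties
broken by region index; regions are reported for a cluster when they
contribute more than 10 voxels, with the percentage computed against the
region's total labeled voxels in the analysis set. The 25% floor is applied
to the assigned (maximum) region's probability — the only deterministic
reading when a voxel's probabilities are spread over several regions.

**Associations.** All association models are ordinary least squares on
z-transformed variables, giving standardized coefficients; factors are coded
numerically before z-scoring. Candidate predictors are first screened for
collinearity: pairs with |r| > 0.5 lose their later member in the declared
column order, iteratively, making the filter deterministic and auditable.
Each component's model includes the remaining components' scores as
covariates; FDR correction spans the declared predictors-by-components
family. Variance explained is reported as the squared partial correlation
t²/(t² + df). This is a convention: semi-partial or hierarchical ΔR²
definitions are equally defensible, and the partial form was chosen because
it is computable from the reported t and df alone. p values that underflow
are floored at 1e-300 rather than reported as 0. Voxel-wise models reuse the
same design without component covariates, vectorized through a single QR
factorization.

**Stability.** Bootstrap stability draws two *disjoint* subject subsamples
per run, decomposes each, matches both to the full-sample reference by
maximal absolute loading correlation, and correlates the matched loadings
across the two subsamples. Matching is greedy per estimated component
without a uniqueness constraint (mirroring a per-component "best match"
rule); a one-to-one assignment mode is available and is what the recovery
tests use, since with planted ground truth a permutation is known to exist.
Matched components are sign-aligned before any averaging of regression
coefficients — unaligned averaging would cancel. Cross-validation splits
subjects into disjoint training and test sets, decomposes the training set,
projects the sources onto the test subjects, and regresses the projected
scores on performance measures plus sex and age; the statistic is the
percentage of runs with nominal p < 0.05. Its permutation null permutes the
performance columns across subjects and repeats the cross-validation.
Because permuting the outcome side changes neither the decompositions nor
the projected scores, the implementation reuses the per-run projections and
recomputes only the regressions; this is algebraically identical to a full
re-run at a fraction of the cost. Empirical p values use the add-one
estimator (1 + #{null ≥ observed})/(n + 1), which cannot return 0.

**White matter.** Per region, the component score is regressed on the
region's mean FA with sex, age, handedness, intracranial volume, and the
remaining components' scores as covariates. Two global tests summarize the
70 region p values per component: a two-sided one-sample Kolmogorov–Smirnov
test against Uniform(0,1) (asymptotic by default; the exact small-sample
distribution is available, n = 70 being moderate), and a permutation test on
the count of nominally significant regions, permuting the component's scores
only so the covariate–FA linkage stays intact. Both are BH-corrected across
components. Hemisphere-averaged ("both") scopes can be added, in which case
the FDR family covers all fitted scope-by-region tests.

## The synthetic generator

The generator is the package's ground truth, not a fixture: contrast maps
are `A S` plus per-voxel batch offset fields plus i.i.d. Gaussian noise.
Sources are Laplace-distributed on a sparse support (default 20% of voxels)
and z-scaled — sparse super-Gaussian maps are exactly the regime in which
spatial ICA is identifiable, matching the heavy-tailed diagnostics the
pipeline checks for. Scores are exactly standardized normals. Batch factors
default to 3 hardware, 2 software, and 2 processing levels with offset
fields of SD 0.5 — an additive structure that the residualization stage must
remove. Behavioral variables tied to a component use
`slope · score + sqrt(1 − slope²) · ε`, so the population standardized slope
is the configured value and the total variance is 1; the default plants
slopes of 0.24 (component 3 on 2-back performance) and 0.25 (component 4 on
0-back performance), the effect sizes around which the association tests are
designed. Remaining behavioral variables are independent standard normals,
and covariates are drawn with realistic marginals (e.g. 90.3% right-handed,
binary chronotype, Likert motivation/difficulty/smoking) but carry no
planted effect. FA tables hold 70 regions (35 bilateral pairs) on a
plausible FA scale (0.45 ± 0.04) with standardized planted slopes where
configured. The probabilistic atlas places region seeds by farthest-point
sampling and builds Gaussian blobs (SD 3 voxels) normalized so per-voxel
probability sums stay ≤ 1; with the default 20 regions on a 20³ grid every
region keeps a core of well over 30 voxels above 25% probability. Trial
responses come from the equal-variance signal-detection model with a
configurable miss rate.

What the generator does **not** emulate: spatial autocorrelation beyond blob
smoothing, raw BOLD time series and first-level GLM noise structure,
realistic inter-regional covariance of FA, or lure-specific response
processes. Passing recovery tests therefore demonstrate correctness of the
algorithms under the assumed generative model, not performance on real
scanner data.

The optional skew/kurtosis tuning of the contrast distribution was
considered and not adopted: sparse Laplace sources already produce the
super-Gaussian regime the decomposition requires, and matching printed
moment ranges would add parameters without changing what the recovery tests
can show.

## Numerical choices and degenerate inputs

Convergence: tolerance 1e-6 on the unmixing directions, 1000 iterations,
5 restarts; non-convergence is a warning plus `converged = FALSE`, never a
silent failure. Rank: requesting more components than the numerical rank
(eigenvalues above 1e-10 of the largest) is an error. Constant vectors are
errors where a statistic is undefined (z-scoring, residualization input,
one-component FA columns) and flags where a map-level statistic can carry on
(zero-variance voxels in t maps, constant rows in diagnostics). Exact batch
fits (zero residual variance) warn and return zeros rather than dividing by
zero. Cluster labeling breaks probability ties by the lower region index;
cluster ordering is by decreasing size with the smallest member index as
tie-break, so all annotation output is enumeration-order independent. All
randomness flows through a single seed-scoped helper that restores the
caller's RNG state, making every generator and resampling function a pure
function of (inputs, seed).

## Problem sizes used by the test suite

The suite exercises the pipeline at deliberately reduced scale: grids of
2000–4000 voxels, 200–300 subjects for decomposition tests, 100 runs and 50
permutation repeats for cross-validation calibration, 999 permutations for
FA empirical p values, and 50–200 generator seeds for effect-size recovery.
These sizes were chosen so that Monte-Carlo error bounds derived from the
corresponding closed forms (binomial SEs, regression coefficient SEs of
roughly 1/√n) are tight enough to make each assertion informative.

## Known limitations

Component indices are identifiable only relative to a reference
decomposition; any cross-run aggregation must match and sign-align first,
and the package exposes both greedy and one-to-one matching because they can
disagree when two estimated components both resemble one reference. The KS
test treats the 70 region p values as independent, which real FA tables
violate; the permutation test does not rely on that assumption and is the
more robust of the two global summaries. The collinearity filter's outcome
depends on the declared priority order by design. Voxel-wise regression
assumes a common design across voxels and complete cases throughout.
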