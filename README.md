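# wmnica

Spatial ICA decomposition and functional annotation of working-memory fMRI
contrast maps.

`wmnica` is for researchers who study individual differences in working
memory with n-back fMRI and want to move from voxel-wise maps to a small
number of data-driven brain networks. Given a subjects × voxels matrix `X`
of 2-back − 0-back contrast estimates, the package models

```
X ≈ A S
```

with `S` a k × voxels matrix of statistically independent spatial sources
("voxel loadings") estimated by fixed-point FastICA (PCA whitening,
symmetric log-cosh updates), and `A` a subjects × k matrix of mixing
coefficients ("subject scores"). Around that core it implements the full
analysis a working-memory network (WMN) study needs:

- n-back task schedules, signal-detection d′ = Φ⁻¹(H) − Φ⁻¹(F) scoring with
  extreme-proportion correction, and response-based subject exclusions;
- the WMN mask from voxel-wise one-sample t tests with Benjamini–Hochberg
  FDR control, plus batch residualization and distributional diagnostics;
- connected-component clustering of thresholded loadings and labeling
  against a probabilistic atlas;
- standardized multiple-regression association of component scores (and
  single voxels) with behavior, with collinearity filtering and family-wise
  FDR;
- disjoint-split bootstrap stability, dual-regression-style projection
  cross-validation, and permutation empirical p values;
- region-wise fractional-anisotropy (FA) association tests with
  Kolmogorov–Smirnov uniformity and permutation-count statistics;
- a synthetic-data generator with planted sources, behavioral effects,
  batch offsets, and signal-detection responders, used as ground truth by
  the entire test suite.

## Worked example

```r
library(wmnica)

## simulate a study: 300 subjects, 15x15x10 grid, 6 planted networks
cfg <- synth_config(n_subjects = 300, grid_dims = c(15, 15, 10), seed = 42)
ds  <- generate_dataset(cfg)

## behavioral scoring of one simulated responder
sch  <- build_schedule(seed = 1)
resp <- generate_trial_responses(sch, d_prime = 2.5, miss_rate = 0.02, seed = 2)
score_dprime(resp, sch, "2back")
#> [1] 2.89

## batch residualization, then decomposition
resid <- residualize_matrix(ds$contrast, ds$batches)
scree <- pca_scree(resid)
round(scree$eigenvalues[1:8], 1)
#> [1] 24.2 23.5 22.3 20.8 20.3 19.1  1.4  1.3     # six components stand out
dec <- fastica_decompose(resid, k = 6, seed = 1)
dec
#> <wmn_ica> k = 6 components, 300 subjects x 2250 voxels; converged after 8 iterations

## associate component scores with behavior (FDR over predictors x components)
res <- associate_components(dec, ds$behavior,
         c("d_prime_2back", "d_prime_0back", "rt_difference",
           "episodic_memory", "item_familiarity", "age"))
head(res[order(res$q), c("component", "term", "beta", "p", "q", "r_squared")], 2)
#>   component          term   beta        p        q r_squared
#> 7         2 d_prime_2back -0.299 2.80e-07 1.01e-05    0.0877
#> 26        5 d_prime_0back -0.265 5.89e-06 1.06e-04    0.0689
```

The two FDR-significant rows are exactly the planted effects: the generator
tied 2-back performance (standardized slope 0.24) to one planted network and
0-back performance (slope 0.25) to another, and `match_components()`
confirms those planted sources are the decomposition's components 2 and 5
(the signs of ICA estimates are arbitrary; matching reports them). The
`r_squared` column is the squared partial correlation t²/(t² + df).

```r
## threshold, cluster, and label the components against the atlas
th <- pooled_threshold(dec, 0.10)      # 10% most extreme |z| across components
round(th$threshold, 2)
#> [1] 1.97
ann <- annotate_components(dec, th, ds$atlas, ds$contrast$coordinates)

## global FA association per component (KS uniformity + permutation count)
g <- fa_global_tests(dec, ds$fa[, -1],
                     ds$behavior[, c("sex", "age", "hand", "icv")],
                     n_perm = 999, seed = 3)
g[2, c("component", "observed_count", "empirical_p", "empirical_q")]
#>   component observed_count empirical_p empirical_q
#> 2         2              9       0.008       0.048
```

Component 2 — the network carrying the planted 2-back effect — is also the
one with a planted FA association (9 of 70 regions nominally significant,
permutation empirical p = 0.008, FDR-corrected 0.048 across the six
components); the other components stay at null levels.

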