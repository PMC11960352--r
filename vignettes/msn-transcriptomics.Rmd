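---
title: "Morphometric similarity networks and imaging transcriptomics with msntx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks and imaging transcriptomics with msntx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msntx)
```

## The analysis chain

`msntx` implements a case-control imaging-transcriptomics pipeline for
parcellated structural MRI. Its stages, each usable on its own:

1. **Morphometric similarity networks (MSN).** Each cortical region carries a
   vector of morphometric features — by default cortical thickness (CT), gray
   matter volume (GM), surface area (SA), Gaussian curvature (GC) and mean
   curvature (MC). Features are z-normalized across regions (sample SD,
   denominator $N-1$), and the MSN entry for regions $i, j$ is the Pearson
   correlation of their feature vectors:
   $\mathrm{MSN}_{ij} = r(z_i, z_j)$, with the diagonal defined as 0. The
   **regional strength** $s_i = \sum_{j \ne i} \mathrm{MSN}_{ij}$ is the
   signed sum of a region's correlations with all others: high strength means
   the region's morphometric profile resembles most of the cortex, low (or
   negative) strength means it is differentiated.
2. **Case-control contrast.** Per region, strength is modelled by Gaussian
   ordinary least squares, `strength ~ group + age + sex + eTIV`, and the
   two-sided $t$ statistic of the group coefficient (case $-$ control) is
   extracted with $p$ from the exact $t$ distribution on the residual degrees
   of freedom. Exploratory significance uses the $P < 1/N$ rule ($N$ = number
   of regions): under the global null fewer than one false positive is
   expected across the map.
3. **Spin-permutation nulls.** Correlations between two cortical maps are
   never tested against the parametric Pearson null, which ignores spatial
   autocorrelation. Instead parcel centroids are rotated on the sphere by a
   uniform random rotation, each parcel takes the value of the nearest
   rotated parcel (duplicates permitted), and the observed $|r|$ is compared
   with the spun distribution: $p_{\mathrm{spin}} = (1 + \#\{|r_k| \ge
   |r_{\mathrm{obs}}|\})/(1 + n_{\mathrm{perm}})$.
4. **PLS regression on gene expression.** With a regions $\times$ genes
   expression matrix $X$ (an Allen Human Brain Atlas style table, left
   hemisphere by default) and the $t$-map $y$ as the univariate response, the
   first partial least squares component has the exact closed form
   $w \propto X^\top y$ after columnwise standardization; the PLS1 score map
   is $Xw$, sign-aligned so that it correlates positively with $y$.
5. **Bootstrap gene ranking and selection.** Regions are resampled with
   replacement, PLS1 is refit per resample, replicate weight vectors are
   sign-aligned to the full fit, and each gene's $Z$ is its full-fit weight
   divided by the bootstrap SD of its replicate weights. Two-sided normal
   $p$-values are corrected by Benjamini-Hochberg FDR (default $q < 0.005$,
   i.e. 5 per mille) and split into PLS1+/PLS1- by weight sign; separate
   hard cuts ($Z > 5$, $Z < -5$) produce the lists conventionally uploaded to
   enrichment platforms.
6. **Candidate panels.** A candidate gene list (e.g. neuroinflammation genes
   such as *SMAD3*, *IRF3*, *PRR5*, *JAK1*) is intersected with the
   expression universe; each overlapping gene's map is correlated with the
   $t$-map, tested by spin permutation, and BH-corrected across the panel,
   with pre- and post-FDR flags reported.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| features per region | 5 (CT, GM, SA, GC, MC) | — | the standard T1-derived set; ≥ 3 required for a meaningful 5-point Pearson |
| Euler QC threshold | $-200$ | Euler number | subjects with FreeSurfer Euler number strictly below are excluded; missing values pass with a warning |
| significance rule | $P < 1/N$ | — | exploratory nodal correction; strict inequality |
| analysis hemisphere | left | — | donor expression data are typically left-hemisphere only; configurable |
| `n_perm` | 1000 | spins | minimum attainable $p_{\mathrm{spin}} = 1/1001$ resolves $p \approx 0.001$ claims |
| `n_boot` | 1000 | resamples | stabilizes bootstrap SEs at ~3% relative error |
| `fdr_alpha` | 0.005 | q | 5-per-mille FDR for the PLS1± gene families |
| `z_cut` | 5 | Z | hard threshold for enrichment export lists |
| candidate alpha | 0.05 | p | candidate panels form their own BH family |

The FDR family structure is deliberate: all genes form one family for PLS1±
selection; the candidate panel forms a second, separate family. Regions are
never an FDR family — the $1/N$ rule covers the map.

## The synthetic-data generator

Real inputs for this kind of study are restricted clinical MRI plus a
donor-derived expression matrix, so the package ships a generator that
emulates the study design with known ground truth; every pipeline stage is
validated against it.

**Geometry.** `make_parcellation()` lays quasi-uniform parcels on the unit
sphere (area-uniform spiral with golden-angle azimuths plus seeded jitter),
152 left / 156 right by default, emulating a ~308-parcel subdivided cortical
atlas. Hemispheres occupy the $x<0$ / $x>0$ half-spheres; the
anterior-posterior axis is operationalized as the $y$ coordinate.

**Spatial autocorrelation.** All latent fields are Gaussian processes on the
parcel centroids with covariance $\exp(-\theta_{ij}/\rho)$, $\theta$ the
geodesic angle and $\rho$ = 0.5 rad by default. This is the simplest model
under which spin-test calibration is a meaningful claim.

**Features.** In standardized units, a subject's regions $\times$ 5 matrix is
a shared population pattern plus a subject-specific smooth field, a
covariate-modulated second pattern (so age/sex/eTIV adjustment is
non-vacuous), and white noise; the result is mapped to realistic raw scales
(e.g. CT ≈ 2.5 ± 0.25 mm). The shared pattern gives every region a common
profile direction with a **lognormal (right-skewed, all-positive) amplitude**
plus two weaker heterogeneous components. The skew matters: most regions then
align moderately with the cortical mean profile and a few strongly, as in
real cortex. A symmetric amplitude would leave the mean profile
near-degenerate, making planted effects unstable in sign and letting the
global subject mode flip between subjects — early designs of this generator
showed exactly that pathology (rare cohorts with dozens of coherent false
positives), which disappears with the skewed amplitude.

**The planted effect.** Cases shift each effect region's feature vector by
`effect_size` standardized units along the direction from its population
profile toward a strongly expressed (90th-percentile norm) profile fully
aligned with the cortical mean profile (sign $+1$), or its opposite
($-1$), capped at arrival. Moving toward the mean profile raises the
region's correlation with the average region and hence its strength;
moving away lowers it. Effect regions are drawn from the middle (15-85%)
band of baseline mean-profile alignment, where change in either direction
is detectable — a region already maximally similar to the cortex cannot
become more similar. Defaults: 59 cases vs 61 controls, 8 effect regions
(6 increases, 2 decreases, echoing the bilateral frontal/parietal pattern
such studies report) at `effect_size = 1.5`, which yields planted $|t|$
values of roughly 3-10 at this sample size. The effect is planted on
features, not on strengths, so recovery tests exercise the entire MSN
pipeline.

**Expression.** Background genes share a fixed anterior-posterior gradient
(amplitude `gradient_strength`) plus independent smooth noise, emulating the
dominant spatial mode of cortical expression; signal genes are
$\pm\,\beta \cdot \mathrm{std}(\text{target}) + \text{smooth noise}$ with
recorded signs (defaults: 1000 genes, 20 signal genes, $\beta = 0.8$, noise
SD 0.5). All columns are standardized on output.

**What the generator does not emulate.** Real cortical geometry and parcel
size variability, FreeSurfer segmentation artifacts, scanner and site
effects, donor structure and probe-to-gene aggregation of the expression
atlas, and spatial non-stationarity. Passing recovery tests therefore shows
the pipeline is correct and well calibrated under its stated model — not
that the biological findings of any particular cohort are reproducible.

## Numerical choices

- **Closed-form PLS1.** With a univariate response the first PLS weight
  vector is exactly $X^\top y / \lVert X^\top y \rVert$ on standardized
  data, so no iterative fit (and no convergence nondeterminism) is involved;
  the implementation and an independently coded oracle are compared in the
  tests at $10^{-10}$.
- **QR with pivot handling.** The region-wise GLM is one QR decomposition
  shared by all regions. Base R's `qr()` pivots columns for rank detection;
  the group-coefficient variance is read off $(X^\top X)^{-1}$ only after
  un-pivoting. (The label-swap property test — swapping case/control labels
  must negate every $t$ — is what catches this class of bug.)
- **Seeds.** One master seed per run; each stage derives a named sub-stream
  (`derive_seed`), so changing `n_perm` never perturbs the bootstrap stream,
  and every output is a pure function of (inputs, config, seed).
- **Degenerate inputs.** Constant feature columns, zero-variance maps and
  zero-variance genes are errors naming the offender; bootstrap resamples
  with fewer than 3 distinct regions are redrawn and counted; genes constant
  within a resample contribute zero weight to that replicate.
- **Ties.** Nearest-rotated-centroid assignment breaks ties by first index;
  sign alignment uses the sign of the inner product with the full-fit
  weights, with ties resolved toward no flip.
- **Add-one p-values.** Spin $p$-values use the $(1+k)/(1+n)$ rule, so
  $p = 0$ is unattainable and the minimum is reported exactly.

## Identifiability caveats of the bootstrap Z

The $Z$ statistic ranks genes by the *stability* of their PLS1 weight under
region resampling, not by effect size alone. Two consequences worth knowing:

- When the target map is substantially aligned with the shared expression
  gradient, background genes most aligned with the gradient acquire very
  stable weights (tiny bootstrap SE) and can out-rank planted signal genes
  whose correlation with the target is far larger. The package's acceptance
  script therefore evaluates planted-gene recovery against a reference
  target orthogonal to the gradient, where the statistic is identified.
- When the target is spiky (signal concentrated in a handful of regions),
  signal-gene weights depend on those few regions surviving the resample,
  inflating their bootstrap SE. Region-level bootstrap is the natural choice
  for region-level maps, but rankings against near-discrete maps should be
  interpreted with care.

## Validation design and problem sizes

The test suite validates each stage against independent oracles and the
whole pipeline against ground truth, at sizes chosen to make the stochastic
checks sharp while keeping the full suite fast:

- MSN and strength vs a brute-force double-loop Pearson oracle: 100 random
  10-region × 5-feature instances at $10^{-12}$; affine invariance of the
  MSN under feature rescaling at $10^{-10}$.
- Region GLM vs the pooled two-sample $t$ (no covariates, algebraic
  identity) and an explicit normal-equations oracle (with covariates), 50
  random cohorts at $10^{-10}$.
- Spin-test calibration: 200 independent pairs of smooth left-hemisphere
  maps (152 regions, 500 spins); the empirical rate of
  $p_{\mathrm{spin}} < 0.05$ must fall in $[0.02, 0.09]$, the 99% binomial
  band around 0.05 widened for permutation granularity.
- PLS1 vs the normalized $X^\top y$ oracle: 100 random 20 × 50 instances at
  $10^{-10}$.
- Planted-gene recovery: 152 regions, 1000 genes, 20 signal genes at
  $\beta = 0.8$, noise SD 0.5, 500 bootstrap replicates; at least 90% of
  planted genes must land in the top 5% of $|Z|$ with correct signs.
- Planted-region recovery: 20 replicates of the 60 + 60 cohort with 8
  effect regions at $\delta = 1.5$ (at least 80% of replicates must recover
  ≥ 7/8 regions with ≤ 2 false positives), plus 100 null replicates at
  $\delta = 0$ whose total false-positive count must be consistent with the
  $1/N$ rate (band 55-160 around the Poisson mean of 100, allowing for
  between-region correlation overdispersion).
- End-to-end determinism: two runs of the full pipeline on the same dataset
  and seed must produce byte-identical tables.

## Known limitations

- Pearson correlations over five feature points are intrinsically noisy;
  the MSN is meaningful in aggregate (strengths sum ~150 correlations), not
  entry-wise. More morphometric features reduce this noise.
- The spin test assumes parcels of comparable size on a sphere; strongly
  unequal parcels or non-spherical topologies would need vertex-level or
  variogram-matching nulls, which are out of scope.
- "GLM" here is Gaussian OLS with identity link — appropriate for the
  continuous strength response; no mixed-effects, longitudinal or
  site-harmonization models are provided.
- The $1/N$ rule is an exploratory correction, not family-wise control;
  spin correction applies to map-level correlations, not to the region-wise
  contrast.
- Whether eTIV should be standardized before inclusion is immaterial: the
  OLS $t$ is invariant to affine covariate rescaling (and the pivot-aware
  implementation keeps it numerically so).
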