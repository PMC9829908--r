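---
title: "Quantifying treatment-induced transcriptome shifts and microglial phenotypes"
author: "microshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying treatment-induced transcriptome shifts and microglial phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microshift)
library(dplyr)
```

## The problem

Colony-stimulating-factor-1-receptor (CSF1R) inhibitors deplete microglia.
In tauopathy models this intervention changes bulk brain expression in two
entangled ways: microglial transcripts fall simply because microglia are
fewer, and the remaining (non-microglial) transcriptome relaxes from a
disease-associated pattern back toward the wild-type pattern. On top of
that, brain drug exposure varies between animals — and between sexes — so
dose-driven programs such as immediate early genes (IEGs) move with measured
drug concentration rather than with treatment group.

`microshift` implements the analysis chain that untangles these effects on
targeted-panel count data (genes × samples), plus the image morphometry used
to phenotype the surviving microglia:

1. **Panel pooling and cell-type filtering** — merge multi-panel counts,
   then split genes into microglial / astrocytic / neuronal / unassigned
   sets with a reference-transcriptome dominance rule.
2. **Disease-axis quantification** — partial least squares (PLS) on vehicle
   groups, least-squares projection of treated samples, Mahalanobis
   population-vector distances and vector angles to the wild-type vehicle
   group.
3. **Dose/sex gene discovery** — two-response PLS (brain drug
   concentration; sex) with variable importance in projection (VIP).
4. **Gene-module discovery** — Louvain community detection on the gene-gene
   Pearson correlation network of the microglial genes.
5. **Resilient-microglia renormalization** — rescale microglial genes by
   six microglial housekeeping markers to estimate per-surviving-cell
   expression.
6. **Composite scores** — a PCA "tau score" over standardized pathology
   measures, a geometric-mean home-cage activity score, and the
   comparative-CT (2^-ddCT) fold change.
7. **Microglia morphometry** — largest-inscribed-circle soma detection,
   skeletonization of processes, branch/length/territory metrics, and cell
   density as a function of distance to the nearest pathology deposit.

Every step is exercised against a seeded synthetic cohort generator with
planted ground truth, so the package's claims are parameter-recovery
statements, not illustrations.

## The disease axis: PLS, projection, distance, angle

Let $X$ be the samples × genes matrix of one brain region (forebrain and
hindbrain are always analyzed separately) restricted to the non-microglial
genes, and let $y$ encode genotype (wild type 0, transgenic 1). Only
vehicle-treated samples enter the fit. `pls_fit()` runs SIMPLS on
column-centered, unscaled predictors, returning orthonormal score vectors
$T$, predictor loadings $P$, weights $R$ and per-component explained
variance for both blocks. Five components are the default.

Treated samples are mapped into the latent space by the least-squares solve

$$\hat{s} = P^{+} (x - \bar{x}),$$

i.e. `project_samples()` solves `loadings %*% s = raw - mean` per sample.
The projection is affine, so samples constructed a fraction $\rho$ along the
segment between group centroids land at the same fraction between score
centroids — this linearity is what makes the distance-ratio estimator of the
restoration fraction consistent. On residual-free (rank-consistent) data the
projection reproduces the training scores exactly; with residuals it is the
best approximation in the loading span.

Each sample's displacement from the wild-type vehicle group is summarized
two ways:

* **Squared Mahalanobis distance** `mahalanobis_sq()`:
  $(s-\mu)^\top S^{+} (s-\mu)$ with $\mu, S$ the reference group's sample
  mean and covariance ($n-1$ denominator). With 6 reference mice in 5
  dimensions the covariance is near-singular; the implementation uses an
  SVD pseudo-inverse (relative tolerance $10^{-10}$) and warns whenever
  $n_\mathrm{ref} \le d + 1$ rather than failing, which reproduces the
  study-scale setting while surfacing its fragility.
* **Vector angle** `vector_angle()`:
  $A = \cos^{-1}\!\big((u \cdot v)/(|u||v|)\big)$ against the reference mean
  vector, with the cosine clamped to $[-1, 1]$; note that `acos` amplifies
  rounding error near $\pm 1$ to about $\sqrt{\epsilon} \approx 10^{-8}$,
  so angles of numerically parallel vectors are near zero but not zero.

`restoration_estimate()` reports $\hat\rho = 1 - \bar d_{\mathrm{Tg,PLX}} /
\bar d_{\mathrm{Tg,veh}}$ on unsquared distances. Under the generator's
linear restoration model this recovers the planted fraction to within 0.1
at study-size groups; averaging the forebrain and hindbrain estimates
halves the estimator variance and is what the tests and the acceptance
script do.

## VIP and the dose/sex model

`fit_dose_sex_pls()` regresses the non-microglial genes on a two-column
response (measured brain drug concentration in µg/g; sex coded F = 0,
M = 1). Importance is the standard Wold VIP,

$$\mathrm{VIP}_j = \sqrt{\; p \sum_a \mathrm{SSY}_a \, (w_{ja}/\lVert w_a
\rVert)^2 \Big/ \sum_a \mathrm{SSY}_a \;},$$

computable per response dimension (using that response's explained sum of
squares) or overall; the mean of squared VIPs over genes is exactly 1, an
identity the tests assert at $10^{-10}$. `projected_dose()` converts the
fitted coefficients back to a per-sample dose prediction (centered
expression × coefficients + intercept).

A caution the test suite makes explicit: genes that form a correlated block
(such as IEGs sharing an activity factor) act as one effective variable.
A single permutation of dose labels can still chance-align the fitted dose
axis with that block, so the permutation null is assessed in aggregate over
200 permutations — on average, permuted IEG importance falls below the 95th
percentile of background genes, while the unpermuted signal stands far
above it.

## Gene modules

`gene_similarity()` computes pairwise Pearson correlations between genes
across the samples of one region (32 by default), zeroes the diagonal, and
excludes zero-variance genes with a warning. `louvain_modules()` clips
negative correlations to zero (a signed mode that uses absolute values is
available as a sensitivity flag), canonicalizes gene order so results are
input-order invariant, and keeps the best of 100 seeded Louvain restarts at
resolution $\gamma = 1$ (ties break toward the lexicographically smallest
canonical labeling); community ids are relabeled by descending size. The
community count is emergent — nothing forces three modules; three is what
the default synthetic cohort yields because three co-regulation factors are
planted. `module_profile()` labels each module by its mean log2 fold changes
(transgenic vehicle vs wild-type vehicle; treated vs vehicle transgenic)
with bootstrap confidence intervals; |log2 FC| < 0.263 (1.2-fold) reads as
"inert"/"stable".

## Resilient-microglia renormalization

Bulk microglial counts confound per-cell expression with cell number.
`resilient_expression()` uses six microglial housekeeping genes (Tmem119,
P2ry12, Fcrls, Olfml3 and the two Itgam probe variants) as abundance
proxies: per sample, the scale factor is the arithmetic mean over
housekeeping genes of the sample's level relative to the matched
vehicle-group mean (geometric mean behind a flag), and every other
microglial gene is divided by it. The reference is matched on genotype and
region, so treated transgenic samples are anchored to transgenic vehicle —
comparisons stay within genotype. Per-sample (not per-group) scaling is the
default because it yields per-mouse resilient profiles.

The estimator is scale-equivariant (multiplying one sample's microglial
block by c multiplies its factor by c and leaves its resilient profile
unchanged) and unbiased in simulation: across 100 simulated cohorts the
mean recovered per-cell fold change of a gene planted at 2× under 50%
depletion is within 2% of truth. Any single cohort of 10 mice per group
carries sampling noise of the same order as a ±0.15 band, which is why the
tests average fold-change recovery over replicate cohorts.

## Composite scores

* `standardize_to_vehicle()` z-scores each tau measure against the
  vehicle-treated group of the same sex and dosing paradigm.
* `tau_score_pca()` runs PCA on the four standardized measures and reports
  PC1 as the tau score. PCA's sign is arbitrary; the package orients PC1 so
  its mean loading across measures is positive, i.e. higher score = more
  pathogenic tau. The PC1/PC1+PC2 variance shares are returned — on data,
  not assumed.
* `activity_score()` normalizes wheel use, locomotion and rearing by their
  dataset-wide maxima (after dropping the first circadian cycle, when
  behavior is unsettled) and returns the geometric mean, so one all-zero
  metric zeroes the session and the score is invariant to joint rescaling
  of any metric.
* `ddct_fold_change()` is the comparative-CT method:
  $2^{-\Delta\Delta C_T}$ with
  $\Delta\Delta C_T = (C_T^{gene} - C_T^{ctrl})_{treated} -
  (C_T^{gene} - C_T^{ctrl})_{vehicle}$.

## Morphometry

`preprocess_stack()` Gaussian-smooths each z-plane (σ = 1 px default) and
takes the pixelwise maximum. `binarize_image()` thresholds (Otsu by
default; a fixed level reproduces exact fixtures) and can keep the largest
connected component. `detect_soma()` fits the largest inscribed circle via
the Euclidean distance transform: center at the argmax, radius the maximum.
After removing the soma disc, `skeleton_metrics()` thins the processes with
Zhang–Suen iterations and decomposes the skeleton into branches — maximal
segments between endpoints and junctions, with 8-connected junction pixels
merged into single nodes and endpoint spurs shorter than 3 px pruned as
thinning artifacts. Branch length is the pixel-step path length (diagonal
steps √2) plus one terminal pixel, which compensates the end erosion
inherent to thinning; on noise-free synthetic cells total length tracks
planted arm length with unit slope within 5%. Territory is the axis-aligned
bounding-box area of the whole cell mask (soma included); a processes-only
reading would systematically shrink small cells and is not what "territory"
means in the field. `measure_cells()` replaces manual cell selection by
connected-component enumeration with an area gate (50–5000 px² default),
and `per_mouse_summary()` averages metrics per animal.

`density_by_distance()` measures every cell's distance as the Euclidean
distance transform of the deposit mask evaluated at the cell centroid —
distance from the deposit boundary, not centroid-to-centroid, which matches
how distance rings are drawn around extended deposits — and divides per-bin
cell counts by per-bin field area (cells/mm²). Bins with no field area
report `NA` with a warning.

## The synthetic cohort generator

`cohort_truth()` fixes the study design: 32 mice (10 transgenic vehicle, 10
transgenic treated, 6 wild-type vehicle, 6 wild-type treated; sexes
balanced), forebrain and hindbrain samples per mouse, 1841 genes of which
242 are microglial-specific (red/blue/green modules of 80/76/80 plus the 6
housekeeping markers), 47 astrocyte- and 70 neuron-specific genes, 56 IEGs,
one male-only marker (a Uty-like Y-linked gene, zero in females), and 150
non-microglial transgene-responsive genes.

Per gene and sample the mean is a product of effects:

* **baseline** — log-normal (meanlog log 150, sdlog 1), typical of
  targeted-panel counts;
* **genotype** — module folds (red 3×, blue 1.8×, green 1×; per-gene
  disease folds log-uniform in [1.5, 2.5] with random direction; IEGs 1.4×,
  reflecting hyperexcitability-driven IEG elevation in tauopathy), boosted
  1.25× on the log scale in hindbrain where pathology is stronger;
* **restoration** — treated transgenic means move linearly a fraction ρ
  (default 0.7) back toward wild type, which is what makes the
  distance-ratio estimator consistent;
* **abundance** — red, blue and housekeeping genes scale by δ = 0.4 under
  treatment (~60% depletion); green-module genes mark the
  treatment-resilient subpopulation and keep their level (configurable);
* **latent factors** — per-sample module activations (log-normal, σ = 0.8
  for red/blue/green — microglial state varies severalfold between
  animals — plus a weak shared factor σ = 0.2 setting the cross-module
  correlation floor) and an IEG activity factor (σ = 0.3) reflecting
  behavioral-state fluctuation; these factors are what correlation
  clustering detects and what gives the fitted axes IEG loadings;
* **dose** — IEG means scale as $e^{\beta_g c_s}$ with per-gene slopes
  around 0.15 per µg/g (≈ 2.9× induction at 7 µg/g), female brain
  concentration N(5, 1.5²) µg/g truncated at 0.1 and male means 1.449×
  higher, matching the wide measured exposure ranges and the male/female
  exposure gap such studies report;
* **counts** — negative binomial with dispersion 0.05 (Poisson at 0;
  `noise = "none"` returns the deterministic means for exactness tests).

What the generator does **not** emulate: compositional coupling between
cell types (losing microglia does not inflate the measured counts of other
genes here, though it would on a fixed sequencing budget), panel background
and probe-affinity artifacts, region-specific baselines, litter or batch
effects, and any dose dependence of the restoration fraction. Passing
parameter-recovery tests on this cohort therefore demonstrates correctness
of the estimators under the stated generative model, not robustness to
those real-data complications.

`generate_reference_transcriptome()` plants cell-type-specific genes whose
own-type expression is `fold` times the sum over other types, so the 5×
dominance rule (`assign_specificity()`, strict inequality) recovers the
planted sets exactly iff `fold` exceeds the threshold; non-planted genes
are drawn inside a band that can never satisfy a threshold of 3 or more.
`generate_tau_table()` drives four pathology measures on different raw
scales from a per-mouse latent severity plus a region factor;
`generate_microglia_image()` renders soma discs with straight radial arms
and records per-cell ground truth (an arm of length L spans L pixels beyond
the soma edge, so a radius-10 soma with length-30 arms has a bounding box
of side 81 px).

## Numerical choices and degenerate inputs

* SIMPLS stops with an informative error when the deflated covariance
  collapses (component norm below $10^{-10}$ of the first component's):
  asking for more components than the data's effective rank is a caller
  error, not something to paper over. For the same reason noise-free
  fixtures in the tests use constructions of known rank.
* Component signs follow the response: each component is flipped so its
  response loading is nonnegative, making "transgenic scores higher"
  deterministic.
* Projection refuses rank-deficient loadings, naming the first deficient
  component.
* `pool_panels()` treats a measurement as detected when it reaches
  `detection_floor` (default 20 counts, a typical background floor for
  targeted panels); a gene detected in no panel for a given sample falls
  back to the mean of its raw (sub-floor) measurements, and a gene detected
  nowhere at all is dropped and reported. Pooling raw counts (not
  normalized values) is the default; variant probe names like the two
  Itgam entries are distinct genes, matched case-sensitively.
* Replicate reference columns collapse by arithmetic mean before the
  specificity rule (the ratio test is scale-invariant, so the collapse is
  harmless); panel genes absent from the reference stay unassigned.
* Otsu requires a non-constant image; an all-background threshold result is
  an error rather than an empty mask propagating silently.
* All generators save and restore the caller's RNG state; every stochastic
  routine takes an explicit seed, and restart seeds are spawned
  deterministically from it.

## Problem sizes used by the tests and the acceptance script

The default test run simulates full-size cohorts (1841 genes × 64 samples)
where the claim concerns the study design, and reduced cohorts (~120 genes,
20 mice) for property loops such as the 200-permutation VIP null or the
100-cohort unbiasedness check; the whole suite runs in about a minute on
one CPU. `scripts/acceptance.R` regenerates the default cohort, the
reference transcriptome, the low-dispersion variance-bookkeeping cohort,
ten cohorts for the module-count majority vote, and one synthetic cell
image — about 20 seconds end to end.

## Known limitations

* With 6 reference animals in 5 latent dimensions the Mahalanobis metric is
  estimated from a near-singular covariance; distances are comparable
  within one analysis but their absolute scale is unstable. The package
  warns rather than failing because that is the study-scale design.
* Distance-versus-dose correlations at n = 10 mice carry sampling error of
  ±0.3; conclusions drawn from them should rest on the with/without-module
  contrast, not the raw coefficient.
* The Louvain default clips negative correlations; strongly anti-correlated
  modules would be invisible to it (use `signed = TRUE` to check).
* Zhang–Suen thinning produces occasional 2-px staircases; branch counts on
  tortuous real cells depend on the spur-pruning threshold (3 px default),
  which should be reported alongside results.
* The tau-score PCA assumes the four measures share one dominant pathology
  axis; if measures split into independent axes the "tau score" reading of
  PC1 is not meaningful — inspect the reported variance shares.
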