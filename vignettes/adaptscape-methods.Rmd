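---
title: "Methods: climate adaptedness, genomic offset and seed sourcing with adaptscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate adaptedness, genomic offset and seed sourcing with adaptscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

adaptscape implements a complete landscape-genomics workflow for long-lived
sessile species: from a filtered SNP matrix and gridded climate data to
candidate adaptive loci, genomic-offset ("adaptedness") surfaces under
future climate scenarios, and donor–recipient seed-sourcing maps. This
vignette documents the statistical models, the assumptions behind them, the
defaults and tie-breaking rules, and what the synthetic landscape generator
does and does not emulate.

## The analysis in one paragraph

Genotype–environment association (GEA) methods assume that stands are
locally adapted to the climate of the grid cell they occupy. A partial
redundancy analysis (pRDA) of individual dosages on climate, conditioned on
geography and neutral population structure, identifies candidate adaptive
SNPs. Three "turnover" engines — gradient forest (GF), an RDA adaptive
index, and generalized dissimilarity modelling (GDM) — are then fitted on
the candidates and used to predict, for every grid cell, the mismatch
(genomic offset) between the adaptive composition supported by the cell's
current climate and the composition its future climate will demand. We work
with the *adaptedness index*, defined as −1 × offset, so that larger values
(closer to zero) mean a better predicted match. Transfer analyses evaluate
every donor cell (current climate) against every recipient cell (future
climate) to rank seed sources for focal sites.

## Genotype quality control

`load_genotypes()` reads GT and DP from a VCF (via vcfR), keeps biallelic
SNPs only, and sets genotypes sequenced at depth below 5 to missing (a
genotype at exactly depth 5 is kept). `filter_variants()` then removes SNPs
with mean depth below 5, minor allele frequency below 0.01 (computed on
non-missing dosages), or a missing fraction of **at least** 10% — the
boundary itself is removed. `ld_prune()` slides windows of 50 variants by
steps of 10 within each chromosome and, while any pair of retained variants
has squared dosage correlation above 0.1, greedily removes the
later-positioned member of the worst pair; the sweep repeats until a full
pass removes nothing, so the *output* satisfies the bound in every window.
`impute_major()` replaces missing entries with the SNP's modal dosage
class, breaking ties toward the smaller dosage (deterministic, and
conservative with respect to the alternate allele).

## Structure diagnostics and the pRDA

Population structure is summarized by a centered PCA of the imputed dosage
matrix; PC1 is the structure covariate of the pRDA (the package accepts any
number of PCs). Isolation by distance is a Mantel test of Euclidean genetic
distance against Haversine geographic distance (sphere radius 6371 km);
isolation by environment is a partial Mantel test conditioning on
geography. The partial statistic is the correlation of the lower-triangle
residuals of the two matrices after regression on the conditioning
triangle; a degenerate (constant) conditioning matrix therefore reduces it
to the simple Mantel statistic, and a matrix fully explained by the
conditioner yields 0. Permutation p-values are one-sided,
`(count + 1) / (n_perm + 1)`, with 999 permutations by default.

`rda_fit()` implements RDA with conditioning directly: response and
predictors are column-centered, residualized on the conditioning matrix,
and the fitted values of the multivariate least-squares regression are
decomposed by SVD. Predictor directions that survive conditioning only as
numerical noise (singular values below 1e−9 of the predictor scale) are
discarded, so a predictor block fully contained in the conditioning span
contributes exactly zero constrained variance. The unit tests cross-check
eigenvalues and inertia decompositions against vegan's `rda()`.

`variance_partition()` reports the fraction of total genomic variance
uniquely explained by climate, geography (standardized latitude, longitude
and their product) and structure — each conditioned on the other two — plus
their confounded share and the unexplained remainder; these five fractions
sum to one by construction. Significance of each partial model is assessed
by permuting rows of the residualized response.

### Candidate adaptive loci

`prda_outliers()` fits the pRDA of all loci on climate conditioned on
geography and structure and retains constrained axes by a sequential
permutation test: axis k is tested after projecting out the previously
established axes, comparing its leading eigenvalue with leading eigenvalues
of row-permuted copies of the remainder (250 permutations, α = 0.05,
seed-controlled); a fixed axis count can be supplied instead. Each locus's
loadings on the retained axes are converted to a squared Mahalanobis
distance using a **deterministic robust covariance**: an iteratively
trimmed estimate (keep the 75% of loci with smallest distances, three
iterations) with the multivariate-normal consistency factor, so the neutral
bulk sets the scale and strong outliers cannot mask themselves, while the
procedure stays free of RNG and invariant to locus order. Distances are
recalibrated by the genomic inflation factor (median distance over the
χ² median at df = retained axes), converted to χ² p-values, and flagged at
the Bonferroni threshold α = 0.01/n. Under null simulations the GIF sits at
1.0 ± 0.05 and false positives average well below one per 1000 loci.

## The three offset engines

All engines satisfy three contracts, enforced by tests: offset is zero when
future climate equals current climate; adaptedness equals −1 × offset at
every cell; and offset is non-decreasing in the size of a single-variable
displacement. Climate values outside an engine's training range are clamped
to it (with a reported count) — extrapolated turnover is not meaningful.

**Gradient forest.** For each candidate locus a regression forest of
dosage on climate is grown (500 trees; `mtry = max(p/3, 1)`; terminal node
size `max(5, n/12)`, kept deliberately large because a 0/1/2 dosage
response is mostly binomial noise and deep trees would chase it). Every
split's in-bag impurity reduction is recorded against its variable and
split value by re-walking the trees with their in-bag samples. A locus's
splits are rescaled to sum to its out-of-bag R² (floored at zero; loci with
no predictive power are excluded), binned into 101 bins along each
variable's observed range, standardized by the density of observed values
(floored at 1e−6), rescaled to conserve total importance, and accumulated
into a monotone cumulative-importance curve per variable. The transform of
a climate vector is the vector of curve values; offsets are Euclidean
distances in that space. Because in-bag impurity always credits a split
positively, inert variables retain a visible noise share of total
importance even in a pure single-driver simulation — rankings are reliable,
exact zeroes are not. The curve evaluation is a step function at bin
resolution: zero at or below the variable's minimum, saturating at the
curve total above its maximum.

**RDA adaptive index.** An RDA of candidate dosages on internally
standardized climate (optionally conditioned). The adaptive index of a
climate vector on axis k is its dot product with the axis's climate
coefficients; the offset between two climate vectors is
`sqrt(sum_k w_k (Δindex_k)^2)` with `w_k` the eigenvalue fraction over the
retained axes (two by default, matching the retained-axis count of the
outlier scan). In one dimension this reduces to |coefficient| × |Δclimate|,
which the tests verify exactly.

**GDM.** The response is the pairwise Euclidean distance between site
allele-frequency vectors at the candidate loci, rescaled into [0, 1); the
predictors are per-variable monotone I-spline basis differences
|f(v_i) − f(v_j)|. Three I-splines per variable are built as exact
integrals of order-2 M-splines with knots at the minimum, median and
maximum of the variable's distribution (the pipeline supplies
recent-grid knots so curves cover the prediction domain). The model
dissimilarity = 1 − exp(−η) is fitted by iteratively reweighted
*non-negative* least squares (pracma's NNLS on the working response), which
guarantees monotone fitted turnover; non-convergence raises an error
carrying the deviance trace. The intercept is treated as a between-site
sampling effect and excluded from the within-cell current→future
prediction — otherwise the defining identity offset(current, current) = 0
would fail. Parameter-recovery tests at 50 sites reproduce known
coefficients within 20% with over 90% deviance explained.

Variable importance is R²-weighted total cumulative importance (GF),
eigenvalue-weighted squared coefficients (RDA), and total spline height
(GDM); ties break alphabetically.

## Seed transfer

`pairwise_transfer()` evaluates the fitted engine between every donor cell
under current climate and every recipient cell under future climate; the
same matrix underlies both directions. Reverse adaptedness (row means)
ranks donors for a focal site; forward adaptedness (column means) ranks
planting locations for a focal site's seeds. `seed_source_priority()`
compares each donor's post-transfer adaptedness with the recipient's
no-transfer baseline; the improvement indicator is **strict** (a tie counts
as no improvement), and the priority is the improved fraction of the focal
site. Donor scopes are the focal site itself, all cells within a Haversine
radius (50 km by default) of the *nearest* focal cell, or the entire
range. Cells are the atomic unit throughout; there are no sub-cell donors.

## Method comparison

Raw offsets are not comparable across engines, so spatial concordance is
assessed two ways: Spearman rank correlations between per-cell offset maps
per scenario, and Procrustes residuals between PCA-reduced method
configurations (k = 3; the GF and RDA configurations are their transformed
climate grids, the GDM configuration a classical-scaling embedding of its
predicted dissimilarities, subsampled to 400 cells for tractability).
Symmetric Procrustes superimposition makes the residual sum independent of
argument order; significance uses vegan's permutation test.

The protection analysis fits the fixed-effects nested ANOVA
`adaptedness ~ protection * model/rcp/year` with `aov()` and Tukey's HSD,
treating grid cells as independent observations. Spatial autocorrelation of
cells is a known violation of that assumption and is acknowledged, not
modelled.

## The synthetic landscape generator

The generator exists so that every stage is testable against known truth.
Its defaults mirror the reference study design: a 30 × 30 grid of 5 km
cells; 171 individuals at 10 sites in the unbalanced
4/4/4/3/4/4/48/4/48/48 design with three intensively sampled focal sites;
20 clinal adaptive loci among 980 neutral; six climate variables (cwd, rch,
run, str, tmn, tmx); and eight future scenarios (two synthetic models, a
warm-wet and a hot-dry one, × RCP 4.5/8.5 × two periods, mid-century shifts
55% of late-century). Choices that matter, and why:

* **Climate fields** are a mixture of a regional Gaussian random field
  (range 30% of the domain), a short-range "topographic" field (range 8% of
  the domain), a mild linear trend and white noise, standardized on the
  recent grid. Fine-resolution climate over complex terrain is far from a
  planar lat/lon surface; without the short-range component the entire
  climate signal would be absorbed by the geographic conditioning of the
  pRDA and the fixture would misrepresent the analysis it feeds.
* **Individuals scatter within ±15 km of their site center**, so the trees
  of a focal site occupy many distinct cells, emulating stratified
  within-preserve sampling across local climate gradients — the within-site
  climate variation this creates is precisely what gives the pRDA power
  once between-site variation is conditioned away.
* **Adaptive loci are locally adapted at cell scale**:
  `logit p = logit(p0) + effect × driver(cell of the individual)`, with
  `p0` drawn at intermediate frequencies (0.25–0.75) so the configured
  2-SD cline is realizable rather than truncated by the polymorphism clamp
  at [0.01, 0.99] (clamps are counted and messaged).
* **Neutral loci share two low-dimensional spatial factors** (half of
  their logit variance, the first factor dominant) plus a locus-specific
  autocorrelated field. Shared demographic history makes the leading
  genotype PCs *neutral* axes in real data; independent per-locus fields
  would instead let the adaptive block capture PC1, and conditioning on
  PC1 would then erase the signal the fixture is supposed to carry. With
  these defaults PC1 explains 5–11% of variance, in line with weakly
  structured outcrossing trees.
* **Future displacement** multiplies each configured shift by
  `1 + p`, where `p` is a mean-zero smooth perturbation field (SD 0.1), so
  the realized cell-mean displacement equals the configured shift exactly —
  a convenient exact invariant for testing.
* Depths are 5 + Poisson(10) for called genotypes and 0–4 for missing
  ones, so a written fixture round-trips the depth mask exactly.

What the generator does **not** emulate: linkage disequilibrium decay along
chromosomes (loci are independent draws; the LD-pruning stage is exercised
by chance correlations and dedicated constructed fixtures), selection
dynamics through time, coalescent genealogies, allele surfing, range
edges, or read-level sequencing artifacts. Passing tests on this fixture
therefore validate the statistical machinery and its calibration, not the
biological fidelity of any particular real dataset.

## Problem sizes and seeds used by the test suite

Unit tests run on a 12 × 12 landscape with 60 individuals and 130 loci;
calibration checks use 50 null simulations of 100 individuals × 1000
neutral loci; recovery checks average three replicates of the full
reference design (171 × 1000, 20 planted loci, effect 2 SD); the end-to-end
pipeline is run twice at full scale to assert bit-identical manifests.
Every stochastic step takes an explicit seed, and seeds for internal stages
are derived deterministically from the run seed.

## Known limitations

* Impurity-based GF importance attributes part of the binomial sampling
  noise to inert variables; importance shares below ~10% should not be
  interpreted.
* The sequential axis test loses power when the constrained signal is
  spread thinly over many loci; supplying a fixed `n_axes` (the reference
  analysis retained two) is the robust choice at small locus counts.
* Conditioning on PC1 removes adaptive signal whenever neutral structure
  and the selective gradient are collinear — a property of the design, not
  of the implementation; the fixture makes this visible on unlucky seeds.
* GDM predictions are bounded by the knot range; cells beyond it saturate.
* The ANOVA treats cells as independent; its p-values are optimistic under
  spatial autocorrelation.
* Grid I/O is long-format CSV; raster formats are out of scope.
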