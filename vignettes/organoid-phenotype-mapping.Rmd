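---
title: "Methods: morphometric profiling and phenotype mapping of branched organoids"
author: "organoidmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric profiling and phenotype mapping of branched organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidmap)
```

# Scope and model

Branched organoids grown from single pancreatic-cancer cells in floating
collagen gels develop family-specific architectures along the
epithelial-mesenchymal spectrum: ductal-network families (terminal end bud
branching organoids, cystic branched, thick branched, tree-like) and
invasive mesenchymal families (branched mesenchymal, firework, star-like,
clump), plus a post-treatment "scattered" debris phenotype. `organoidmap`
implements the quantitative chain that turns brightfield-style images of
such organoids into phenotype calls, an imaging-feature map, potency
estimates and phenotype gene signatures — together with a synthetic
generator whose ground truth makes every stage testable without microscopy
data.

The package covers four analysis blocks:

1. **Skeleton-graph morphometrics.** A mask is segmented (Otsu, dark
   phase), thinned to a unit-width skeleton, traced into an
   endpoint/branch-node graph, and measured: major axis (maximum Feret
   diameter), core thickness (twice the maximum inscribed radius), branch
   and node counts, terminal end buds, spiky invasive branches, lumens
   (enclosed holes, counted and summed in square micrometres), core
   geometry and a granularity index. A fixed-order decision list turns a
   record into a phenotype call.
2. **Imaging phenotype map.** Morphometric profiles (or a small CNN's
   penultimate activations) are embedded by PCA followed by t-SNE;
   k-means with an elbow rule sets the number of imaging phenotypes;
   per-condition kernel densities visualize treatment effects, quantified
   as composition tables with Jensen-Shannon divergence and chi-square
   homogeneity tests. Dose-response viability curves are summarized as
   normalized AUC, interpolated GI50 and per-drug z-scores across clones.
3. **Limiting-dilution potency.** The single-hit Poisson model
   `P(well negative | dose d) = exp(-f d)` is fitted by a binomial GLM
   with complementary log-log link and log-dose offset; potency is
   reported as "1 in x cells" with Wald (default) or profile CIs, and a
   likelihood-ratio slope test checks the single-hit assumption.
4. **Phenotype signatures.** One-vs-rest negative binomial Wald tests
   (median-of-ratios size factors, gene-wise ML dispersion with a floor)
   define per-phenotype marker sets at BH-adjusted p < 0.05 and log2 fold
   change > 2, genes passing in more than one phenotype are removed, and
   signature activity is scored per sample as the rank-based
   recovery-curve AUC of signature genes within the top fraction of the
   expression ranking.

# The synthetic generator and what it does (not) emulate

Organoids are unions of geometric primitives whose ground truth is exact
by construction: capsules (thick segments) for trunk and branches, disks
for cores, terminal end buds and cysts, and carved background holes for
lumens. Families differ in their primitive recipes; for example a TEBBO is
a 340 µm trunk (22 µm thick) with four side branches ending in 20 µm
bulbs, while a firework radiates sixteen 5 µm-thin spokes from a 25 µm
core. Defaults were chosen once to echo the reported scale of the real
families (major axes of a few hundred micrometres at a fixed 1.29 µm/px
calibration; the source imagery publishes no pixel calibration, so
absolute sizes are plausible rather than matched). Per-organoid parameters
are jittered lognormally (relative sd = `jitter`, truncated at ±2.5 sd so
that clearance guarantees hold), angles are drawn inside family-specific
cones, and a rejection step enforces collision-free geometry — branch
crossings would otherwise silently change the true topology. Brightfield
rendering is dark-on-bright with multiplicative speckle inside the mask
(granularity), a fixed 1 px Gaussian blur and additive Gaussian noise.

Ground truth (node/endpoint counts, maximum Feret diameter computed
exactly from the enclosing circles of all primitives, lumen areas, bud and
branch counts) is recorded *before* rasterization and noise. The generator
reproduces the structural vocabulary of the real families, not their
biology: no growth dynamics, no 3-D structure, no optics/PSF model, no
intensity texture beyond speckle. Passing tests therefore demonstrate that
the measurement chain is correct on known geometry, not that it segments
arbitrary real micrographs.

Well tables are Binomial(`n_wells`, `1 - exp(-f·dose)`) draws at the bench
design of 20/10/3/1 cells per gel with at least 8 gels per density. Count
matrices are negative binomial (variance `mu + alpha mu^2`) with lognormal
baseline means, planted phenotype markers and recorded per-sample depth
factors. Viability curves follow a Hill function on a 7-point 3-fold
dilution series.

# Numerical choices in the morphometry engine

Skeletonization is Zhang-Suen thinning with two corrections that matter in
practice (src/skeleton.cpp):

* a **corner-tip guard** during the parallel passes — a pixel whose only
  two neighbours touch each other heads a 2-px diagonal front, and
  deleting such pixels lets the classical algorithm erode diagonal
  strokes end-on, silently swallowing whole branches;
* a **sequential simple-point cleanup** using the exact (8,4) test (one
  8-connected foreground component in the neighbourhood, one 4-connected
  background component) to reach a minimally connected unit-width
  skeleton; ring-transition counts alone miss 2-px diagonal ribbons.

The traced graph is simplified with radius-adaptive rules, because
thinning artefacts scale with local thickness: terminal spurs are dropped
when tip disk plus Euclidean distance stay within the junction's inscribed
disk (they add no mask coverage; a genuine short bud protrudes beyond it);
junction pairs closer than 1.5 x the local radius are contracted (this
collapses the junction cloud inside a thick core to one branch node);
micro self-loops (1-px triangles at cluster rims) are removed; pass-through
nodes are spliced. Lumens would put cycles into the skeleton and make
branch counts depend on lumen placement, so the graph is computed on the
hole-filled mask and lumens are measured separately as holes. Compact
components whose whole skeleton is shorter than 2.5 x the maximum inscribed
radius are blobs (disks) with no endpoints.

Conventions the source procedure leaves open, fixed here and frozen in the
test suite: the trunk is the endpoint-to-endpoint path maximizing
radius-weighted length; main branches are non-trunk edges incident to the
trunk with mean radius at least half the trunk radius; a terminal end bud
is an endpoint whose local radius is at least 1.3 x the median edge radius
*and* 1.15 x its own edge's mean radius (a bud is a swelling, not merely a
thick end); a spiky branch is a terminal edge at most half the trunk
radius thick and at least 30 µm long; granularity — only qualitatively
assessed at the bench — is quantified as the intensity coefficient of
variation inside the mask; core circularity compares the core's area
(after radius-scaled opening) with the perfect circle over its measured
(Feret) diameter, mirroring the bench procedure for star-like cores.

# The elbow rule and clustering geometry

The number of imaging phenotypes is selected Kneedle-style: k-means
inertia for k = 1..k_max, then the k farthest (perpendicular, after axis
normalization) from the chord joining the curve's ends. Two refinements
proved necessary. First, the window must extend well past any plausible
knee (default `k_max = 20`): with the window barely beyond the knee the
chord hugs the decaying segment and the pick collapses toward small k.
Second, a knee only counts when it leaves at most 10% of the total
inertia drop in its tail; a featureless curve — one Gaussian blob decays
smoothly like 1/k — then correctly yields k = 1 instead of an arbitrary
interior point.

Cluster number selection and clustering operate on cosine-normalized
morphometric profiles (each z-scored row projected to the unit sphere).
Family separations are otherwise dominated by overall-size components,
which makes the inertia curve near-geometric and hides the knee; direction
("shape") rather than magnitude is also the natural similarity for
standardized profile data. The embedding shown to users remains PCA +
t-SNE of the z-scored features (perplexity 30, capped at (n-2)/3; PCA
depth 10 by default for 18 classical features). Whether clustering should
happen in feature or embedding space is genuinely ambiguous in the source
description; feature-space clustering is the default here because t-SNE
distances are not metrically meaningful.

The CNN backend is deliberately desk-scale: three seeded random
convolution + ReLU + max-pool blocks (frozen) and a trained 64-unit dense
layer with softmax head; `epochs` applies to the head, so `epochs = 0`
exposes the untrained random-feature network, still bit-reproducible for
a fixed seed. This random-feature design trains in seconds on a CPU while
preserving the pipeline contract of the original transfer-learning
extractor (penultimate activations in, embedding out); it is not a
re-implementation of an ImageNet-pretrained ResNet-50, and the
`architecture = "resnet50"` flag errors informatively.

# Statistical calibration choices

**Limiting dilution.** The GLM intercept equals log f exactly, so
single-dose tables reproduce the closed form `-ln(F_neg)/d` to optimizer
tolerance. Wald intervals are computed on the log-frequency scale
(symmetric there) and transformed to the potency scale; profile-likelihood
intervals are available via `ci = "profile"`. Boundary tables (all or no
wells responding) are flagged as non-estimable instead of being corrected.
The CI-coverage simulation uses the bench design (4 doses x 8 wells). The
slope-test calibration and power studies use 30 wells per dose, chosen
once by a design power argument: at 8 wells the likelihood-ratio test has
only ~70% power against the quadratic-dose alternative
`P(neg) = exp(-0.05 d^2)`, while 30 wells give >95% power with type-I
error within its tolerance band — a calibration study should characterize
the test, not the smallest bench assay.

**Signatures.** The DE step is a plain gene-wise NB Wald test (ML
dispersion via `glm.nb`, capped at a dispersion floor of 1e-4; genes whose
ML fit fails fall back to a fixed-dispersion fit at the floor). Dispersion
shrinkage and fold-change moderation of full DE frameworks are
intentionally not replicated; correctness is assessed as planted-marker
recovery, not coefficient equality with any external tool. With three
replicates the Wald p-values are anticonservative in the tail (raw
p < 0.05 for ~15% of null genes), but the BH-significant *fraction* on
null data stays well below the 7% tolerance; the signature thresholds
(adjusted p < 0.05, log2 fold change > +2, up-regulation only) and the
uniqueness filter (thresholds first, then removal of genes shared between
provisional signatures) do the heavy lifting. The recovery-curve AUC uses
`top_fraction = 0.05` of the ranking by default and breaks expression
ties by fixed gene order, making scores exactly rank-invariant.

# Problem sizes and reproducibility

The standard study designs exercised by the test suite and
`scripts/acceptance.R`: a 320-image cohort (8 families x 40, geometric
jitter 0.1, no pixel noise) for morphometric recovery and classification;
the same cohort for the feature/embedding/clustering map; a 200-image
2-family task for the CNN backend; 500 simulated assays each for CI
coverage (4x8 wells), slope-test type-I error and power (4x30 wells);
2000-gene, 3x3-replicate count matrices with 50 planted markers per
phenotype at log2 fold change 3 and dispersion 0.1. Every random step
flows from explicit integer seeds (`with_seed` restores the caller's RNG
state), so cohorts, fits and embeddings are bit-reproducible.

# Known limitations

* The generator's archetypes are stylized: exact ground truth comes at
  the price of simple geometry (no curved branches, no texture beyond
  speckle, no touching organoids), so classifier thresholds tuned here
  will need re-tuning for real micrographs.
* Lumens are topological holes; swollen low-intensity regions that do not
  close into holes are not counted.
* Wald intervals are first-order; at 8 wells per dose the coverage
  simulation shows ~95%, but very small assays near the response
  boundaries can undercover, which is why boundary outcomes are flagged.
* The NB Wald test assumes enough replicates for ML dispersion; with
  n = 3 its raw p-values are optimistic and only the thresholded,
  uniqueness-filtered signatures are calibrated end-to-end.
* t-SNE coordinates are for display; quantitative statements (ARI,
  compositions, divergences) are computed from features or labels, never
  from embedding distances.

# A compact worked example

```{r example, eval = FALSE}
co <- generate_cohort(setNames(rep(10, 8), murine_families()),
                      jitter = 0.1, seed = 1)
run <- morphomap_pipeline(co, seed = 1)
table(truth = co$manifest$phenotype, cluster = as.integer(run$clusters))

tab <- generate_limiting_dilution(1 / 3, seed = 1)
fit_single_hit(tab)

ct <- generate_count_matrix(2000, rep(c("A", "B", "C"), each = 3), 50,
                            log2fc = 3, seed = 1)
de <- lapply(c(A = "A", B = "B", C = "C"), function(p)
  phenotype_de(ct$counts, ct$phenotype_labels, p))
derive_signatures(de)
```
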