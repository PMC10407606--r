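---
title: "From root images to QTL candidates: the rootgwas pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From root images to QTL candidates: the rootgwas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootgwas)
```

# Scope and model of the data

`rootgwas` implements a complete phenomics-plus-GWAS workflow for
adventitious rooting (AR) in clonally propagated trees: plants are imaged
against a two-colour felt background (basal roots laid downward over blue
felt, lateral roots to the side over grey felt, with a ruler and label in
frame), per-root geodesic lengths and areas are extracted from segmentation
masks, genotype-level trait tables are built and transformed, and three
association engines scan a SNP panel: a linear mixed-model (LMM) Wald scan
for continuous traits, a logistic mixed-model score scan for binarized
traits, and a windowed SNP-set kernel association test (SKAT) for
untransformed traits, complemented by augmented rank truncation (ART)
combination of single-SNP p-values over 1-kb windows. QTL peaks are called
with a 30-kb local-minimum rule and annotated against GFF3 gene models with
a 5-kb proximity rule.

Because no public imaging or sequencing data accompany the assay, the
package ships a first-class synthetic-data module. Every downstream stage
is tested against the exact ground truth that module produces.

# The synthetic scene generator

`scene_spec()` describes a canvas split into a grey top zone and a blue
bottom zone at a configurable row, with a ruler (default 300 px drawn for a
150-mm ruler, so 0.5 mm/px), a label, a stem rectangle crossing the zone
boundary, leaf ellipses, and roots drawn as disk-stamped polylines.
Basal roots attach at the stem base and live entirely in the bottom zone;
lateral roots attach at the stem flank and live in the top zone — the same
convention that lets the segmentation stage classify root type by the felt
colour beneath each root. Roots never touch one another (placement enforces
a separation buffer), so each root is one 8-connected component and its
ground-truth length (polyline arc length) and area (stamped pixel count)
are well defined. Rendering adds per-channel Gaussian jitter
(`noise_sd`, default 0.02) and is deterministic given `(spec, seed)`.

What the generator does *not* emulate: perspective, shadows, specular
highlights, root hairs, overlapping or crossing roots, and the soft colour
gradients of real photographs. Passing the recovery tests therefore
demonstrates the correctness of the measurement geometry and of the mask
contract, not the performance of any particular segmenter on field images;
the deep segmentation models used on real data sit outside this package
and can be dropped in at the mask level.

# Segmentation

`segment_scene()` assigns each pixel to the nearest palette colour within a
tolerance (default 0.15 in RGB Euclidean distance; palette colours must be
separated by more than twice the tolerance). Unmatched pixels fall back to
the background zone they sit in, using a zone boundary estimated from the
matched background pixels. Components smaller than 10 px are merged into
their surrounding label to suppress jitter speckle. `segment_tissue()`
repeats the rule inside the plant region for leaf/stem/root. Portrait
images are rotated to landscape first. Segmentation is idempotent: a
rendered visualisation of a mask re-segments to the same mask.

# Root measurement

`extract_root_instances()` labels 8-connected root components. A component
touching the stem yields one instance per contiguous run of stem-contact
pixels (the origin is the run pixel nearest the run centroid); a
multi-contact component is partitioned by geodesic proximity to the runs.
Components touching only another root become children of that root,
measured from their own attachment; components touching nothing are
orphans, flagged and excluded from summaries.

`measure_root()` builds the weighted pixel graph (axial step cost 1,
diagonal cost `sqrt(2)`), takes the tip as the pixel at maximal
shortest-path distance from the origin, and reports two lengths:

* `length_geodesic_px` — the raw octile shortest-path distance, the
  quantity the pixel-graph oracle checks exactly;
* `length_px` — the primary length used in summaries: the shortest pixel
  path is simplified by Ramer–Douglas–Peucker with a 1-px tolerance and the
  Euclidean lengths of the simplified segments are summed.

The correction exists because the octile metric overestimates Euclidean
length by up to 8.2% for straight runs at 22.5 degrees to the grid axes;
straightening removes that rasterisation bias while preserving the
"shortest path from tip to origin" semantics. For thick roots the geodesic
follows an outer fiber of the ribbon, a small accepted positive bias.
Across random synthetic batches the corrected lengths sit within about
2–5% of the true polyline lengths.

Root type is classified by majority vote of each root pixel's nearest
background zone (Euclidean distance maps to the two felt classes), ties
breaking to basal. The metric scale is `ruler_mm` divided by the ruler
component's extent along its principal axis; stem diameter is the median
stem run-length perpendicular to the stem's principal axis.

# Trait tables and transformations

`build_trait_table()` averages the six base trait families (lateral, basal
and total root area; lateral, basal and overall longest root length) over
clonal replicates per genotype and week (weeks 2–5: 24 base traits), with
single-replicate cells flagged. `add_growth_traits()` appends the three
week-5 minus week-2 area differences. `add_pc_traits()` runs centred,
scaled PCA over three fixed trait groups (areas; LRLs; both) and keeps the
first two components of each as six PC traits, with a deterministic sign
convention (largest-magnitude loading positive).

Transformations: Box–Cox lambda is profile maximum likelihood on a grid
over [-5, 5] in steps of 0.01 (strictly positive data required; zeros can
be removed first); the rank-based inverse normal (RB-INV) maps averaged
ranks through Blom plotting positions (r - 3/8)/(n + 1/4). The outlier
rule drops values beyond 3 IQR from the quartiles — such calls are usually
made case by case in practice, so the package fixes a conservative
default and records every removal in the provenance.
Binarization defaults to rooting presence/absence (`zero_vs_positive`),
the natural reading for zero-inflated rooting traits; a median split is
available. The default transformation policy (`transformation_tracks()`)
keeps untransformed values for the kernel-association track, uses Box–Cox
for the mixed-model track unless the transformed trait still fails
Shapiro–Wilk at p < 0.01 (then RB-INV), and carries both Box–Cox and
RB-INV versions of PC traits.

`estimate_h2()` fits the null mixed model y = Wa + u + e with
u ~ N(0, sg2 K) by REML via the eigen-decomposition of the kinship matrix
(rescaled to mean diagonal 1) and a one-dimensional search over
delta = se2/sg2, and reports PVE = sg2/(sg2 + se2) with a gate at
PVE > 0.10 — the conventional bar a trait must clear before association
scans. An identity-proportional kinship makes the two components
unidentifiable; the estimate is then flagged rather than reported.

# Association engines

*Genotype preparation.* MAF and missingness are computed on non-missing
calls, so the two filter bounds commute. The kinship is the centred
relatedness K = XcXc'/m with per-variant mean imputation. Genotype PCs are
the top eigenvectors of the standardized-genotype covariance computed on
common variants (MAF >= 0.05), signed deterministically. Windows tile each
chromosome on a 1-anchored step grid (default 3-kb windows every 1 kb, so
a variant belongs to up to three windows); empty windows are dropped.

*LMM Wald scan.* The null REML fit profiles delta on a log grid and
refines by golden-section search; the scan holds delta fixed, rotates each
mean-imputed variant by the kinship eigenvectors, and tests the GLS slope
with (beta/se)^2 against chi-square(1). Variants with squared multiple
correlation above 0.9999 with the covariate span are skipped. With an
identity-proportional kinship the scan provably reduces to OLS, which the
suite checks to 1e-6.

*GLMM score scan.* The binary-trait null model is fitted by penalized
quasi-likelihood — iterating working response and weights with a REML
update of sg2 until successive estimates differ by less than 1e-6 (at most
100 iterations; non-convergence flags the trait and skips it). Each
variant is then scored as (x'Pz)^2 / (x'Px), which needs no per-variant
fit and therefore stays finite under complete separation. At sg2 = 0 the
statistic equals the ordinary logistic score test; fidelity to AI-REML-based binary-trait
GWAS software is targeted at the level of null calibration, not numeric
identity.

*SKAT.* The linear null model regresses the untransformed trait on
intercept, stem diameter, batch and six genotype PCs. For a window with
weighted genotypes Gw (weights: Beta(1,25) density at the MAF, the
customary rare-variant up-weighting; configurable, including flat),
Q = r'GwGw'r, and the asymptotic p-value comes from the weighted
chi-square null via four-moment matching, which is exact for a single
eigenvalue — so a single-variant window reproduces the marginal score
test. Empirical p-values permute the null-model residuals with adaptive
batches (1e3, 1e4, 1e5, 1e6, then 1e6 chunks to the budget), stop once 10
exceedances accumulate, and report r/B with a floor of 1/B_max — at the
full 1e7 budget the smallest attainable value is exactly 1e-7. By default
only windows with asymptotic p < 1e-4 are resampled.

*ART.* For a window's ordered p-values with truncation k = min(L, 5):
conditional on the k-th order statistic, the smaller ratios behave as
independent uniforms, so
T = -2 * sum(log(p_(i)/p_(k))) + Qchisq2(Beta CDF of p_(k))
is chi-square with 2k degrees of freedom under independence. A Monte-Carlo
calibration mode resamples uniform p-value sets and serves both as the
validation oracle in the test suite and as a runtime fallback. A single
p-value combines to itself; p-values of exactly 0 are clamped to the
machine minimum with a warning.

# Thresholds, peaks and annotation

`significance_thresholds()` computes the conservative Bonferroni cut
(alpha/number of SNP or window tests), the ART–Bonferroni cut (alpha/number
of 1-kb ART windows), and Benjamini–Hochberg FDR flags (step-up at
alpha = 0.10, applied per scan). At realistic genome-wide scan sizes the cuts land
where Manhattan-plot threshold lines are customarily drawn (about 4e-9
for ~12.8 million SNPs and about 1.3e-7 for ~0.4 million 1-kb windows).

A QTL peak is a result with no lower-p result of the same (trait,
transform, method) group within 30 kb on its chromosome, ties breaking to
the lower position — the locally most significant signal of a Manhattan
peak. The package applies the rule within each scan; pooling across
methods is left to the caller. Peak anchors are SNP positions for
single-variant methods and window centers for window methods. Annotation
measures the distance to the nearest gene boundary: 0 inside a gene
(exonic if inside an annotated exon, else intragenic non-exonic),
otherwise five-prime or three-prime respecting strand, with a within-5-kb
flag.

# The synthetic genetic architecture

`genetic_architecture()` fixes the study conditions: a realistic MAF
spectrum (Beta(0.4, 1.6) scaled to (0, 0.5], floored at 0.005, so the
panel carries many rare variants), 2% missing calls, variants every 100 bp,
LD from block-copied founder haplotypes (1-kb blocks, 24 founders),
optional Balding–Nichols subpopulations, two clonal replicates, four
weekly time points, eight assay batches (both replicates of a genotype
share a batch), and target heritability h2 = 0.4 on the single-measurement
scale with a 5% batch and 2% stem-diameter variance share.

Phenotypes are linear in latent genetic values: each family combines the
causal-window component at full strength with a shared and a
family-private polygenic part (70% shared), scaled by a weekly growth
factor; total area is the sum of the class areas and overall LRL the
maximum of the class LRLs, exactly as the measurement pipeline defines
them, and measurements are floored at zero, which leaves a realistic
zero-inflated fraction for binarization. Causal windows follow the
Beta(1,25)-weighted variance-component model — rarer variants carry larger
per-allele effects — the architecture the windowed kernel test is designed
for. The realized heritability of each family is reported alongside the
draws.

# Numerical choices and problem sizes

Tolerances and defaults worth knowing: colour tolerance 0.15 with palette
separation > 0.3; small-component cleanup 10 px; RDP simplification 1 px;
REML delta searched over [1e-5, 1e5]; PQL convergence 1e-6; kinship PSD
tolerance -1e-8 on the smallest eigenvalue; collinearity guard R^2 >
0.9999; empirical-p early stop at 10 exceedances. The test suite and the
acceptance script run the statistical checks at desk scale — panels of
200–500 genotypes and 2 000–5 000 variants, 50-scene image batches,
calibration suites of roughly two thousand tests per engine — sizes chosen
so the whole suite completes in minutes while keeping binomial bands tight
enough to detect real miscalibration.

# Known limitations

* The rule-based segmenter assumes the synthetic palette; real photographs
  need a learned segmenter producing the same mask contract.
* Geodesics on the full pixel set (not a skeleton) carry a small positive
  bias for thick roots.
* PQL is an approximation; its score test is calibrated but not numerically
  identical to adaptive-quadrature or AI-REML fits.
* The ART closed form assumes independent p-values within a window; under
  strong LD its calibration is inherited from the Monte-Carlo fallback
  rather than the chi-square null.
* Root counting, time-lapse registration, manual correction workflows and
  GO enrichment are out of scope.
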