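---
title: "Methods: stratifying steatotic liver disease by a hepatic ferroptosis signature"
author: "ferroStrat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying steatotic liver disease by a hepatic ferroptosis signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroStrat)
```

# Scope and rationale

Ferroptosis — iron-catalyzed necrosis driven by peroxidation of
polyunsaturated (PUFA) membrane phospholipids — appears in only a subset
of patients with metabolic dysfunction-associated steatotic liver
disease (MASLD). ferroStrat implements the computational chain needed to
find that subset from three complementary data types:

1. **Tissue images**: where in the liver lobule a stain (4HNE, GPX4)
   sits, quantified against the portal-to-central axis;
2. **Per-specimen marker tables**: cell death (TUNEL), lipid
   peroxidation aggregates (4HNE), nuclear GPX4, cytoplasmic ACSL4 and a
   binary ferrous-iron stain, clustered into phenotypic groups;
3. **Transcriptomes and lipidomes**: per-sample ferroptosis gene-set
   scores with latent-subgroup discovery, and PUFA-tail classification
   of phospholipid species.

Patient material is replaced throughout by seeded synthetic generators,
so every stage is testable end to end. This vignette records the models,
their assumptions, the tunable parameters, and the design decisions
taken where the methodology was genuinely open.

# Lobule zonation

Liver lobules are reconstructed from two landmark classes — portal
triads (PT) and central veins (CV) — on the Voronoi principle: each
pixel belongs to the lobule of its nearest CV. The position of a pixel
along the portal-to-central axis is the *relative lobular distance*

$$r = \frac{d_{PT}}{d_{PT} + d_{CV}} \in [0, 1],$$

with $d_{PT}$, $d_{CV}$ the Euclidean distances (in pixels, on pixel
centres) to the nearest landmark of each class. The anchors are exact:
$r = 0$ at a portal triad and $r = 1$ at a central vein. The
interpolation between the anchors is not dictated by the anchors
themselves; this normalized two-class distance is the standard choice
and the one implemented. Geodesic-within-tissue distances were rejected:
they add a dependency on tissue topology that is hard to validate, while
the Euclidean field admits an exhaustive per-pixel oracle that the test
suite checks bit-for-bit on 128×128 images.

Stain positivity is profiled as the positive-area fraction in $B = 20$
equal-width bins of $r$ (half-open bins, the last closed at 1). Bins
with no tissue pixels report `NA` rather than 0/0. `profileCentroid()`
condenses a profile to the positive-count-weighted mean bin midpoint: a
pericentral stain scores near 1, a panlobular one near 0.5.

Landmarks are points by default; real triads and veins are regions, so
`relativeDistanceMap()` also accepts binary region masks (distance to
the nearest mask pixel). Point mode is canonical and is the mode all
oracles test.

# Cell-level marker quantification

The segmentation chain is deliberately classical and fully specified:
Gaussian smoothing (σ = 2 px default) → threshold (Otsu on the
specimen's own histogram by default, fixed value optional) → connected
components → area filter → watershed split on the distance transform for
touching nuclei. Cytoplasm is a ring: each nucleus dilated by a fixed
radius, minus all nuclei and the excluded-region (lipid vacuole) mask,
contested pixels resolved to the nearest nucleus centroid. This stands
in for learned hepatocyte-reconstruction models on real biopsies: the
substitution trades segmentation accuracy on real tissue for exact
testability, and is the main reason marker values from this module
should not be read as clinically calibrated.

Marker rules: a GPX4⁺ nucleus has mean nuclear intensity above the
threshold; a TUNEL focus or iron deposit is a connected supra-threshold
component of ≥ 4 px²; a 4HNE *aggregate* must reach 100 px², which is
what separates it from granular lipofuscin — the morphology-based
distinction made by eye is operationalized as a single area cutoff.
Densities are per mm² of imaged area, converted with the pixel size
(µm/px; default 0.5, a typical 20× digital-pathology resolution).

# Marker-table stratification

Specimens mix numeric markers with a binary iron stain, so clustering
uses k-prototypes: numeric columns standardized to zero mean/unit SD,
cost per row

$$\sum_j (x_j - \mu_j)^2 \;+\; \gamma \sum_c \mathbf{1}[x_c \neq \text{mode}_c],$$

minimized by alternating assignment and mean/mode refitting. Defaults:
$k = 3$ (the phenotypic structure the package is built around: a
no-ferroptosis cluster, a ferroptosis-signature cluster, a low-marker
cluster), $\gamma = 0.5$ — half the mean SD of the standardized numeric
columns, i.e. Huang's heuristic, since nothing in the data dictates a
mismatch weight — and 50 seeded random restarts, keeping the lowest-cost
solution with ties broken by the lexicographically smallest assignment
vector. Because $k$ is not self-justifying, `silhouetteReport()` emits a
mean-silhouette-versus-k table under the same mixed dissimilarity.
Degenerate inputs: missing numeric values are median-imputed with a
warning (defensible only because marker tables are small); constant
columns are dropped with a warning since their standardization is
undefined; an emptied cluster captures the currently worst-fitting
point, which cannot raise the cost, so the per-iteration cost trace is
provably non-increasing and is asserted as such.

Clusters are characterized the way cohort tables are built: median (IQR)
per numeric covariate with Kruskal–Wallis p-values (tie-corrected H,
χ²-reference), count (%) per categorical level with exact Fisher r×c
p-values, and a Benjamini–Hochberg-adjusted column across the covariate
family. The Fisher test is Freeman–Halton by exhaustive enumeration over
all tables with the observed margins; the two-sided p sums the
probabilities of tables no more probable than the observed one, with a
relative guard of 1e-7 on the comparison because tables probability-tied
with the observed one must count. Enumeration is exact and fast at
cohort scale (2×3 and 4×3 tables with n = 27 enumerate in well under a
second); Dunn's post-hoc z-tests use pooled mid-ranks with tie
correction and BH adjustment across pairs.

# Gene-set scoring and latent subtyping

Each sample is scored on four gene sets (enzymatic ferroptosis
defenses, glutathione synthesis, PUFA incorporation, iron handling) by a
single-sample rank-based enrichment statistic: per gene, a Gaussian
kernel CDF across samples (bandwidth SD/4) locates the sample in that
gene's expression distribution; the statistics are rank-normalized per
sample to symmetric scores $s = \text{rank} - (p+1)/2$; per set, a
weighted Kolmogorov–Smirnov random walk over the sample's gene ranking
with weight $|s|^\tau$, $\tau = 1$. The default `maxdiff` statistic —
maximum positive plus maximum negative walk deviation — penalizes sets
deviating in both directions and is bounded in (−1, 1); a `twosided`
largest-magnitude alternative is exposed. Constant gene rows get
statistic 0 by the tie rule. The Gaussian kernel assumes continuous
log-scale expression; RNA-seq counts should arrive as log-CPM.
These scores are exactly invariant to a constant added to the whole
matrix, but *not* to a constant added to a single sample: the per-gene
kernel CDFs saturate and cross-gene ranks move. The tests therefore
assert exact global-shift invariance and only high rank agreement for
per-sample shifts.

The package's default four sets (22 genes over well-known pathway
members, `defaultFerroptosisSets()`) exist so the pipeline runs
self-contained; any signature of interest should be supplied as a GMT
(`readGmt()`/`writeGmt()`).

Latent subgroups come from a full-covariance Gaussian mixture fitted by
EM on the standardized score matrix: covariance ridge 1e-6, best of
`nInit` seeded restarts per component count, restarts with singular
covariances discarded, log-likelihood asserted non-decreasing at every
step. The component count is chosen over k = 1..5 by minimum
$\mathrm{BIC} = -2\log L + p\ln n$ with
$p = (k-1) + kd + kd(d+1)/2$, $d = 4$ — an explicit criterion where the
subtyping itself reports only the resulting count. Components are then
labeled by phenotype: **red** maximizes mean(PUFA) + mean(Iron) −
mean(defenses) − mean(GSH) (PUFA/iron drive with lowered defenses),
**green** maximizes mean(defenses) among the rest, everything else is
**gray**; ties break to the lower component index, and a model whose
component means are all equal is labeled by tie-break with a warning
that the labels are uninformative.

# Lipid PUFA classification

Shorthand names parse under the grammar
`CLASS [O-|P-]C1:D1[_|/]C2:D2[...]`; `/` marks known sn-positions, `_`
unknown (recorded, never used — classification is tail-order
invariant); `O-` (plasmanyl) and `P-` (plasmenyl) both set the ether
flag, the vinyl-ether distinction surviving only as metadata. A tail is
polyunsaturated at ≥ 2 double bonds — the conventional cutoff, chosen
because nothing in the biology pins a number — so a species is PUFA$_k$
by its count of PUFA tails, with ether species carrying any PUFA tail
additionally flagged ePUFA. Species given only as totals (`TAG 52:2`)
are *sum resolution*: excluded from class denominators and counted
separately rather than guessed. Class fractions are abundance-weighted
percentages within each headgroup class; the PUFA$_0$/PUFA$_1$/PUFA$_2$
(/PUFA$_3$) columns partition each class's resolved abundance exactly,
while ePUFA is an overlapping flag normalized against the same
denominator.

# Synthetic-data generators

Every generator is a pure function of its seed and parameters, and
ground-truth labels never enter feature tables.

* **Tissue images**: CVs on a jittered hexagonal lattice, PTs on the
  offset (cell-corner) lattice — the classic lobule idealization, chosen
  because no layout is dictated by the landmark data itself. Patterns:
  pericentral stains $r \ge r_0$, periportal mirrors it, panlobular is
  Bernoulli coverage at every $r$, `none` is empty. Noise is independent
  per-pixel label flipping — the simplest model that exercises
  robustness; it reproduces neither spatially correlated staining
  artifacts nor intensity gradients.
* **Marker cohorts**: Gaussian numeric markers and Bernoulli iron per
  cluster. Cohort summaries in the field report medians and IQRs, not
  distributions; Gaussians were chosen for analytic recovery checks, not
  realism (no skew, no heavy tails). Defaults mirror a 27-specimen
  cohort in three clusters of 7/10/10 with iron-positivity rates 1/7,
  0.7 and 0.1 and histology mixes matching the fixture counts.
* **Expression cohorts**: log2-scale Gaussian per gene (so the raw scale
  is strictly positive log-normal), subgroup structure as stated
  SD-shifts of designated gene sets. Defaults: n = 78 samples, a neutral
  subgroup, a red-like subgroup (PUFA/Iron +2 SD, defenses/GSH −2 SD)
  and a green-like subgroup (defenses/GSH +2 SD) in proportions
  0.45/0.30/0.25.
* **Lipid tables**: random species over PC/PE/PG/TAG with per-tail PUFA
  probability 0.4, ether probability 0.15 for PC/PE, log-normal
  abundances; every generated name round-trips through the parser.

Passing tests on these generators demonstrates algorithmic correctness
and recovery under the stated models — not performance on real biopsies,
where staining variability, segmentation error and batch structure
dominate.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use sizes chosen to make
every stochastic check decisive yet quick on one CPU: 128×128 oracle
images; 27–90-specimen marker cohorts with recovery checked at 6-SD
separation (ARI = 1) and monotone ARI across 0.5/2.5/6 SD; 30-sample ×
200-gene expression cohorts for spike separation; mixture-model
selection and weight recovery over 20 seeds at n = 500, d = 4; 2000
permutations for the Kruskal–Wallis type-I-error check. Numerical
guards worth knowing: the Fisher comparison tolerance (1e-7, relative),
the EM ridge (1e-6) and its non-decreasing-likelihood assertion, the
half-open binning with closed last bin, and the deterministic tie-breaks
(lexicographic assignment vectors; lowest component index).

# Known limitations

* Point landmarks and Euclidean distance idealize lobule geometry;
  region mode helps but tissue-geodesic distances are not offered.
* The classical segmentation chain under-performs learned models on
  real stains; marker rows from it are for pipeline validation.
* BH adjustment is applied per covariate family as a whole; it is not
  idempotent, so already-adjusted values must not be re-adjusted.
* Exhaustive Fisher enumeration is exponential in table size; it is
  meant for cohort-table dimensions (≤ ~4×4 at n ≲ 50).
* The default gene sets are a documented package default, not a
  validated signature; supply your own GMT for real analyses.
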