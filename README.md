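# ferroStrat

Ferroptosis — iron-catalyzed cell death driven by peroxidation of
polyunsaturated (PUFA) membrane phospholipids — marks out a subset of
patients with metabolic dysfunction-associated steatotic liver disease
(MASLD). ferroStrat is an R package for finding that subset: it
quantifies ferroptosis markers in liver tissue images, stratifies
specimens on the resulting marker table, subtypes transcriptomic cohorts
by ferroptosis gene-set scores, and classifies phospholipids by PUFA
tail content. It is aimed at computational biologists working with
digital pathology, bulk transcriptomics and lipidomics of steatotic
liver disease.

## What it computes

* **Lobule zonation** (`relativeDistanceMap`, `zonatedPositivity`):
  lobules are reconstructed from portal-triad (PT) and central-vein (CV)
  landmarks on the Voronoi principle, and each pixel gets the relative
  lobular distance *r* = d_PT / (d_PT + d_CV) ∈ [0, 1] (0 at portal
  triads, 1 at central veins). Stain positivity is profiled as the
  positive-area fraction per *r*-bin.
* **Marker quantification** (`segmentNuclei`, `cytoplasmRings`,
  `quantifySpecimen`): TUNEL foci/mm², 4HNE aggregates/mm² and area
  fraction, % GPX4⁺ nuclei, cytoplasmic/nuclear ACSL4 intensity and a
  binary iron call, from a classical smooth → threshold → watershed
  segmentation.
* **Stratification** (`kPrototypes`, `characterizeClusters`):
  k-prototypes clustering of mixed numeric/categorical marker tables
  with cost Σ(x−μ)² + γ·Σ1[x≠mode], characterized with Kruskal–Wallis +
  Dunn, exact Fisher r×c (Freeman–Halton by exhaustive enumeration) and
  Benjamini–Hochberg adjustment.
* **Gene-set subtyping** (`gsvaScores`, `fitGmm`,
  `assignPhenotypeLabels`): single-sample enrichment scores from a
  weighted Kolmogorov–Smirnov random walk over kernel-CDF expression
  statistics, then a full-covariance Gaussian mixture with BIC
  selection (−2·logL + p·ln n) and red/green/gray phenotype labels.
* **Lipid classification** (`parseLipid`, `classFractions`): shorthand
  parsing (`PG 18:2_20:4`, `PC O-16:0/20:4`, `TAG 52:2`) and
  abundance-weighted PUFA₀/PUFA₁/PUFA₂ (+ ether-PUFA) class fractions.
* **Synthetic generators** (`simulateLobuleImage`,
  `simulateMarkerCohort`, `simulateExpressionCohort`,
  `simulateLipidTable`, `simulateCellImage`): seeded fixtures with known
  ground truth for every stage.

## Worked example

Recompute the cohort-table statistics from the shipped worked-example
counts (27 specimens in three marker-derived clusters):

```r
library(ferroStrat)
stats <- recomputeTable1Stats()
round(stats$ironFisherP, 4)
#> [1] 0.0141
stats$histologyPct
#>           cluster1 cluster2 cluster3
#> Control       20.0      0.0     80.0
#> MASL          37.5     37.5     25.0
#> MASH F0-1     42.9     42.9     14.3
#> MASH F2-3      0.0     57.1     42.9
```

The exact Fisher test on the iron-by-cluster counts gives p ≈ 0.014:
iron deposits concentrate in cluster 2, the cluster carrying the
ferroptosis signature, which also holds 37.5 % of MASL and 57.1 % of
fibrotic MASH specimens.

Cluster a synthetic marker cohort and compare to generator truth:

```r
co  <- simulateMarkerCohort(seed = 1)   # 7/10/10 specimens, 3 clusters
fit <- kPrototypes(co$table, k = 3, seed = 1)
fit
#> KPrototypesModel: k = 3 , gamma = 0.5
#>   n = 27 ; sizes: 7/10/10
#>   cost = 33.84306 after 6 iterations
adjustedRand(assignments(fit), co$labels)
#> [1] 1
```

Profile a pericentral stain along the portal-to-central axis:

```r
sim  <- simulateLobuleImage(96, 96, nCV = 3, nPT = 6,
                            pattern = "pericentral", r0 = 0.8,
                            noise = 0, seed = 1)
prof <- zonatedPositivity(sim$field, sim$stain, B = 10)
round(positiveFraction(prof), 2)
#>  [1] 0 0 0 0 0 0 0 0 1 1
round(profileCentroid(prof), 3)
#> [1] 0.868
```

Only the two bins beyond r = 0.8 are positive, and the profile centroid
sits at 0.87 — a pericentral stain.

A full simulated run (`runPipeline(outdir = "run", seed = 1)`) writes
landmark CSVs, masks, profiles, cluster/subtype tables, a lipid report
and a `summary.json`; `inst/scripts/ferrostrat.R` wraps it for the
shell.

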