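Package: ferroStrat
Title: Stratification of Steatotic Liver Disease by a Hepatic Ferroptosis Signature
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies hepatic ferroptosis markers from stained liver sections and
    stratifies patients on the resulting signature. Reconstructs liver lobules from
    portal-triad and central-vein landmarks on the Voronoi principle and profiles
    stain positivity along the portal-to-central axis; derives per-specimen marker
    rows (TUNEL foci, 4HNE aggregates, nuclear GPX4, cytoplasmic ACSL4, ferrous iron)
    from segmented hepatocytes; clusters mixed numeric/categorical marker tables with
    k-prototypes and characterizes clusters with Kruskal-Wallis/Dunn and exact Fisher
    r-by-c tests; scores transcriptomes on ferroptosis gene sets with a single-sample
    rank-based enrichment statistic and discovers latent subgroups by Gaussian-mixture
    modeling with BIC selection; and classifies phospholipids by polyunsaturated acyl
    tail content. Ships seeded synthetic-data generators for every input so the whole
    pipeline is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
biocViews: CellBiology, Clustering, GeneSetEnrichment, ImageAnalysis, Lipidomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'cellquant.R'
    'ferroStrat-package.R'
    'fixtures.R'
    'lipidclass.R'
    'pipeline.R'
    'setscore.R'
    'stats.R'
    'stratify.R'
    'synthetic.R'
    'utils.R'
    'zonation.R'
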