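# End-to-end orchestration: simulate -> zonation -> cellquant ->
# stratify -> subtype -> lipids, behind one seeded, configured entry
# point with standard-format I/O.

drawDisk <- function(mat, cx, cy, r, value) {
  g <- pixelGrid(nrow(mat), ncol(mat))
  mat[(g$x - cx)^2 + (g$y - cy)^2 <= r^2] <- value
  mat
}

#' Simulate a stained cell-field image set
#'
#' Builds a deterministic multi-marker specimen image: nuclei as bright
#' disks on a jittered grid, a GPX4 channel with a known positive-nucleus
#' subset, TUNEL foci and 4HNE aggregates as disks of known count, and an
#' optional iron deposit. Ground truth is returned alongside.
#'
#' @param nCells number of nuclei.
#' @param radius nucleus radius in pixels.
#' @param size image edge length in pixels.
#' @param gpx4PositiveFraction fraction of nuclei painted GPX4-positive.
#' @param nTunelFoci,nHneAggregates counts of TUNEL foci (small disks)
#'   and 4HNE aggregates (large disks).
#' @param ironPositive paint an iron deposit?
#' @param seed integer RNG seed.
#' @return list of marker images (`nucleiImage`, `gpx4`, `tunel`, `hne`,
#'   `iron`, `acsl4`) and a `truth` list.
#' @export
simulateCellImage <- function(nCells = 30L, radius = 4L, size = 128L,
                              gpx4PositiveFraction = 0.25, nTunelFoci = 3L,
                              nHneAggregates = 1L, ironPositive = FALSE,
                              seed = 1L) {
  withSeed(seed, {
    side <- ceiling(sqrt(nCells))
    sp <- size / side
    centers <- expand.grid(i = seq_len(side), j = seq_len(side))[seq_len(nCells), ]
    cx <- (centers$j - 0.5) * sp + runif(nCells, -1, 1)
    cy <- (centers$i - 0.5) * sp + runif(nCells, -1, 1)
    blank <- matrix(0, size, size)
    nucImg <- blank
    for (i in seq_len(nCells)) nucImg <- drawDisk(nucImg, cx[i], cy[i], radius, 0.9)
    nPos <- round(gpx4PositiveFraction * nCells)
    pos <- if (nPos > 0) sample(nCells, nPos) else integer()
    gpx4 <- blank + 0.1
    for (i in seq_len(nCells))
      gpx4 <- drawDisk(gpx4, cx[i], cy[i], radius,
                       if (i %in% pos) 0.9 else 0.2)
    tunel <- blank
    if (nTunelFoci > 0)
      for (i in seq_len(nTunelFoci))
        tunel <- drawDisk(tunel, runif(1, 10, size - 10),
                          runif(1, 10, size - 10), 2, 1)
    hne <- blank
    if (nHneAggregates > 0)
      for (i in seq_len(nHneAggregates))
        hne <- drawDisk(hne, runif(1, 15, size - 15),
                        runif(1, 15, size - 15), 7, 1)
    iron <- blank
    if (ironPositive) iron <- drawDisk(iron, size / 2, size / 2, 4, 1)
    acsl4 <- matrix(runif(size * size, 0.45, 0.55), size, size)
    list(nucleiImage = nucImg, gpx4 = gpx4, tunel = tunel, hne = hne,
         iron = iron, acsl4 = acsl4,
         truth = list(nCells = nCells, gpx4Positive = sort(pos),
                      nTunelFoci = nTunelFoci,
                      nHneAggregates = nHneAggregates,
                      ironPositive = ironPositive))
  })
}

#' Write/read landmark CSV (columns x, y, class)
#'
#' @param landmarks a [LandmarkSet].
#' @param path CSV path.
#' @export
writeLandmarks <- function(landmarks, path) {
  df <- data.frame(x = landmarks@coords[, 1L], y = landmarks@coords[, 2L],
                   class = as.character(landmarks@type))
  utils::write.csv(df, path, row.names = FALSE)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path)
  LandmarkSet(df$x, df$y, df$class)
}

#' Write/read a binary mask as 8-bit PNG
#'
#' Masks are stored with x rightward and y downward (matrix rows become
#' image rows).
#'
#' @param mask logical matrix.
#' @param path PNG path.
#' @export
writeMask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask) * 1), path, type = "png")
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  t(EBImage::imageData(EBImage::readImage(path))) > 0.5
}

#' Default pipeline configuration
#'
#' Every parameter of every stage with its documented default; unknown
#' keys in a user config are rejected.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    image = list(width = 96L, height = 96L, nCV = 3L, nPT = 6L,
                 jitter = 0.1, pattern = "pericentral", r0 = 0.8,
                 coverage = 0.3, noise = 0.02),
    zonation = list(bins = 20L),
    cellquant = list(nCells = 30L, radius = 4L, ringRadius = 4L,
                     pixelSize = 0.5, fociMinArea = 4L, aggMinArea = 100L),
    stratify = list(k = 3L, gamma = 0.5, nInit = 50L),
    expression = list(nSamples = 78L, nGenes = 300L),
    setscore = list(tau = 1, kMax = 4L, nInit = 5L),
    lipids = list(nSpecies = 60L)
  )
}

mergeConfig <- function(user, def, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(def))
      stop("unknown config key: ", path, nm)
    def[[nm]] <- if (is.list(def[[nm]]) && is.list(user[[nm]]))
      mergeConfig(user[[nm]], def[[nm]], paste0(path, nm, "."))
    else user[[nm]]
  }
  def
}

#' Run the full stratification pipeline on simulated inputs
#'
#' Executes the requested stages into a run directory: input simulation,
#' zonated stain profiling, per-specimen marker quantification, marker
#' stratification (k-prototypes + cluster characterization), gene-set
#' subtyping (scoring + mixture model + phenotype labels), and lipid
#' PUFA-class reporting. Deterministic given the seed; a machine-readable
#' `summary.json` records the package version, a config hash and all
#' per-stage seeds, and `columns.json` documents table columns and units.
#'
#' @param config `NULL` (defaults), a nested list, or a path to a YAML
#'   file overriding [defaultRunConfig()] keys; unknown keys are
#'   rejected.
#' @param outdir run directory (created if needed).
#' @param seed integer global seed; overrides the config's.
#' @param stage one of `"all"`, `"simulate"`, `"zonation"`, `"cellquant"`,
#'   `"stratify"`, `"subtype"`, `"lipids"`. Stages other than
#'   `"simulate"` simulate their own inputs if missing.
#' @param logLevel `"debug"`, `"info"` or `"warn"`.
#' @return (invisibly) the summary list.
#' @export
runPipeline <- function(config = NULL, outdir, seed = NULL,
                        stage = c("all", "simulate", "zonation", "cellquant",
                                  "stratify", "subtype", "lipids"),
                        logLevel = c("info", "debug", "warn")) {
  stage <- match.arg(stage)
  logLevel <- match.arg(logLevel)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- mergeConfig(if (is.null(config)) list() else config,
                     defaultRunConfig())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outdir, "run.log")
  lvl <- c(debug = 1L, info = 2L, warn = 3L)
  logMsg <- function(level, ...) {
    if (lvl[[level]] < lvl[[logLevel]]) return(invisible())
    line <- paste0("[", level, "] ", ...)
    message(line)
    cat(line, "\n", file = logFile, append = TRUE)
  }
  inStage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  want <- function(s) stage %in% c("all", s)
  seeds <- list()
  stageSeed <- function(s, offset) {
    seeds[[s]] <<- cfg$seed + offset
    seeds[[s]]
  }
  outputs <- character()
  summary <- list()

  if (want("simulate") || want("zonation")) inStage("simulate", {
    logMsg("info", "simulating lobule image and landmarks")
    im <- cfg$image
    sim <- simulateLobuleImage(im$width, im$height, im$nCV, im$nPT, im$jitter,
                               im$pattern, im$r0, im$coverage, im$noise,
                               seed = stageSeed("simulate", 0L))
    writeLandmarks(sim$landmarks, file.path(outdir, "landmarks.csv"))
    writeMask(sim$tissue, file.path(outdir, "tissue_mask.png"))
    writeMask(sim$stain, file.path(outdir, "stain_mask.png"))
    outputs <- c(outputs, "landmarks.csv", "tissue_mask.png", "stain_mask.png")
    if (want("zonation")) {
      logMsg("info", "computing zonation profile")
      prof <- zonatedPositivity(sim$field, sim$stain, cfg$zonation$bins)
      utils::write.csv(profileAsData(prof),
                       file.path(outdir, "zonation_profile.csv"),
                       row.names = FALSE)
      outputs <- c(outputs, "zonation_profile.csv")
      summary$zonationCentroid <- profileCentroid(prof)
    }
  })

  if (want("cellquant")) inStage("cellquant", {
    logMsg("info", "quantifying specimen markers")
    cq <- cfg$cellquant
    cell <- simulateCellImage(cq$nCells, cq$radius,
                              seed = stageSeed("cellquant", 1L))
    nuc <- segmentNuclei(cell$nucleiImage, sigma = 1, minArea = 10L)
    cyto <- suppressWarnings(cytoplasmRings(nuc, cq$ringRadius))
    row <- quantifySpecimen(cellMap(nuc, cyto),
                            markers = cell[c("tunel", "hne", "gpx4",
                                             "acsl4", "iron")],
                            fociMinArea = cq$fociMinArea,
                            aggMinArea = cq$aggMinArea,
                            pixelSize = cq$pixelSize, specimen = "SIM001")
    utils::write.csv(row, file.path(outdir, "marker_row.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "marker_row.csv")
  })

  if (want("stratify")) inStage("stratify", {
    logMsg("info", "clustering marker cohort")
    co <- simulateMarkerCohort(seed = stageSeed("stratify", 2L))
    utils::write.csv(co$table, file.path(outdir, "marker_table.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(specimen = co$table$specimen,
                                trueCluster = co$labels),
                     file.path(outdir, "marker_truth.csv"), row.names = FALSE)
    st <- cfg$stratify
    fit <- kPrototypes(co$table, k = st$k, gamma = st$gamma,
                       nInit = st$nInit, seed = cfg$seed)
    utils::write.csv(data.frame(specimen = co$table$specimen,
                                cluster = assignments(fit)),
                     file.path(outdir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(characterizeClusters(fit, co$table),
                     file.path(outdir, "cluster_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(silhouetteReport(co$table, 2:4, nInit = 10L,
                                      seed = cfg$seed),
                     file.path(outdir, "silhouette.csv"), row.names = FALSE)
    outputs <- c(outputs, "marker_table.csv", "marker_truth.csv",
                 "clusters.csv", "cluster_summary.csv", "silhouette.csv")
    summary$markerARI <- adjustedRand(assignments(fit), co$labels)
  })

  if (want("subtype")) inStage("subtype", {
    logMsg("info", "scoring gene sets and fitting mixture model")
    ex <- cfg$expression
    sim <- simulateExpressionCohort(ex$nSamples, ex$nGenes,
                                    seed = stageSeed("subtype", 3L))
    utils::write.table(sim$expr, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    writeGmt(sim$geneSets, file.path(outdir, "genesets.gmt"))
    sc <- gsvaScores(sim$expr, sim$geneSets, tau = cfg$setscore$tau)
    utils::write.csv(as.data.frame(sc), file.path(outdir, "gsva_scores.csv"))
    gmm <- fitGmm(sc, kRange = seq_len(cfg$setscore$kMax),
                  nInit = cfg$setscore$nInit, seed = cfg$seed)
    gmm <- assignPhenotypeLabels(gmm)
    utils::write.csv(data.frame(sample = rownames(sc),
                                component = assignments(gmm),
                                label = phenotypeLabels(gmm)[assignments(gmm)],
                                trueSubgroup = sim$labels),
                     file.path(outdir, "subgroups.csv"), row.names = FALSE)
    outputs <- c(outputs, "expression.tsv", "genesets.gmt",
                 "gsva_scores.csv", "subgroups.csv")
    summary$selectedK <- nClusters(gmm)
    summary$phenotypes <- phenotypeLabels(gmm)
  })

  if (want("lipids")) inStage("lipids", {
    logMsg("info", "classifying lipid species")
    tab <- simulateLipidTable(cfg$lipids$nSpecies,
                              seed = stageSeed("lipids", 4L))
    utils::write.csv(tab, file.path(outdir, "lipids.csv"), row.names = FALSE)
    fr <- suppressMessages(classFractions(tab))
    utils::write.csv(fr, file.path(outdir, "lipid_fractions.csv"),
                     row.names = FALSE)
    outputs <- c(outputs, "lipids.csv", "lipid_fractions.csv")
  })

  cfgPath <- file.path(outdir, "config_used.yaml")
  yaml::write_yaml(cfg, cfgPath)
  summary <- c(list(
    package = "ferroStrat",
    version = as.character(utils::packageVersion("ferroStrat")),
    configHash = unname(tools::md5sum(cfgPath)),
    seed = cfg$seed, stageSeeds = seeds, stage = stage,
    outputs = outputs), summary)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(columnMetadata(), file.path(outdir, "columns.json"),
                       auto_unbox = TRUE)
  logMsg("info", "run complete: ", outdir)
  invisible(summary)
}

# Sidecar metadata: column names and units of every emitted table.
columnMetadata <- function() {
  list(
    landmarks.csv = list(x = "pixels (rightward)", y = "pixels (downward)",
                         class = "CV | PT"),
    zonation_profile.csv = list(binStart = "relative distance",
                                binEnd = "relative distance",
                                mid = "relative distance",
                                tissue = "pixel count",
                                positive = "pixel count",
                                fraction = "positive/tissue"),
    marker_row.csv = list(tunel = "foci per mm2", hne = "aggregates per mm2",
                          hneAreaFraction = "area fraction",
                          gpx4 = "positive-nucleus fraction",
                          acsl4 = "mean cytoplasmic intensity (a.u.)",
                          acsl4Nuclear = "mean nuclear intensity (a.u.)",
                          iron = "positive | negative"),
    marker_table.csv = list(tunel = "foci per mm2", hne = "aggregates per mm2",
                            gpx4 = "positive-nucleus fraction",
                            acsl4 = "intensity (a.u.)",
                            iron = "positive | negative",
                            histology = "histologic group"),
    gsva_scores.csv = list(value = "enrichment score in (-1, 1)"),
    lipid_fractions.csv = list(PUFA0 = "% of class abundance",
                               PUFA1 = "% of class abundance",
                               PUFA2 = "% of class abundance",
                               PUFA3 = "% of class abundance",
                               ePUFA = "% of class abundance (overlapping flag)",
                               unresolved = "species count"))
}
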