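# Seeded generators for every input the pipeline consumes: lobule images
# with landmarks and stain masks, marker cohorts with known cluster
# labels, expression cohorts with known subgroup labels, and lipid tables.
# Every generator is a pure function of its seed and parameters, and
# ground-truth labels are always returned separately from the feature
# tables.

# Jittered hexagonal lattice of at least n points covering a
# width x height image; returns the first n points in row-major order.
hexLattice <- function(n, width, height, jitter, offset = FALSE) {
  ncols <- max(1L, ceiling(sqrt(n * width / max(height, 1))))
  nrows <- max(1L, ceiling(n / ncols))
  while (nrows * ncols < n) ncols <- ncols + 1L
  sx <- width / ncols
  sy <- height / nrows
  pts <- matrix(0, nrows * ncols, 2L)
  i <- 0L
  for (ry in seq_len(nrows)) {
    # hexagonal stagger: odd rows shifted half a spacing
    rowShift <- if (ry %% 2L == 0L) sx / 2 else 0
    for (cx in seq_len(ncols)) {
      i <- i + 1L
      pts[i, ] <- c((cx - 0.5) * sx + rowShift, (ry - 0.5) * sy)
    }
  }
  if (offset) pts <- sweep(pts, 2L, c(sx / 2, sy / 2), "+")
  pts <- pts[seq_len(n), , drop = FALSE]
  spacing <- min(sx, sy)
  pts <- pts + matrix(runif(2L * n, -jitter * spacing, jitter * spacing), n, 2L)
  pts[, 1L] <- pmin(pmax(pts[, 1L], 0), width - 1)
  pts[, 2L] <- pmin(pmax(pts[, 2L], 0), height - 1)
  pts
}

#' Simulate a lobular tissue image with landmarks and a stain mask
#'
#' Emulates zonated staining in a reconstructed liver lobule: central
#' veins sit on a jittered hexagonal lattice, portal triads on the offset
#' (cell-corner) lattice, and the stain mask follows the requested zonal
#' pattern of the relative lobular distance r (portal = 0, central = 1):
#'
#' * `pericentral`: stained where `r >= r0` (stain hugs the central vein);
#' * `periportal`: stained where `r <= 1 - r0` (mirror pattern);
#' * `panlobular`: stained pixels drawn Bernoulli(`coverage`) at every r;
#' * `none`: empty stain.
#'
#' Independent per-pixel label flips at rate `noise` are applied after the
#' pattern; the pre-noise mask is returned as `stainClean`.
#'
#' @param width,height image size in pixels.
#' @param nCV,nPT number of central veins / portal triads (each >= 1).
#' @param jitter landmark jitter as a fraction of the lattice spacing.
#' @param pattern stain pattern, one of `"pericentral"`, `"panlobular"`,
#'   `"periportal"`, `"none"`.
#' @param r0 pattern boundary on the relative-distance axis, in `[0, 1]`.
#' @param coverage stained fraction for the panlobular pattern.
#' @param noise per-pixel label-flip probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param intensity if `TRUE`, also return a Gaussian-blurred intensity
#'   image of the stain (for segmentation-style consumers).
#' @return list with `landmarks` ([LandmarkSet]), `tissue` and `stain`
#'   logical matrices, `stainClean` (pre-noise stain), `field`
#'   ([ZonationField]) and optionally `intensity`.
#' @examples
#' sim <- simulateLobuleImage(64, 64, nCV = 2, nPT = 4, pattern = "pericentral",
#'                            r0 = 0.8, noise = 0, seed = 7)
#' min(relDistance(sim$field)[sim$stain])   # >= 0.8
#' @export
simulateLobuleImage <- function(width = 128L, height = 128L, nCV = 4L, nPT = 9L,
                                jitter = 0.1,
                                pattern = c("pericentral", "panlobular",
                                            "periportal", "none"),
                                r0 = 0.8, coverage = 0.3, noise = 0,
                                seed = 1L, intensity = FALSE) {
  pattern <- match.arg(pattern)
  if (nCV < 1L || nPT < 1L)
    stop("at least one CV and one PT landmark required")
  checkProb(r0, "r0"); checkProb(noise, "noise"); checkProb(coverage, "coverage")
  withSeed(seed, {
    cv <- hexLattice(nCV, width, height, jitter)
    pt <- hexLattice(nPT, width, height, jitter, offset = TRUE)
    # a CV/PT coordinate collision would leave r undefined at that pixel
    while (any(paste(pt[, 1], pt[, 2]) %in% paste(cv[, 1], cv[, 2])))
      pt[, 1L] <- pmin(pt[, 1L] + 0.5, width - 1)
    lm <- LandmarkSet(x = c(cv[, 1L], pt[, 1L]), y = c(cv[, 2L], pt[, 2L]),
                      class = rep(c("CV", "PT"), c(nCV, nPT)))
    tissue <- matrix(TRUE, height, width)
    field <- relativeDistanceMap(lm, tissue)
    r <- field@r
    stain <- switch(pattern,
      none        = matrix(FALSE, height, width),
      pericentral = r >= r0,
      periportal  = r <= 1 - r0,
      panlobular  = matrix(runif(height * width) < coverage, height, width))
    stain <- stain & tissue
    clean <- stain
    if (noise > 0) {
      flip <- matrix(runif(height * width) < noise, height, width) & tissue
      stain <- xor(stain, flip)
    }
    out <- list(landmarks = lm, tissue = tissue, stain = stain,
                stainClean = clean, field = field)
    if (intensity) {
      img <- EBImage::gblur(EBImage::Image(clean * 0.8), sigma = 2)
      out$intensity <- EBImage::imageData(img)
    }
    out
  })
}

#' Default marker-cohort simulation parameters
#'
#' Three latent clusters shaped like the stratified biopsy cohort: a
#' "no-ferroptosis MASLD" cluster (low cell death, high nuclear GPX4), a
#' "ferroptosis signature" cluster (high TUNEL/4HNE, frequent iron
#' deposits, low GPX4), and a low-marker cluster holding most controls.
#' ACSL4 does not separate the clusters.
#'
#' @return list of `sizes`, `means`, `sds`, `ironProb`, `histProb`.
#' @export
markerCohortDefaults <- function() {
  markers <- c("tunel", "hne", "gpx4", "acsl4")
  hist <- c("Control", "MASL", "MASH F0-1", "MASH F2-3")
  means <- rbind(c(5, 2, 0.70, 50),
                 c(30, 15, 0.30, 50),
                 c(3, 1, 0.40, 50))
  sds <- rbind(c(3, 1.5, 0.08, 8),
               c(6, 4, 0.08, 8),
               c(2, 0.8, 0.08, 8))
  dimnames(means) <- dimnames(sds) <- list(paste0("cluster", 1:3), markers)
  histProb <- rbind(c(1, 3, 3, 0) / 7,
                    c(0, 3, 3, 4) / 10,
                    c(4, 2, 1, 3) / 10)
  dimnames(histProb) <- list(paste0("cluster", 1:3), hist)
  list(sizes = c(7L, 10L, 10L), means = means, sds = sds,
       ironProb = c(1 / 7, 0.7, 0.1), histProb = histProb)
}

#' Simulate a marker cohort with known cluster labels
#'
#' Draws numeric ferroptosis markers from per-cluster Gaussians and the
#' binary iron stain from per-cluster Bernoullis; histology labels are
#' sampled per cluster from `histProb` and attached as metadata (never a
#' clustering feature). True cluster labels are returned separately from
#' the table.
#'
#' @param sizes integer vector of per-cluster sample sizes (all >= 1).
#' @param means,sds numeric k x p matrices of per-cluster marker means and
#'   SDs (SDs > 0; `sds = 0` is allowed only as an explicit degenerate
#'   limit via `allowZeroSd`).
#' @param ironProb per-cluster probability of a positive iron stain.
#' @param histProb k x 4 matrix of histology mixing proportions per
#'   cluster (rows sum to 1).
#' @param seed integer RNG seed.
#' @param allowZeroSd permit `sds == 0` (degenerate point-mass draws).
#' @return list with `table` (data.frame: specimen, numeric markers, iron
#'   factor, histology factor) and `labels` (true cluster index).
#' @export
simulateMarkerCohort <- function(sizes = NULL, means = NULL, sds = NULL,
                                 ironProb = NULL, histProb = NULL, seed = 1L,
                                 allowZeroSd = FALSE) {
  def <- markerCohortDefaults()
  if (is.null(sizes)) sizes <- def$sizes
  if (is.null(means)) means <- def$means
  if (is.null(sds)) sds <- def$sds
  if (is.null(ironProb)) ironProb <- def$ironProb
  if (is.null(histProb)) histProb <- def$histProb
  k <- length(sizes)
  if (any(sizes < 1L)) stop("all cluster sizes must be >= 1")
  if (!allowZeroSd && any(sds <= 0)) stop("all marker SDs must be > 0")
  if (any(sds < 0)) stop("negative SD")
  checkProb(ironProb, "ironProb"); checkProb(histProb, "histProb")
  if (any(abs(rowSums(histProb) - 1) > 1e-8))
    stop("histology proportions must sum to 1 per cluster")
  stopifnot(nrow(means) == k, nrow(sds) == k, length(ironProb) == k,
            nrow(histProb) == k)
  withSeed(seed, {
    rows <- lapply(seq_len(k), function(cl) {
      n <- sizes[cl]
      num <- vapply(seq_len(ncol(means)),
                    function(j) rnorm(n, means[cl, j], sds[cl, j]),
                    numeric(n))
      num <- matrix(num, nrow = n,
                    dimnames = list(NULL, colnames(means)))
      iron <- rbinom(n, 1L, ironProb[cl])
      hist <- sample(colnames(histProb), n, replace = TRUE,
                     prob = histProb[cl, ])
      list(num = num, iron = iron, hist = hist)
    })
    num <- do.call(rbind, lapply(rows, `[[`, "num"))
    n <- nrow(num)
    tab <- data.frame(specimen = sprintf("S%03d", seq_len(n)), num,
                      iron = factor(ifelse(unlist(lapply(rows, `[[`, "iron")) == 1L,
                                           "positive", "negative"),
                                    levels = c("negative", "positive")),
                      histology = factor(unlist(lapply(rows, `[[`, "hist")),
                                         levels = colnames(histProb)))
    list(table = tab, labels = rep(seq_len(k), sizes))
  })
}

#' Default ferroptosis gene sets
#'
#' Package-default four-set collection over well-known ferroptosis pathway
#' members, grouped for interpretation: enzymatic defenses, glutathione
#' synthesis, PUFA incorporation into membranes, and iron handling. Users
#' studying a specific signature should supply their own GMT via
#' [readGmt()]; this default exists so the pipeline runs self-contained.
#'
#' @return named list of character vectors of gene symbols (22 genes).
#' @export
defaultFerroptosisSets <- function() {
  list(
    defenses = c("GPX4", "AIFM2", "GCH1"),
    GSH = c("GCLC", "GCLM", "GSS", "GSR", "SLC7A11", "SLC3A2"),
    PUFA = c("ACSL4", "LPCAT3", "ALOX15", "ELOVL5", "FADS1", "FADS2"),
    Iron = c("TFRC", "SLC40A1", "FTH1", "FTL", "HMOX1", "NCOA4", "IREB2")
  )
}

#' Simulate an expression cohort with latent subgroups
#'
#' Log-scale expression (log2 units) is Gaussian per gene; each latent
#' subgroup shifts designated gene sets by a stated number of baseline
#' SDs. The raw scale (`2^expr`) is strictly positive by construction.
#' True subgroup labels are returned separately.
#'
#' @param nSamples,nGenes cohort dimensions; `nGenes` must cover all set
#'   members.
#' @param geneSets named list of gene-symbol vectors (default
#'   [defaultFerroptosisSets()]); sets must be disjoint unless
#'   `allowOverlap = TRUE`.
#' @param shifts numeric matrix, subgroups x sets, in SD units; row s /
#'   column t shifts set t in subgroup s. Default: 3 subgroups shaped like
#'   the latent structure of the public-cohort analysis — a neutral
#'   subgroup, a "red" subgroup (PUFA/Iron up, defenses/GSH down) and a
#'   "green" subgroup (defenses/GSH up).
#' @param proportions subgroup mixing proportions (sum to 1).
#' @param baselineMean,baselineSd per-gene log2 expression mean and SD.
#' @param seed integer RNG seed.
#' @param allowOverlap permit overlapping gene sets.
#' @return list with `expr` (genes x samples, log2 scale), `labels`
#'   (true subgroup per sample) and `geneSets` (as matched to rows).
#' @export
simulateExpressionCohort <- function(nSamples = 78L, nGenes = 500L,
                                     geneSets = defaultFerroptosisSets(),
                                     shifts = NULL,
                                     proportions = c(0.45, 0.3, 0.25),
                                     baselineMean = 6, baselineSd = 1,
                                     seed = 1L, allowOverlap = FALSE) {
  if (is.null(shifts)) {
    shifts <- rbind(gray = c(0, 0, 0, 0),
                    red = c(-2, -2, 2, 2),
                    green = c(2, 2, 0, 0))
    colnames(shifts) <- c("defenses", "GSH", "PUFA", "Iron")
    shifts <- shifts[, names(geneSets)[names(geneSets) %in% colnames(shifts)],
                     drop = FALSE]
    if (ncol(shifts) != length(geneSets))
      stop("default shifts need the default set names; supply 'shifts'")
  }
  if (!all(is.finite(shifts))) stop("shifts must be finite")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("subgroup proportions must sum to 1")
  if (nrow(shifts) != length(proportions))
    stop("one shift row per subgroup required")
  allSet <- unlist(geneSets, use.names = FALSE)
  if (!allowOverlap && anyDuplicated(allSet))
    stop("gene sets overlap; set allowOverlap = TRUE to permit")
  if (nGenes < length(unique(allSet)))
    stop("nGenes smaller than the total gene-set size")
  withSeed(seed, {
    genes <- c(unique(allSet),
               sprintf("gene%04d", seq_len(nGenes - length(unique(allSet)))))
    labels <- sample(nrow(shifts), nSamples, replace = TRUE, prob = proportions)
    expr <- matrix(rnorm(nGenes * nSamples, baselineMean, baselineSd),
                   nGenes, nSamples,
                   dimnames = list(genes, sprintf("sample%03d", seq_len(nSamples))))
    for (s in seq_len(nrow(shifts)))
      for (t in seq_along(geneSets)) {
        if (shifts[s, t] == 0) next
        gi <- match(geneSets[[t]], genes)
        expr[gi, labels == s] <- expr[gi, labels == s] +
          shifts[s, t] * baselineSd
      }
    list(expr = expr, labels = labels, geneSets = geneSets)
  })
}

#' Simulate a lipid species table
#'
#' Random lipid species in shorthand nomenclature with log-normal
#' abundances, mixing saturated/monounsaturated and polyunsaturated acyl
#' tails. All generated names round-trip through [parseLipid()].
#'
#' @param nSpecies number of species (0 gives an empty table).
#' @param classMix named numeric vector of headgroup-class mixing
#'   proportions; must cover at least PC, PE, PG and TAG.
#' @param etherProb probability of an ether (O-) linkage for PC/PE.
#' @param pufaProb per-tail probability of a polyunsaturated tail
#'   (>= 2 double bonds).
#' @param seed integer RNG seed.
#' @return data.frame with `name` (shorthand) and `abundance`.
#' @export
simulateLipidTable <- function(nSpecies = 60L,
                               classMix = c(PC = 0.3, PE = 0.25, PG = 0.2,
                                            TAG = 0.25),
                               etherProb = 0.15, pufaProb = 0.4, seed = 1L) {
  if (!all(c("PC", "PE", "PG", "TAG") %in% names(classMix)))
    stop("classMix must cover at least PC, PE, PG, TAG")
  if (nSpecies == 0L)
    return(data.frame(name = character(), abundance = numeric()))
  withSeed(seed, {
    cls <- sample(names(classMix), nSpecies, replace = TRUE,
                  prob = classMix / sum(classMix))
    name <- vapply(cls, function(cl) {
      nt <- if (cl == "TAG") 3L else 2L
      tails <- vapply(seq_len(nt), function(i) {
        db <- if (runif(1) < pufaProb) sample(2:6, 1L) else sample(0:1, 1L)
        carbons <- sample(seq(14L, 22L, by = 2L), 1L)
        sprintf("%d:%d", carbons, db)
      }, character(1))
      ether <- cl %in% c("PC", "PE") && runif(1) < etherProb
      paste0(cl, " ", if (ether) "O-" else "", paste(tails, collapse = "_"))
    }, character(1))
    data.frame(name = name, abundance = rlnorm(nSpecies, meanlog = 2, sdlog = 1))
  })
}
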