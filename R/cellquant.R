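# Per-specimen marker quantification from segmented hepatocytes.
# Segmentation is a fully specified classical chain (smooth -> threshold
# -> watershed on the distance transform) so every marker value is
# deterministic and testable.

relabelContiguous <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
  out <- matrix(match(lab, ids, nomatch = 0L), nrow(lab), ncol(lab))
  storage.mode(out) <- "integer"
  out
}

# Threshold rule: a fixed numeric value, or "otsu" on the image's own
# histogram. A constant image thresholds to +Inf (nothing positive).
resolveThreshold <- function(img, rule) {
  if (is.numeric(rule)) return(rule)
  if (!identical(rule, "otsu")) stop("threshold rule must be numeric or 'otsu'")
  rng <- range(img)
  if (diff(rng) == 0) return(Inf)
  EBImage::otsu(EBImage::Image(img), range = rng)
}

#' Segment nuclei by smoothing, thresholding and watershed splitting
#'
#' Connected components of the smoothed, thresholded image are
#' area-filtered; touching components are split by a watershed on the
#' distance transform. A blank image yields zero labels, not an error.
#'
#' @param img single-channel numeric matrix.
#' @param sigma Gaussian smoothing SD in pixels (0 disables smoothing).
#' @param threshold `"otsu"` (default: Otsu on the specimen's own
#'   histogram) or a fixed numeric cutoff.
#' @param minArea,maxArea component area bounds in pixels.
#' @return integer label matrix with labels contiguous `1..N`.
#' @export
segmentNuclei <- function(img, sigma = 2, threshold = "otsu",
                          minArea = 20L, maxArea = Inf) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("'img' must be a single-channel numeric matrix")
  sm <- if (sigma > 0)
    EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  else img
  thr <- resolveThreshold(sm, threshold)
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- EBImage::distmap(EBImage::Image(mask))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= minArea & areas <= maxArea)
  lab[!(lab %in% keep)] <- 0L
  relabelContiguous(lab)
}

#' Cytoplasm rings around segmented nuclei
#'
#' Dilates each nucleus by `radius` pixels, removes all nuclei and the
#' excluded-region mask (lipid vacuoles), and resolves pixels contested
#' between nuclei to the nucleus with the nearest centroid (ties to the
#' lower label). Nuclei left with no cytoplasm are flagged in the
#' `"emptyCytoplasm"` attribute.
#'
#' @param nuclei integer nucleus label matrix (labels `1..N`).
#' @param radius ring radius in pixels (>= 1).
#' @param excluded optional logical mask of excluded regions.
#' @return integer cytoplasm label matrix in the same label space.
#' @export
cytoplasmRings <- function(nuclei, radius = 5L, excluded = NULL) {
  if (radius < 1L) stop("'radius' must be >= 1 pixel")
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(nuclei), ncol(nuclei))
  stopifnot(identical(dim(excluded), dim(nuclei)))
  n <- max(nuclei)
  out <- matrix(0L, nrow(nuclei), ncol(nuclei))
  if (n == 0L) return(out)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  allowed <- nuclei == 0L & !excluded
  grid <- pixelGrid(nrow(nuclei), ncol(nuclei))
  cx <- vapply(seq_len(n), function(i) mean(grid$x[nuclei == i]), numeric(1))
  cy <- vapply(seq_len(n), function(i) mean(grid$y[nuclei == i]), numeric(1))
  claims <- vector("list", n)
  for (i in seq_len(n)) {
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(nuclei == i), brush))
    claims[[i]] <- which(dil > 0 & allowed)
  }
  idx <- unlist(claims)
  lab <- rep.int(seq_len(n), lengths(claims))
  nclaim <- tabulate(factor(idx, levels = seq_len(length(out))))
  single <- nclaim[idx] == 1L
  out[idx[single]] <- lab[single]
  cont <- !single
  if (any(cont)) {
    ci <- idx[cont]; cl <- lab[cont]
    px <- grid$x[ci]; py <- grid$y[ci]
    d2 <- (px - cx[cl])^2 + (py - cy[cl])^2
    ord <- order(ci, d2, cl)   # per pixel: nearest centroid first, tie -> lower label
    first <- !duplicated(ci[ord])
    out[ci[ord][first]] <- cl[ord][first]
  }
  empty <- setdiff(seq_len(n), unique(out[out > 0L]))
  if (length(empty))
    warning(length(empty), " nucleus/nuclei have no cytoplasm ring ",
            "(fully excluded or crowded)")
  attr(out, "emptyCytoplasm") <- empty
  out
}

#' Assemble a cell map
#'
#' @param nuclei integer nucleus label matrix.
#' @param cytoplasm integer cytoplasm label matrix in the same label
#'   space (e.g. from [cytoplasmRings()]).
#' @param excluded optional logical excluded-region mask (lipid vacuoles).
#' @return validated list of class `CellMap`.
#' @export
cellMap <- function(nuclei, cytoplasm, excluded = NULL) {
  if (is.null(excluded)) excluded <- matrix(FALSE, nrow(nuclei), ncol(nuclei))
  stopifnot(identical(dim(nuclei), dim(cytoplasm)),
            identical(dim(nuclei), dim(excluded)))
  if (any(nuclei > 0L & cytoplasm > 0L))
    stop("cytoplasm overlaps nuclei")
  if (any(cytoplasm > 0L & excluded))
    stop("cytoplasm overlaps the excluded mask")
  ids <- sort(unique(nuclei[nuclei > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    stop("nucleus labels must be contiguous 1..N")
  structure(list(nuclei = nuclei, cytoplasm = cytoplasm, excluded = excluded),
            class = "CellMap")
}

countComponents <- function(mask, minArea) {
  if (!any(mask)) return(list(n = 0L, pixels = 0L))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  areas <- tabulate(lab[lab > 0L])
  keep <- areas >= minArea
  list(n = sum(keep), pixels = sum(areas[keep]))
}

#' Quantify ferroptosis markers for one specimen
#'
#' Produces the per-specimen marker row feeding the stratification:
#' TUNEL focus density, 4HNE aggregate density and area fraction (an
#' aggregate is a connected supra-threshold component of at least
#' `aggMinArea` pixels, distinguishing it from granular lipofuscin),
#' fraction of GPX4-positive nuclei (mean nuclear intensity above the
#' threshold), mean cytoplasmic and nuclear ACSL4 intensity, and a binary
#' ferrous-iron call (any deposit component of at least `ironMinArea`
#' pixels).
#'
#' @param cellmap a [cellMap()].
#' @param markers named list of single-channel matrices among `tunel`,
#'   `hne`, `gpx4`, `acsl4`, `iron`; all must match the cell-map shape.
#' @param thresholds named list of per-marker threshold rules (numeric or
#'   `"otsu"`, the default for every marker).
#' @param fociMinArea minimum TUNEL focus area (px).
#' @param aggMinArea minimum 4HNE aggregate area (px; default 100).
#' @param ironMinArea minimum iron deposit area (px).
#' @param pixelSize pixel edge length in micrometres (> 0); densities are
#'   reported per mm^2 of imaged area.
#' @param specimen specimen identifier.
#' @return one-row data.frame (`MarkerRow`): specimen, `tunel` (foci/mm2),
#'   `hne` (aggregates/mm2), `hneAreaFraction`, `gpx4` (positive-nucleus
#'   fraction), `acsl4` (mean cytoplasmic), `acsl4Nuclear`, `iron`
#'   (factor positive/negative).
#' @export
quantifySpecimen <- function(cellmap, markers, thresholds = list(),
                             fociMinArea = 4L, aggMinArea = 100L,
                             ironMinArea = 4L, pixelSize = 0.5,
                             specimen = "specimen") {
  stopifnot(inherits(cellmap, "CellMap"), pixelSize > 0)
  shp <- dim(cellmap$nuclei)
  for (nm in names(markers))
    if (!identical(dim(markers[[nm]]), shp))
      stop("marker image '", nm, "' shape differs from the cell map")
  thr <- function(nm) {
    rule <- if (nm %in% names(thresholds)) thresholds[[nm]] else "otsu"
    resolveThreshold(markers[[nm]], rule)
  }
  areaMm2 <- prod(shp) * (pixelSize / 1000)^2

  tunel <- hne <- hneFrac <- gpx4 <- acsl4c <- acsl4n <- NA_real_
  iron <- NA_character_
  if ("tunel" %in% names(markers)) {
    cc <- countComponents(markers$tunel > thr("tunel"), fociMinArea)
    tunel <- cc$n / areaMm2
  }
  if ("hne" %in% names(markers)) {
    cc <- countComponents(markers$hne > thr("hne"), aggMinArea)
    hne <- cc$n / areaMm2
    hneFrac <- cc$pixels / prod(shp)
  }
  if ("gpx4" %in% names(markers)) {
    n <- max(cellmap$nuclei)
    if (n > 0L) {
      m <- vapply(seq_len(n),
                  function(i) mean(markers$gpx4[cellmap$nuclei == i]),
                  numeric(1))
      gpx4 <- mean(m > thr("gpx4"))
    }
  }
  if ("acsl4" %in% names(markers)) {
    if (any(cellmap$cytoplasm > 0L))
      acsl4c <- mean(markers$acsl4[cellmap$cytoplasm > 0L])
    if (any(cellmap$nuclei > 0L))
      acsl4n <- mean(markers$acsl4[cellmap$nuclei > 0L])
  }
  if ("iron" %in% names(markers)) {
    cc <- countComponents(markers$iron > thr("iron"), ironMinArea)
    iron <- if (cc$n > 0L) "positive" else "negative"
  }
  data.frame(specimen = specimen, tunel = tunel, hne = hne,
             hneAreaFraction = hneFrac, gpx4 = gpx4, acsl4 = acsl4c,
             acsl4Nuclear = acsl4n,
             iron = factor(iron, levels = c("negative", "positive")))
}
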