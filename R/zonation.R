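#' Reconstruct lobular zonation from portal/central landmarks
#'
#' Computes, for every tissue pixel, the Euclidean distance to the nearest
#' portal triad (`dPT`) and nearest central vein (`dCV`) and the relative
#' lobular distance
#' \deqn{r = d_{PT} / (d_{PT} + d_{CV}),}
#' which is exactly 0 at portal triads and 1 at central veins. Lobules are
#' reconstructed on the Voronoi principle: each pixel is labeled with the
#' index of its nearest CV.
#'
#' Distances are measured on pixel centres (pixel `[i, j]` sits at
#' `x = j - 1`, `y = i - 1`). Real portal triads and veins are regions,
#' not points: `cvMask`/`ptMask` optionally replace the point landmarks
#' of that class by a binary region mask, with distances taken to the
#' nearest mask pixel. Point mode is the canonical, tested mode; region
#' mode shares the same r definition.
#'
#' @param landmarks a [LandmarkSet] with at least one CV and one PT.
#' @param tissue logical matrix, the tissue mask; must contain at least
#'   one `TRUE` pixel.
#' @param cvMask,ptMask optional logical matrices marking vein / portal
#'   regions; when supplied they replace that class's point landmarks.
#' @return A [ZonationField].
#' @examples
#' lm <- LandmarkSet(x = c(0, 100), y = c(0, 0), class = c("PT", "CV"))
#' fld <- relativeDistanceMap(lm, matrix(TRUE, 1, 101))
#' relDistance(fld)[1, 26]   # pixel x = 25 -> r = 0.25
#' @export
relativeDistanceMap <- function(landmarks, tissue, cvMask = NULL,
                                ptMask = NULL) {
  stopifnot(is(landmarks, "LandmarkSet"))
  validObject(landmarks)
  if (!is.logical(tissue) || !any(tissue))
    stop("'tissue' must be a logical mask with at least one TRUE pixel")
  nr <- nrow(tissue); nc <- ncol(tissue)
  grid <- pixelGrid(nr, nc)
  co <- landmarks@coords
  cls <- landmarks@type

  nearest <- function(idx) {
    d <- matrix(Inf, nr, nc)
    lab <- matrix(0L, nr, nc)
    for (i in seq_along(idx)) {
      k <- idx[i]
      dk <- sqrt((grid$x - co[k, 1L])^2 + (grid$y - co[k, 2L])^2)
      upd <- dk < d
      d[upd] <- dk[upd]
      lab[upd] <- i
    }
    list(d = d, lab = lab)
  }
  # region mode: every mask pixel acts as a landmark of that class;
  # labels index the mask's connected components
  nearestRegion <- function(mask) {
    stopifnot(identical(dim(mask), dim(tissue)), any(mask))
    comp <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
    idx <- which(mask)
    d <- matrix(Inf, nr, nc)
    lab <- matrix(0L, nr, nc)
    for (k in idx) {
      dk <- sqrt((grid$x - grid$x[k])^2 + (grid$y - grid$y[k])^2)
      upd <- dk < d
      d[upd] <- dk[upd]
      lab[upd] <- as.integer(comp[k])
    }
    list(d = d, lab = lab)
  }

  pt <- if (is.null(ptMask)) nearest(which(cls == "PT"))
  else nearestRegion(ptMask)
  cv <- if (is.null(cvMask)) nearest(which(cls == "CV"))
  else nearestRegion(cvMask)
  denom <- pt$d + cv$d
  if (any(denom[tissue] == 0))
    stop("a CV and a PT coincide at a tissue pixel; r = 0/0 undefined")
  r <- pt$d / denom
  dPT <- pt$d; dCV <- cv$d; lob <- cv$lab
  dPT[!tissue] <- NA_real_; dCV[!tissue] <- NA_real_
  r[!tissue] <- NA_real_; lob[!tissue] <- NA_integer_
  new("ZonationField", dPT = dPT, dCV = dCV, r = r, lobule = lob,
      tissue = tissue, landmarks = landmarks)
}

# Bin index on [0,1]: B equal-width half-open bins, last bin closed at 1.
zonationBinIndex <- function(r, B) {
  pmin(floor(r * B) + 1L, B)
}

#' Positive-area fraction along the portal-to-central axis
#'
#' Bins tissue pixels by relative lobular distance into `B` equal-width
#' bins (half-open, last bin closed at 1) and reports the stain-positive
#' fraction per bin. Bins without tissue pixels report `NA`, never 0/0.
#'
#' @param field a [ZonationField] from [relativeDistanceMap()].
#' @param stain logical matrix of stain-positive pixels; must be a subset
#'   of the field's tissue mask.
#' @param B integer number of bins (default 20).
#' @param perLobule if `TRUE`, return a list of per-lobule profiles instead
#'   of the pooled profile.
#' @return A [ZonationProfile] (or a list of them when `perLobule = TRUE`).
#' @export
zonatedPositivity <- function(field, stain, B = 20L, perLobule = FALSE) {
  stopifnot(is(field, "ZonationField"))
  B <- as.integer(B)
  if (B < 2L) stop("'B' must be >= 2")
  if (!is.logical(stain) || !identical(dim(stain), dim(field@tissue)))
    stop("'stain' must be a logical mask matching the field shape")
  if (any(stain & !field@tissue))
    stop("stain pixels outside the tissue mask (mask inconsistency)")
  profileOne <- function(keep) {
    r <- field@r[keep]
    pos <- stain[keep]
    idx <- zonationBinIndex(r, B)
    tis <- tabulate(idx, B)
    ps <- tabulate(idx[pos], B)
    frac <- ifelse(tis > 0, ps / tis, NA_real_)
    new("ZonationProfile", edges = seq(0, 1, length.out = B + 1L),
        tissueCount = as.numeric(tis), positiveCount = as.numeric(ps),
        fraction = frac)
  }
  if (!perLobule) return(profileOne(field@tissue))
  lobs <- sort(unique(field@lobule[field@tissue]))
  out <- lapply(lobs, function(l) profileOne(field@tissue & !is.na(field@lobule) &
                                               field@lobule == l))
  names(out) <- paste0("lobule", lobs)
  out
}

#' Mean relative position of the positive area
#'
#' Area-weighted mean of bin midpoints, weighted by positive pixel counts:
#' a scalar in `[0, 1]` summarizing where along the portal-to-central axis
#' the stain sits (pericentral stains score high, panlobular stains near
#' 0.5).
#'
#' @param profile a [ZonationProfile] with at least one positive pixel.
#' @return Numeric scalar in `[0, 1]`.
#' @export
profileCentroid <- function(profile) {
  stopifnot(is(profile, "ZonationProfile"))
  if (sum(profile@positiveCount) == 0)
    stop("profile has zero positive pixels; centroid undefined")
  mids <- (profile@edges[-1L] + profile@edges[-length(profile@edges)]) / 2
  sum(mids * profile@positiveCount) / sum(profile@positiveCount)
}

#' Zonation profile as a data.frame
#'
#' @param profile a [ZonationProfile].
#' @return data.frame with bin edges, midpoints, counts and fraction.
#' @export
profileAsData <- function(profile) {
  stopifnot(is(profile, "ZonationProfile"))
  e <- profile@edges
  data.frame(binStart = e[-length(e)], binEnd = e[-1L],
             mid = (e[-1L] + e[-length(e)]) / 2,
             tissue = profile@tissueCount, positive = profile@positiveCount,
             fraction = profile@fraction)
}
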