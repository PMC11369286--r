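#' @include AllGenerics.R
NULL

# Central S4 containers. Coordinate convention throughout the package:
# images are matrices indexed [row, col]; a pixel's centre has
# x = col - 1 (rightward), y = row - 1 (downward), origin at the top-left
# pixel, all in pixel units.

#' Landmark set anchoring lobule geometry
#'
#' Typed 2-D points marking central veins (`CV`) and portal triads (`PT`)
#' on a tissue image. Lobule reconstruction needs at least one landmark of
#' each class; a CV and a PT at identical coordinates would make the
#' relative distance 0/0 and is rejected.
#'
#' @slot coords numeric matrix with columns `x`, `y` (pixel units,
#'   origin top-left, x rightward, y downward).
#' @slot class factor with levels `CV`, `PT`, one per row of `coords`.
#' @export
setClass("LandmarkSet",
  representation(coords = "matrix", type = "factor"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
      msg <- c(msg, "'coords' must be a numeric matrix with columns x, y")
    if (length(object@type) != nrow(object@coords))
      msg <- c(msg, "one class per coordinate row required")
    if (!identical(levels(object@type), c("CV", "PT")))
      msg <- c(msg, "class levels must be exactly CV, PT")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "landmark coordinates must be finite")
    for (cl in c("CV", "PT"))
      if (sum(object@type == cl) < 1L)
        msg <- c(msg, paste0("at least one landmark of class ", cl, " required"))
    if (length(msg) == 0L) {
      key <- paste(object@coords[, 1L], object@coords[, 2L])
      if (anyDuplicated(key)) {
        dup <- key[duplicated(key)]
        cls <- split(as.character(object@type), key)
        if (any(vapply(cls[dup], function(x) length(unique(x)) > 1L, logical(1))))
          msg <- c(msg, "CV and PT at identical coordinates (relative distance undefined)")
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a LandmarkSet
#'
#' @param x,y numeric vectors of pixel coordinates (origin top-left,
#'   x rightward, y downward).
#' @param class character or factor, one of `"CV"` (central vein) or
#'   `"PT"` (portal triad) per point.
#' @return A [LandmarkSet].
#' @examples
#' LandmarkSet(x = c(0, 100), y = c(0, 0), class = c("PT", "CV"))
#' @export
LandmarkSet <- function(x, y, class) {
  cl <- factor(as.character(class), levels = c("CV", "PT"))
  if (anyNA(cl))
    stop("landmark class must be 'CV' or 'PT'")
  new("LandmarkSet",
      coords = cbind(x = as.numeric(x), y = as.numeric(y)),
      type = cl)
}

#' @describeIn LandmarkSet-class coordinates as an n x 2 matrix.
#' @param object a `LandmarkSet`.
#' @export
landmarkCoords <- function(object) object@coords

#' @describeIn LandmarkSet-class landmark classes as a factor (`CV`/`PT`).
#' @export
landmarkClass <- function(object) object@type

setMethod("show", "LandmarkSet", function(object) {
  tab <- table(object@type)
  cat("LandmarkSet with", nrow(object@coords), "points:",
      tab[["CV"]], "CV,", tab[["PT"]], "PT\n")
})

#' Per-pixel lobular zonation field
#'
#' Holds, for every tissue pixel, the Euclidean distance to the nearest
#' portal triad (`dPT`) and central vein (`dCV`), the relative lobular
#' distance `r = dPT / (dPT + dCV)` (0 at portal triads, 1 at central
#' veins), and the Voronoi lobule label (index of the nearest CV).
#' Pixels outside the tissue mask carry `NA`.
#'
#' @slot dPT,dCV,r numeric matrices (pixels; r dimensionless in `[0,1]`).
#' @slot lobule integer matrix of nearest-CV indices.
#' @slot tissue logical matrix, the tissue mask.
#' @slot landmarks the [LandmarkSet] the field was computed from.
#' @export
setClass("ZonationField",
  representation(dPT = "matrix", dCV = "matrix", r = "matrix",
                 lobule = "matrix", tissue = "matrix",
                 landmarks = "LandmarkSet"),
  validity = function(object) {
    dims <- vapply(list(object@dPT, object@dCV, object@r, object@lobule,
                        object@tissue), function(m) paste(dim(m), collapse = "x"),
                   character(1))
    if (length(unique(dims)) != 1L)
      return("all field matrices must share one shape")
    rr <- object@r[object@tissue]
    if (any(rr < 0 | rr > 1, na.rm = TRUE))
      return("relative distance outside [0, 1]")
    TRUE
  }
)

setMethod("relDistance", "ZonationField", function(object) object@r)

setMethod("show", "ZonationField", function(object) {
  cat("ZonationField", paste(dim(object@r), collapse = " x "),
      "px,", sum(object@tissue), "tissue pixels,",
      length(unique(object@lobule[object@tissue])), "lobules\n")
})

#' Zonated positivity profile
#'
#' Positive-area fraction binned by relative lobular distance: B
#' equal-width bins on `[0, 1]`, half-open `[e_i, e_{i+1})` with the last
#' bin closed at 1. Bins that contain no tissue pixels report `NA`
#' fraction rather than 0/0.
#'
#' @slot edges numeric vector of B + 1 bin edges.
#' @slot tissueCount,positiveCount numeric per-bin pixel counts.
#' @slot fraction numeric per-bin positive fraction (`NA` for empty bins).
#' @export
setClass("ZonationProfile",
  representation(edges = "numeric", tissueCount = "numeric",
                 positiveCount = "numeric", fraction = "numeric"),
  validity = function(object) {
    B <- length(object@edges) - 1L
    if (B < 2L) return("at least 2 bins required")
    if (length(object@tissueCount) != B || length(object@positiveCount) != B ||
        length(object@fraction) != B)
      return("per-bin vectors must have length(edges) - 1")
    if (any(object@positiveCount > object@tissueCount))
      return("positive count exceeds tissue count in some bin")
    fr <- object@fraction[!is.na(object@fraction)]
    if (any(fr < 0 | fr > 1)) return("fractions outside [0, 1]")
    TRUE
  }
)

setMethod("positiveFraction", "ZonationProfile", function(object) object@fraction)
setMethod("binEdges", "ZonationProfile", function(object) object@edges)

setMethod("show", "ZonationProfile", function(object) {
  B <- length(object@edges) - 1L
  cat("ZonationProfile with", B, "bins;",
      sum(object@tissueCount), "tissue px,",
      sum(object@positiveCount), "positive px\n")
})

#' k-prototypes cluster model for mixed marker tables
#'
#' Result of Huang-style alternating optimization on standardized numeric
#' columns plus categorical columns, with cost
#' \deqn{\sum_j (x_j - \mu_j)^2 + \gamma \sum_c 1[x_c \ne mode_c].}
#'
#' @slot k integer cluster count.
#' @slot gamma numeric categorical mismatch weight.
#' @slot centers numeric matrix (k x numeric columns) of prototypes in the
#'   standardized space.
#' @slot modes data.frame (k rows) of categorical prototype modes.
#' @slot cluster integer assignments, one per specimen.
#' @slot cost numeric final total cost.
#' @slot costTrace numeric per-iteration cost of the winning restart.
#' @slot iterations integer iteration count of the winning restart.
#' @slot seed integer seed used.
#' @slot numericCols,categoricalCols character column names used.
#' @slot center,scale numeric standardization parameters per numeric column.
#' @export
setClass("KPrototypesModel",
  representation(k = "integer", gamma = "numeric", centers = "matrix",
                 modes = "data.frame", cluster = "integer", cost = "numeric",
                 costTrace = "numeric", iterations = "integer", seed = "integer",
                 numericCols = "character", categoricalCols = "character",
                 center = "numeric", scale = "numeric"),
  validity = function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (any(object@cluster < 1L | object@cluster > object@k))
      return("assignments outside 1..k")
    if (any(diff(object@costTrace) > 1e-8))
      return("cost increased between iterations")
    TRUE
  }
)

setMethod("assignments", "KPrototypesModel", function(object) object@cluster)
setMethod("nClusters", "KPrototypesModel", function(object) object@k)

setMethod("show", "KPrototypesModel", function(object) {
  cat("KPrototypesModel: k =", object@k, ", gamma =", format(object@gamma),
      "\n  n =", length(object@cluster),
      "; sizes:", paste(tabulate(object@cluster, object@k), collapse = "/"),
      "\n  cost =", format(object@cost),
      "after", object@iterations, "iterations\n")
})

#' Gaussian mixture model over gene-set scores
#'
#' Full-covariance mixture fitted by EM; component count selected by
#' minimum BIC = -2 logL + p ln(n) with
#' p = (k - 1) + k d + k d(d+1)/2. Components may carry ferroptosis
#' phenotype labels (`red`/`green`/`gray`) after [assignPhenotypeLabels()].
#'
#' @slot k integer component count.
#' @slot means numeric matrix (k x d) of component means (standardized space).
#' @slot covariances numeric array (d x d x k).
#' @slot weights numeric mixing weights summing to 1.
#' @slot responsibilities numeric matrix (n x k), rows summing to 1.
#' @slot cluster integer hard assignments (argmax responsibility).
#' @slot logLik,bic numeric fit statistics at the selected k.
#' @slot bicTable data.frame of k vs BIC over the searched range.
#' @slot labels character per-component phenotype labels (`NA` before labeling).
#' @slot scoreNames character names of the score dimensions.
#' @slot seed integer seed used.
#' @export
setClass("GaussianMixtureModel",
  representation(k = "integer", means = "matrix", covariances = "array",
                 weights = "numeric", responsibilities = "matrix",
                 cluster = "integer", logLik = "numeric", bic = "numeric",
                 bicTable = "data.frame", labels = "character",
                 scoreNames = "character", seed = "integer"),
  validity = function(object) {
    if (abs(sum(object@weights) - 1) > 1e-8)
      return("mixing weights must sum to 1")
    rs <- rowSums(object@responsibilities)
    if (any(abs(rs - 1) > 1e-8))
      return("responsibility rows must sum to 1")
    if (length(object@labels) != object@k)
      return("one phenotype label (or NA) per component required")
    TRUE
  }
)

setMethod("assignments", "GaussianMixtureModel", function(object) object@cluster)
setMethod("nClusters", "GaussianMixtureModel", function(object) object@k)
setMethod("phenotypeLabels", "GaussianMixtureModel", function(object) object@labels)

setMethod("show", "GaussianMixtureModel", function(object) {
  cat("GaussianMixtureModel: k =", object@k,
      "| logLik =", format(object@logLik), "| BIC =", format(object@bic), "\n")
  lab <- if (all(is.na(object@labels))) "(unlabeled)" else
    paste(object@labels, collapse = "/")
  cat("  components:", paste(tabulate(object@cluster, object@k), collapse = "/"),
      "samples;", lab, "\n")
})
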