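#' Cluster assignments of a fitted model
#'
#' @param object a fitted [KPrototypesModel] or [GaussianMixtureModel].
#' @return Integer vector of 1-based cluster indices, one per observation.
#' @export
setGeneric("assignments", function(object) standardGeneric("assignments"))

#' Number of clusters/components of a fitted model
#'
#' @param object a fitted [KPrototypesModel] or [GaussianMixtureModel].
#' @return Integer scalar.
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' Phenotype labels attached to mixture components
#'
#' @param object a [GaussianMixtureModel] after [assignPhenotypeLabels()].
#' @return Character vector, one label per component, or per-component `NA`
#'   if labels have not been assigned yet.
#' @export
setGeneric("phenotypeLabels", function(object) standardGeneric("phenotypeLabels"))

#' Positive-area fraction per zonation bin
#'
#' @param object a [ZonationProfile].
#' @return Numeric vector of per-bin positive fractions (`NA` for bins with
#'   no tissue pixels).
#' @export
setGeneric("positiveFraction", function(object) standardGeneric("positiveFraction"))

#' Bin edges of a zonation profile
#'
#' @param object a [ZonationProfile].
#' @return Numeric vector of length `nBins + 1` on `[0, 1]`.
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' Relative lobular distance map
#'
#' @param object a [ZonationField].
#' @return Numeric matrix of per-pixel relative distances r in `[0, 1]`
#'   (`NA` outside tissue).
#' @export
setGeneric("relDistance", function(object) standardGeneric("relDistance"))
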