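# Versioned worked-example fixtures from the stratified biopsy cohort
# (n = 27): histology-by-cluster and iron-by-cluster counts, and the
# public transcriptomic cohort sizes. Counts only are stored;
# percentages and test statistics are always recomputed. Note: the
# source table's printed percentages for sevenths are pair-rounded so
# complementary rows sum to 100 (e.g. 57.2/42.8 where plain 1-decimal
# rounding of 4/7 and 3/7 gives 57.1/42.9); recomputation from counts is
# authoritative here.

#' Worked-example cohort fixture
#'
#' Cluster-by-histology and cluster-by-iron counts of the 27-specimen
#' biopsy cohort (clusters of size 7, 10 and 10 over 5 controls, 8 MASL,
#' 7 MASH F0-1 and 7 MASH F2-3), plus the sizes of the three public
#' transcriptomic cohorts. Loaded from versioned CSV fixtures and
#' validated against every printed marginal.
#'
#' @return list with `histology` (4 x 3 count matrix), `iron` (2 x 3
#'   count matrix), `clusterSizes` and `cohortSizes`.
#' @export
table1Fixture <- function() {
  readCounts <- function(file) {
    df <- utils::read.csv(system.file("extdata", file, package = "ferroStrat",
                                      mustWork = TRUE), check.names = FALSE)
    m <- as.matrix(df[, -1L])
    rownames(m) <- df[[1L]]
    storage.mode(m) <- "integer"
    m
  }
  hist <- readCounts("table1_histology.csv")
  iron <- readCounts("table1_iron.csv")
  sizes <- utils::read.csv(system.file("extdata", "cohort_sizes.csv",
                                       package = "ferroStrat", mustWork = TRUE))
  cohorts <- stats::setNames(sizes$n, sizes$dataset)
  # reconcile against every printed marginal simultaneously; a failure
  # here is a packaging bug, not a statistics bug
  stopifnot(identical(unname(as.integer(colSums(hist))), c(7L, 10L, 10L)),
            identical(unname(as.integer(rowSums(hist))), c(5L, 8L, 7L, 7L)),
            identical(unname(as.integer(colSums(iron))), c(7L, 10L, 10L)),
            sum(hist) == 27L)
  list(histology = hist, iron = iron,
       clusterSizes = colSums(hist), cohortSizes = cohorts)
}

#' Recompute cohort-table statistics from the fixture counts
#'
#' Exact Fisher r x c p-values for the iron and histology contingencies
#' (via [fisherExactRxC()]), histology percentages within each histologic
#' group (100 * count / group size, rounded to 1 decimal), and the
#' combined transcriptomic cohort size.
#'
#' @param fixture output of [table1Fixture()].
#' @return list with `ironFisherP`, `histologyFisherP`, `histologyPct`
#'   (4 x 3 matrix) and `combinedCohortN`.
#' @export
recomputeTable1Stats <- function(fixture = table1Fixture()) {
  pct <- round(100 * sweep(fixture$histology, 1L, rowSums(fixture$histology),
                           "/"), 1L)
  list(ironFisherP = as.numeric(fisherExactRxC(fixture$iron)),
       histologyFisherP = as.numeric(fisherExactRxC(fixture$histology)),
       histologyPct = pct,
       combinedCohortN = sum(fixture$cohortSizes))
}
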