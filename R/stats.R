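# Cohort statistics: exact Fisher r x c, Kruskal-Wallis with Dunn's
# post-hoc, Benjamini-Hochberg adjustment.

# All non-negative integer r x c tables with the margins of `tab`,
# visited row by row; `fun(table)` is called on each.
enumerateTables <- function(rowSums, colSums, fun) {
  r <- length(rowSums)
  c <- length(colSums)
  cur <- matrix(0L, r, c)
  recurseRow <- function(i, colLeft) {
    if (i == r) {
      if (all(colLeft >= 0L) && sum(colLeft) == rowSums[r]) {
        cur[r, ] <<- colLeft
        fun(cur)
      }
      return(invisible())
    }
    fillCell <- function(j, left, colLeft) {
      if (j == c) {
        if (left <= colLeft[c]) {
          cur[i, c] <<- left
          recurseRow(i + 1L, colLeft - cur[i, ])
        }
        return(invisible())
      }
      for (v in 0:min(left, colLeft[j])) {
        cur[i, j] <<- v
        fillCell(j + 1L, left - v, colLeft)
      }
    }
    fillCell(1L, rowSums[i], colLeft)
  }
  recurseRow(1L, as.integer(colSums))
  invisible()
}

logTableProb <- function(tab, rs, cs, N) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1) -
    sum(lgamma(tab + 1))
}

#' Exact Fisher test for an r x c contingency table
#'
#' Freeman-Halton two-sided exact test by exhaustive enumeration over all
#' tables with the observed margins: the p-value is the total
#' hypergeometric probability of tables no more probable than the
#' observed one (a relative tolerance of `tol` guards the comparison
#' against floating-point noise).
#'
#' @param tab matrix of non-negative integer counts, at least 2 x 2.
#' @param tol relative tolerance on the probability comparison.
#' @return The two-sided exact p-value, with attributes `tables` (number
#'   of tables enumerated) and `probTotal` (their total probability,
#'   equal to 1 up to rounding).
#' @examples
#' fisherExactRxC(rbind(c(1, 7, 1), c(6, 3, 9)))   # ~0.014
#' @export
fisherExactRxC <- function(tab, tol = 1e-7) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("table must be at least 2 x 2")
  N <- sum(tab)
  if (N == 0) stop("total count is zero")
  rs <- rowSums(tab); cs <- colSums(tab)
  logPObs <- logTableProb(tab, rs, cs, N)
  p <- 0; total <- 0; ntab <- 0L
  enumerateTables(rs, cs, function(t) {
    lp <- logTableProb(t, rs, cs, N)
    total <<- total + exp(lp)
    ntab <<- ntab + 1L
    if (lp <= logPObs + log1p(tol)) p <<- p + exp(lp)
  })
  structure(min(p, 1), tables = ntab, probTotal = total)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' adjusted p_(i) = min over j >= i of m p_(j) / j, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference
#' (df = groups - 1), followed by Dunn's pairwise z-tests on pooled
#' mid-ranks with tie correction; pairwise p-values are two-sided and
#' Benjamini-Hochberg-adjusted across the pairs.
#'
#' @param values numeric observations.
#' @param groups factor (or coercible) of group labels, at least 2 groups
#'   with at least 1 observation each.
#' @return list with `H`, `p` and a data.frame `dunn` of pairwise
#'   comparisons (`group1`, `group2`, `z`, `p`, `pAdj`).
#' @export
kruskalWallisDunn <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  g <- nlevels(groups)
  if (g < 2L) stop("at least 2 groups required")
  stopifnot(length(values) == length(groups))
  N <- length(values)
  pairs <- utils::combn(levels(groups), 2L)
  if (length(unique(values)) == 1L) {
    dunn <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                       z = 0, p = 1, pAdj = 1)
    return(list(H = 0, p = 1, dunn = dunn))
  }
  kw <- stats::kruskal.test(values, groups)
  rk <- rank(values)
  tie <- base::table(values)
  Tcorr <- sum(tie^3 - tie) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - Tcorr
  rbar <- tapply(rk, groups, mean)
  ns <- base::table(groups)
  z <- apply(pairs, 2L, function(pr) {
    (rbar[[pr[1L]]] - rbar[[pr[2L]]]) /
      sqrt(sigma2 * (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
  })
  pw <- 2 * stats::pnorm(-abs(z))
  dunn <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                     z = z, p = pw, pAdj = bhAdjust(pw))
  list(H = unname(kw$statistic), p = kw$p.value, dunn = dunn)
}
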