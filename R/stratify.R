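# Mixed-type clustering of the marker table and cluster characterization.

# Mixed k-prototypes cost of every row against every prototype:
# squared Euclidean on standardized numerics + gamma * categorical
# mismatch count.
kprotoCost <- function(num, cat, centers, modes, gamma) {
  n <- nrow(num); k <- nrow(centers)
  cost <- matrix(0, n, k)
  for (j in seq_len(k)) {
    cn <- if (ncol(num)) rowSums(sweep(num, 2L, centers[j, ], "-")^2) else 0
    cc <- 0
    if (length(modes) && ncol(cat))
      cc <- rowSums(cat != matrix(unlist(modes[j, , drop = FALSE]),
                                  n, ncol(cat), byrow = TRUE))
    cost[, j] <- cn + gamma * cc
  }
  cost
}

canonicalizeLabels <- function(cl) {
  match(cl, unique(cl))
}

#' k-prototypes clustering of a mixed marker table
#'
#' Huang-style alternating optimization for mixed numeric/categorical
#' data: numeric columns are standardized to zero mean and unit SD, the
#' per-row cost against a prototype is
#' \deqn{\sum_j (x_j - \mu_j)^2 + \gamma \sum_c 1[x_c \ne mode_c],}
#' and means/modes are refit until assignments stabilize. The best of
#' `nInit` seeded random initializations (by final cost; ties broken by
#' the lexicographically smallest assignment vector) is returned, with
#' clusters renumbered by order of first appearance.
#'
#' Missing numeric values are median-imputed with a warning; constant
#' numeric columns are dropped with a warning (their standardization is
#' undefined). Identifier and histology columns are never used as
#' features.
#'
#' @param table data.frame with numeric marker columns and optional
#'   factor/character columns (e.g. the iron stain).
#' @param k number of clusters (default 3; must not exceed the number of
#'   specimens).
#' @param gamma categorical mismatch weight; default 0.5, i.e. half the
#'   mean SD of the standardized numeric columns (Huang's heuristic).
#' @param nInit number of random initializations (default 50).
#' @param maxIter maximum alternating iterations per initialization.
#' @param seed integer RNG seed.
#' @param exclude column names never used as features (default the
#'   specimen identifier and histology metadata).
#' @return A [KPrototypesModel].
#' @export
kPrototypes <- function(table, k = 3L, gamma = NULL, nInit = 50L,
                        maxIter = 100L, seed = 1L,
                        exclude = c("specimen", "histology")) {
  stopifnot(is.data.frame(table))
  k <- as.integer(k)
  n <- nrow(table)
  if (k > n) stop("k exceeds the number of specimens (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  feats <- setdiff(names(table), exclude)
  numCols <- feats[vapply(table[feats], is.numeric, logical(1))]
  catCols <- feats[vapply(table[feats], function(x)
    is.factor(x) || is.character(x), logical(1))]

  num <- as.matrix(table[numCols])
  if (anyNA(num)) {
    warning("missing numeric marker values median-imputed")
    for (j in seq_len(ncol(num))) {
      miss <- is.na(num[, j])
      num[miss, j] <- stats::median(num[, j], na.rm = TRUE)
    }
  }
  sds <- apply(num, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("constant numeric column(s) dropped: ",
            paste(numCols[sds == 0], collapse = ", "))
    num <- num[, sds > 0, drop = FALSE]
    numCols <- numCols[sds > 0]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(num)
  num <- scale(num, center = ctr, scale = sds)
  cat <- as.matrix(as.data.frame(lapply(table[catCols], as.character),
                                 stringsAsFactors = FALSE))
  if (length(catCols) == 0L) cat <- matrix(character(), n, 0L)
  if (is.null(gamma)) gamma <- 0.5

  runOne <- function() {
    init <- sample(n, k)
    centers <- num[init, , drop = FALSE]
    modes <- as.data.frame(cat[init, , drop = FALSE],
                           stringsAsFactors = FALSE)
    assign <- integer(n)
    trace <- numeric(0)
    for (it in seq_len(maxIter)) {
      cost <- kprotoCost(num, cat, centers, modes, gamma)
      newAssign <- max.col(-cost, ties.method = "first")
      rowCost <- cost[cbind(seq_len(n), newAssign)]
      # an emptied cluster captures the worst-fitting point (cost cannot rise)
      for (j in seq_len(k)) {
        if (!any(newAssign == j)) {
          worst <- which.max(rowCost)
          newAssign[worst] <- j
          rowCost[worst] <- 0
          centers[j, ] <- num[worst, ]
          if (ncol(cat)) modes[j, ] <- cat[worst, , drop = FALSE]
        }
      }
      for (j in seq_len(k)) {
        rows <- newAssign == j
        if (ncol(num))
          centers[j, ] <- colMeans(num[rows, , drop = FALSE])
        if (ncol(cat))
          modes[j, ] <- lapply(seq_len(ncol(cat)),
                               function(c) statMode(cat[rows, c]))
      }
      cost <- kprotoCost(num, cat, centers, modes, gamma)
      trace <- c(trace, sum(cost[cbind(seq_len(n), newAssign)]))
      if (identical(newAssign, assign)) { assign <- newAssign; break }
      assign <- newAssign
    }
    list(assign = assign, centers = centers, modes = modes,
         cost = trace[length(trace)], trace = trace, iter = length(trace))
  }

  withSeed(seed, {
    best <- NULL
    for (i in seq_len(nInit)) {
      cand <- runOne()
      cand$assign <- canonicalizeLabels(cand$assign)
      take <- is.null(best) || cand$cost < best$cost - 1e-12 ||
        (abs(cand$cost - best$cost) <= 1e-12 &&
           paste(cand$assign, collapse = ",") <
             paste(best$assign, collapse = ","))
      if (take) best <- cand
    }
    # prototypes consistent with the canonical labeling
    ord <- vapply(seq_len(k), function(j) which(best$assign == j)[1L],
                  integer(1))
    centers <- num[ord, , drop = FALSE] * 0
    modes <- as.data.frame(cat[ord, , drop = FALSE], stringsAsFactors = FALSE)
    for (j in seq_len(k)) {
      rows <- best$assign == j
      if (ncol(num)) centers[j, ] <- colMeans(num[rows, , drop = FALSE])
      if (ncol(cat))
        modes[j, ] <- lapply(seq_len(ncol(cat)),
                             function(c) statMode(cat[rows, c]))
    }
    rownames(centers) <- NULL
    colnames(centers) <- numCols
    if (ncol(cat)) names(modes) <- catCols
    new("KPrototypesModel", k = k, gamma = gamma, centers = centers,
        modes = modes, cluster = as.integer(best$assign),
        cost = best$cost, costTrace = best$trace,
        iterations = as.integer(best$iter), seed = as.integer(seed),
        numericCols = numCols, categoricalCols = catCols,
        center = ctr, scale = sds)
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' observations; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b integer/factor label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sumnij <- sum(choose(tab, 2))
  sumai <- sum(choose(rowSums(tab), 2))
  sumbj <- sum(choose(colSums(tab), 2))
  expected <- sumai * sumbj / choose(length(a), 2)
  maxi <- (sumai + sumbj) / 2
  if (maxi == expected) return(1)
  (sumnij - expected) / (maxi - expected)
}

#' Mean silhouette width over a range of k
#'
#' Companion report for choosing the cluster count: for each k, fits
#' [kPrototypes()] and computes the mean silhouette width under the same
#' mixed dissimilarity the clustering optimizes.
#'
#' @param table marker table as for [kPrototypes()].
#' @param kRange integer vector of candidate cluster counts (all >= 2).
#' @param ... passed to [kPrototypes()].
#' @return data.frame with columns `k` and `meanSilhouette`.
#' @export
silhouetteReport <- function(table, kRange = 2:6, ...) {
  stopifnot(all(kRange >= 2L))
  res <- vapply(kRange, function(k) {
    fit <- kPrototypes(table, k = k, ...)
    num <- scale(as.matrix(table[fit@numericCols]),
                 center = fit@center, scale = fit@scale)
    cat <- as.matrix(as.data.frame(lapply(table[fit@categoricalCols],
                                          as.character)))
    n <- nrow(num)
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      dn <- rowSums(sweep(num, 2L, num[i, ], "-")^2)
      dc <- if (length(fit@categoricalCols))
        rowSums(cat != matrix(cat[i, ], n, ncol(cat), byrow = TRUE)) else 0
      d[i, ] <- dn + fit@gamma * dc
    }
    cl <- fit@cluster
    s <- vapply(seq_len(n), function(i) {
      own <- cl[i]
      if (sum(cl == own) == 1L) return(0)
      a <- mean(d[i, cl == own & seq_len(n) != i])
      b <- min(vapply(setdiff(seq_len(fit@k), own),
                      function(j) mean(d[i, cl == j]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }, numeric(1))
  data.frame(k = as.integer(kRange), meanSilhouette = res)
}

#' Characterize clusters in the style of a cohort table
#'
#' Per cluster: n, count (%) per histology group and per categorical
#' marker level, and median (IQR) per numeric covariate; p-values from
#' Kruskal-Wallis (numeric) or the exact Fisher r x c test (categorical),
#' with a Benjamini-Hochberg-adjusted column over the covariate family.
#'
#' @param model a fitted [KPrototypesModel].
#' @param table the marker table the model was fitted on (may carry extra
#'   numeric covariates and a `histology` column).
#' @param covariates optional character vector restricting which columns
#'   are characterized; default: histology, all categorical features and
#'   all numeric columns except the specimen identifier.
#' @return data.frame with one row per characteristic (and level), the
#'   per-cluster summaries as strings, and columns `p` and `pAdj`.
#' @export
characterizeClusters <- function(model, table, covariates = NULL) {
  stopifnot(is(model, "KPrototypesModel"), nrow(table) == length(model@cluster))
  cl <- model@cluster
  k <- model@k
  if (is.null(covariates)) {
    covariates <- setdiff(names(table), "specimen")
  }
  rows <- list()
  pvals <- c()
  for (cov in covariates) {
    x <- table[[cov]]
    if (is.numeric(x)) {
      p <- kruskalWallisDunn(x, factor(cl))$p
      cells <- vapply(seq_len(k), function(j) {
        v <- x[cl == j]
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
      }, character(1))
      rows[[length(rows) + 1L]] <-
        data.frame(characteristic = cov, level = "median (IQR)",
                   t(matrix(cells, dimnames = list(paste0("cluster", seq_len(k))))),
                   p = p)
      pvals <- c(pvals, p)
    } else {
      tab <- base::table(factor(x), factor(cl, levels = seq_len(k)))
      p <- fisherExactRxC(unclass(tab))
      for (lev in rownames(tab)) {
        cells <- vapply(seq_len(k), function(j) {
          nj <- sum(cl == j)
          sprintf("%d (%.1f)", tab[lev, j], 100 * tab[lev, j] / nj)
        }, character(1))
        rows[[length(rows) + 1L]] <-
          data.frame(characteristic = cov, level = lev,
                     t(matrix(cells, dimnames = list(paste0("cluster", seq_len(k))))),
                     p = if (lev == rownames(tab)[1L]) as.numeric(p) else NA_real_)
      }
      pvals <- c(pvals, as.numeric(p))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  adj <- bhAdjust(pvals)
  out$pAdj <- NA_real_
  out$pAdj[!is.na(out$p)] <- adj
  out
}
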