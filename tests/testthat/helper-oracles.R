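# Independent oracles and small fixture builders, kept deliberately
# naive: exhaustive loops and closed forms, never the package's own
# vectorized paths.

# Exhaustive per-pixel, per-landmark zonation field (double loop).
bruteZonationField <- function(landmarks, tissue) {
  co <- landmarkCoords(landmarks)
  cls <- as.character(landmarkClass(landmarks))
  nr <- nrow(tissue); nc <- ncol(tissue)
  dPT <- dCV <- r <- matrix(NA_real_, nr, nc)
  lob <- matrix(NA_integer_, nr, nc)
  cvIdx <- which(cls == "CV")
  ptIdx <- which(cls == "PT")
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!tissue[i, j]) next
    x <- j - 1; y <- i - 1
    dpt <- Inf; dcv <- Inf; lb <- NA_integer_
    for (k in seq_along(ptIdx)) {
      d <- sqrt((x - co[ptIdx[k], 1])^2 + (y - co[ptIdx[k], 2])^2)
      if (d < dpt) dpt <- d
    }
    for (k in seq_along(cvIdx)) {
      d <- sqrt((x - co[cvIdx[k], 1])^2 + (y - co[cvIdx[k], 2])^2)
      if (d < dcv) { dcv <- d; lb <- k }
    }
    dPT[i, j] <- dpt; dCV[i, j] <- dcv
    r[i, j] <- dpt / (dpt + dcv); lob[i, j] <- lb
  }
  list(dPT = dPT, dCV = dCV, r = r, lobule = lob)
}

# Best k=2 partition of numeric rows by exhaustive enumeration of all
# assignments; returns minimal within-cluster sum of squares and one
# optimal assignment (canonical labels).
bruteKmeans2 <- function(x) {
  n <- nrow(x)
  best <- list(cost = Inf, assign = NULL)
  for (code in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster 1
    a <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    cost <- 0
    for (j in 1:2) {
      rows <- x[a == j, , drop = FALSE]
      if (nrow(rows) == 0L) { cost <- Inf; break }
      cost <- cost + sum(sweep(rows, 2L, colMeans(rows), "-")^2)
    }
    if (cost < best$cost) best <- list(cost = cost, assign = a)
  }
  best
}

# Direct step-up Benjamini-Hochberg evaluation.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * p[o[i]] / i)
    adj[o[i]] <- min(run, 1)
  }
  adj
}

# Two-sided 2x2 Fisher p by summing hypergeometric point probabilities
# no larger than the observed one.
fisher2x2Oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(x, m, n, k) * (1 + 1e-7)])
}

# Filled disk on a matrix (same pixel-centre convention as the package).
diskMatrix <- function(size, cx, cy, r, base = NULL, value = 1) {
  m <- if (is.null(base)) matrix(0, size, size) else base
  xs <- matrix(rep(seq_len(size) - 1, each = size), size, size)
  ys <- matrix(rep(seq_len(size) - 1, times = size), size, size)
  m[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- value
  m
}
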