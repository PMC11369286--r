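# Single-sample gene-set scoring (rank-based Kolmogorov random walk over
# kernel-CDF expression statistics) and latent subgroup discovery by
# Gaussian-mixture EM with BIC selection.

#' Read a GMT gene-set file
#'
#' @param path path to a tab-delimited GMT file (set name, description,
#'   member genes).
#' @return named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
writeGmt <- function(sets, path, description = "") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

#' Single-sample gene-set variation scores
#'
#' For each gene, a kernel-CDF expression statistic across samples
#' (Gaussian kernel, bandwidth = per-gene SD / 4) locates each sample in
#' the gene's expression distribution. Statistics are rank-normalized per
#' sample to symmetric rank scores, and each set/sample pair is scored by
#' a weighted Kolmogorov-Smirnov random walk down the sample's gene
#' ranking with weight |rank score|^tau. The default `"maxdiff"`
#' statistic sums the maximum positive and maximum negative deviations of
#' the walk (bounded in (-1, 1)); `"twosided"` takes the deviation of
#' largest magnitude. Higher scores mean higher expression of the set's
#' genes in that sample.
#'
#' @param expr numeric matrix, genes x samples, log-scale expression with
#'   gene symbols as rownames; at least 3 samples recommended (fewer is
#'   allowed with a warning: the kernel CDF then carries little
#'   information).
#' @param geneSets named list of gene-symbol vectors; a set with no
#'   matching gene is an error naming the unmatched symbols, partially
#'   matched symbols are dropped with a warning.
#' @param tau tail-weight exponent (default 1).
#' @param statistic `"maxdiff"` (default) or `"twosided"`.
#' @return samples x sets numeric score matrix with attributes `tau` and
#'   `statistic`.
#' @export
gsvaScores <- function(expr, geneSets, tau = 1,
                       statistic = c("maxdiff", "twosided")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (any(lengths(geneSets) == 0L)) stop("empty gene set")
  n <- ncol(expr); p <- nrow(expr)
  if (n < 3L)
    warning("fewer than 3 samples: kernel CDF statistics are degenerate")
  matched <- lapply(names(geneSets), function(nm) {
    hit <- geneSets[[nm]] %in% rownames(expr)
    if (!any(hit))
      stop("gene set '", nm, "' has no genes in the matrix; unmatched: ",
           paste(geneSets[[nm]], collapse = ", "))
    if (!all(hit))
      warning("gene set '", nm, "': dropped unmatched symbols ",
              paste(geneSets[[nm]][!hit], collapse = ", "))
    match(geneSets[[nm]][hit], rownames(expr))
  })
  names(matched) <- names(geneSets)

  # kernel-CDF statistic per gene across samples; constant rows score 0
  z <- matrix(0, p, n)
  for (i in seq_len(p)) {
    x <- expr[i, ]
    h <- stats::sd(x) / 4
    if (is.na(h) || h == 0) next
    z[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }

  scores <- matrix(0, n, length(geneSets),
                   dimnames = list(colnames(expr), names(geneSets)))
  for (j in seq_len(n)) {
    rnk <- rank(z[, j], ties.method = "average")
    s <- rnk - (p + 1) / 2
    ord <- order(z[, j], decreasing = TRUE)
    w <- abs(s[ord])^tau
    for (t in seq_along(matched)) {
      inSet <- ord %in% matched[[t]]
      m <- sum(inSet)
      sumw <- sum(w[inSet])
      stepIn <- if (sumw > 0) w / sumw else rep(1 / m, p)
      step <- ifelse(inSet, stepIn, -1 / (p - m))
      nu <- cumsum(step)
      scores[j, t] <- if (statistic == "maxdiff")
        max(0, max(nu)) + min(0, min(nu))
      else nu[which.max(abs(nu))]
    }
  }
  structure(scores, tau = tau, statistic = statistic)
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log density of rows of x under N(mu, sigma); sigma via Cholesky.
mvnLogDensity <- function(x, mu, sigma) {
  R <- chol(sigma)
  d <- ncol(x)
  xc <- sweep(x, 2L, mu, "-")
  sol <- backsolve(R, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(sol^2)
}

emFit <- function(x, k, maxIter, tol, ridge) {
  n <- nrow(x); d <- ncol(x)
  mu <- x[sample(n, k), , drop = FALSE]
  sigma <- array(0, c(d, d, k))
  base <- stats::cov(x) + diag(ridge, d)
  for (j in seq_len(k)) sigma[, , j] <- base
  w <- rep(1 / k, k)
  prevLL <- -Inf
  resp <- matrix(0, n, k)
  for (it in seq_len(maxIter)) {
    logd <- vapply(seq_len(k), function(j)
      log(w[j]) + mvnLogDensity(x, mu[j, ], sigma[, , j]), numeric(n))
    logd <- matrix(logd, n, k)
    norm <- apply(logd, 1L, logSumExp)
    ll <- sum(norm)
    if (ll < prevLL - 1e-6)
      stop("EM log-likelihood decreased")   # invariant; never expected
    resp <- exp(logd - norm)
    if (is.finite(prevLL) && ll - prevLL < tol) { prevLL <- ll; break }
    prevLL <- ll
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("empty component")
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * x) / nk[j]
      xc <- sweep(x, 2L, mu[j, ], "-")
      sigma[, , j] <- crossprod(xc * sqrt(resp[, j])) / nk[j] + diag(ridge, d)
    }
  }
  list(mu = mu, sigma = sigma, w = w, resp = resp, logLik = prevLL)
}

#' Fit a Gaussian mixture to gene-set scores with BIC selection
#'
#' Full-covariance EM (covariance ridge `ridge` on the diagonal), best of
#' `nInit` seeded restarts per component count, component count selected
#' by minimum BIC = -2 logL + p ln(n) with
#' p = (k - 1) + k d + k d(d+1)/2. Score columns are standardized before
#' fitting. Restarts whose covariance turns singular despite the ridge
#' are discarded; if every restart for some k fails, fitting errors.
#'
#' @param scores samples x sets numeric matrix (e.g. from
#'   [gsvaScores()]).
#' @param kRange candidate component counts (default 1:5); requires
#'   `nrow(scores) > max(kRange) * 5`.
#' @param nInit random restarts per k.
#' @param maxIter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param ridge covariance regularization added to the diagonal.
#' @param seed integer RNG seed.
#' @return A [GaussianMixtureModel].
#' @export
fitGmm <- function(scores, kRange = 1:5, nInit = 10L, maxIter = 200L,
                   tol = 1e-6, ridge = 1e-6, seed = 1L) {
  x <- as.matrix(scores)
  n <- nrow(x); d <- ncol(x)
  if (n <= max(kRange) * 5L)
    stop("need more than max(kRange) * 5 samples (have ", n, ")")
  x <- scale(x)
  withSeed(seed, {
    bicTab <- data.frame(k = integer(), bic = numeric(), logLik = numeric())
    best <- NULL
    for (k in sort(unique(as.integer(kRange)))) {
      fits <- list()
      for (i in seq_len(nInit)) {
        f <- tryCatch(emFit(x, k, maxIter, tol, ridge),
                      error = function(e) NULL)
        if (!is.null(f)) fits[[length(fits) + 1L]] <- f
      }
      if (length(fits) == 0L)
        stop("all EM restarts failed for k = ", k)
      ll <- vapply(fits, `[[`, numeric(1), "logLik")
      f <- fits[[which.max(ll)]]
      npar <- (k - 1) + k * d + k * d * (d + 1) / 2
      bic <- -2 * f$logLik + npar * log(n)
      bicTab <- rbind(bicTab,
                      data.frame(k = k, bic = bic, logLik = f$logLik))
      if (is.null(best) || bic < best$bic)
        best <- list(k = k, bic = bic, fit = f)
    }
    f <- best$fit
    new("GaussianMixtureModel", k = as.integer(best$k), means = f$mu,
        covariances = f$sigma, weights = f$w, responsibilities = f$resp,
        cluster = as.integer(max.col(f$resp, ties.method = "first")),
        logLik = f$logLik, bic = best$bic, bicTable = bicTab,
        labels = rep(NA_character_, best$k),
        scoreNames = if (is.null(colnames(scores)))
          paste0("score", seq_len(d)) else colnames(scores),
        seed = as.integer(seed))
  })
}

#' Label mixture components by ferroptosis phenotype
#'
#' The `red` component maximizes mean(PUFA) + mean(Iron) -
#' mean(defenses) - mean(GSH) (ferroptosis-sensitizing PUFA/iron drive
#' with lowered defenses); among the remaining components, `green`
#' maximizes mean(defenses); all others are `gray`. A single-component
#' model is labeled `gray`. Ties break deterministically toward the lower
#' component index; models whose component means are all equal are
#' labeled by tie-break and flagged with a warning as uninformative.
#'
#' @param model a fitted [GaussianMixtureModel] whose score names include
#'   `defenses`, `GSH`, `PUFA` and `Iron`.
#' @return The model with phenotype labels filled in.
#' @export
assignPhenotypeLabels <- function(model) {
  stopifnot(is(model, "GaussianMixtureModel"))
  if (model@k == 1L) { model@labels <- "gray"; return(model) }
  need <- c("defenses", "GSH", "PUFA", "Iron")
  if (!all(need %in% model@scoreNames))
    stop("score names must include: ", paste(need, collapse = ", "))
  m <- model@means[, match(need, model@scoreNames), drop = FALSE]
  colnames(m) <- need
  if (all(abs(sweep(m, 2L, m[1L, ], "-")) < 1e-12))
    warning("all component means equal; phenotype labels are uninformative")
  redScore <- m[, "PUFA"] + m[, "Iron"] - m[, "defenses"] - m[, "GSH"]
  labels <- rep("gray", model@k)
  red <- which.max(redScore)
  labels[red] <- "red"
  rest <- setdiff(seq_len(model@k), red)
  labels[rest[which.max(m[rest, "defenses"])]] <- "green"
  model@labels <- labels
  model
}

#' Distribution of histology groups across phenotype labels
#'
#' @param model a labeled [GaussianMixtureModel].
#' @param metadata factor (or coercible) of histologic group per sample,
#'   aligned with the score matrix rows; `"Control"` marks
#'   non-disease samples.
#' @return list with `counts` (histology x label contingency), `rowPct`
#'   (row percentages) and `redDiseaseFraction` (fraction of disease
#'   samples labeled red).
#' @export
subgroupReport <- function(model, metadata) {
  stopifnot(is(model, "GaussianMixtureModel"))
  if (length(metadata) != length(model@cluster))
    stop("metadata length does not match the number of samples")
  if (length(metadata) == 0L || all(is.na(metadata)))
    stop("empty metadata column")
  if (all(is.na(model@labels))) stop("assign phenotype labels first")
  lab <- factor(model@labels[model@cluster],
                levels = c("red", "green", "gray"))
  meta <- factor(metadata)
  counts <- base::table(histology = meta, label = lab)
  rowPct <- 100 * prop.table(counts, margin = 1L)
  disease <- meta != "Control"
  list(counts = counts, rowPct = rowPct,
       redDiseaseFraction = if (any(disease))
         mean(lab[disease] == "red") else NA_real_)
}
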