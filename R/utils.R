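# Internal helpers.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stop unless all probabilities lie in [0, 1].
checkProb <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("'", what, "' must lie in [0, 1]")
  invisible(p)
}

# First mode of a vector (ties broken by first factor level / sort order).
statMode <- function(x) {
  tab <- table(x)
  names(tab)[which.max(tab)]
}

# Pixel-centre coordinate grids for an nr x nc image (0-based, x rightward
# along columns, y downward along rows).
pixelGrid <- function(nr, nc) {
  list(x = matrix(rep(seq_len(nc) - 1, each = nr), nr, nc),
       y = matrix(rep(seq_len(nr) - 1, times = nc), nr, nc))
}
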