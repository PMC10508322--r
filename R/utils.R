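# Internal helpers: seeded evaluation, seed splitting, column standardization.

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library functions never disturb the
# user's stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministic seed splitting: one user seed fans out to per-stage streams.
# Kept below 2^31 - 1 so the result is always a valid R integer.
.splitSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + stream * 104729) %%
               2147483647)
}

# Column-standardize a matrix (mean 0, SD 1, n-1 denominator). Errors name
# zero-variance columns because a constant column makes correlations
# undefined.
.colStandardize <- function(X, what = "block") {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  bad <- s == 0 | !is.finite(s)
  if (any(bad)) {
    nm <- colnames(X)
    lab <- if (is.null(nm)) paste0("#", which(bad)) else nm[bad]
    stop(sprintf("zero-variance column(s) in %s: %s", what,
                 paste(utils::head(lab, 5), collapse = ", ")))
  }
  sweep(Xc, 2L, s, "/")
}

# Column SDs without standardizing (used to detect degenerate resamples).
.colSDs <- function(X) {
  mu <- colMeans(X)
  sqrt(colSums(sweep(X, 2L, mu, "-")^2) / (nrow(X) - 1L))
}

.assertAligned <- function(idsA, idsB, whatA = "brain block",
                           whatB = "behavior block") {
  if (!identical(idsA, idsB))
    stop(sprintf("subject ids of %s and %s do not match", whatA, whatB))
  invisible(TRUE)
}
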