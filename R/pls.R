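#' Cross-block matrix between brain and behavior
#'
#' Computes the measures x voxels matrix relating the two blocks across
#' subjects. In `"correlation"` mode (the behavioral-PLS convention) both
#' blocks are column-standardized first, so entry (b, v) is the Pearson
#' correlation between measure b and voxel v. `"covariance"` mode centers
#' the columns without scaling.
#'
#' @param brain numeric matrix, subjects x voxels.
#' @param behavior numeric matrix, subjects x measures.
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @return Numeric matrix, measures x voxels.
#' @export
crossBlockMatrix <- function(brain, behavior,
                             mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  if (nrow(brain) != nrow(behavior))
    stop("blocks must have one row per subject, aligned")
  n <- nrow(brain)
  if (n < 3L) stop("at least 3 subjects are required")
  if (mode == "correlation") {
    Xz <- .colStandardize(brain, "brain block")
    Yz <- .colStandardize(behavior, "behavior block")
  } else {
    Xz <- sweep(brain, 2L, colMeans(brain), "-")
    Yz <- sweep(behavior, 2L, colMeans(behavior), "-")
  }
  crossprod(Yz, Xz) / (n - 1L)
}

# Deterministic reflection convention: within each LV the behavior salience
# of largest magnitude is made positive (ties broken by the first such
# entry), and the voxel salience column is flipped in step.
.applySignConvention <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

#' Singular value decomposition of the cross-block matrix
#'
#' Decomposes the measures x voxels matrix `R = U S V'` into orthogonal
#' latent variables: `U` holds behavior saliences, `V` voxel saliences and
#' `diag(S)` the singular values. Covariance explained per LV is the squared
#' singular value over the sum of all squared singular values; brain scores
#' are the projection of the (standardized) brain block onto the voxel
#' saliences. A deterministic reflection convention is applied (largest
#' behavior salience per LV made positive).
#'
#' @param R numeric matrix, measures x voxels.
#' @param brain optional subjects x voxels matrix; when given, brain scores
#'   are computed on its standardized (or centered, for covariance mode)
#'   columns.
#' @param mode block scaling used to build `R`; controls how `brain` is
#'   prepared for scoring.
#' @return A [PLSDecomposition-class].
#' @export
plsDecompose <- function(R, brain = NULL,
                         mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  R <- as.matrix(R)
  if (any(!is.finite(R)))
    stop("cross-block matrix contains non-finite entries")
  L <- min(dim(R))
  sv <- svd(R, nu = L, nv = L)
  fixed <- .applySignConvention(sv$u, sv$v)
  d <- sv$d[seq_len(L)]
  scores <- matrix(numeric(0), 0, L)
  if (!is.null(brain)) {
    brain <- as.matrix(brain)
    Xz <- if (mode == "correlation") .colStandardize(brain, "brain block")
          else sweep(brain, 2L, colMeans(brain), "-")
    scores <- Xz %*% fixed$V
    rownames(scores) <- rownames(brain)
  }
  new("PLSDecomposition",
      behaviorSaliences = fixed$U, voxelSaliences = fixed$V,
      singularValues = d,
      covarianceExplained = d^2 / sum(d^2),
      brainScores = scores, mode = mode)
}

#' Permutation test of the PLS singular values
#'
#' Re-pairs the blocks by permuting the behavior rows relative to the brain
#' rows, recomputing the cross-block matrix and its singular values each
#' time. The k-th permuted singular value is compared with the k-th observed
#' one, and `p_k = (#{permuted s_k >= observed s_k} + 1) / (N + 1)` — the
#' add-one convention, whose smallest attainable value is `1/(N+1)` (0.001
#' at the conventional 1000 resamples).
#'
#' @param brain numeric matrix, subjects x voxels.
#' @param behavior numeric matrix, subjects x measures.
#' @param nPermutations number of resamples (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param mode cross-block scaling, as in [crossBlockMatrix()].
#' @return A [PermutationResult-class].
#' @export
permutationTest <- function(brain, behavior, nPermutations = 1000L,
                            seed = 1L, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  n <- nrow(brain)
  if (n < 3L) stop("at least 3 subjects are required")
  if (nrow(behavior) != n) stop("blocks must be aligned by subject")
  nPermutations <- as.integer(nPermutations)
  stopifnot(nPermutations >= 1L)
  obs <- svd(crossBlockMatrix(brain, behavior, mode), nu = 0, nv = 0)$d
  L <- min(dim(behavior)[2], dim(brain)[2])
  obs <- obs[seq_len(L)]
  # Column statistics are invariant under row permutation, so standardizing
  # once and permuting rows is identical to re-standardizing each resample.
  Xz <- if (mode == "correlation") .colStandardize(brain, "brain block")
        else sweep(brain, 2L, colMeans(brain), "-")
  Yz <- if (mode == "correlation") .colStandardize(behavior, "behavior block")
        else sweep(behavior, 2L, colMeans(behavior), "-")
  perm <- .withSeed(seed, {
    t(vapply(seq_len(nPermutations), function(b) {
      idx <- sample.int(n)
      svd(crossprod(Yz[idx, , drop = FALSE], Xz) / (n - 1L),
          nu = 0, nv = 0)$d[seq_len(L)]
    }, numeric(L)))
  })
  pvals <- (colSums(perm >= rep(obs, each = nPermutations)) + 1) /
    (nPermutations + 1)
  new("PermutationResult", nPermutations = nPermutations,
      pValues = pvals, permutedSingularValues = perm,
      seed = as.integer(seed))
}

#' Bootstrap inference: salience stability and correlation intervals
#'
#' Resamples subjects with replacement; for every resample the full
#' estimation pipeline is repeated (column standardization, cross-block
#' matrix, SVD), resampled saliences are aligned to the original
#' decomposition (sign alignment by default, orthogonal Procrustes
#' optionally), and two quantities are accumulated: the per-voxel bootstrap
#' standard error of the voxel saliences, whose ratio to the original
#' salience is the bootstrap ratio (BSR), and the correlations between
#' resampled brain scores and behavioral measures, summarized as percentile
#' confidence intervals. Resamples in which any block column collapses to
#' zero variance are redrawn (and counted).
#'
#' Voxels whose salience does not vary across resamples (bootstrap SE below
#' `seTolerance`) are flagged in `stableMask` and reported as signed `Inf`
#' rather than an overflowed division.
#'
#' @param brain numeric matrix, subjects x voxels.
#' @param behavior numeric matrix, subjects x measures.
#' @param nBootstrap number of resamples (default 1000).
#' @param seed integer seed for the bootstrap stream.
#' @param ciLevel confidence level of the percentile intervals (default
#'   0.95).
#' @param alignment `"sign"` (default) or `"procrustes"`.
#' @param mode cross-block scaling, as in [crossBlockMatrix()].
#' @param seTolerance bootstrap SEs at or below this are treated as
#'   numerically zero. Saliences have unit norm, so genuine bootstrap
#'   variability sits orders of magnitude above this floor while pure SVD
#'   round-off sits below it.
#' @return A [BootstrapResult-class].
#' @export
bootstrapInference <- function(brain, behavior, nBootstrap = 1000L,
                               seed = 1L, ciLevel = 0.95,
                               alignment = c("sign", "procrustes"),
                               mode = c("correlation", "covariance"),
                               seTolerance = 1e-6) {
  alignment <- match.arg(alignment)
  mode <- match.arg(mode)
  brain <- as.matrix(brain)
  behavior <- as.matrix(behavior)
  n <- nrow(brain)
  if (nrow(behavior) != n) stop("blocks must be aligned by subject")
  nBootstrap <- as.integer(nBootstrap)
  stopifnot(nBootstrap >= 2L, ciLevel > 0, ciLevel < 1)
  orig <- plsDecompose(crossBlockMatrix(brain, behavior, mode),
                       brain = brain, mode = mode)
  V0 <- orig@voxelSaliences
  L <- ncol(V0)
  nv <- nrow(V0)
  nb <- ncol(behavior)
  corOrig <- stats::cor(orig@brainScores, behavior)  # LVs x behaviors
  sumV <- matrix(0, nv, L)
  sumV2 <- matrix(0, nv, L)
  corBoot <- array(NA_real_, c(nb, L, nBootstrap))
  nRedrawn <- 0L
  .withSeed(seed, {
    for (b in seq_len(nBootstrap)) {
      repeat {
        idx <- sample.int(n, replace = TRUE)
        okBrain <- .colSDs(brain[idx, , drop = FALSE]) > 0
        okBeh <- .colSDs(behavior[idx, , drop = FALSE]) > 0
        if (all(okBrain) && all(okBeh)) break
        nRedrawn <- nRedrawn + 1L
      }
      Xb <- brain[idx, , drop = FALSE]
      Yb <- behavior[idx, , drop = FALSE]
      Xz <- if (mode == "correlation") .colStandardize(Xb) else
        sweep(Xb, 2L, colMeans(Xb), "-")
      Yz <- if (mode == "correlation") .colStandardize(Yb) else
        sweep(Yb, 2L, colMeans(Yb), "-")
      svb <- svd(crossprod(Yz, Xz) / (n - 1L), nu = L, nv = L)
      Ub <- svb$u
      Vb <- svb$v
      if (alignment == "sign") {
        flips <- colSums(Vb * V0) < 0
        if (any(flips)) {
          Vb[, flips] <- -Vb[, flips, drop = FALSE]
          Ub[, flips] <- -Ub[, flips, drop = FALSE]
        }
      } else {
        M <- crossprod(Vb, V0)
        sm <- svd(M)
        Q <- sm$u %*% t(sm$v)
        Vb <- Vb %*% Q
        Ub <- Ub %*% Q
      }
      sumV <- sumV + Vb
      sumV2 <- sumV2 + Vb^2
      corBoot[, , b] <- t(stats::cor(Xz %*% Vb, Yb))
    }
  })
  meanV <- sumV / nBootstrap
  varV <- (sumV2 - nBootstrap * meanV^2) / (nBootstrap - 1L)
  se <- sqrt(pmax(varV, 0))
  stable <- se <= seTolerance & abs(V0) > 0
  bsrMat <- V0 / se
  bsrMat[stable] <- sign(V0[stable]) * Inf
  bsrMat[se <= seTolerance & abs(V0) == 0] <- 0
  alpha <- (1 - ciLevel) / 2
  ciLow <- apply(corBoot, c(1, 2), stats::quantile, probs = alpha,
                 names = FALSE)
  ciHigh <- apply(corBoot, c(1, 2), stats::quantile, probs = 1 - alpha,
                  names = FALSE)
  pointCor <- t(corOrig)  # behaviors x LVs
  dimnames(pointCor) <- list(colnames(behavior), NULL)
  dimnames(ciLow) <- dimnames(ciHigh) <- dimnames(pointCor)
  new("BootstrapResult", nBootstrap = nBootstrap, bsr = bsrMat,
      salienceSE = se, stableMask = stable,
      behaviorCorrelations = pointCor,
      correlationCILow = ciLow, correlationCIHigh = ciHigh,
      ciLevel = ciLevel, nRedrawn = nRedrawn, alignment = alignment,
      seed = as.integer(seed))
}

#' Run the full behavioral PLS analysis
#'
#' Orchestrates [crossBlockMatrix()], [plsDecompose()], [permutationTest()]
#' and [bootstrapInference()] on an [SDMatrix-class] brain block and a
#' behavior matrix, with all randomness derived from one seed through a
#' fixed splitting scheme (permutation and bootstrap streams are
#' independent).
#'
#' @param sd an [SDMatrix-class].
#' @param behaviorBlock numeric matrix, subjects x measures, rownames =
#'   subject ids (see [buildBehaviorBlock()]).
#' @param nPermutations permutation resamples (default 1000).
#' @param nBootstrap bootstrap resamples (default 1000).
#' @param seed integer master seed.
#' @param mode cross-block scaling.
#' @param alignment bootstrap salience alignment.
#' @return A [PLSResult-class].
#' @export
runBehavioralPLS <- function(sd, behaviorBlock, nPermutations = 1000L,
                             nBootstrap = 1000L, seed = 1L,
                             mode = c("correlation", "covariance"),
                             alignment = c("sign", "procrustes")) {
  mode <- match.arg(mode)
  alignment <- match.arg(alignment)
  stopifnot(is(sd, "SDMatrix"))
  brain <- sd@values
  behaviorBlock <- as.matrix(behaviorBlock)
  .assertAligned(rownames(brain), rownames(behaviorBlock))
  dec <- plsDecompose(crossBlockMatrix(brain, behaviorBlock, mode),
                      brain = brain, mode = mode)
  perm <- permutationTest(brain, behaviorBlock, nPermutations,
                          seed = .splitSeed(seed, 1L), mode = mode)
  boot <- bootstrapInference(brain, behaviorBlock, nBootstrap,
                             seed = .splitSeed(seed, 2L),
                             alignment = alignment, mode = mode)
  new("PLSResult", decomposition = dec, permutation = perm,
      bootstrap = boot,
      subjectIds = rownames(brain),
      measureNames = colnames(behaviorBlock),
      voxelIndex = sd@voxelIndex, gridShape = sd@gridShape,
      affine = sd@affine,
      provenance = list(seed = as.integer(seed),
                        permutationSeed = .splitSeed(seed, 1L),
                        bootstrapSeed = .splitSeed(seed, 2L),
                        nPermutations = as.integer(nPermutations),
                        nBootstrap = as.integer(nBootstrap),
                        mode = mode, alignment = alignment))
}
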