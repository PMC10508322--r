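#' @describeIn accessors subject ids of an SDMatrix (row order).
#' @export
setMethod("subjectIds", "SDMatrix", function(object) rownames(object@values))

#' @describeIn accessors subject ids of a BehaviorTable.
#' @export
setMethod("subjectIds", "BehaviorTable", function(object) object@subjectId)

#' @describeIn accessors subject ids of a PLSResult.
#' @export
setMethod("subjectIds", "PLSResult", function(object) object@subjectIds)

#' @describeIn accessors subjects x voxels matrix of an SDMatrix.
#' @export
setMethod("sdValues", "SDMatrix", function(object) object@values)

#' @describeIn accessors 3D value array of an SDMap.
#' @export
setMethod("sdValues", "SDMap", function(object) object@values)

#' @describeIn accessors column-to-voxel mapping of an SDMatrix.
#' @export
setMethod("voxelIndex", "SDMatrix", function(object) object@voxelIndex)

#' @describeIn accessors column-to-voxel mapping retained in a PLSResult.
#' @export
setMethod("voxelIndex", "PLSResult", function(object) object@voxelIndex)

#' @describeIn accessors measure block (data.frame) of a BehaviorTable.
#' @export
setMethod("measures", "BehaviorTable", function(object) object@measures)

#' @describeIn accessors confound block (data.frame) of a BehaviorTable.
#' @export
setMethod("confounds", "BehaviorTable", function(object) object@confounds)

#' @describeIn accessors per-LV singular values.
#' @export
setMethod("singularValues", "PLSDecomposition",
          function(object) object@singularValues)

#' @describeIn accessors per-LV singular values of a PLSResult.
#' @export
setMethod("singularValues", "PLSResult",
          function(object) object@decomposition@singularValues)

#' @describeIn accessors per-LV fraction of cross-block covariance.
#' @export
setMethod("covarianceExplained", "PLSDecomposition",
          function(object) object@covarianceExplained)

#' @describeIn accessors per-LV fraction of cross-block covariance.
#' @export
setMethod("covarianceExplained", "PLSResult",
          function(object) object@decomposition@covarianceExplained)

#' @describeIn accessors behaviors x LVs salience matrix.
#' @export
setMethod("behaviorSaliences", "PLSDecomposition",
          function(object) object@behaviorSaliences)

#' @describeIn accessors behaviors x LVs salience matrix.
#' @export
setMethod("behaviorSaliences", "PLSResult",
          function(object) object@decomposition@behaviorSaliences)

#' @describeIn accessors voxels x LVs salience matrix.
#' @export
setMethod("voxelSaliences", "PLSDecomposition",
          function(object) object@voxelSaliences)

#' @describeIn accessors voxels x LVs salience matrix.
#' @export
setMethod("voxelSaliences", "PLSResult",
          function(object) object@decomposition@voxelSaliences)

#' @describeIn accessors subjects x LVs brain scores.
#' @export
setMethod("brainScores", "PLSDecomposition",
          function(object) object@brainScores)

#' @describeIn accessors subjects x LVs brain scores.
#' @export
setMethod("brainScores", "PLSResult",
          function(object) object@decomposition@brainScores)

#' @describeIn accessors per-LV permutation p-values.
#' @export
setMethod("pValues", "PermutationResult", function(object) object@pValues)

#' @describeIn accessors per-LV permutation p-values.
#' @export
setMethod("pValues", "PLSResult", function(object) object@permutation@pValues)

#' @describeIn accessors voxels x LVs bootstrap-ratio matrix.
#' @export
setMethod("bsr", "BootstrapResult", function(object) object@bsr)

#' @describeIn accessors voxels x LVs bootstrap-ratio matrix.
#' @export
setMethod("bsr", "PLSResult", function(object) object@bootstrap@bsr)

#' @describeIn accessors behaviors x LVs brain-score/behavior correlations.
#' @export
setMethod("behaviorCorrelations", "BootstrapResult",
          function(object) object@behaviorCorrelations)

#' @describeIn accessors behaviors x LVs brain-score/behavior correlations.
#' @export
setMethod("behaviorCorrelations", "PLSResult",
          function(object) object@bootstrap@behaviorCorrelations)

#' @describeIn accessors list with `low`/`high` percentile CI matrices.
#' @export
setMethod("correlationCI", "BootstrapResult", function(object)
  list(low = object@correlationCILow, high = object@correlationCIHigh))

#' @describeIn accessors list with `low`/`high` percentile CI matrices.
#' @export
setMethod("correlationCI", "PLSResult",
          function(object) correlationCI(object@bootstrap))

setMethod("show", "SubjectScan", function(object) {
  d <- dim(object@data)
  cat(sprintf("SubjectScan \"%s\": %d x %d x %d grid, %d timepoints, %d in-mask voxels\n",
              object@subjectId, d[1], d[2], d[3], d[4], sum(object@mask)))
})

setMethod("show", "SDMap", function(object) {
  d <- dim(object@values)
  v <- object@values[object@mask]
  cat(sprintf("SDMap \"%s\" (metric: %s): %d x %d x %d grid, %d in-mask voxels\n",
              object@subjectId, object@metric, d[1], d[2], d[3], length(v)))
  cat(sprintf("  in-mask range: [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "SDMatrix", function(object) {
  cat(sprintf("SDMatrix: %d subjects x %d voxels (grid %s)\n",
              nrow(object@values), ncol(object@values),
              paste(object@gridShape, collapse = " x ")))
})

setMethod("show", "BehaviorTable", function(object) {
  cat(sprintf("BehaviorTable: %d subjects, %d measures (%s), confounds: %s\n",
              length(object@subjectId), ncol(object@measures),
              paste(utils::head(names(object@measures), 4), collapse = ", "),
              paste(names(object@confounds), collapse = ", ")))
})

setMethod("show", "PLSDecomposition", function(object) {
  k <- length(object@singularValues)
  cat(sprintf("PLSDecomposition (%s mode): %d LVs\n", object@mode, k))
  cat(sprintf("  LV1: singular value %.4g, covariance explained %.1f%%\n",
              object@singularValues[1], 100 * object@covarianceExplained[1]))
})

setMethod("show", "PLSResult", function(object) {
  d <- object@decomposition
  p <- object@permutation@pValues
  cat(sprintf("PLSResult: %d subjects, %d measures, %d voxels, %d LVs\n",
              length(object@subjectIds), length(object@measureNames),
              nrow(d@voxelSaliences), length(d@singularValues)))
  k <- min(3L, length(p))
  for (i in seq_len(k))
    cat(sprintf("  LV%d: %.1f%% covariance, permutation p = %.4g\n",
                i, 100 * d@covarianceExplained[i], p[i]))
  cat(sprintf("  permutations: %d, bootstraps: %d (redrawn: %d)\n",
              object@permutation@nPermutations, object@bootstrap@nBootstrap,
              object@bootstrap@nRedrawn))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig: %d subjects, grid %s, %d timepoints, %d behaviors\n",
              object@nSubjects, paste(object@gridShape, collapse = "x"),
              object@nTimepoints, object@nBehaviors))
  cat(sprintf("  latent rank %d, effect size %.3g, AR(1) %.2f, seed %d\n",
              object@latentRank, object@effectSize, object@arCoefficient,
              object@seed))
})
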