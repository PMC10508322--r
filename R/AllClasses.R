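#' @import methods
NULL

#' SubjectScan: one subject's 4D resting-state time series
#'
#' Container for a denoised 4D BOLD volume (x, y, z, t), its brain mask and
#' the voxel-to-mm affine. The time series are assumed to be fully
#' preprocessed (motion-corrected, filtered, denoised) upstream; this package
#' only normalizes intensities and computes temporal variability.
#'
#' @slot data 4D numeric array (x, y, z, t) of BOLD intensities.
#' @slot mask 3D logical array; TRUE marks in-brain voxels.
#' @slot affine 4x4 numeric matrix mapping voxel indices (0-based, homogeneous)
#'   to mm coordinates.
#' @slot subjectId length-1 character identifier.
#' @export
setClass("SubjectScan",
  representation(
    data = "array",
    mask = "array",
    affine = "matrix",
    subjectId = "character"
  )
)

setValidity("SubjectScan", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4D array (x, y, z, t)")
  else {
    if (!identical(dim(object@mask), dim(object@data)[1:3]))
      msg <- c(msg, "mask shape must equal the spatial shape of data")
    if (dim(object@data)[4] < 2L)
      msg <- c(msg, "at least 2 timepoints are required")
  }
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  else if (!any(object@mask))
    msg <- c(msg, "mask must contain at least one voxel")
  if (!identical(dim(object@affine), c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-missing string")
  if (is.null(msg)) TRUE else msg
})

#' SDMap: a per-voxel temporal variability map
#'
#' Holds one subject's voxelwise variability values (BOLD-SD or MSSD) on the
#' scan grid. Values outside the mask are NA.
#'
#' @slot values 3D numeric array; NA outside the mask.
#' @slot mask 3D logical array.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @slot subjectId length-1 character.
#' @slot metric "sd" or "mssd".
#' @export
setClass("SDMap",
  representation(
    values = "array",
    mask = "array",
    affine = "matrix",
    subjectId = "character",
    metric = "character"
  )
)

setValidity("SDMap", function(object) {
  msg <- NULL
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array")
  if (!identical(dim(object@mask), dim(object@values)))
    msg <- c(msg, "mask shape must equal values shape")
  if (!object@metric %in% c("sd", "mssd"))
    msg <- c(msg, "metric must be \"sd\" or \"mssd\"")
  inmask <- object@values[object@mask]
  if (length(inmask) && any(!is.finite(inmask)))
    msg <- c(msg, "in-mask values must be finite")
  if (length(inmask) && any(inmask < 0))
    msg <- c(msg, "in-mask variability values must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' SDMatrix: subjects x in-mask-voxels variability matrix
#'
#' The brain block entering PLS. Rows are subjects (in a fixed order), columns
#' are voxels of a common mask, linearized in column-major (x fastest) order.
#' `voxelIndex` maps each column back to grid indices and mm coordinates.
#'
#' @slot values numeric matrix, subjects x voxels, rownames = subject ids.
#' @slot voxelIndex data.frame with columns `column`, `i`, `j`, `k` (1-based
#'   grid indices) and `x`, `y`, `z` (mm).
#' @slot gridShape integer(3), the source grid dimensions.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @export
setClass("SDMatrix",
  representation(
    values = "matrix",
    voxelIndex = "data.frame",
    gridShape = "integer",
    affine = "matrix"
  )
)

setValidity("SDMatrix", function(object) {
  msg <- NULL
  if (is.null(rownames(object@values)))
    msg <- c(msg, "values must carry subject ids as rownames")
  if (nrow(object@voxelIndex) != ncol(object@values))
    msg <- c(msg, "voxelIndex must have one row per matrix column")
  need <- c("column", "i", "j", "k", "x", "y", "z")
  if (!all(need %in% names(object@voxelIndex)))
    msg <- c(msg, sprintf("voxelIndex must contain columns: %s",
                          paste(need, collapse = ", ")))
  if (length(object@gridShape) != 3L)
    msg <- c(msg, "gridShape must have length 3")
  if (is.null(msg)) TRUE else msg
})

#' BehaviorTable: subjects x behavioral measures with separate confounds
#'
#' Keeps the confound block (age in years, mean framewise displacement in mm)
#' apart from the behavioral measures that enter PLS, so residualization can
#' address each block explicitly.
#'
#' @slot subjectId character vector, one id per subject.
#' @slot confounds data.frame of numeric confound columns (at least `age`,
#'   `mean_fd`), one row per subject.
#' @slot measures data.frame of numeric measure columns, one row per subject.
#' @export
setClass("BehaviorTable",
  representation(
    subjectId = "character",
    confounds = "data.frame",
    measures = "data.frame"
  )
)

setValidity("BehaviorTable", function(object) {
  msg <- NULL
  n <- length(object@subjectId)
  if (anyDuplicated(object@subjectId))
    msg <- c(msg, "subject ids must be unique")
  if (nrow(object@confounds) != n || nrow(object@measures) != n)
    msg <- c(msg, "confounds and measures must have one row per subject")
  if (!all(vapply(object@confounds, is.numeric, logical(1))))
    msg <- c(msg, "confound columns must be numeric")
  if (!all(vapply(object@measures, is.numeric, logical(1))))
    msg <- c(msg, "measure columns must be numeric")
  if (is.null(msg)) TRUE else msg
})

#' GeneratorConfig: parameters of the synthetic-data generator
#'
#' Describes a synthetic study: sample size, voxel grid, planted latent rank,
#' signal-to-noise, AR(1) temporal structure and confound contamination.
#' `effectSize` is the ratio of the latent-driven variation to the additive
#' noise SD, applied per block; `brainNoiseSD` (normalized BOLD-SD units) and
#' `behaviorNoiseSD` (T-score units) set the noise scales, so an effect size
#' of zero yields mutually independent blocks and zero noise yields exact
#' low-rank structure.
#'
#' @slot nSubjects integer >= 1.
#' @slot gridShape integer(3) voxel grid dimensions.
#' @slot nTimepoints integer >= 3 (default 297, one 10-min rest run at
#'   TR = 2 s).
#' @slot nBehaviors integer >= 1.
#' @slot latentRank integer >= 0, number of planted latent variables.
#' @slot signalVoxelFraction fraction of voxels carrying latent signal.
#' @slot effectSize latent-signal SD as a multiple of the noise SD.
#' @slot arCoefficient AR(1) coefficient in (-1, 1) for simulated series.
#' @slot confoundStrengthAge contamination rate per year of (centered) age;
#'   each block receives a slope of this rate times its own noise SD.
#' @slot confoundStrengthFD contamination rate per mm of (centered) mean FD,
#'   scaled per block like the age rate.
#' @slot brainNoiseSD additive noise SD of the brain block.
#' @slot behaviorNoiseSD additive noise SD of the behavior block.
#' @slot baselineSD median baseline BOLD-SD level of the brain block.
#' @slot seed integer RNG seed.
#' @export
setClass("GeneratorConfig",
  representation(
    nSubjects = "integer",
    gridShape = "integer",
    nTimepoints = "integer",
    nBehaviors = "integer",
    latentRank = "integer",
    signalVoxelFraction = "numeric",
    effectSize = "numeric",
    arCoefficient = "numeric",
    confoundStrengthAge = "numeric",
    confoundStrengthFD = "numeric",
    brainNoiseSD = "numeric",
    behaviorNoiseSD = "numeric",
    baselineSD = "numeric",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msg <- NULL
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be 3 positive integers")
  if (object@nTimepoints < 3L) msg <- c(msg, "nTimepoints must be >= 3")
  if (object@nBehaviors < 1L) msg <- c(msg, "nBehaviors must be >= 1")
  if (object@latentRank < 0L) msg <- c(msg, "latentRank must be >= 0")
  if (object@signalVoxelFraction < 0 || object@signalVoxelFraction > 1)
    msg <- c(msg, "signalVoxelFraction must lie in [0, 1]")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (abs(object@arCoefficient) >= 1)
    msg <- c(msg, "arCoefficient must satisfy |ar| < 1")
  if (object@brainNoiseSD < 0 || object@behaviorNoiseSD < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@baselineSD <= 0) msg <- c(msg, "baselineSD must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticTruth: the planted structure of a generator run
#'
#' @slot latentScores subjects x rank matrix; columns have mean 0, SD 1.
#' @slot voxelSaliencesTrue voxels x rank; unit-norm columns.
#' @slot behaviorWeightsTrue behaviors x rank; unit-norm columns.
#' @slot confoundCoeffs named numeric: age/FD slopes used for each block.
#' @slot targetSDMap subjects x voxels matrix of target BOLD-SD values.
#' @slot age numeric vector of simulated ages (years).
#' @slot meanFD numeric vector of simulated mean framewise displacements (mm).
#' @export
setClass("SyntheticTruth",
  representation(
    latentScores = "matrix",
    voxelSaliencesTrue = "matrix",
    behaviorWeightsTrue = "matrix",
    confoundCoeffs = "numeric",
    targetSDMap = "matrix",
    age = "numeric",
    meanFD = "numeric"
  )
)

#' ConfoundSpec: which confounds leave which block
#'
#' @slot brainConfounds ordered confound names regressed from the brain block.
#' @slot behaviorConfounds ordered confound names regressed from the behavior
#'   block.
#' @export
setClass("ConfoundSpec",
  representation(
    brainConfounds = "character",
    behaviorConfounds = "character"
  )
)

#' PLSDecomposition: SVD of the cross-block matrix
#'
#' @slot behaviorSaliences behaviors x LVs (left singular vectors).
#' @slot voxelSaliences voxels x LVs (right singular vectors).
#' @slot singularValues non-increasing, >= 0.
#' @slot covarianceExplained per-LV squared singular value over their sum.
#' @slot brainScores subjects x LVs projections of the (standardized) brain
#'   block onto voxel saliences.
#' @slot mode "correlation" or "covariance" cross-block scaling.
#' @export
setClass("PLSDecomposition",
  representation(
    behaviorSaliences = "matrix",
    voxelSaliences = "matrix",
    singularValues = "numeric",
    covarianceExplained = "numeric",
    brainScores = "matrix",
    mode = "character"
  )
)

setValidity("PLSDecomposition", function(object) {
  msg <- NULL
  s <- object@singularValues
  if (length(s) && any(diff(s) > 1e-12))
    msg <- c(msg, "singular values must be non-increasing")
  if (length(s) && any(s < -1e-12))
    msg <- c(msg, "singular values must be non-negative")
  ce <- object@covarianceExplained
  if (length(ce) && abs(sum(ce) - 1) > 1e-10)
    msg <- c(msg, "covarianceExplained must sum to 1")
  for (slot in c("behaviorSaliences", "voxelSaliences")) {
    U <- slot(object, slot)
    if (ncol(U)) {
      G <- crossprod(U)
      if (max(abs(G - diag(ncol(U)))) > 1e-8)
        msg <- c(msg, sprintf("%s columns must be orthonormal", slot))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' PermutationResult: permutation test of the singular values
#'
#' @slot nPermutations count of permutation resamples.
#' @slot pValues per-LV p-values, (k+1)/(N+1) convention.
#' @slot permutedSingularValues permutations x LVs matrix.
#' @slot seed integer seed the resampling was run under.
#' @export
setClass("PermutationResult",
  representation(
    nPermutations = "integer",
    pValues = "numeric",
    permutedSingularValues = "matrix",
    seed = "integer"
  )
)

setValidity("PermutationResult", function(object) {
  msg <- NULL
  lo <- 1 / (object@nPermutations + 1)
  if (any(object@pValues < lo - 1e-12) || any(object@pValues > 1 + 1e-12))
    msg <- c(msg, "p-values must lie in [1/(N+1), 1]")
  if (is.null(msg)) TRUE else msg
})

#' BootstrapResult: bootstrap stability of saliences and correlations
#'
#' @slot nBootstrap count of bootstrap resamples.
#' @slot bsr voxels x LVs bootstrap ratios (salience / bootstrap SE);
#'   `Inf` with the matching sign where the bootstrap SE vanished (see
#'   `stableMask`).
#' @slot salienceSE voxels x LVs bootstrap standard errors.
#' @slot stableMask voxels x LVs logical; TRUE flags voxels whose salience was
#'   numerically invariant across resamples (SE ~ 0), reported as perfectly
#'   stable rather than as an overflowed ratio.
#' @slot behaviorCorrelations behaviors x LVs point-estimate correlations
#'   between brain scores and measures.
#' @slot correlationCILow,correlationCIHigh behaviors x LVs percentile
#'   bootstrap interval bounds.
#' @slot ciLevel confidence level of the interval.
#' @slot nRedrawn resamples redrawn because a block column had zero variance.
#' @slot alignment "sign" or "procrustes" salience alignment used.
#' @slot seed integer seed.
#' @export
setClass("BootstrapResult",
  representation(
    nBootstrap = "integer",
    bsr = "matrix",
    salienceSE = "matrix",
    stableMask = "matrix",
    behaviorCorrelations = "matrix",
    correlationCILow = "matrix",
    correlationCIHigh = "matrix",
    ciLevel = "numeric",
    nRedrawn = "integer",
    alignment = "character",
    seed = "integer"
  )
)

setValidity("BootstrapResult", function(object) {
  msg <- NULL
  if (any(object@correlationCILow > object@correlationCIHigh + 1e-12))
    msg <- c(msg, "CI lower bounds must not exceed upper bounds")
  if (is.null(msg)) TRUE else msg
})

#' PLSResult: bundled behavioral-PLS analysis
#'
#' @slot decomposition a [PLSDecomposition-class].
#' @slot permutation a [PermutationResult-class].
#' @slot bootstrap a [BootstrapResult-class].
#' @slot subjectIds subjects entering the analysis, in row order.
#' @slot measureNames behavior column names, in block order.
#' @slot voxelIndex voxel column mapping (from the [SDMatrix-class]).
#' @slot gridShape integer(3) source grid.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @slot provenance list echoing seeds and options.
#' @export
setClass("PLSResult",
  representation(
    decomposition = "PLSDecomposition",
    permutation = "PermutationResult",
    bootstrap = "BootstrapResult",
    subjectIds = "character",
    measureNames = "character",
    voxelIndex = "data.frame",
    gridShape = "integer",
    affine = "matrix",
    provenance = "list"
  )
)

#' ThresholdSpec: BSR thresholding and cluster-extent filtering parameters
#'
#' @slot bsrCutoff positive threshold applied to |BSR| (default 2.5).
#' @slot minClusterVoxels minimum connected-component size kept (default 15).
#' @slot connectivity 6, 18 or 26 voxel neighborhood.
#' @export
setClass("ThresholdSpec",
  representation(
    bsrCutoff = "numeric",
    minClusterVoxels = "integer",
    connectivity = "integer"
  )
)

setValidity("ThresholdSpec", function(object) {
  msg <- NULL
  if (object@bsrCutoff <= 0) msg <- c(msg, "bsrCutoff must be > 0")
  if (object@minClusterVoxels < 1L)
    msg <- c(msg, "minClusterVoxels must be >= 1")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (is.null(msg)) TRUE else msg
})

#' AtlasDefinition: parcel volume plus parcel-to-network lookup
#'
#' @slot labels 3D integer array of parcel labels (0 = unassigned).
#' @slot lookup data.frame with columns `label`, `parcelName`, `networkName`;
#'   every nonzero parcel label maps to exactly one network.
#' @slot affine 4x4 voxel-to-mm matrix.
#' @export
setClass("AtlasDefinition",
  representation(
    labels = "array",
    lookup = "data.frame",
    affine = "matrix"
  )
)

setValidity("AtlasDefinition", function(object) {
  msg <- NULL
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  need <- c("label", "parcelName", "networkName")
  if (!all(need %in% names(object@lookup)))
    msg <- c(msg, sprintf("lookup must contain columns: %s",
                          paste(need, collapse = ", ")))
  else if (anyDuplicated(object@lookup$label))
    msg <- c(msg, "each parcel label must map to exactly one network")
  if (is.null(msg)) TRUE else msg
})
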