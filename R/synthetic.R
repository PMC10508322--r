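#' Construct a GeneratorConfig
#'
#' Defaults describe a realistic desk-scale synthetic study: a 10 mm-scale
#' toy grid, 297 timepoints (a 10-minute rest run at TR = 2 s), behaviors on
#' the T-score scale (mean 50, SD 10), ages uniform on 20-86 years and
#' mean-FD values log-normal around 0.15 mm. `effectSize` is the SD of the
#' latent-driven variation expressed as a multiple of the additive noise SD
#' in each block; 0 yields mutually independent blocks.
#'
#' @param nSubjects number of subjects.
#' @param gridShape integer(3) voxel grid.
#' @param nTimepoints timepoints per simulated scan (default 297).
#' @param nBehaviors number of behavioral measures.
#' @param latentRank number of planted latent variables (>= 0).
#' @param signalVoxelFraction fraction of voxels carrying latent signal.
#' @param effectSize latent-signal amplitude in units of the reference noise
#'   scale (0.25 BOLD-SD units / 10 T-score units); with the default noise
#'   SDs this is exactly the signal-to-noise ratio, and it stays nonzero
#'   when a noise SD is set to zero.
#' @param arCoefficient AR(1) coefficient of simulated time series.
#' @param confoundStrengthAge contamination rate per year of centered age;
#'   the slope applied to each block is this rate times the block's noise
#'   SD, so one knob contaminates both blocks comparably despite their
#'   different units.
#' @param confoundStrengthFD contamination rate per mm of centered mean FD,
#'   scaled per block like the age rate.
#' @param brainNoiseSD additive noise SD of the brain block (normalized
#'   BOLD-SD units).
#' @param behaviorNoiseSD additive noise SD of the behavior block (T-score
#'   units).
#' @param baselineSD median baseline BOLD-SD level.
#' @param seed integer RNG seed.
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(nSubjects = 150L, gridShape = c(10L, 10L, 10L),
                            nTimepoints = 297L, nBehaviors = 22L,
                            latentRank = 1L, signalVoxelFraction = 0.2,
                            effectSize = 1, arCoefficient = 0.3,
                            confoundStrengthAge = 0,
                            confoundStrengthFD = 0,
                            brainNoiseSD = 0.25, behaviorNoiseSD = 10,
                            baselineSD = 2, seed = 1L) {
  new("GeneratorConfig",
      nSubjects = as.integer(nSubjects),
      gridShape = as.integer(gridShape),
      nTimepoints = as.integer(nTimepoints),
      nBehaviors = as.integer(nBehaviors),
      latentRank = as.integer(latentRank),
      signalVoxelFraction = signalVoxelFraction,
      effectSize = effectSize,
      arCoefficient = arCoefficient,
      confoundStrengthAge = confoundStrengthAge,
      confoundStrengthFD = confoundStrengthFD,
      brainNoiseSD = brainNoiseSD,
      behaviorNoiseSD = behaviorNoiseSD,
      baselineSD = baselineSD,
      seed = as.integer(seed))
}

# Reference scales of the two blocks: one "noise unit" of normalized
# BOLD-SD and one T-score SD. Latent amplitudes and confound slopes are
# expressed in these units.
.brainNoiseRef <- 0.25
.behaviorNoiseRef <- 10

# Standardize columns to mean 0, SD 1 (n-1); used for planted latent scores.
.standardizeScores <- function(Z) {
  if (!ncol(Z)) return(Z)
  Z <- sweep(Z, 2L, colMeans(Z), "-")
  sweep(Z, 2L, apply(Z, 2L, stats::sd), "/")
}

# Unit-norm columns.
.unitNorm <- function(M) {
  if (!ncol(M)) return(M)
  sweep(M, 2L, sqrt(colSums(M^2)), "/")
}

#' Generate a synthetic SD-matrix / behavior-table pair with planted truth
#'
#' Builds a subjects x voxels BOLD-SD matrix and a subjects x behaviors
#' table coupled through a planted low-rank latent structure:
#'
#' * latent scores `Z` (subjects x rank, columns standardized),
#' * voxel saliences `U` (unit-norm columns, supported on a random
#'   `signalVoxelFraction` of voxels) and behavior weights `W` (unit-norm
#'   columns),
#' * brain block: `baseline_v + effectSize * 0.25 * (Z U')_iv +
#'   brainNoiseSD * noise`, floored at a small positive SD (0.25 normalized
#'   BOLD-SD units is the block's reference noise scale),
#' * behavior block: `50 + effectSize * 10 * (Z W')_ib +
#'   behaviorNoiseSD * noise` (10 T-score units is the reference scale),
#' * confounds: age (uniform 20-86 years) and mean FD (log-normal around
#'   0.15 mm), centered and added to every column of both blocks with the
#'   configured slopes, so both blocks are contaminated the way real aging
#'   and head-motion effects contaminate real data.
#'
#' @param config a [GeneratorConfig-class].
#' @param behaviorWeights optional behaviors x rank matrix to plant a chosen
#'   weight pattern (columns are re-normalized to unit norm).
#' @param voxelSaliences optional voxels x rank matrix planting a chosen
#'   salience pattern (columns re-normalized).
#' @return List with `sd` ([SDMatrix-class]), `behavior`
#'   ([BehaviorTable-class]) and `truth` ([SyntheticTruth-class]).
#' @export
generateDataset <- function(config, behaviorWeights = NULL,
                            voxelSaliences = NULL) {
  stopifnot(is(config, "GeneratorConfig"))
  nv <- prod(config@gridShape)
  n <- config@nSubjects
  r <- config@latentRank
  if (r > min(config@nBehaviors, nv))
    stop("latentRank must not exceed min(nBehaviors, nVoxels)")
  .withSeed(config@seed, {
    Z <- .standardizeScores(matrix(stats::rnorm(n * r), n, r))
    if (is.null(voxelSaliences)) {
      U <- matrix(0, nv, r)
      if (r > 0) {
        nSignal <- max(1L, round(config@signalVoxelFraction * nv))
        for (k in seq_len(r)) {
          support <- sample.int(nv, nSignal)
          U[support, k] <- stats::rnorm(nSignal)
        }
      }
    } else U <- as.matrix(voxelSaliences)
    U <- .unitNorm(U)
    W <- if (is.null(behaviorWeights))
      matrix(stats::rnorm(config@nBehaviors * r), config@nBehaviors, r)
    else as.matrix(behaviorWeights)
    W <- .unitNorm(W)

    age <- stats::runif(n, 20, 86)
    fd <- stats::rlnorm(n, meanlog = log(0.15), sdlog = 0.4)
    ageC <- age - mean(age)
    fdC <- fd - mean(fd)

    baseline <- stats::rlnorm(nv, meanlog = log(config@baselineSD),
                              sdlog = 0.15)
    signalB <- if (r > 0) Z %*% t(U) else matrix(0, n, nv)
    # Latent amplitudes and confound slopes are anchored to fixed reference
    # scales (the default noise SDs), not to the configured noise: with the
    # defaults effectSize is exactly the signal-to-noise ratio, and setting
    # a noise SD to zero leaves the planted low-rank structure intact.
    ageSlopeBrain <- config@confoundStrengthAge * .brainNoiseRef
    fdSlopeBrain <- config@confoundStrengthFD * .brainNoiseRef
    ageSlopeBeh <- config@confoundStrengthAge * .behaviorNoiseRef
    fdSlopeBeh <- config@confoundStrengthFD * .behaviorNoiseRef
    sdMat <- matrix(baseline, n, nv, byrow = TRUE) +
      config@effectSize * .brainNoiseRef * signalB +
      config@brainNoiseSD * matrix(stats::rnorm(n * nv), n, nv) +
      ageSlopeBrain * ageC +
      fdSlopeBrain * fdC
    sdMat <- pmax(sdMat, 0.01)

    signalY <- if (r > 0) Z %*% t(W) else matrix(0, n, config@nBehaviors)
    Y <- 50 +
      config@effectSize * .behaviorNoiseRef * signalY +
      config@behaviorNoiseSD * matrix(stats::rnorm(n * config@nBehaviors),
                                      n, config@nBehaviors) +
      ageSlopeBeh * ageC +
      fdSlopeBeh * fdC

    ids <- sprintf("sub-%03d", seq_len(n))
    rownames(sdMat) <- ids
    d <- config@gridShape
    affine <- diag(c(4, 4, 4, 1))  # 4 mm isotropic synthetic grid
    ijk <- arrayInd(seq_len(nv), d)
    mm <- t(affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
    voxelIndex <- data.frame(column = seq_len(nv),
                             i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                             x = mm[, 1], y = mm[, 2], z = mm[, 3])
    sd <- new("SDMatrix", values = sdMat, voxelIndex = voxelIndex,
              gridShape = d, affine = affine)
    colnames(Y) <- .syntheticMeasureNames(config@nBehaviors)
    behavior <- behaviorTable(ids, age, fd, as.data.frame(Y))
    truth <- new("SyntheticTruth", latentScores = Z,
                 voxelSaliencesTrue = U, behaviorWeightsTrue = W,
                 confoundCoeffs = c(ageBrain = ageSlopeBrain,
                                    fdBrain = fdSlopeBrain,
                                    ageBehavior = ageSlopeBeh,
                                    fdBehavior = fdSlopeBeh),
                 targetSDMap = sdMat, age = age, meanFD = fd)
    list(sd = sd, behavior = behavior, truth = truth)
  })
}

.syntheticMeasureNames <- function(k) {
  base <- c("gF", "gC", paste0("soc_pos_", 1:7), paste0("soc_neg_", 1:10),
            "meq_global", "synchrony")
  if (k <= length(base)) base[seq_len(k)] else
    c(base, paste0("measure_", seq_len(k - length(base))))
}

#' Generate per-subject AR(1) time series matching a target SD map
#'
#' Emits, for each subject, a 4D scan whose per-voxel sample SD equals the
#' subject's target BOLD-SD value exactly: a Gaussian AR(1) series is
#' simulated at the configured coefficient, demeaned, and rescaled
#' post hoc so its sample SD (n - 1 denominator) hits the target to machine
#' precision. A positive mean offset of 100 is added, matching grand-mean
#' normalized data. Voxels with a zero target emit a constant series.
#'
#' @param config a [GeneratorConfig-class].
#' @param truth a [SyntheticTruth-class] from [generateDataset()] (its
#'   `targetSDMap` is the target).
#' @param subjects which subjects (row indices) to generate; defaults to
#'   all. Generating scans is the expensive path, so subsetting keeps test
#'   fixtures cheap.
#' @return List of [SubjectScan-class] objects.
#' @export
generateTimeseries <- function(config, truth, subjects = NULL) {
  stopifnot(is(config, "GeneratorConfig"), is(truth, "SyntheticTruth"))
  if (config@nTimepoints < 3L)
    stop("nTimepoints must be >= 3")
  nt <- config@nTimepoints
  d <- config@gridShape
  nv <- prod(d)
  if (ncol(truth@targetSDMap) != nv)
    stop("targetSDMap does not match the configured grid")
  if (is.null(subjects)) subjects <- seq_len(nrow(truth@targetSDMap))
  ar <- config@arCoefficient
  affine <- diag(c(4, 4, 4, 1))
  .withSeed(.splitSeed(config@seed, 3L), {
    lapply(subjects, function(i) {
      E <- matrix(stats::rnorm(nv * nt), nv, nt)
      X <- E
      for (t in 2:nt) X[, t] <- ar * X[, t - 1L] + E[, t]
      X <- X - rowMeans(X)
      sdNow <- sqrt(rowSums(X^2) / (nt - 1L))
      target <- truth@targetSDMap[i, ]
      scaleF <- ifelse(sdNow > 0, target / sdNow, 0)
      X <- X * scaleF + 100
      subjectScan(array(X, c(d, nt)),
                  mask = array(TRUE, d), affine = affine,
                  subjectId = rownames(truth@targetSDMap)[i])
    })
  })
}

#' Write a synthetic dataset to disk
#'
#' SD maps go out as one 3D NIfTI per subject, the behavior table as TSV
#' (`subject_id`, `age`, `mean_fd`, measure columns) and the planted truth
#' as a JSON sidecar.
#'
#' @param dataset list returned by [generateDataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sdm <- dataset$sd
  for (id in rownames(sdm@values)) {
    map <- unstackSDMap(sdm, id)
    writeSDMap(map, file.path(dir, paste0(id, "_sd.nii.gz")))
  }
  writeBehaviorTable(dataset$behavior, file.path(dir, "behavior.tsv"))
  tr <- dataset$truth
  jsonlite::write_json(
    list(latentScores = tr@latentScores,
         voxelSaliencesTrue = tr@voxelSaliencesTrue,
         behaviorWeightsTrue = tr@behaviorWeightsTrue,
         confoundCoeffs = as.list(tr@confoundCoeffs),
         age = tr@age, meanFD = tr@meanFD),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
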