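#' PipelineConfig: one end-to-end analysis configuration
#'
#' @slot scanPaths 4D NIfTI scans, one per subject (may be empty when
#'   pre-computed SD maps are supplied instead).
#' @slot sdMapPaths 3D NIfTI variability maps, one per subject.
#' @slot subjectIds ids matching `scanPaths`/`sdMapPaths` (defaults to file
#'   name stems).
#' @slot maskPath optional study mask NIfTI.
#' @slot behaviorPath behavior TSV (subject_id, age, mean_fd, measures).
#' @slot atlasPath,atlasLabelsPath optional atlas NIfTI + lookup TSV.
#' @slot outDir output directory.
#' @slot metric "sd" or "mssd".
#' @slot normalize grand-mean-normalize scans before the metric.
#' @slot adjust TRUE: age + FD out of brain, age out of behavior; FALSE: FD
#'   only out of brain (the younger-subsample convention).
#' @slot subsampleAgeBelow keep only subjects strictly younger than this age
#'   (NA = full sample).
#' @slot nPermutations,nBootstrap resampling sizes.
#' @slot seed master seed.
#' @slot bsrCutoff,minClusterVoxels,connectivity threshold spec fields.
#' @export
setClass("PipelineConfig",
  representation(
    scanPaths = "character",
    sdMapPaths = "character",
    subjectIds = "character",
    maskPath = "character",
    behaviorPath = "character",
    atlasPath = "character",
    atlasLabelsPath = "character",
    outDir = "character",
    metric = "character",
    normalize = "logical",
    adjust = "logical",
    subsampleAgeBelow = "numeric",
    nPermutations = "integer",
    nBootstrap = "integer",
    seed = "integer",
    bsrCutoff = "numeric",
    minClusterVoxels = "integer",
    connectivity = "integer"
  )
)

#' Construct a PipelineConfig
#'
#' @param scanPaths,sdMapPaths,subjectIds,maskPath,behaviorPath,atlasPath,atlasLabelsPath,outDir see [PipelineConfig-class].
#' @param metric,normalize,adjust,subsampleAgeBelow,nPermutations,nBootstrap,seed,bsrCutoff,minClusterVoxels,connectivity see [PipelineConfig-class].
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(scanPaths = character(0),
                           sdMapPaths = character(0),
                           subjectIds = character(0),
                           maskPath = character(0),
                           behaviorPath,
                           atlasPath = character(0),
                           atlasLabelsPath = character(0),
                           outDir = "boldvar-out",
                           metric = c("sd", "mssd"),
                           normalize = TRUE,
                           adjust = TRUE,
                           subsampleAgeBelow = NA_real_,
                           nPermutations = 1000L,
                           nBootstrap = 1000L,
                           seed = 1L,
                           bsrCutoff = 2.5,
                           minClusterVoxels = 15L,
                           connectivity = 26L) {
  metric <- match.arg(metric)
  if (!length(scanPaths) && !length(sdMapPaths))
    stop("supply scanPaths or sdMapPaths")
  if (!length(subjectIds))
    subjectIds <- sub("(_sd|_mssd)?\\.nii(\\.gz)?$", "",
                      basename(if (length(scanPaths)) scanPaths
                               else sdMapPaths))
  new("PipelineConfig", scanPaths = scanPaths, sdMapPaths = sdMapPaths,
      subjectIds = subjectIds, maskPath = maskPath,
      behaviorPath = behaviorPath, atlasPath = atlasPath,
      atlasLabelsPath = atlasLabelsPath, outDir = outDir, metric = metric,
      normalize = normalize, adjust = adjust,
      subsampleAgeBelow = subsampleAgeBelow,
      nPermutations = as.integer(nPermutations),
      nBootstrap = as.integer(nBootstrap), seed = as.integer(seed),
      bsrCutoff = bsrCutoff, minClusterVoxels = as.integer(minClusterVoxels),
      connectivity = as.integer(connectivity))
}

#' Validate pipeline inputs
#'
#' Checks referenced files, grid/affine agreement across volumes, subject
#' alignment between imaging and behavior, value ranges (MEQ global scores
#' in 16-86, scan times in [0, 24)) and atlas label coverage. Fatal problems
#' and warnings are distinguished; nothing is thrown.
#'
#' @param config a [PipelineConfig-class].
#' @return data.frame with columns `level` ("fatal"/"warning"), `check`,
#'   `message`; zero rows when everything passes.
#' @export
validateInputs <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  rows <- list()
  add <- function(level, check, message)
    rows[[length(rows) + 1L]] <<- data.frame(level = level, check = check,
                                             message = message)
  paths <- c(config@scanPaths, config@sdMapPaths, config@maskPath,
             config@behaviorPath, config@atlasPath, config@atlasLabelsPath)
  for (p in paths)
    if (!file.exists(p)) add("fatal", "paths", sprintf("missing file: %s", p))
  beh <- NULL
  if (file.exists(config@behaviorPath %||% ""))
    beh <- tryCatch(readBehaviorTable(config@behaviorPath),
                    error = function(e) {
                      add("fatal", "behavior", conditionMessage(e))
                      NULL
                    })
  if (!is.null(beh)) {
    nImg <- max(length(config@scanPaths), length(config@sdMapPaths))
    missingBeh <- setdiff(config@subjectIds, beh@subjectId)
    if (length(missingBeh))
      add("fatal", "alignment",
          sprintf("subject(s) with imaging but no behavior row: %s",
                  paste(missingBeh, collapse = ", ")))
    m <- beh@measures
    if ("meq_global" %in% names(m) &&
        any(m$meq_global < 16 | m$meq_global > 86))
      add("fatal", "ranges", "meq_global outside [16, 86]")
    if ("scan_midpoint_time" %in% names(m) &&
        any(m$scan_midpoint_time < 0 | m$scan_midpoint_time >= 24))
      add("fatal", "ranges", "scan_midpoint_time outside [0, 24)")
    if (anyNA(m))
      add("fatal", "completeness", "behavior measures contain missing values")
  }
  vols <- c(config@scanPaths, config@sdMapPaths, config@maskPath,
            config@atlasPath)
  vols <- vols[file.exists(vols)]
  if (length(vols) > 1L) {
    hdr <- lapply(vols, function(p) {
      img <- RNifti::readNifti(p, volumes = 1L)
      list(dim = dim(img)[1:3], xf = unclass(RNifti::xform(img)))
    })
    ref <- hdr[[1L]]
    for (i in seq_along(hdr)[-1L]) {
      if (!identical(hdr[[i]]$dim, ref$dim))
        add("fatal", "grid", sprintf("grid mismatch: %s", vols[i]))
      else if (max(abs(hdr[[i]]$xf - ref$xf)) > 1e-4)
        add("fatal", "grid", sprintf("affine mismatch: %s", vols[i]))
    }
  }
  if (length(config@atlasPath) && length(config@atlasLabelsPath) &&
      all(file.exists(c(config@atlasPath, config@atlasLabelsPath)))) {
    atlas <- tryCatch(readAtlas(config@atlasPath, config@atlasLabelsPath),
                      error = function(e) {
                        add("fatal", "atlas", conditionMessage(e))
                        NULL
                      })
    if (!is.null(atlas)) {
      present <- setdiff(unique(as.vector(atlas@labels)), 0L)
      unmapped <- setdiff(present, atlas@lookup$label)
      if (length(unmapped))
        add("warning", "atlas",
            sprintf("unmapped parcel label(s): %s",
                    paste(sort(unmapped), collapse = ", ")))
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(level = character(0), check = character(0),
               message = character(0))
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Run the full analysis pipeline
#'
#' Executes the stages in order — variability maps (when 4D scans are given),
#' stacking onto the common mask, confound residualization, behavior-block
#' assembly, behavioral PLS, thresholded reporting — and writes the result
#' tables, BSR and significance-mask volumes and a provenance manifest under
#' `outDir`. With `subsampleAgeBelow` set, only subjects strictly younger
#' than the threshold enter the analysis (pair with `adjust = FALSE` to
#' reproduce the unadjusted younger-subsample convention).
#'
#' @param config a [PipelineConfig-class].
#' @return Invisibly, a list with the [PLSResult-class], the report list
#'   from [lvReport()] and the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(is(config, "PipelineConfig"))
  report <- validateInputs(config)
  fatal <- report[report$level == "fatal", , drop = FALSE]
  if (nrow(fatal))
    stop("input validation failed:\n  ",
         paste(sprintf("[%s] %s", fatal$check, fatal$message),
               collapse = "\n  "))
  dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
  log <- function(fmt, ...) message(sprintf(paste0("[boldvar] ", fmt), ...))

  studyMask <- NULL
  if (length(config@maskPath)) {
    m <- RNifti::readNifti(config@maskPath)
    studyMask <- array(as.numeric(m) != 0, dim(m))
  }
  if (length(config@scanPaths)) {
    log("variability stage: %d scans, metric %s", length(config@scanPaths),
        config@metric)
    maps <- lapply(seq_along(config@scanPaths), function(i) {
      scan <- readSubjectScan(config@scanPaths[i],
                              subjectId = config@subjectIds[i])
      if (config@normalize) scan <- normalizeGrandMean(scan)
      if (config@metric == "sd") computeSDMap(scan) else
        computeMSSDMap(scan)
    })
  } else {
    log("loading %d precomputed SD maps", length(config@sdMapPaths))
    maps <- lapply(seq_along(config@sdMapPaths), function(i)
      readSDMap(config@sdMapPaths[i], subjectId = config@subjectIds[i],
                metric = config@metric))
  }
  sdm <- stackSDMaps(maps, commonMask = studyMask)
  log("stacked: %d subjects x %d voxels", nrow(sdm@values),
      ncol(sdm@values))

  behavior <- readBehaviorTable(config@behaviorPath)
  behavior <- subsetBehavior(behavior, rownames(sdm@values))

  if (!is.na(config@subsampleAgeBelow)) {
    keep <- behavior@confounds$age < config@subsampleAgeBelow
    log("subsample: %d of %d subjects below age %.1f", sum(keep),
        length(keep), config@subsampleAgeBelow)
    behavior <- subsetBehavior(behavior, which(keep))
    sdm <- subsetSubjects(sdm, which(keep))
  }

  blocks <- prepareBlocks(sdm, behavior, confoundSpec(),
                          adjust = config@adjust)
  log("confounds: adjust=%s", config@adjust)
  behBlock <- buildBehaviorBlock(blocks$behavior)

  result <- runBehavioralPLS(blocks$sd, behBlock,
                             nPermutations = config@nPermutations,
                             nBootstrap = config@nBootstrap,
                             seed = config@seed)
  log("PLS: LV1 covariance explained %.1f%%, p = %.4g, redrawn bootstraps %d",
      100 * covarianceExplained(result)[1], pValues(result)[1],
      result@bootstrap@nRedrawn)

  atlas <- NULL
  if (length(config@atlasPath) && length(config@atlasLabelsPath))
    atlas <- readAtlas(config@atlasPath, config@atlasLabelsPath)
  spec <- thresholdSpec(config@bsrCutoff, config@minClusterVoxels,
                        config@connectivity)
  rep1 <- lvReport(result, spec, atlas, lv = 1L, outDir = config@outDir)
  log("reporting: %d cluster(s), %d significant voxel(s)",
      nrow(rep1$clusters), sum(rep1$significanceMask))
  writeVolume(rep1$bsrVolume, result@affine,
              file.path(config@outDir, "bsr_lv1.nii.gz"))
  writeVolume(rep1$significanceMask, result@affine,
              file.path(config@outDir, "significance_mask_lv1.nii.gz"))

  manifest <- list(
    package = as.character(utils::packageVersion("boldvar")),
    config = list(
      metric = config@metric, normalize = config@normalize,
      adjust = config@adjust,
      subsampleAgeBelow = config@subsampleAgeBelow,
      nPermutations = config@nPermutations,
      nBootstrap = config@nBootstrap, seed = config@seed,
      bsrCutoff = config@bsrCutoff,
      minClusterVoxels = config@minClusterVoxels,
      connectivity = config@connectivity),
    counts = list(
      subjects = nrow(blocks$sd@values),
      voxels = ncol(blocks$sd@values),
      measures = ncol(behBlock),
      clusters = nrow(rep1$clusters),
      significantVoxels = sum(rep1$significanceMask),
      redrawnBootstraps = result@bootstrap@nRedrawn),
    seeds = result@provenance[c("seed", "permutationSeed", "bootstrapSeed")],
    inputChecksums = as.list(tools::md5sum(
      c(config@scanPaths, config@sdMapPaths, config@behaviorPath))))
  jsonlite::write_json(manifest, file.path(config@outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(result = result, report = rep1, manifest = manifest))
}
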