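#' Construct a SubjectScan
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param mask 3D logical array; defaults to all-TRUE.
#' @param affine 4x4 voxel-to-mm matrix; defaults to identity spacing.
#' @param subjectId subject identifier.
#' @return A [SubjectScan-class].
#' @export
subjectScan <- function(data, mask = NULL, affine = NULL,
                        subjectId = "subject") {
  data <- as.array(data)
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  if (is.null(affine)) affine <- diag(4)
  new("SubjectScan", data = data, mask = array(as.logical(mask), dim(mask)),
      affine = affine, subjectId = as.character(subjectId))
}

#' Grand-mean intensity normalization
#'
#' Rescales a 4D scan so that the mean intensity over all in-mask voxels and
#' all timepoints equals 100, the convention under which BOLD-SD values are
#' comparable across subjects and scanners. Out-of-mask voxels are left
#' untouched. The normalization is computed over the masked brain only:
#' including background air voxels would let the (near-zero) background drive
#' the scaling.
#'
#' @param scan a [SubjectScan-class].
#' @param target the target grand mean (default 100).
#' @return A [SubjectScan-class] with rescaled in-mask intensities.
#' @export
normalizeGrandMean <- function(scan, target = 100) {
  stopifnot(is(scan, "SubjectScan"))
  d <- dim(scan@data)
  nt <- d[4]
  mask4 <- array(scan@mask, dim = d)  # recycle mask across timepoints
  gm <- mean(scan@data[mask4])
  if (!is.finite(gm) || gm <= 0)
    stop("in-mask grand mean must be positive; got ", format(gm))
  out <- scan@data
  out[mask4] <- out[mask4] * (target / gm)
  initialize(scan, data = out)
}

# Reshape the 4D array into an (in-mask voxels) x t matrix.
.maskedTimeMatrix <- function(scan) {
  d <- dim(scan@data)
  m <- matrix(scan@data, nrow = prod(d[1:3]), ncol = d[4])
  m[as.vector(scan@mask), , drop = FALSE]
}

.newSDMap <- function(scan, inmaskValues, metric) {
  vals <- array(NA_real_, dim(scan@mask))
  vals[scan@mask] <- inmaskValues
  new("SDMap", values = vals, mask = scan@mask, affine = scan@affine,
      subjectId = scan@subjectId, metric = metric)
}

#' Per-voxel temporal standard deviation (BOLD-SD)
#'
#' For each in-mask voxel, subtracts the voxel's temporal mean and computes
#' the standard deviation across the time series. The sample (n - 1)
#' denominator is the default; the population denominator is available via
#' `denominator = "n"`.
#'
#' @param scan a [SubjectScan-class] (typically already grand-mean
#'   normalized; use [normalizeGrandMean()] first, or `normalize = TRUE`).
#' @param normalize if TRUE, apply [normalizeGrandMean()] internally first.
#' @param denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return An [SDMap-class] with `metric == "sd"`.
#' @export
computeSDMap <- function(scan, normalize = FALSE,
                         denominator = c("n-1", "n")) {
  stopifnot(is(scan, "SubjectScan"))
  denominator <- match.arg(denominator)
  if (dim(scan@data)[4] < 3L)
    stop("at least 3 timepoints are required to compute an SD map")
  if (normalize) scan <- normalizeGrandMean(scan)
  m <- .maskedTimeMatrix(scan)
  nt <- ncol(m)
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2)
  denom <- if (denominator == "n-1") nt - 1L else nt
  .newSDMap(scan, sqrt(ss / denom), "sd")
}

#' Per-voxel mean square successive difference (MSSD)
#'
#' The classical von Neumann statistic: the mean of squared differences
#' between consecutive timepoints, an alternative temporal-variability metric
#' that tracks SD closely on typical resting-state data. Reported as the raw
#' mean square (no halving, no square root).
#'
#' @inheritParams computeSDMap
#' @return An [SDMap-class] with `metric == "mssd"`.
#' @export
computeMSSDMap <- function(scan, normalize = FALSE) {
  stopifnot(is(scan, "SubjectScan"))
  if (dim(scan@data)[4] < 3L)
    stop("at least 3 timepoints are required to compute an MSSD map")
  if (normalize) scan <- normalizeGrandMean(scan)
  m <- .maskedTimeMatrix(scan)
  nt <- ncol(m)
  dm <- m[, -1L, drop = FALSE] - m[, -nt, drop = FALSE]
  .newSDMap(scan, rowMeans(dm^2), "mssd")
}

#' Stack per-subject variability maps into a subjects x voxels matrix
#'
#' Builds the brain block for PLS. All maps must share grid shape and affine;
#' the common mask must be contained in every subject's mask. Columns are
#' linearized in column-major (x fastest) voxel order, and the mapping from
#' column to grid/mm coordinates is recorded so maps can be reconstructed.
#'
#' @param maps list of [SDMap-class] objects (names ignored; subject ids are
#'   taken from the maps).
#' @param commonMask 3D logical array; defaults to the intersection of all
#'   subject masks.
#' @return An [SDMatrix-class].
#' @export
stackSDMaps <- function(maps, commonMask = NULL) {
  stopifnot(length(maps) >= 1L, all(vapply(maps, is, logical(1), "SDMap")))
  ref <- maps[[1L]]
  for (m in maps) {
    if (!identical(dim(m@values), dim(ref@values)))
      stop("all maps must share the same grid shape")
    if (max(abs(m@affine - ref@affine)) > 1e-6)
      stop("all maps must share the same affine")
  }
  if (is.null(commonMask)) {
    commonMask <- Reduce(`&`, lapply(maps, slot, "mask"))
  } else {
    commonMask <- array(as.logical(commonMask), dim(commonMask))
    if (!identical(dim(commonMask), dim(ref@values)))
      stop("commonMask grid shape does not match the maps")
    for (m in maps)
      if (any(commonMask & !m@mask))
        stop(sprintf("commonMask exceeds the mask of subject \"%s\"",
                     m@subjectId))
  }
  if (!any(commonMask)) stop("common mask is empty")
  sel <- which(as.vector(commonMask))
  d <- dim(commonMask)
  ijk <- arrayInd(sel, d)
  mm <- t(ref@affine %*% rbind(t(ijk) - 1, 1))[, 1:3, drop = FALSE]
  voxelIndex <- data.frame(column = seq_along(sel),
                           i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                           x = mm[, 1], y = mm[, 2], z = mm[, 3])
  vals <- t(vapply(maps, function(m) as.vector(m@values)[sel],
                   numeric(length(sel))))
  rownames(vals) <- vapply(maps, slot, character(1), "subjectId")
  new("SDMatrix", values = vals, voxelIndex = voxelIndex,
      gridShape = as.integer(d), affine = ref@affine)
}

#' Reconstruct one subject's SDMap from an SDMatrix row
#'
#' Inverse of [stackSDMaps()] for a single subject: values are written back to
#' their grid positions, all other voxels are NA.
#'
#' @param sdm an [SDMatrix-class].
#' @param subjectId which row to unstack.
#' @param metric metric label for the resulting map.
#' @return An [SDMap-class] masked to the common mask.
#' @export
unstackSDMap <- function(sdm, subjectId, metric = "sd") {
  stopifnot(is(sdm, "SDMatrix"))
  row <- match(subjectId, rownames(sdm@values))
  if (is.na(row)) stop(sprintf("subject \"%s\" not found", subjectId))
  vals <- array(NA_real_, sdm@gridShape)
  mask <- array(FALSE, sdm@gridShape)
  lin <- (sdm@voxelIndex$k - 1L) * sdm@gridShape[1] * sdm@gridShape[2] +
    (sdm@voxelIndex$j - 1L) * sdm@gridShape[1] + sdm@voxelIndex$i
  vals[lin] <- sdm@values[row, ]
  mask[lin] <- TRUE
  new("SDMap", values = vals, mask = mask, affine = sdm@affine,
      subjectId = subjectId, metric = metric)
}

#' Subset an SDMatrix by subject
#'
#' @param sdm an [SDMatrix-class].
#' @param keep subject ids (or a logical/integer row index) to retain.
#' @return An [SDMatrix-class] with the selected rows, voxel mapping intact.
#' @export
subsetSubjects <- function(sdm, keep) {
  stopifnot(is(sdm, "SDMatrix"))
  if (is.character(keep)) {
    idx <- match(keep, rownames(sdm@values))
    if (anyNA(idx))
      stop("unknown subject id(s): ",
           paste(keep[is.na(idx)], collapse = ", "))
  } else idx <- keep
  initialize(sdm, values = sdm@values[idx, , drop = FALSE])
}
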