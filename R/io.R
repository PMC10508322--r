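# NIfTI and table I/O. RNifti handles the NIfTI-1 format; this layer only
# moves data between files and the package's containers.

.setAffine <- function(img, affine) {
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  img
}

#' Read a 4D NIfTI scan into a SubjectScan
#'
#' @param path 4D NIfTI file.
#' @param maskPath optional 3D NIfTI mask (nonzero = in-brain); defaults to
#'   voxels with nonzero temporal SD.
#' @param subjectId subject identifier; defaults to the file name stem.
#' @return A [SubjectScan-class].
#' @export
readSubjectScan <- function(path, maskPath = NULL, subjectId = NULL) {
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  if (length(dim(data)) != 4L)
    stop(sprintf("\"%s\" is not a 4D volume", path))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    mask <- array(as.numeric(m) != 0, dim(m))
    if (!identical(dim(mask), dim(data)[1:3]))
      stop(sprintf("mask \"%s\" is not on the scan grid", maskPath))
  } else {
    nt <- dim(data)[4]
    flat <- matrix(data, ncol = nt)
    mask <- array(.rowVarNonzero(flat), dim(data)[1:3])
    if (!any(mask)) stop("derived mask is empty; supply a mask file")
  }
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  subjectScan(data, mask, affine, subjectId)
}

.rowVarNonzero <- function(flat) {
  mu <- rowMeans(flat)
  rowSums((flat - mu)^2) > 0
}

#' Read a 3D NIfTI variability map
#'
#' @param path 3D NIfTI file.
#' @param maskPath optional mask file; defaults to finite, nonzero voxels.
#' @param subjectId identifier; defaults to the file name stem.
#' @param metric metric label ("sd" or "mssd").
#' @return An [SDMap-class].
#' @export
readSDMap <- function(path, maskPath = NULL, subjectId = NULL,
                      metric = "sd") {
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img))
  if (length(dim(vals)) != 3L)
    stop(sprintf("\"%s\" is not a 3D volume", path))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!is.null(maskPath)) {
    m <- RNifti::readNifti(maskPath)
    mask <- array(as.numeric(m) != 0, dim(m))
  } else {
    mask <- is.finite(vals) & vals != 0
  }
  vals[!mask] <- NA_real_
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  new("SDMap", values = vals, mask = mask, affine = affine,
      subjectId = as.character(subjectId), metric = metric)
}

#' Write an SDMap (or any 3D array) as NIfTI
#'
#' Out-of-mask (NA) voxels are written as 0.
#'
#' @param map an [SDMap-class].
#' @param path output file (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeSDMap <- function(map, path) {
  stopifnot(is(map, "SDMap"))
  vals <- map@values
  vals[is.na(vals)] <- 0
  img <- .setAffine(RNifti::asNifti(vals), map@affine)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a SubjectScan as 4D NIfTI
#'
#' @param scan a [SubjectScan-class].
#' @param path output file.
#' @param maskPath optional path to also write the mask as a 3D volume.
#' @return `path`, invisibly.
#' @export
writeSubjectScan <- function(scan, path, maskPath = NULL) {
  stopifnot(is(scan, "SubjectScan"))
  img <- .setAffine(RNifti::asNifti(scan@data), scan@affine)
  RNifti::writeNifti(img, path)
  if (!is.null(maskPath)) {
    m <- .setAffine(RNifti::asNifti(array(as.numeric(scan@mask),
                                          dim(scan@mask))), scan@affine)
    RNifti::writeNifti(m, maskPath)
  }
  invisible(path)
}

#' Write a 3D volume (e.g. a BSR map or significance mask) as NIfTI
#'
#' @param values 3D numeric or logical array; NA written as 0.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(values, affine, path) {
  v <- array(as.numeric(values), dim(values))
  v[is.na(v)] <- 0
  v[is.infinite(v)] <- sign(v[is.infinite(v)]) * .Machine$double.xmax / 2
  img <- .setAffine(RNifti::asNifti(v), affine)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a parcellation atlas (NIfTI labels + TSV lookup)
#'
#' The lookup TSV must have columns `label`, `parcel_name`, `network_name`.
#'
#' @param labelsPath 3D integer NIfTI of parcel labels.
#' @param lookupPath TSV lookup table.
#' @return An [AtlasDefinition-class].
#' @export
readAtlas <- function(labelsPath, lookupPath) {
  img <- RNifti::readNifti(labelsPath)
  labels <- array(as.integer(round(as.numeric(img))), dim(img))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  lut <- utils::read.delim(lookupPath, stringsAsFactors = FALSE)
  need <- c("label", "parcel_name", "network_name")
  missing <- setdiff(need, names(lut))
  if (length(missing))
    stop("atlas lookup lacks column(s): ", paste(missing, collapse = ", "))
  atlasDefinition(labels,
                  data.frame(label = lut$label,
                             parcelName = lut$parcel_name,
                             networkName = lut$network_name),
                  affine)
}
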