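#' Construct a ThresholdSpec
#'
#' Defaults follow the reporting convention for bootstrap-ratio maps: a
#' cutoff of 2.5 on |BSR| and a minimum cluster extent of 15 voxels, with
#' 26-connectivity (vertex-adjacent) components.
#'
#' @param bsrCutoff positive |BSR| threshold.
#' @param minClusterVoxels minimum component size kept.
#' @param connectivity 6, 18 or 26.
#' @return A [ThresholdSpec-class].
#' @export
thresholdSpec <- function(bsrCutoff = 2.5, minClusterVoxels = 15L,
                          connectivity = 26L) {
  new("ThresholdSpec", bsrCutoff = as.numeric(bsrCutoff),
      minClusterVoxels = as.integer(minClusterVoxels),
      connectivity = as.integer(connectivity))
}

#' Construct an AtlasDefinition
#'
#' @param labels 3D integer array of parcel labels (0 = unassigned).
#' @param lookup data.frame with `label`, `parcelName`, `networkName`.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return An [AtlasDefinition-class].
#' @export
atlasDefinition <- function(labels, lookup, affine = diag(4)) {
  new("AtlasDefinition", labels = array(as.integer(labels), dim(labels)),
      lookup = lookup, affine = affine)
}

# Neighborhood offsets for 6/18/26 3D connectivity.
.neighborOffsets <- function(connectivity) {
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  manh <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6" = manh == 1, "18" = manh <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

# Label connected components of a 3D logical array by breadth-first search.
# Returns an integer array: 0 outside, component id inside. Component ids are
# assigned in scan order of their first voxel, so labeling is deterministic.
.labelComponents <- function(maskArr, connectivity = 26L) {
  d <- dim(maskArr)
  labels <- array(0L, d)
  inMask <- which(maskArr)
  if (!length(inMask)) return(labels)
  offsets <- .neighborOffsets(connectivity)
  nextLabel <- 0L
  queue <- integer(length(inMask))
  for (start in inMask) {
    if (labels[start] != 0L) next
    nextLabel <- nextLabel + 1L
    labels[start] <- nextLabel
    queue[1L] <- start
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      cur <- queue[head]
      head <- head + 1L
      ci <- arrayInd(cur, d)
      ni <- ci[1L] + offsets[, 1L]
      nj <- ci[2L] + offsets[, 2L]
      nk <- ci[3L] + offsets[, 3L]
      ok <- ni >= 1L & ni <= d[1L] & nj >= 1L & nj <= d[2L] &
        nk >= 1L & nk <= d[3L]
      lin <- (nk[ok] - 1L) * d[1L] * d[2L] + (nj[ok] - 1L) * d[1L] + ni[ok]
      lin <- lin[maskArr[lin] & labels[lin] == 0L]
      if (length(lin)) {
        labels[lin] <- nextLabel
        queue[(tail + 1L):(tail + length(lin))] <- lin
        tail <- tail + length(lin)
      }
    }
  }
  labels
}

#' Threshold a BSR map and extract clusters
#'
#' Voxels with `|BSR| >= bsrCutoff` are grouped into connected components
#' under the requested neighborhood, separately for positive and negative
#' signs (opposite-signed voxels never merge, because the sign encodes the
#' direction of the brain-behavior correlation). Components smaller than
#' `minClusterVoxels` are discarded. The cluster table reports, per retained
#' cluster, its size, sign, peak |BSR| voxel (grid indices and mm
#' coordinates) and peak BSR value, sorted by peak |BSR| descending.
#'
#' @param bsrMap 3D numeric array of bootstrap ratios (NA outside the
#'   analysis mask; `Inf` marks perfectly stable voxels and always survives
#'   thresholding).
#' @param spec a [ThresholdSpec-class].
#' @param affine 4x4 voxel-to-mm matrix for peak coordinates.
#' @return List with `mask` (3D logical significance mask) and `clusters`
#'   (data.frame: `cluster`, `sign`, `size`, `peakBSR`, `i`, `j`, `k`, `x`,
#'   `y`, `z`).
#' @export
thresholdAndCluster <- function(bsrMap, spec = thresholdSpec(),
                                affine = diag(4)) {
  stopifnot(is(spec, "ThresholdSpec"), length(dim(bsrMap)) == 3L)
  if (any(is.nan(bsrMap)))
    stop("BSR map contains NaN values")
  d <- dim(bsrMap)
  vals <- bsrMap
  vals[is.na(vals)] <- 0
  rows <- list()
  outMask <- array(FALSE, d)
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) vals >= spec@bsrCutoff else vals <= -spec@bsrCutoff
    labels <- .labelComponents(supra, spec@connectivity)
    if (!max(labels)) next
    sizes <- tabulate(labels[labels > 0L])
    for (id in which(sizes >= spec@minClusterVoxels)) {
      vox <- which(labels == id)
      outMask[vox] <- TRUE
      absVals <- abs(vals[vox])
      peak <- vox[which.max(absVals)]  # ties: lowest linear index
      pc <- arrayInd(peak, d)
      mm <- as.vector(affine %*% c(pc - 1L, 1))[1:3]
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "+" else "-",
        size = sizes[id], peakBSR = vals[peak],
        i = pc[1L], j = pc[2L], k = pc[3L],
        x = mm[1L], y = mm[2L], z = mm[3L])
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sign = character(0), size = integer(0),
               peakBSR = numeric(0), i = integer(0), j = integer(0),
               k = integer(0), x = numeric(0), y = numeric(0),
               z = numeric(0))
  if (nrow(clusters)) {
    ord <- order(-abs(clusters$peakBSR), -clusters$size,
                 clusters$i, clusters$j, clusters$k)
    clusters <- clusters[ord, , drop = FALSE]
    rownames(clusters) <- NULL
  }
  clusters <- cbind(cluster = seq_len(nrow(clusters)), clusters)
  list(mask = outMask, clusters = clusters)
}

#' Per-network contribution of significant voxels
#'
#' Overlays a significance mask on a parcellation atlas and reports, per
#' network/region group, the number of significant voxels falling in it, the
#' network's total voxel count and their ratio. Voxels outside the atlas
#' (label 0 or unmapped) are unassigned and do not contribute to any
#' network.
#'
#' @param mask 3D logical significance mask.
#' @param atlas an [AtlasDefinition-class] on the same grid.
#' @return data.frame with columns `network`, `nSignificant`, `nTotal`,
#'   `proportion`, one row per network in lookup order.
#' @export
networkContributions <- function(mask, atlas) {
  stopifnot(is(atlas, "AtlasDefinition"))
  if (!identical(dim(mask), dim(atlas@labels)))
    stop("significance mask and atlas are on different grids")
  networks <- unique(atlas@lookup$networkName)
  lab2net <- atlas@lookup$networkName[match(atlas@labels, atlas@lookup$label)]
  net <- factor(lab2net, levels = networks)  # NA: unassigned labels / 0
  nTotal <- as.integer(table(net))
  nSig <- as.integer(table(net[as.vector(mask)]))
  data.frame(network = networks, nSignificant = nSig, nTotal = nTotal,
             proportion = ifelse(nTotal > 0, nSig / nTotal, 0))
}

#' Assemble a latent-variable report
#'
#' Collects, for one LV of a [PLSResult-class]: the LV summary (singular
#' value, covariance explained, permutation p), the behavior correlations
#' with their bootstrap CIs — flagged robust when the interval excludes zero
#' — the thresholded cluster table and, if an atlas is supplied, the
#' per-network contribution table. Optionally writes each table as TSV under
#' `outDir`.
#'
#' @param result a [PLSResult-class].
#' @param spec a [ThresholdSpec-class].
#' @param atlas optional [AtlasDefinition-class].
#' @param lv which latent variable to report (default 1).
#' @param outDir optional output directory for TSV files.
#' @return List with `lvSummary`, `behaviorCorrelations`, `clusters`,
#'   `significanceMask` and (when an atlas is given) `networkContributions`.
#' @export
lvReport <- function(result, spec = thresholdSpec(), atlas = NULL,
                     lv = 1L, outDir = NULL) {
  stopifnot(is(result, "PLSResult"))
  dec <- result@decomposition
  boot <- result@bootstrap
  if (lv > length(dec@singularValues))
    stop("requested LV exceeds the decomposition rank")
  lvSummary <- data.frame(
    lv = seq_along(dec@singularValues),
    singularValue = dec@singularValues,
    covarianceExplained = dec@covarianceExplained,
    pValue = result@permutation@pValues)
  ciLow <- boot@correlationCILow[, lv]
  ciHigh <- boot@correlationCIHigh[, lv]
  behCor <- data.frame(
    measure = result@measureNames,
    correlation = boot@behaviorCorrelations[, lv],
    ciLow = ciLow, ciHigh = ciHigh,
    robust = ciLow > 0 | ciHigh < 0,
    direction = ifelse(ciLow > 0, "+", ifelse(ciHigh < 0, "-", "")))
  rownames(behCor) <- NULL
  bsrVol <- array(NA_real_, result@gridShape)
  lin <- (result@voxelIndex$k - 1L) * result@gridShape[1] *
    result@gridShape[2] +
    (result@voxelIndex$j - 1L) * result@gridShape[1] + result@voxelIndex$i
  bsrVol[lin] <- boot@bsr[, lv]
  tc <- thresholdAndCluster(bsrVol, spec, result@affine)
  out <- list(lvSummary = lvSummary, behaviorCorrelations = behCor,
              clusters = tc$clusters, significanceMask = tc$mask,
              bsrVolume = bsrVol)
  if (!is.null(atlas))
    out$networkContributions <- networkContributions(tc$mask, atlas)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name)
      utils::write.table(df, file.path(outDir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(lvSummary, "lv_summary.tsv")
    wt(behCor, sprintf("behavior_correlations_lv%d.tsv", lv))
    wt(tc$clusters, sprintf("clusters_lv%d.tsv", lv))
    if (!is.null(out$networkContributions))
      wt(out$networkContributions,
         sprintf("network_contributions_lv%d.tsv", lv))
  }
  out
}
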