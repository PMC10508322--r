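# Place a cuboid blob of given extent into an array.
addBlob <- function(arr, corner, size, value) {
  idx <- Map(function(c0, s) c0:(c0 + s - 1), corner, size)
  arr[idx[[1]], idx[[2]], idx[[3]]] <- value
  arr
}

test_that("cluster-extent filtering keeps 15-voxel blobs and drops 14-voxel ones", {
  d <- c(20, 20, 10)
  bsrMap <- array(0, d)
  bsrMap <- addBlob(bsrMap, c(2, 2, 2), c(3, 5, 1), 3)     # 15 voxels: kept
  bsrMap <- addBlob(bsrMap, c(10, 10, 5), c(2, 7, 1), 3)   # 14 voxels: dropped
  tc <- thresholdAndCluster(bsrMap, thresholdSpec())
  expect_identical(nrow(tc$clusters), 1L)
  expect_identical(tc$clusters$size, 15L)
  expect_identical(sum(tc$mask), 15L)

  # exactly at the cutoff counts as supra-threshold
  at <- array(0, c(6, 6, 6))
  at <- addBlob(at, c(1, 1, 1), c(4, 4, 1), 2.5)
  expect_identical(nrow(thresholdAndCluster(
    at, thresholdSpec(minClusterVoxels = 16))$clusters), 1L)

  empty <- thresholdAndCluster(array(0, c(5, 5, 5)), thresholdSpec())
  expect_identical(nrow(empty$clusters), 0L)
  expect_false(any(empty$mask))
})

test_that("clusters match the flood-fill oracle on known blobs and report peaks in mm", {
  d <- c(15, 15, 12)
  bsrMap <- array(0, d)
  bsrMap <- addBlob(bsrMap, c(1, 1, 1), c(3, 3, 2), 4)      # 18 voxels
  bsrMap <- addBlob(bsrMap, c(8, 8, 8), c(4, 4, 2), 3)      # 32 voxels
  bsrMap <- addBlob(bsrMap, c(1, 10, 1), c(5, 2, 2), -5)    # 20 voxels, negative
  bsrMap[9, 9, 9] <- 6  # peak inside the second blob
  affine <- diag(c(4, 4, 4, 1)); affine[1:3, 4] <- c(-30, -30, -24)
  tc <- thresholdAndCluster(bsrMap, thresholdSpec(minClusterVoxels = 10),
                            affine)
  expect_identical(nrow(tc$clusters), 3L)
  expect_identical(tc$clusters$size, c(32L, 20L, 18L))   # sorted by peak |BSR|
  expect_identical(tc$clusters$sign, c("+", "-", "+"))
  top <- tc$clusters[1, ]
  expect_identical(c(top$i, top$j, top$k), c(9L, 9L, 9L))
  expect_equal(c(top$x, top$y, top$z), c(4 * 8 - 30, 4 * 8 - 30, 4 * 8 - 24))

  oracleLabels <- oracleFloodFill(abs(bsrMap) >= 2.5, 26L)
  expect_identical(sort(tabulate(oracleLabels[oracleLabels > 0])),
                   sort(tc$clusters$size))
})

test_that("component labeling agrees with the oracle across random maps and connectivities", {
  set.seed(20)
  for (rep in 1:12) {
    conn <- sample(c(6L, 18L, 26L), 1)
    mask <- array(runif(8 * 8 * 8) < 0.25, c(8, 8, 8))
    got <- boldvar:::.labelComponents(mask, conn)
    want <- oracleFloodFill(mask, conn)
    expect_identical(componentSets(got), componentSets(want))
  }
})

test_that("thresholding is monotone and never merges opposite signs", {
  set.seed(21)
  bsrMap <- array(rnorm(10^3, sd = 2), c(10, 10, 10))
  spec1 <- thresholdSpec(bsrCutoff = 2, minClusterVoxels = 1)
  spec2 <- thresholdSpec(bsrCutoff = 3, minClusterVoxels = 1)
  n1 <- sum(thresholdAndCluster(bsrMap, spec1)$mask)
  n2 <- sum(thresholdAndCluster(bsrMap, spec2)$mask)
  expect_lte(n2, n1)

  touching <- array(0, c(8, 4, 4))
  touching <- addBlob(touching, c(1, 1, 1), c(3, 2, 2), 4)
  touching <- addBlob(touching, c(4, 1, 1), c(3, 2, 2), -4)
  tc <- thresholdAndCluster(touching, thresholdSpec(minClusterVoxels = 5))
  expect_identical(nrow(tc$clusters), 2L)
  expect_setequal(tc$clusters$sign, c("+", "-"))
})

test_that("network contributions are exact voxel-count ratios", {
  d <- c(12, 12, 12)
  labels <- array(0L, d)
  labels[1:6, , 1:6] <- 1L
  labels[7:12, , 1:6] <- 2L
  labels[1:6, , 7:12] <- 3L
  labels[7:12, , 7:12] <- 4L
  atlas <- atlasDefinition(labels, data.frame(
    label = 1:4, parcelName = paste0("p", 1:4),
    networkName = c("VIS", "SomMot", "DMN", "CON")))

  # a mask covering exactly network 3
  mask <- labels == 3L
  nc <- networkContributions(mask, atlas)
  expect_equal(nc$proportion, c(0, 0, 1, 0))

  expect_equal(networkContributions(array(FALSE, d), atlas)$proportion,
               rep(0, 4))

  # random mask vs hand counting
  set.seed(22)
  rmask <- array(runif(prod(d)) < 0.3, d)
  nc <- networkContributions(rmask, atlas)
  for (g in 1:4) {
    expect_identical(nc$nSignificant[g], sum(rmask & labels == g))
    expect_identical(nc$nTotal[g], sum(labels == g))
    expect_equal(nc$proportion[g], sum(rmask & labels == g) / sum(labels == g))
  }
  expect_lte(sum(nc$nSignificant), sum(rmask))

  expect_error(networkContributions(array(FALSE, c(5, 5, 5)), atlas),
               "grids")
})

test_that("LV reports flag robust correlations by CI sign and write tables", {
  cfg <- generatorConfig(nSubjects = 80, gridShape = c(6, 6, 6),
                         nBehaviors = 8, latentRank = 1, effectSize = 8,
                         seed = 23)
  ds <- generateDataset(cfg)
  blocks <- prepareBlocks(ds$sd, ds$behavior)
  res <- runBehavioralPLS(blocks$sd, buildBehaviorBlock(blocks$behavior),
                          nPermutations = 50, nBootstrap = 100, seed = 24)
  dir <- withr::local_tempdir()
  rep1 <- lvReport(res, thresholdSpec(minClusterVoxels = 5), lv = 1,
                   outDir = dir)
  bc <- rep1$behaviorCorrelations
  expect_identical(bc$robust, bc$ciLow > 0 | bc$ciHigh < 0)
  expect_identical(bc$direction[bc$ciLow > 0],
                   rep("+", sum(bc$ciLow > 0)))
  expect_identical(bc$direction[bc$ciHigh < 0],
                   rep("-", sum(bc$ciHigh < 0)))
  expect_true(all(file.exists(file.path(dir,
    c("lv_summary.tsv", "behavior_correlations_lv1.tsv",
      "clusters_lv1.tsv")))))
})
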