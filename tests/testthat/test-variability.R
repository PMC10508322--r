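test_that("grand-mean normalization fixes the in-mask mean at 100 and is scale invariant", {
  # hand example: 2 voxels x 2 timepoints, values 1..4, grand mean 2.5
  scan <- subjectScan(array(c(1, 2, 3, 4), c(2, 1, 1, 2)))
  norm <- normalizeGrandMean(scan)
  expect_equal(as.vector(norm@data), c(40, 80, 120, 160))

  scan <- makeScan(c(5, 4, 3), nt = 12, seed = 3)
  norm <- normalizeGrandMean(scan)
  expect_equal(mean(norm@data), 100)

  # scaling the input by any positive constant gives the identical output
  scaled <- initialize(scan, data = scan@data * 37.5)
  expect_equal(normalizeGrandMean(scaled)@data, norm@data)
})

test_that("normalization leaves out-of-mask voxels untouched and rejects non-positive means", {
  mask <- array(FALSE, c(4, 4, 4))
  mask[2:3, 2:3, 2:3] <- TRUE
  scan <- makeScan(c(4, 4, 4), nt = 10, seed = 5, mask = mask)
  norm <- normalizeGrandMean(scan)
  out4 <- !array(mask, dim(scan@data))
  expect_identical(norm@data[out4], scan@data[out4])
  m4 <- array(mask, dim(scan@data))
  expect_equal(mean(norm@data[m4]), 100)

  bad <- initialize(scan, data = scan@data - 1e4)
  expect_error(normalizeGrandMean(bad), "positive")
})

test_that("SD maps match closed forms and the two-pass oracle", {
  scan <- subjectScan(array(c(98, 100, 102), c(1, 1, 1, 3)))
  expect_equal(sdValues(computeSDMap(scan))[1, 1, 1], 2)
  expect_equal(sdValues(computeSDMap(scan, denominator = "n"))[1, 1, 1],
               sqrt(8 / 3))

  flat <- subjectScan(array(rep(7, 5), c(1, 1, 1, 5)))
  expect_equal(sdValues(computeSDMap(flat))[1, 1, 1], 0)

  scan <- makeScan(c(6, 6, 6), nt = 25, seed = 11)
  got <- sdValues(computeSDMap(scan))[scan@mask]
  expect_equal(got, oracleSDMap(scan@data, scan@mask), tolerance = 1e-12)

  # SD is invariant to adding a constant to a voxel's series
  shifted <- initialize(scan, data = scan@data + 123.4)
  expect_equal(sdValues(computeSDMap(shifted)), sdValues(computeSDMap(scan)),
               tolerance = 1e-10)
})

test_that("MSSD matches closed forms, the oracle, and E[MSSD] = 2 Var on iid data", {
  scan <- subjectScan(array(c(0, 1, 0, 1), c(1, 1, 1, 4)))
  expect_equal(sdValues(computeMSSDMap(scan))[1, 1, 1], 1)
  flat <- subjectScan(array(rep(3, 6), c(1, 1, 1, 6)))
  expect_equal(sdValues(computeMSSDMap(flat))[1, 1, 1], 0)

  scan <- makeScan(c(6, 6, 6), nt = 25, seed = 13)
  got <- sdValues(computeMSSDMap(scan))[scan@mask]
  expect_equal(got, oracleMSSDMap(scan@data, scan@mask), tolerance = 1e-12)

  # iid series: MSSD concentrates near twice the variance
  long <- makeScan(c(10, 10, 2), nt = 10000, seed = 17)
  ratio <- sdValues(computeMSSDMap(long))[long@mask] /
    sdValues(computeSDMap(long))[long@mask]^2
  expect_lt(max(abs(ratio - 2)), 0.1)
})

test_that("stacking SD maps preserves values, subject order and round-trips", {
  scans <- lapply(1:4, function(i) makeScan(c(5, 5, 3), nt = 15, seed = i))
  for (i in seq_along(scans)) scans[[i]]@subjectId <- sprintf("sub-%02d", i)
  maps <- lapply(scans, computeSDMap)
  sdm <- stackSDMaps(maps)
  expect_identical(subjectIds(sdm), sprintf("sub-%02d", 1:4))

  one <- stackSDMaps(maps[1])
  expect_equal(as.vector(sdValues(one)), sdValues(maps[[1]])[maps[[1]]@mask])

  # permuting the input order permutes rows; the voxel mapping is unchanged
  perm <- stackSDMaps(maps[c(3, 1, 4, 2)])
  expect_equal(sdValues(perm), sdValues(sdm)[c(3, 1, 4, 2), ])
  expect_identical(voxelIndex(perm), voxelIndex(sdm))

  # round-trip: unstacking reproduces each subject's masked map exactly
  for (i in seq_along(maps)) {
    back <- unstackSDMap(sdm, sprintf("sub-%02d", i))
    expect_equal(back@values[back@mask], maps[[i]]@values[maps[[i]]@mask])
  }
})

test_that("stacking rejects mismatched grids and masks outside subjects' masks", {
  mapA <- computeSDMap(makeScan(c(5, 5, 3), nt = 10, seed = 1))
  mapB <- computeSDMap(makeScan(c(4, 5, 3), nt = 10, seed = 2))
  expect_error(stackSDMaps(list(mapA, mapB)), "grid")

  smallMask <- array(FALSE, c(5, 5, 3)); smallMask[1:2, 1:2, 1] <- TRUE
  mapC <- computeSDMap(makeScan(c(5, 5, 3), nt = 10, seed = 3,
                                mask = smallMask))
  full <- array(TRUE, c(5, 5, 3))
  expect_error(stackSDMaps(list(mapC), commonMask = full), "exceeds")
  expect_error(stackSDMaps(list(mapA), commonMask = array(FALSE, c(5, 5, 3))),
               "empty")
})
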