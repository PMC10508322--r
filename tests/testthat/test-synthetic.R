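test_that("the generator is deterministic and validates its configuration", {
  cfg <- generatorConfig(nSubjects = 20, gridShape = c(4, 4, 4),
                         nBehaviors = 6, latentRank = 2, seed = 42)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(sdValues(a$sd), sdValues(b$sd))
  expect_identical(measures(a$behavior), measures(b$behavior))
  expect_identical(a$truth@latentScores, b$truth@latentScores)

  expect_error(generateDataset(
    generatorConfig(nSubjects = 10, gridShape = c(2, 2, 1),
                    nBehaviors = 3, latentRank = 5)), "latentRank")
  expect_error(generatorConfig(arCoefficient = 1), "ar")
})

test_that("planted truth satisfies its normalization contracts", {
  cfg <- generatorConfig(nSubjects = 40, gridShape = c(5, 5, 4),
                         nBehaviors = 8, latentRank = 3, seed = 9)
  tr <- generateDataset(cfg)$truth
  expect_equal(colMeans(tr@latentScores), rep(0, 3))
  expect_equal(apply(tr@latentScores, 2, sd), rep(1, 3))
  expect_equal(colSums(tr@voxelSaliencesTrue^2), rep(1, 3))
  expect_equal(colSums(tr@behaviorWeightsTrue^2), rep(1, 3))
})

test_that("with noise and confounds off the behavior block equals the planted low-rank structure exactly", {
  cfg <- generatorConfig(nSubjects = 25, gridShape = c(3, 3, 3),
                         nBehaviors = 5, latentRank = 2, effectSize = 2,
                         brainNoiseSD = 0, behaviorNoiseSD = 0, seed = 4)
  ds <- generateDataset(cfg)
  Y <- buildBehaviorBlock(ds$behavior)
  ZW <- ds$truth@latentScores %*% t(ds$truth@behaviorWeightsTrue)
  # behaviors live on the T-score scale, so the exact identity is the
  # documented affine image of Z W': 50 + effectSize * 10 * Z W'
  expect_identical(unname(Y), 50 + 2 * 10 * ZW)
})

test_that("confound contamination correlates raw behaviors with age and residualization removes it", {
  cfg <- generatorConfig(nSubjects = 120, gridShape = c(4, 4, 4),
                         nBehaviors = 6, latentRank = 0, effectSize = 0,
                         confoundStrengthAge = 0.05, seed = 21)
  ds <- generateDataset(cfg)
  Y <- buildBehaviorBlock(ds$behavior)
  age <- confounds(ds$behavior)$age
  rawCor <- as.vector(cor(age, Y))
  expect_gt(min(abs(rawCor)), 0.3)

  clean <- prepareBlocks(ds$sd, ds$behavior, adjust = TRUE)
  expect_lt(max(abs(cor(age, buildBehaviorBlock(clean$behavior)))), 1e-10)

  # without contamination the raw correlations hover near zero
  cfg0 <- generatorConfig(nSubjects = 120, gridShape = c(4, 4, 4),
                          nBehaviors = 6, latentRank = 0, effectSize = 0,
                          seed = 21)
  ds0 <- generateDataset(cfg0)
  Y0 <- buildBehaviorBlock(ds0$behavior)
  expect_lt(max(abs(cor(confounds(ds0$behavior)$age, Y0))), 0.25)
})

test_that("planted rank dominates the cross-block spectrum at strong effect size", {
  cfg <- generatorConfig(nSubjects = 150, gridShape = c(10, 10, 5),
                         nBehaviors = 10, latentRank = 2, effectSize = 20,
                         seed = 31)
  ds <- generateDataset(cfg)
  R <- crossBlockMatrix(sdValues(ds$sd), buildBehaviorBlock(ds$behavior),
                        mode = "covariance")
  s <- svd(R, nu = 0, nv = 0)$d
  expect_gt(s[1] / s[3], 3)
  expect_gt(s[2] / s[3], 3)
})

test_that("emitted time series hit the target SD exactly and carry the configured autocorrelation", {
  cfg <- generatorConfig(nSubjects = 3, gridShape = c(5, 5, 4),
                         nTimepoints = 80, nBehaviors = 4, latentRank = 1,
                         arCoefficient = 0.4, seed = 8)
  ds <- generateDataset(cfg)
  scans <- generateTimeseries(cfg, ds$truth, subjects = 1:2)
  for (i in 1:2) {
    got <- sdValues(computeSDMap(scans[[i]]))[scans[[i]]@mask]
    expect_equal(got, unname(ds$truth@targetSDMap[i, ]), tolerance = 1e-12)
  }

  # a zero target yields a constant series
  tr <- ds$truth
  tr@targetSDMap[1, 1] <- 0
  scan0 <- generateTimeseries(cfg, tr, subjects = 1)[[1]]
  expect_equal(sd(scan0@data[1, 1, 1, ]), 0)

  # lag-1 autocorrelation across many voxels averages near the AR coefficient
  cfgAC <- generatorConfig(nSubjects = 1, gridShape = c(10, 10, 10),
                           nTimepoints = 297, nBehaviors = 4, latentRank = 0,
                           arCoefficient = 0.4, seed = 12)
  dsAC <- generateDataset(cfgAC)
  scan <- generateTimeseries(cfgAC, dsAC$truth)[[1]]
  flat <- matrix(scan@data, ncol = 297)
  ac1 <- apply(flat, 1, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(abs(mean(ac1) - 0.4), 0.03)

  badCfg <- cfg
  badCfg@nTimepoints <- 2L
  expect_error(generateTimeseries(badCfg, ds$truth), "nTimepoints")
})

test_that("a synthetic dataset round-trips through disk", {
  cfg <- generatorConfig(nSubjects = 4, gridShape = c(4, 4, 3),
                         nBehaviors = 5, latentRank = 1, seed = 77)
  ds <- generateDataset(cfg)
  dir <- withr::local_tempdir()
  writeSyntheticDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "behavior.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  maps <- lapply(rownames(sdValues(ds$sd)), function(id)
    readSDMap(file.path(dir, paste0(id, "_sd.nii.gz")), subjectId = id))
  sdm <- stackSDMaps(maps)
  expect_equal(sdValues(sdm), sdValues(ds$sd), tolerance = 1e-6)
  beh <- readBehaviorTable(file.path(dir, "behavior.tsv"))
  expect_identical(subjectIds(beh), subjectIds(ds$behavior))
})
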