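test_that("cross-block entries are Pearson correlations and jointly permutation invariant", {
  set.seed(10)
  n <- 30
  brain <- matrix(rnorm(n * 40), n, 40,
                  dimnames = list(NULL, paste0("v", 1:40)))
  behavior <- matrix(rnorm(n * 5), n, 5,
                     dimnames = list(NULL, paste0("m", 1:5)))
  behavior[, 1] <- brain[, 7]  # identical columns correlate at exactly 1
  R <- crossBlockMatrix(brain, behavior)
  expect_equal(R[1, 7], 1)

  for (probe in 1:20) {
    b <- sample(5, 1); v <- sample(40, 1)
    expect_equal(R[b, v], cor(behavior[, b], brain[, v]), tolerance = 1e-12)
  }

  perm <- sample(n)
  expect_equal(crossBlockMatrix(brain[perm, ], behavior[perm, ]), R,
               tolerance = 1e-12)

  flat <- behavior; flat[, 3] <- 2
  expect_error(crossBlockMatrix(brain, flat), "m3")
})

test_that("the decomposition matches SVD identities and the eigen oracle", {
  expect_equal(singularValues(plsDecompose(matrix(0.6, 1, 1))), 0.6)
  expect_equal(covarianceExplained(plsDecompose(matrix(0.6, 1, 1))), 1)

  set.seed(11)
  R <- matrix(rnorm(10 * 200), 10, 200)
  dec <- plsDecompose(R)
  s <- singularValues(dec)
  expect_equal(sum(s^2), sum(R^2), tolerance = 1e-10)
  expect_equal(sum(covarianceExplained(dec)), 1, tolerance = 1e-12)

  # reconstruction and agreement with an independent eigendecomposition
  U <- behaviorSaliences(dec); V <- voxelSaliences(dec)
  expect_lt(max(abs(U %*% diag(s) %*% t(V) - R)), 1e-8)
  expect_equal(s, oracleSingularValues(R), tolerance = 1e-8)
  eigU <- eigen(R %*% t(R), symmetric = TRUE)$vectors
  for (k in 1:10)
    expect_equal(abs(sum(U[, k] * eigU[, k])), 1, tolerance = 1e-8)

  # the sign convention makes the largest behavior salience positive
  for (k in 1:10) expect_gt(U[which.max(abs(U[, k])), k], 0)
  expect_error(plsDecompose(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("brain scores project the standardized brain block onto voxel saliences", {
  set.seed(12)
  brain <- matrix(rnorm(25 * 30), 25, 30)
  behavior <- matrix(rnorm(25 * 4), 25, 4)
  dec <- plsDecompose(crossBlockMatrix(brain, behavior), brain = brain)
  Xz <- scale(brain)
  expect_equal(unname(brainScores(dec)),
               unname(Xz %*% voxelSaliences(dec)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("permutation p-values are deterministic, bounded and jointly invariant", {
  set.seed(13)
  brain <- matrix(rnorm(40 * 60), 40, 60)
  behavior <- matrix(rnorm(40 * 5), 40, 5)
  p1 <- permutationTest(brain, behavior, nPermutations = 99, seed = 5)
  p2 <- permutationTest(brain, behavior, nPermutations = 99, seed = 5)
  expect_identical(pValues(p1), pValues(p2))
  expect_true(all(pValues(p1) >= 1 / 100 & pValues(p1) <= 1))

  # jointly permuting the rows of both blocks leaves the observed singular
  # values exactly unchanged and the p-values unchanged up to Monte-Carlo
  # error of the permutation draw
  perm <- sample(40)
  brainP <- brain[perm, ]; behaviorP <- behavior[perm, ]
  expect_equal(svd(crossBlockMatrix(brainP, behaviorP), nu = 0, nv = 0)$d,
               svd(crossBlockMatrix(brain, behavior), nu = 0, nv = 0)$d,
               tolerance = 1e-10)
  p3 <- permutationTest(brainP, behaviorP, nPermutations = 999, seed = 5)
  p1L <- permutationTest(brain, behavior, nPermutations = 999, seed = 5)
  expect_lt(max(abs(pValues(p3) - pValues(p1L))), 0.08)
})

test_that("bootstrap output satisfies its structural contracts", {
  cfg <- generatorConfig(nSubjects = 60, gridShape = c(5, 5, 4),
                         nBehaviors = 6, latentRank = 1, effectSize = 8,
                         seed = 14)
  ds <- generateDataset(cfg)
  brain <- sdValues(ds$sd)
  behavior <- buildBehaviorBlock(ds$behavior)
  b1 <- bootstrapInference(brain, behavior, nBootstrap = 100, seed = 3)
  b2 <- bootstrapInference(brain, behavior, nBootstrap = 100, seed = 3)
  expect_identical(bsr(b1), bsr(b2))
  ci <- correlationCI(b1)
  expect_true(all(ci$low <= ci$high + 1e-12))

  # BSR carries the sign of the original salience wherever defined
  V <- voxelSaliences(plsDecompose(crossBlockMatrix(brain, behavior),
                                   brain = brain))
  defined <- is.finite(bsr(b1)) & abs(V) > 0 & b1@salienceSE > 0
  expect_true(all(sign(bsr(b1)[defined]) == sign(V[defined])))
})

test_that("noise-free planted structure yields the flagged stable sentinel, not overflow", {
  cfg <- generatorConfig(nSubjects = 40, gridShape = c(3, 3, 3),
                         nBehaviors = 4, latentRank = 1, effectSize = 4,
                         signalVoxelFraction = 1, brainNoiseSD = 0,
                         behaviorNoiseSD = 0, seed = 15)
  ds <- generateDataset(cfg)
  b <- bootstrapInference(sdValues(ds$sd), buildBehaviorBlock(ds$behavior),
                          nBootstrap = 50, seed = 4, mode = "covariance")
  sal <- ds$truth@voxelSaliencesTrue[, 1]
  expect_true(all(b@stableMask[abs(sal) > 0, 1]))
  expect_true(all(is.infinite(bsr(b)[abs(sal) > 0, 1])))
  expect_false(any(is.nan(bsr(b))))
})

test_that("percentile CIs of a planted-zero behavior weight cover zero at the nominal rate", {
  # 40 replicate datasets; behavior 1 carries no planted weight
  W <- matrix(c(0, rep(1, 5)), 6, 1)
  covered <- 0L
  for (i in 1:40) {
    cfg <- generatorConfig(nSubjects = 60, gridShape = c(4, 4, 4),
                           nBehaviors = 6, latentRank = 1, effectSize = 3,
                           seed = 500 + i)
    ds <- generateDataset(cfg, behaviorWeights = W)
    b <- bootstrapInference(sdValues(ds$sd),
                            buildBehaviorBlock(ds$behavior),
                            nBootstrap = 200, seed = 600 + i)
    covered <- covered + (b@correlationCILow[1, 1] <= 0 &&
                            b@correlationCIHigh[1, 1] >= 0)
  }
  # binomial(40, 0.95) leaves coverage above 34/40 with high probability
  expect_gte(covered, 34L)
})

test_that("the orchestrated analysis recovers planted sign patterns and is monotone in effect size", {
  # plant positive weights on "positive socioemotional" measures and a
  # negative weight on the gF-like measure, as in a correlation panel
  W <- matrix(c(-1, 0, rep(0.8, 7), rep(-0.6, 10), 0.9, 0, 0), 22, 1)
  cfg <- generatorConfig(nSubjects = 150, gridShape = c(8, 8, 8),
                         nBehaviors = 22, latentRank = 1, effectSize = 10,
                         seed = 16)
  ds <- generateDataset(cfg, behaviorWeights = W)
  blocks <- prepareBlocks(ds$sd, ds$behavior)
  res <- runBehavioralPLS(blocks$sd, buildBehaviorBlock(blocks$behavior),
                          nPermutations = 100, nBootstrap = 100, seed = 17)
  u <- behaviorSaliences(res)[, 1]
  wTrue <- ds$truth@behaviorWeightsTrue[, 1]
  if (cor(u, wTrue) < 0) u <- -u  # overall reflection is unidentified
  nz <- abs(wTrue) > 0
  expect_true(all(sign(u[nz]) == sign(wTrue[nz])))

  # same seed, growing effect size: LV1 covariance explained never drops
  ce <- vapply(c(0.5, 2, 8), function(es) {
    d <- generateDataset(generatorConfig(nSubjects = 80,
                                         gridShape = c(5, 5, 4),
                                         nBehaviors = 8, latentRank = 1,
                                         effectSize = es, seed = 18))
    covarianceExplained(plsDecompose(
      crossBlockMatrix(sdValues(d$sd), buildBehaviorBlock(d$behavior))))[1]
  }, numeric(1))
  expect_true(all(diff(ce) >= 0))

  # identical seeds reproduce the full result bit for bit
  res2 <- runBehavioralPLS(blocks$sd, buildBehaviorBlock(blocks$behavior),
                           nPermutations = 100, nBootstrap = 100, seed = 17)
  expect_identical(bsr(res), bsr(res2))
  expect_identical(pValues(res), pValues(res2))
})
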