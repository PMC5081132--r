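test_that("base expressions reject empty feature sets and are seed-reproducible", {
  expect_error(sampleBaseExpressions(0), "p must be")
  set.seed(11); a <- sampleBaseExpressions(5)
  set.seed(11); b <- sampleBaseExpressions(5)
  expect_identical(a, b)
})

test_that("base expression sample moments match the surrogate distribution", {
  set.seed(2)
  mu <- sampleBaseExpressions(1e4)
  mom <- classiSim:::.baseExpressionMoments()
  se <- mom["sd"] / sqrt(1e4)
  expect_lt(abs(mean(mu) - mom["mean"]), 3 * se)
  # SD of the sample SD ~ sd / sqrt(2 (n - 1))
  expect_lt(abs(sd(mu) - mom["sd"]), 3 * mom["sd"] / sqrt(2 * (1e4 - 1)))
  expect_true(all(mu >= 2 & mu <= 14))
})

test_that("replicate averaging yields marginal variance sigmaB^2 + sigmaE^2 / r", {
  set.seed(3)
  cfg <- SimConfig(n = 1e4, p = 3, sigmaB = 2.5, sigmaE = 1.5, r = 3,
                   corrKind = "independent", seed = 1)
  mu <- c(5, 7, 9)
  X <- simulateReplicateAverage(cfg, mu)
  v <- 2.5^2 + 1.5^2 / 3  # = 7.0
  # MC-SE of a sample variance ~ v * sqrt(2 / (n - 1))
  seVar <- v * sqrt(2 / (1e4 - 1))
  for (j in 1:3) {
    expect_lt(abs(var(X[, j]) - v), 3 * seVar)
    expect_lt(abs(mean(X[, j]) - mu[j]), 3 * sqrt(v / 1e4))
  }
})

test_that("replicate averaging: noiseless limit and monotone variance in r", {
  cfg <- noiselessConfig(n = 10, p = 4)
  mu <- c(2, 4, 6, 8)
  set.seed(1)
  X <- simulateReplicateAverage(cfg, mu)
  expect_lt(max(abs(sweep(X, 2, mu))), 1e-6)

  mkcfg <- function(r) SimConfig(n = 2000, p = 1, sigmaB = 1, sigmaE = 2,
                                 r = r, corrKind = "independent", seed = 1)
  set.seed(7); v1 <- var(simulateReplicateAverage(mkcfg(1), 5)[, 1])
  set.seed(7); v100 <- var(simulateReplicateAverage(mkcfg(100), 5)[, 1])
  expect_gt(v1, v100)

  badcfg <- cfg
  expect_error(SimConfig(n = 10, p = 4, sigmaB = 0, sigmaE = 1), "sigmaB")
})

test_that("block partition follows the floor/remainder rule", {
  expect_identical(makeBlockPartition(4), 4L)           # H forced to 1 for p < 5
  expect_identical(makeBlockPartition(25, H = 4), c(7L, 6L, 6L, 6L))
  expect_identical(makeBlockPartition(25, H = 5), rep(5L, 5))
  expect_error(makeBlockPartition(0), "p must be")
  # property: random H in range, sizes sum to p
  set.seed(42)
  for (p in c(5L, 11L, 30L, 100L)) {
    for (i in 1:20) {
      s <- makeBlockPartition(p)
      expect_equal(sum(s), p)
      expect_lte(length(s), max(1L, p %/% 3L))
      expect_true(all(s >= 1L))
    }
  }
})

test_that("hub-Toeplitz block has the decreasing correlation sequence", {
  R <- hubToeplitzBlock(5, 0.7, 0.3, nu = 1)
  expect_equal(R[1, 2:5], c(0.7, 0.7 - 0.4 / 3, 0.7 - 0.8 / 3, 0.3),
               tolerance = 1e-12)
  expect_true(isSymmetric(R))
  expect_equal(diag(R), rep(1, 5))
  # Toeplitz: constant along diagonals
  expect_equal(R[2, 3], R[1, 2])
  expect_equal(R[2, 4], R[1, 3])
  # degenerate cases
  expect_equal(hubToeplitzBlock(2, 0.7, 0.3)[1, 2], 0.7)
  expect_equal(hubToeplitzBlock(1, 0.7, 0.3), matrix(1, 1, 1))
  expect_error(hubToeplitzBlock(0, 0.7, 0.3), "d must be")
  expect_error(hubToeplitzBlock(3, 0.3, 0.7), "rhoMin")
})

test_that("assembled correlation: identity, exchangeable and block-diagonal forms", {
  cfgI <- SimConfig(n = 10, p = 3, corrKind = "independent", seed = 1)
  cm <- assembleCorrelation(cfgI)
  expect_equal(cm@R, diag(3))
  expect_false(cm@pdRepaired)

  cfgE <- SimConfig(n = 10, p = 4, corrKind = "exchangeable_single_block",
                    rhoFixed = 0.6, seed = 1)
  cmE <- assembleCorrelation(cfgE)
  ev <- eigen(cmE@R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(min(ev), 1 - 0.6, tolerance = 1e-12)
  expect_equal(max(ev), 1 + 3 * 0.6, tolerance = 1e-12)
  expect_error(SimConfig(n = 10, p = 4, corrKind = "exchangeable_single_block",
                         seed = 1), "rhoFixed")
  expect_error(SimConfig(n = 10, p = 4, corrKind = "exchangeable_single_block",
                         rhoFixed = 1.2, seed = 1), "positive-definite")

  cfgH <- SimConfig(n = 10, p = 25, seed = 5)
  set.seed(5)
  cmH <- assembleCorrelation(cfgH)
  expect_equal(sum(cmH@blockSizes), 25L)
  # off-block entries exactly zero; first row of each block matches the
  # recorded rho sequence
  at <- 0L
  for (h in seq_along(cmH@blockSizes)) {
    d <- cmH@blockSizes[h]
    idx <- at + seq_len(d)
    if (at > 0) expect_true(all(cmH@R[idx, seq_len(at)] == 0))
    if (d > 1) expect_equal(cmH@R[at + 1L, idx[-1]], cmH@rhoSequences[[h]])
    at <- at + d
  }
  expect_gt(min(eigen(cmH@R, symmetric = TRUE, only.values = TRUE)$values),
            1e-10)
})

test_that("correlation imposition preserves means/variances and hits the target", {
  # identity: exact pass-through
  set.seed(8)
  X <- matrix(rnorm(50 * 4, 3, 2), 50, 4)
  expect_identical(imposeCorrelation(X, rep(3, 4), 4, diag(4)), X)

  # p = 2 exchangeable rho = 0.7 Monte-Carlo check
  n <- 1e5; v <- 7; mu <- c(8, 10); rho <- 0.7
  R <- matrix(c(1, rho, rho, 1), 2)
  set.seed(9)
  X <- cbind(rnorm(n, mu[1], sqrt(v)), rnorm(n, mu[2], sqrt(v)))
  Y <- imposeCorrelation(X, mu, v, R)
  seCor <- (1 - rho^2) / sqrt(n)
  expect_lt(abs(cor(Y[, 1], Y[, 2]) - rho), 3 * seCor)
  seVar <- v * sqrt(2 / (n - 1))
  expect_lt(abs(var(Y[, 1]) - v), 3 * seVar)
  expect_lt(abs(var(Y[, 2]) - v), 3 * seVar)
  for (j in 1:2) expect_lt(abs(mean(Y[, j]) - mu[j]), 3 * sqrt(v / n))
})

test_that("truncated-normal mean matches the closed forms and the integral oracle", {
  expect_equal(truncnormMean(0, 1), sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(truncnormMean(1, 1), truncMeanByIntegration(1, 1),
               tolerance = 1e-8)
  # scale equivariance
  expect_equal(truncnormMean(1, 2), 2 * truncnormMean(0.5, 1),
               tolerance = 1e-12)
  expect_equal(averageFoldChange(2, 1), 2^truncnormMean(1, 1),
               tolerance = 1e-12)
  expect_error(truncnormMean(-0.1, 1), "alpha")
})

test_that("effect-size sampler honours truncation, ordering and its mean", {
  set.seed(12)
  em <- sampleEffectSizes(5, thetaMin = 2)
  expect_true(all(em@delta >= 1))
  expect_false(is.unsorted(rev(em@delta)))
  expect_true(all(em@z %in% c(-1L, 1L)))

  set.seed(13)
  big <- sampleEffectSizes(1e5, thetaMin = 2, tau = 1)
  target <- truncMeanByIntegration(1, 1)  # ~ 1.5251
  se <- sd(big@delta) / sqrt(1e5)
  expect_lt(abs(mean(big@delta) - target), 3 * se)

  set.seed(14)
  half <- sampleEffectSizes(1e5, thetaMin = 1, tau = 1)  # alpha = 0
  expect_lt(abs(mean(half@delta) - sqrt(2 / pi)),
            3 * sd(half@delta) / sqrt(1e5))
  expect_error(sampleEffectSizes(5, thetaMin = 0.5), "thetaMin")
})

test_that("group-effect injection shifts only G2 by z * delta", {
  em <- new("EffectModel", alpha = 0, tau = 1, delta = c(1, 1),
            z = c(1L, -1L))
  lab <- injectGroupEffect(matrix(0, 4, 2), em, n1 = 2)
  expect_equal(lab$X[1:2, ], matrix(0, 2, 2))
  expect_equal(lab$X[3:4, ], matrix(rep(c(1, -1), each = 2), 2, 2))
  expect_equal(as.character(lab$y), c("G1", "G1", "G2", "G2"))
  expect_error(injectGroupEffect(matrix(0, 4, 3), em, 2), "length|columns|match")

  # n = 61 convention: 30 / 31 split
  cfg <- SimConfig(n = 61, p = 3, seed = 2)
  ds <- simulateDataset(cfg)
  expect_equal(as.vector(table(groupLabels(ds))), c(30, 31))

  # Monte-Carlo recovery of the injected effect
  set.seed(15)
  n <- 1e4
  em2 <- new("EffectModel", alpha = 0, tau = 1, delta = c(2, 1.5),
             z = c(-1L, 1L))
  noise <- matrix(rnorm(n * 2), n, 2)
  lab2 <- injectGroupEffect(noise, em2, n1 = n %/% 2)
  dHat <- colMeans(lab2$X[lab2$y == "G2", ]) - colMeans(lab2$X[lab2$y == "G1", ])
  se <- sqrt(4 / n)  # var 1 in each group, n/2 per group
  expect_lt(abs(dHat[1] - (-2)), 3 * se)
  expect_lt(abs(dHat[2] - 1.5), 3 * se)
})

test_that("simulateDataset is reproducible and respects the noiseless limit", {
  cfg <- SimConfig(n = 100, p = 10, sigmaB = 2.5, sigmaE = 1.5, thetaMin = 2,
                   r = 3, seed = 21)
  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(datasetMatrix(d1), datasetMatrix(d2))
  expect_identical(effectModel(d1)@delta, effectModel(d2)@delta)
  expect_identical(correlationModel(d1)@blockSizes,
                   correlationModel(d2)@blockSizes)
  expect_equal(as.vector(table(groupLabels(d1))), c(50, 50))
  expect_equal(dim(datasetMatrix(d1)), c(100L, 10L))
  expect_equal(marginalVariance(d1), 2.5^2 + 1.5^2 / 3)

  nl <- simulateDataset(noiselessConfig(n = 8, p = 5, seed = 3))
  X <- datasetMatrix(nl); y <- groupLabels(nl); em <- effectModel(nl)
  expect_lt(max(abs(sweep(X[y == "G1", ], 2, X[1, ]))), 1e-6)
  gap <- colMeans(X[y == "G2", ]) - colMeans(X[y == "G1", ])
  expect_lt(max(abs(gap - em@z * em@delta)), 1e-6)
})

test_that("poisson variant: marginal moments, integer support, copula correlation", {
  cfg <- SimConfig(n = 1e4, p = 2, family = "poisson", lambdaRate = 4,
                   corrKind = "independent", seed = 31)
  ds <- simulatePoissonDataset(cfg)
  X <- datasetMatrix(ds); y <- groupLabels(ds)
  # G1 rows are untouched by injection: marginally Poisson(4)
  X1 <- X[y == "G1", ]
  expect_true(all(X1 == floor(X1) & X1 >= 0))
  n1 <- nrow(X1)
  for (j in 1:2) {
    expect_lt(abs(mean(X1[, j]) - 4), 3 * sqrt(4 / n1))
    expect_lt(abs(var(X1[, j]) - 4), 3 * 4 * sqrt(2 / (n1 - 1)))
  }

  # copula-imposed correlation close to the in-package NORTA oracle
  cfg2 <- SimConfig(n = 1e5, p = 2, family = "poisson", lambdaRate = 4,
                    corrKind = "exchangeable_single_block", rhoFixed = 0.7,
                    seed = 32)
  ds2 <- simulatePoissonDataset(cfg2)
  X2 <- datasetMatrix(ds2); y2 <- groupLabels(ds2)
  emp <- cor(X2[y2 == "G1", 1], X2[y2 == "G1", 2])
  target <- poissonCopulaCorrelation(0.7, 4)
  expect_lt(target, 0.7)           # attenuation
  expect_gt(target, 0.6)
  expect_lt(abs(emp - target), 0.05)
  expect_error(SimConfig(n = 10, p = 2, family = "poisson", lambdaRate = 0),
               "lambdaRate")
})

test_that("simulated correlation structure is recovered empirically", {
  rho <- 0.5
  cfg <- SimConfig(n = 1e5, p = 3, corrKind = "exchangeable_single_block",
                   rhoFixed = rho, thetaMin = 1.0001, seed = 41)
  ds <- simulateDataset(cfg)
  X <- datasetMatrix(ds); y <- groupLabels(ds)
  # remove the group effect, then compare empirical correlation to R
  em <- effectModel(ds)
  X[y == "G2", ] <- sweep(X[y == "G2", ], 2, em@z * em@delta)
  emp <- cor(X)
  expect_lt(max(abs(emp - correlationModel(ds)@R)), 0.02)
})

test_that("dataset writer/reader round-trips data and metadata", {
  cfg <- SimConfig(n = 12, p = 4, seed = 77)
  ds <- simulateDataset(cfg)
  path <- tempfile(fileext = ".tsv")
  writeDataset(ds, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- readDataset(path)
  expect_equal(datasetMatrix(back), datasetMatrix(ds), tolerance = 1e-12)
  expect_identical(as.character(groupLabels(back)), as.character(groupLabels(ds)))
  expect_equal(effectModel(back)@delta, effectModel(ds)@delta, tolerance = 1e-12)
  expect_equal(simConfig(back)@sigmaB, cfg@sigmaB)
})
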