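test_that("rf grid: sampled mtry includes the default, full Cartesian product", {
  set.seed(1)
  g <- buildRfGrid(100)
  expect_equal(length(g$candidates), 5 * 5 * 4)
  mtry <- sort(unique(vapply(g$candidates, `[[`, 0, "mtry")))
  expect_equal(length(mtry), 5L)
  expect_true(all(mtry >= 1 & mtry <= 50))
  expect_true(10 %in% mtry)  # floor(sqrt(100)), the classification default

  g6 <- buildRfGrid(6)   # floor(p/2) = 3 < 5 elements -> the whole sequence
  expect_equal(sort(unique(vapply(g6$candidates, `[[`, 0, "mtry"))), 1:3)
  g1 <- buildRfGrid(1)
  expect_equal(unique(vapply(g1$candidates, `[[`, 0, "mtry")), 1L)
})

test_that("svm grid spans (d/10, 10d) around the defaults", {
  g <- buildSvmGrid(100)
  expect_equal(length(g$candidates), 25L)
  costs <- sort(unique(vapply(g$candidates, `[[`, 0, "cost")))
  gammas <- sort(unique(vapply(g$candidates, `[[`, 0, "gamma")))
  expect_equal(range(costs), c(0.1, 10))
  expect_true(all(gammas >= 0.001 & gammas <= 0.1))
  # contains the default pair (cost = 1, gamma = 1/p)
  hasDefault <- any(vapply(g$candidates, function(c)
    isTRUE(all.equal(c$cost, 1)) && isTRUE(all.equal(c$gamma, 0.01)), TRUE))
  expect_true(hasDefault)

  g1 <- buildSvmGrid(1)
  gam1 <- sort(unique(vapply(g1$candidates, `[[`, 0, "gamma")))
  expect_equal(range(gam1), c(0.1, 10))
  expect_true(1 %in% gam1)
})

test_that("knn grid caps k at the training-fold size", {
  expect_equal(max(vapply(buildKnnGrid(10)$candidates, `[[`, 0, "k")), 9L)
  expect_equal(vapply(buildKnnGrid(2)$candidates, `[[`, 0, "k"), 1L)
  expect_equal(max(vapply(buildKnnGrid(100)$candidates, `[[`, 0, "k")), 90L)
})

test_that("tune returns grid members, the argmin, and beats-or-ties the default", {
  sep <- separableXY(n = 30, p = 4)

  # single candidate
  g1 <- classiSim:::.newGrid("knn", list(list(k = 3)))
  set.seed(5)
  tp <- tuneParams("knn", sep, grid = g1)
  expect_equal(tp@params$k, 3)

  # separable data: zero CV error at the optimum
  set.seed(5)
  tp2 <- tuneParams("knn", sep, grid = buildKnnGrid(30))
  expect_equal(tp2@cvError, 0)

  # 3-candidate grid equals an independently recomputed argmin on same folds
  xy <- separableXY(n = 40, p = 3, gap = 1.2, seed = 7)  # non-trivial errors
  g3 <- classiSim:::.newGrid("knn", list(list(k = 1), list(k = 7), list(k = 15)))
  set.seed(99)
  chosen <- tuneParams("knn", xy, grid = g3)
  set.seed(99)
  fold <- classiSim:::.stratifiedFolds(xy$y, 10L)
  oracle <- vapply(c(1, 7, 15), function(k) {
    wrong <- 0L
    for (f in 1:10) {
      te <- fold == f
      pr <- classiSim:::.knnFitPredict(xy$X[!te, , drop = FALSE], xy$y[!te],
                                       xy$X[te, , drop = FALSE], k)
      wrong <- wrong + sum(pr != xy$y[te])
    }
    wrong / length(xy$y)
  }, 0)
  expect_equal(chosen@params$k, c(1, 7, 15)[which.min(oracle)])
  expect_equal(chosen@cvError, min(oracle))

  # lda: nothing to tune
  tplda <- tuneParams("lda", sep)
  expect_identical(tplda@params, list())
})

test_that("cv error at tuned optimum never exceeds the default setting's", {
  xy <- separableXY(n = 50, p = 5, gap = 0.9, seed = 17)
  for (m in c("knn", "svm_rbf")) {
    set.seed(31)
    g <- defaultGrid(m, 50, 5)
    tp <- tuneParams(m, xy, grid = g)
    set.seed(31)
    fold <- classiSim:::.stratifiedFolds(xy$y, 10L)
    defIdx <- classiSim:::.defaultCandidateIndex(
      m, g$candidates[classiSim:::.candidateOrder(m, g$candidates)], 5)
    cands <- g$candidates[classiSim:::.candidateOrder(m, g$candidates)]
    defErr <- classiSim:::.cvErrorForCandidate(m, cands[[defIdx]], xy$X, xy$y,
                                               fold, 10L)
    expect_lte(tp@cvError, defErr + 1e-12)
  }
})

test_that("kNN memorises training points and applies its tie rules", {
  xy <- separableXY(n = 10, p = 2)
  pred <- fitPredict("knn", list(k = 1), xy, xy$X)
  expect_identical(pred, xy$y)
  # forced 2-vote tie resolved by the nearer neighbour (k = 1 subset)
  Xtr <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  ytr <- factor(c("G2", "G1"), levels = c("G1", "G2"))
  pr <- fitPredict("knn", list(k = 2), list(X = Xtr, y = ytr),
                   matrix(c(0.1, 0), 1))
  expect_equal(as.character(pr), "G2")
})

test_that("LDA matches the closed-form discriminant and refuses degeneracy", {
  # separable spherical Gaussians: zero training error
  xy <- separableXY(n = 50, p = 2, gap = 10)
  expect_identical(fitPredict("lda", list(), xy, xy$X), xy$y)

  # p = 1: threshold at the midpoint of class means (equal sizes)
  set.seed(23)
  x <- matrix(c(rnorm(20, 0), rnorm(20, 4)), ncol = 1)
  y <- factor(rep(c("G1", "G2"), each = 20), levels = c("G1", "G2"))
  m1 <- mean(x[1:20, 1]); m2 <- mean(x[21:40, 1])
  mid <- (m1 + m2) / 2
  probe <- matrix(c(mid - 1e-8, mid + 1e-8), ncol = 1)
  pr <- fitPredict("lda", list(), list(X = x, y = y), probe)
  expect_equal(as.character(pr), c("G1", "G2"))

  # degeneracy: p >= n_train signals a typed condition
  xy2 <- separableXY(n = 6, p = 8)
  expect_error(fitPredict("lda", list(), xy2, xy2$X),
               class = "classiSim_lda_degeneracy")
})

test_that("all four methods are near-perfect on a separable simulation", {
  cfg <- SimConfig(n = 60, p = 5, sigmaB = 0.5, sigmaE = 0.5, thetaMin = 4,
                   r = 1, corrKind = "independent", seed = 51)
  ds <- simulateDataset(cfg)
  for (m in c("rf", "svm_rbf", "lda", "knn")) {
    set.seed(61)
    tp <- tuneParams(m, ds, grid = defaultGrid(m, 60, 5, trimmed = TRUE))
    est <- loocv(m, tp, ds)
    expect_lte(est@error, 0.05)
  }
})

test_that("rf and svm are deterministic under a fixed seed", {
  xy <- separableXY(n = 24, p = 3, gap = 1, seed = 3)
  te <- matrix(rnorm(15), 5, 3)
  set.seed(7); a <- fitPredict("rf", list(mtry = 1, nodesize = 1, ntree = 51), xy, te)
  set.seed(7); b <- fitPredict("rf", list(mtry = 1, nodesize = 1, ntree = 51), xy, te)
  expect_identical(a, b)
  s1 <- fitPredict("svm_rbf", list(cost = 1, gamma = 1 / 3), xy, te)
  s2 <- fitPredict("svm_rbf", list(cost = 1, gamma = 1 / 3), xy, te)
  expect_identical(s1, s2)
})

test_that("svm dual solution satisfies the KKT conditions", {
  set.seed(8)
  n <- 40; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- ifelse(rowSums(X[, 1:2]) + rnorm(n, 0, 0.5) > 0, 1L, -1L)
  for (cost in c(0.1, 1, 10)) {
    fit <- classiSim:::.svm_fit_cpp(X, y, cost, 1 / p)
    expect_lt(abs(sum(fit$alpha * y)), 1e-8)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= cost + 1e-12))
    yf <- y * fit$fitted
    tol <- 1.5e-3
    expect_true(all(yf[fit$alpha < 1e-8] >= 1 - tol))
    expect_true(all(yf[fit$alpha > cost - 1e-8] <= 1 + tol))
    free <- fit$alpha > 1e-8 & fit$alpha < cost - 1e-8
    if (any(free)) expect_lt(max(abs(yf[free] - 1)), tol)
  }
})
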