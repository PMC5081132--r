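#' Hyperparameter grids
#'
#' Candidate sets searched by [tuneParams()] under 10-fold cross-validation.
#' Each grid always contains the method's default setting, so the CV error at
#' the optimum can never exceed the CV error at the defaults.
#'
#' * **rf** — `mtry`: a sample of 5 values from `{1, ..., floor(p/2)}`
#'   including the classification default `floor(sqrt(p))` (the whole
#'   sequence when it has fewer than 5 elements); `nodesize`: `{1, ..., 5}`;
#'   `ntree`: `{50, 100, 500, 1000}`. Full Cartesian product.
#' * **svm_rbf** — `cost` and `gamma`: 5 geometrically spaced values
#'   `d * 10^{-1, -1/2, 0, 1/2, 1}` around the defaults `d = 1` and
#'   `d = 1/p`, spanning exactly (d/10, 10d).
#' * **knn** — `k`: `{1, ..., kMax}` where `kMax` is capped at the 10-fold
#'   training-fold size (searching k all the way to n is infeasible once a
#'   fold is held out).
#' * **lda** — nothing to tune.
#'
#' The `mtry`, `nodesize` and `ntree` arguments of `buildRfGrid` override the
#' default candidate sets; scaled-down benchmark runs use trimmed overrides.
#'
#' @param p number of features of the dataset to be tuned on.
#' @param mtry,nodesize,ntree optional candidate overrides for `rf`.
#' @param nTrain training-set size available to `knn`.
#' @param folds CV folds used during tuning (defines the `knn` cap).
#' @param kMax optional override of the largest `k`.
#' @return a list with elements `method`, `candidates` (list of named lists)
#'   and `folds`.
#' @name tuningGrids
NULL

.newGrid <- function(method, candidates, folds = 10L) {
  stopifnot(length(candidates) > 0L)
  list(method = method, candidates = candidates, folds = as.integer(folds))
}

#' @rdname tuningGrids
#' @export
buildRfGrid <- function(p, mtry = NULL, nodesize = 1:5,
                        ntree = c(50L, 100L, 500L, 1000L)) {
  if (p < 1) stop("p must be >= 1")
  if (is.null(mtry)) {
    mtryDefault <- max(1L, floor(sqrt(p)))
    seqMax <- max(1L, p %/% 2L)
    pool <- seq_len(seqMax)
    mtry <- if (seqMax < 5L) pool else
      sort(c(mtryDefault, sample(setdiff(pool, mtryDefault), 4L)))
  }
  mtry <- sort(unique(pmin(as.integer(mtry), p)))
  cand <- expand.grid(mtry = mtry, nodesize = as.integer(nodesize),
                      ntree = as.integer(ntree), KEEP.OUT.ATTRS = FALSE)
  .newGrid("rf", lapply(seq_len(nrow(cand)), function(i) as.list(cand[i, ])))
}

#' @rdname tuningGrids
#' @param randomized logical; FALSE (default) uses 5 deterministic
#'   geometrically spaced values around each default, TRUE draws 4 uniform
#'   samples from each range plus the default (one fresh draw per grid
#'   construction, i.e. per dataset), emulating per-dataset uniform sampling
#'   of the tuning space.
#' @export
buildSvmGrid <- function(p, randomized = FALSE) {
  if (p < 1) stop("p must be >= 1")
  if (randomized) {
    cost <- c(1, runif(4, 1 / 10, 10))
    gamma <- c(1 / p, runif(4, 1 / (10 * p), 10 / p))
  } else {
    steps <- 10^seq(-1, 1, by = 0.5)
    cost <- 1 * steps
    gamma <- (1 / p) * steps
  }
  cand <- expand.grid(cost = cost, gamma = gamma, KEEP.OUT.ATTRS = FALSE)
  .newGrid("svm_rbf", lapply(seq_len(nrow(cand)), function(i) as.list(cand[i, ])))
}

#' @rdname tuningGrids
#' @export
buildKnnGrid <- function(nTrain, folds = 10L, kMax = NULL) {
  if (nTrain < 2) stop("nTrain must be >= 2")
  if (is.null(kMax))
    kMax <- max(1L, nTrain - as.integer(ceiling(nTrain / folds)))
  .newGrid("knn", lapply(seq_len(kMax), function(k) list(k = k)), folds)
}

#' Default (or trimmed) grid for a method
#'
#' @param method classifier key.
#' @param n,p dimensions of the dataset the grid will be tuned on.
#' @param trimmed logical; TRUE yields the small grids used by scaled-down
#'   benchmark runs (rf: default/1/floor(p/2) mtry, nodesize 1, ntree 100;
#'   svm: cost {0.1, 1, 10} x gamma {0.1, 1, 10}/p; knn: odd k up to 15).
#' @return a tuning grid, or NULL for `lda`.
#' @export
defaultGrid <- function(method, n, p, trimmed = FALSE) {
  method <- match.arg(method, .METHODS)
  if (method == "lda") return(NULL)
  if (!trimmed) {
    return(switch(method,
      rf = buildRfGrid(p),
      svm_rbf = buildSvmGrid(p),
      knn = buildKnnGrid(n)))
  }
  switch(method,
    rf = buildRfGrid(p, mtry = unique(c(max(1L, floor(sqrt(p))), 1L,
                                        max(1L, p %/% 2L))),
                     nodesize = 1L, ntree = 100L),
    svm_rbf = {
      cand <- expand.grid(cost = c(0.1, 1, 10), gamma = c(0.1, 1, 10) / p,
                          KEEP.OUT.ATTRS = FALSE)
      .newGrid("svm_rbf", lapply(seq_len(nrow(cand)), function(i) as.list(cand[i, ])))
    },
    knn = {
      kMax <- min(15L, max(1L, n - as.integer(ceiling(n / 10))))
      .newGrid("knn", lapply(seq(1L, kMax, by = 2L), function(k) list(k = k)))
    })
}

# canonical (X, y) extraction for learners
.asXY <- function(dataset) {
  if (is(dataset, "SimulatedSet"))
    return(list(X = datasetMatrix(dataset), y = droplevels2(groupLabels(dataset))))
  if (is(dataset, "FeatureTable"))
    return(list(X = dataset@X, y = dataset@y))
  if (is.list(dataset) && all(c("X", "y") %in% names(dataset)))
    return(list(X = as.matrix(dataset$X), y = as.factor(dataset$y)))
  stop("unsupported dataset type")
}

droplevels2 <- function(y) factor(y, levels = levels(y))

.ldaDegeneracy <- function(msg) {
  structure(class = c("classiSim_lda_degeneracy", "error", "condition"),
            list(message = msg, call = NULL))
}

# ---- classifier implementations -------------------------------------------

# classical LDA: pooled within-class covariance, priors proportional to the
# class sizes; degenerate (signalled, not crashed) when p >= nTrain or the
# pooled covariance is singular
.ldaFitPredict <- function(Xtr, ytr, Xte) {
  n <- nrow(Xtr); p <- ncol(Xtr)
  if (p >= n) stop(.ldaDegeneracy(sprintf(
    "LDA is degenerate for p (%d) >= training size (%d)", p, n)))
  lev <- levels(ytr)
  i1 <- ytr == lev[1]; i2 <- ytr == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop(.ldaDegeneracy("each class needs >= 2 training samples"))
  m1 <- colMeans(Xtr[i1, , drop = FALSE])
  m2 <- colMeans(Xtr[i2, , drop = FALSE])
  S <- ((n1 - 1) * cov(Xtr[i1, , drop = FALSE]) +
        (n2 - 1) * cov(Xtr[i2, , drop = FALSE])) / (n - 2)
  w <- tryCatch(solve(S, m2 - m1), error = function(e)
    stop(.ldaDegeneracy("pooled covariance is singular")))
  # assign to class 2 iff w'x - w'(m1+m2)/2 + log(n2/n1) > 0
  thresh <- sum(w * (m1 + m2)) / 2 - log(n2 / n1)
  scores <- drop(Xte %*% w)
  factor(ifelse(scores > thresh, lev[2], lev[1]), levels = lev)
}

# kNN, Euclidean distance; neighbours ordered by (distance, training index);
# an even-k vote tie is resolved by shrinking to the nearer neighbour set
# (k-1, k-2, ...) until a majority appears, finally falling back to the first
# class level
.knnFitPredict <- function(Xtr, ytr, Xte, k) {
  n <- nrow(Xtr)
  k <- min(as.integer(k), n)
  if (k < 1L) stop("k must be >= 1")
  lev <- levels(ytr)
  yi <- as.integer(ytr)  # 1 or 2
  tr2 <- rowSums(Xtr^2)
  out <- integer(nrow(Xte))
  for (t in seq_len(nrow(Xte))) {
    d2 <- tr2 - 2 * drop(Xtr %*% Xte[t, ]) + sum(Xte[t, ]^2)
    ord <- order(d2, seq_len(n))
    lab <- 0L
    for (kk in k:1) {
      cnt2 <- sum(yi[ord[seq_len(kk)]] == 2L)
      if (2L * cnt2 != kk) { lab <- if (2L * cnt2 > kk) 2L else 1L; break }
    }
    out[t] <- if (lab == 0L) 1L else lab
  }
  factor(lev[out], levels = lev)
}

.rfFitPredict <- function(Xtr, ytr, Xte, mtry, nodesize, ntree) {
  yi <- as.integer(ytr) - 1L
  pred <- .rf_train_predict_cpp(Xtr, yi, Xte, as.integer(ntree),
                                min(as.integer(mtry), ncol(Xtr)),
                                as.integer(nodesize))
  factor(levels(ytr)[pred + 1L], levels = levels(ytr))
}

# features are standardised by the training mean/SD before the RBF kernel is
# evaluated (the convention of the standard SVM implementations, and what
# makes the 1/p default for gamma meaningful); constant columns pass through
.svmFitPredict <- function(Xtr, ytr, Xte, cost, gamma) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, scl, `/`)
  Xte <- sweep(sweep(Xte, 2L, ctr), 2L, scl, `/`)
  yi <- ifelse(as.integer(ytr) == 2L, 1L, -1L)
  pred <- .svm_train_predict_cpp(Xtr, as.integer(yi), Xte, cost, gamma)
  factor(levels(ytr)[ifelse(pred > 0, 2L, 1L)], levels = levels(ytr))
}

#' Train a classifier and predict test rows
#'
#' Uniform train/predict contract over the four classifiers: bagged-CART
#' random forest (`rf`), RBF-kernel support vector machine (`svm_rbf`),
#' classical linear discriminant analysis (`lda`) and k-nearest neighbours
#' (`knn`). LDA and kNN use fixed deterministic tie rules, the SVM solver is
#' deterministic, and the forest consumes R's seeded RNG stream, so all
#' predictions are reproducible under [set.seed()].
#'
#' LDA refuses `p >= nTrain` (and singular pooled covariance) by signalling a
#' `classiSim_lda_degeneracy` condition, which the evaluators convert into a
#' recorded missing estimate rather than a crash.
#'
#' @param method classifier key.
#' @param params a [TunedParams] or plain named list of parameter values.
#' @param train a [SimulatedSet], [FeatureTable] or `list(X =, y =)`.
#' @param testX matrix of test rows (same feature order as training).
#' @return factor of predicted labels, one per test row.
#' @export
fitPredict <- function(method, params, train, testX) {
  method <- match.arg(method, .METHODS)
  xy <- .asXY(train)
  testX <- as.matrix(testX)
  if (ncol(testX) != ncol(xy$X)) stop("test rows have wrong dimension")
  pl <- if (is(params, "TunedParams")) params@params else as.list(params)
  switch(method,
    lda = .ldaFitPredict(xy$X, xy$y, testX),
    knn = .knnFitPredict(xy$X, xy$y, testX, k = pl$k %||% 1L),
    rf = .rfFitPredict(xy$X, xy$y, testX,
                       mtry = pl$mtry %||% max(1L, floor(sqrt(ncol(xy$X)))),
                       nodesize = pl$nodesize %||% 1L,
                       ntree = pl$ntree %||% 500L),
    svm_rbf = .svmFitPredict(xy$X, xy$y, testX,
                             cost = pl$cost %||% 1,
                             gamma = pl$gamma %||% (1 / ncol(xy$X))))
}

# stratified fold assignment: within each class, shuffled samples are dealt
# round-robin so fold class ratios differ by at most one
.stratifiedFolds <- function(y, folds) {
  n <- length(y)
  if (folds > n) stop("folds must be <= n")
  fold <- integer(n)
  at <- 0L
  for (lev in levels(y)) {
    idx <- which(y == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((at + seq_along(idx) - 1L) %% folds) + 1L
    at <- at + length(idx)
  }
  fold
}

.cvErrorForCandidate <- function(method, cand, X, y, fold, folds) {
  wrong <- 0L; total <- 0L
  for (f in seq_len(folds)) {
    te <- fold == f
    if (!any(te)) next
    tr <- !te
    if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
    pred <- fitPredict(method, cand, list(X = X[tr, , drop = FALSE], y = y[tr]),
                       X[te, , drop = FALSE])
    wrong <- wrong + sum(pred != y[te])
    total <- total + sum(te)
  }
  wrong / total
}

# index of the method's default setting among the candidates (NA when the
# grid does not contain it)
.defaultCandidateIndex <- function(method, cands, p) {
  def <- switch(method,
    rf = list(mtry = max(1L, floor(sqrt(p))), nodesize = 1L, ntree = 500L),
    svm_rbf = list(cost = 1, gamma = 1 / p),
    knn = list(k = 1L), NULL)
  if (is.null(def)) return(NA_integer_)
  hit <- which(vapply(cands, function(c)
    all(vapply(names(def), function(k)
      isTRUE(abs(as.numeric(c[[k]]) - as.numeric(def[[k]])) < 1e-10), TRUE)),
    TRUE))
  if (length(hit)) hit[1] else NA_integer_
}

# deterministic tie-break: candidates are pre-ordered ascending in the
# method's key order, so the first argmin is the smallest-parameter winner
.candidateOrder <- function(method, candidates) {
  keys <- switch(method, rf = c("mtry", "nodesize", "ntree"),
                 svm_rbf = c("cost", "gamma"), knn = "k", character())
  if (!length(keys)) return(seq_along(candidates))
  cols <- lapply(keys, function(k) vapply(candidates, function(c) as.numeric(c[[k]]), 0))
  do.call(order, cols)
}

#' Tune a classifier by grid search under k-fold cross-validation
#'
#' Evaluates every candidate on one shared stratified 10-fold split of the
#' dataset and returns the candidate with the smallest CV misclassification
#' error. Ties at the minimum go to the method's default setting when it
#' attains it, and otherwise to the smallest parameter values (in the order
#' mtry, nodesize, ntree / cost, gamma / k); both rules are deterministic.
#' Because the default setting is always a candidate of the full grids, the
#' recorded `cvError` never exceeds the CV error at the defaults. LDA has no
#' tuning parameters and returns immediately.
#'
#' Fold assignment and RF randomness use the current RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param method classifier key.
#' @param dataset a [SimulatedSet], [FeatureTable] or `list(X =, y =)`.
#' @param grid a grid from [buildRfGrid()], [buildSvmGrid()],
#'   [buildKnnGrid()] or [defaultGrid()]; NULL uses the method's default.
#' @param folds cross-validation folds (default 10).
#' @return a [TunedParams].
#' @export
tuneParams <- function(method, dataset, grid = NULL, folds = 10L) {
  method <- match.arg(method, .METHODS)
  if (method == "lda")
    return(new("TunedParams", method = "lda", params = list(),
               cvError = NA_real_))
  xy <- .asXY(dataset)
  n <- nrow(xy$X)
  if (n < folds) stop("cannot build ", folds, " folds from ", n, " samples")
  if (is.null(grid)) grid <- defaultGrid(method, n, ncol(xy$X))
  stopifnot(grid$method == method)
  cands <- grid$candidates[.candidateOrder(method, grid$candidates)]
  fold <- .stratifiedFolds(xy$y, folds)
  errs <- vapply(cands, function(cand)
    .cvErrorForCandidate(method, cand, xy$X, xy$y, fold, folds), numeric(1))
  best <- which.min(errs)
  # ties at the minimum go to the default setting when it attains it (extreme
  # tied candidates - e.g. a near-constant RBF machine from a tiny cost and
  # gamma - can look perfect under balanced k-fold CV yet degenerate under the
  # slight class imbalance of leave-one-out folds); otherwise the smallest
  # parameter values (first in key order) win
  defIdx <- .defaultCandidateIndex(method, cands, ncol(xy$X))
  if (!is.na(defIdx) && errs[defIdx] <= errs[best] + 1e-12) best <- defIdx
  new("TunedParams", method = method, params = cands[[best]],
      cvError = errs[best])
}
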