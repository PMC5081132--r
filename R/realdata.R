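#' Load a delimited case/control feature table
#'
#' Reads a samples x features delimited file (TSV/CSV, auto-detected) with a
#' binary label column, validates that every feature column is numeric, and
#' applies listwise deletion: rows with missing feature values are dropped
#' with a logged count (mirroring studies that exclude cases with missing
#' values in selected variables).
#'
#' @param path file path.
#' @param labelColumn name of the class-label column.
#' @return a [FeatureTable]; the second factor level is the positive class.
#' @export
loadFeatureTable <- function(path, labelColumn = "group") {
  dt <- as.data.frame(data.table::fread(path))
  if (!labelColumn %in% names(dt)) stop("label column '", labelColumn, "' not found")
  y <- as.factor(dt[[labelColumn]])
  if (nlevels(y) != 2L)
    stop("label column must be binary; found levels: ",
         paste(levels(y), collapse = ", "))
  feat <- dt[setdiff(names(dt), labelColumn)]
  for (nm in names(feat)) {
    if (!is.numeric(feat[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(feat[[nm]]))) &
                     !is.na(feat[[nm]]))[1]
      stop(sprintf("non-numeric value in column '%s', row %d", nm,
                   if (is.na(bad)) 1L else bad))
    }
  }
  X <- as.matrix(feat)
  keep <- stats::complete.cases(X)
  if (any(!keep)) {
    message(sum(!keep), " row(s) dropped due to missing feature values")
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  ids <- rownames(X) %||% sprintf("s%03d", seq_len(nrow(X)))
  rownames(X) <- ids
  new("FeatureTable", X = X, y = droplevels(y), sampleIds = ids)
}

#' Construct a FeatureTable from a matrix and labels
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels.
#' @return a [FeatureTable].
#' @export
featureTable <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%03d", seq_len(ncol(X)))
  ids <- rownames(X) %||% sprintf("s%03d", seq_len(nrow(X)))
  rownames(X) <- ids
  new("FeatureTable", X = X, y = as.factor(y), sampleIds = ids)
}

#' Rank features by two-group differential signal
#'
#' Default statistic is the Welch two-sample t (unequal variances); the
#' `moderated_t` option uses limma's empirical-Bayes moderated t instead,
#' matching the kind of test commonly used to pre-select markers. Features
#' with zero variance in both groups are excluded from the output. Features
#' are sorted ascending by p-value, ties broken by absolute statistic
#' (descending) and then by name.
#'
#' @param table a [FeatureTable].
#' @param statistic `"welch_t"` or `"moderated_t"`.
#' @return data.frame (feature, statistic, p.value), best first.
#' @export
rankFeatures <- function(table, statistic = c("welch_t", "moderated_t")) {
  statistic <- match.arg(statistic)
  X <- table@X; y <- table@y
  lev <- levels(y)
  i1 <- y == lev[1]; i2 <- y == lev[2]
  if (sum(i1) < 2L || sum(i2) < 2L) stop("each class needs >= 2 samples")
  v1 <- apply(X[i1, , drop = FALSE], 2L, var)
  v2 <- apply(X[i2, , drop = FALSE], 2L, var)
  keep <- (v1 + v2) > 0
  X <- X[, keep, drop = FALSE]; v1 <- v1[keep]; v2 <- v2[keep]
  if (statistic == "welch_t") {
    n1 <- sum(i1); n2 <- sum(i2)
    m1 <- colMeans(X[i1, , drop = FALSE])
    m2 <- colMeans(X[i2, , drop = FALSE])
    se2 <- v1 / n1 + v2 / n2
    stat <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    pval <- 2 * pt(-abs(stat), df)
  } else {
    design <- cbind(Intercept = 1, g2 = as.integer(y == lev[2]))
    fit <- limma::eBayes(limma::lmFit(t(X), design))
    stat <- fit$t[, "g2"]
    pval <- fit$p.value[, "g2"]
  }
  ord <- order(pval, -abs(stat), colnames(X))
  data.frame(feature = colnames(X)[ord], statistic = unname(stat[ord]),
             p.value = unname(pval[ord]), stringsAsFactors = FALSE)
}

# tune + LOOCV on a feature subset under a derived seed; shared by the curve
# builder and by standalone consistency checks
#' Evaluate one method on a feature subset
#'
#' Tunes the method by stratified 10-fold CV on the subset (trimmed grids by
#' default, matching scaled-down benchmark runs) and returns its leave-one-out
#' performance. Seeded internally from `seed` so that a curve entry and a
#' standalone call with the same seed agree exactly.
#'
#' @param table a [FeatureTable].
#' @param features character vector of feature names to keep (in order).
#' @param method classifier key.
#' @param seed integer seed.
#' @param trimmedGrids logical, use the scaled-down tuning grids.
#' @return a [PerformanceEstimate].
#' @export
evaluateFeatureSubset <- function(table, features, method, seed,
                                  trimmedGrids = TRUE) {
  X <- table@X[, features, drop = FALSE]
  ds <- list(X = X, y = table@y)
  set.seed(seed)
  grid <- if (method == "lda") NULL else
    defaultGrid(method, nrow(X), ncol(X), trimmed = trimmedGrids)
  params <- tuneParams(method, ds, grid = grid)
  loocv(method, params, ds)
}

#' Incremental top-k LOOCV error curves
#'
#' For k = 1, ..., maxK the top-k ranked features are used (features enter in
#' ranking order, emulating biomarkers added in descending order of signal);
#' each method is tuned and evaluated by LOOCV on the submatrix. LDA entries
#' with k >= n - 1 are recorded missing.
#'
#' @param table a [FeatureTable].
#' @param ranking data.frame from [rankFeatures()] (or a character vector of
#'   ordered feature names).
#' @param methods classifier keys.
#' @param maxK largest subset size (<= number of ranked features).
#' @param seed integer; per-(k, method) seeds are derived from it.
#' @param trimmedGrids logical, use the scaled-down tuning grids.
#' @return data.frame (method, k, error, sensitivity, specificity, missing).
#' @export
incrementalErrorCurve <- function(table, ranking, methods = .METHODS,
                                  maxK = 25L, seed = 1L, trimmedGrids = TRUE) {
  feats <- if (is.data.frame(ranking)) ranking$feature else as.character(ranking)
  if (maxK > length(feats)) stop("maxK exceeds the number of ranked features")
  rows <- list()
  for (k in seq_len(maxK)) {
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      est <- evaluateFeatureSubset(table, feats[seq_len(k)], m,
                                   seed = deriveSeed(seed, k, mi),
                                   trimmedGrids = trimmedGrids)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, k = k, error = est@error, sensitivity = est@sensitivity,
        specificity = est@specificity, missing = est@missing,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarise data characteristics of selected features
#'
#' Per feature: the raw group difference `deltaHat = mean(G2) - mean(G1)` on
#' the data scale and the combined variability `sigmaHat`, the pooled
#' within-group SD (without replication the biological and technical
#' components cannot be separated, so only `sqrt(sigmaB^2 + sigmaE^2)` is
#' estimable). Summaries report mean |deltaHat| and mean sigmaHat.
#'
#' @param table a [FeatureTable].
#' @param features feature names to summarise (default: all).
#' @return list with `perFeature` (data.frame feature/deltaHat/sigmaHat) and
#'   `summary` (meanAbsDelta, meanSigma, n, p).
#' @export
estimateCharacteristics <- function(table, features = colnames(table@X)) {
  X <- table@X[, features, drop = FALSE]
  y <- table@y
  lev <- levels(y)
  i1 <- y == lev[1]; i2 <- y == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each class needs >= 2 samples")
  m1 <- colMeans(X[i1, , drop = FALSE]); m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2L, var)
  v2 <- apply(X[i2, , drop = FALSE], 2L, var)
  deltaHat <- m2 - m1
  sigmaHat <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  list(perFeature = data.frame(feature = colnames(X), deltaHat = deltaHat,
                               sigmaHat = sigmaHat, row.names = NULL,
                               stringsAsFactors = FALSE),
       summary = list(meanAbsDelta = mean(abs(deltaHat)),
                      meanSigma = mean(sigmaHat),
                      n = nrow(X), p = ncol(X)))
}

.STUDY_PROFILES <- list(
  # group sizes from the three published case/control studies the fixtures
  # emulate; effect and variability scales follow their reported summary
  # characteristics (EEG: mean |delta| = 0.28, the weakest signal; imaging:
  # largest effects; microarray: moderate log2 effects)
  bipolar_like = list(n1 = 30L, n2 = 31L, p = 25L, meanAbsDelta = 0.55,
                      meanSigma = 0.90, base = 7.5, rho = 0.5),
  adni_like = list(n1 = 186L, n2 = 222L, p = 25L, meanAbsDelta = 1.00,
                   meanSigma = 0.80, base = 2.5, rho = 0.5),
  eeg_like = list(n1 = 39L, n2 = 47L, p = 25L, meanAbsDelta = 0.28,
                  meanSigma = 1.00, base = 0.0, rho = 0.4)
)

#' Synthetic stand-ins for the three case/control studies
#'
#' Generates a correlated Gaussian samples x features table with the group
#' sizes, dimensionality and effect/variability scales of one of three study
#' profiles: a postmortem-brain microarray study (`bipolar_like`, n = 61
#' split 30/31), a structural-imaging study (`adni_like`, n = 418 split
#' 186/222) and an EEG study after exclusions (`eeg_like`, n = 86 split
#' 39/47, the weakest signal with mean |delta| = 0.28). These are synthetic
#' emulations parameterised by published summary characteristics, not the
#' real data.
#'
#' Per-feature |delta| values are drawn around the profile's mean, signs are
#' random, per-feature SDs vary moderately around the profile's mean sigma,
#' and features share an exchangeable correlation.
#'
#' @param profile one of `"bipolar_like"`, `"adni_like"`, `"eeg_like"`.
#' @param seed integer seed.
#' @return a [FeatureTable] with levels G1 (controls-like) and G2 (cases).
#' @export
makeStudyFixture <- function(profile = c("bipolar_like", "adni_like",
                                         "eeg_like"), seed = 1L) {
  profile <- match.arg(profile)
  pr <- .STUDY_PROFILES[[profile]]
  set.seed(seed)
  n <- pr$n1 + pr$n2; p <- pr$p
  absDelta <- truncnorm::rtruncnorm(p, a = 0.05, b = Inf,
                                    mean = pr$meanAbsDelta,
                                    sd = pr$meanAbsDelta / 3)
  delta <- absDelta * sample(c(-1, 1), p, replace = TRUE)
  sigma <- runif(p, 0.7 * pr$meanSigma, 1.3 * pr$meanSigma)
  R <- matrix(pr$rho, p, p); diag(R) <- 1
  Z <- matrix(rnorm(n * p), n, p) %*% chol(R)
  X <- sweep(Z, 2L, sigma, `*`)
  X <- sweep(X, 2L, pr$base + rnorm(p, 0, 0.5), `+`)
  g2 <- (pr$n1 + 1L):n
  X[g2, ] <- sweep(X[g2, , drop = FALSE], 2L, delta, `+`)
  colnames(X) <- sprintf("f%03d", seq_len(p))
  featureTable(X, factor(rep(.GROUPS, c(pr$n1, pr$n2)), levels = .GROUPS))
}
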