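#' Draw synthetic base expressions
#'
#' Surrogate for a base-expression catalogue obtained by averaging normalised
#' log2 microarray data over many healthy samples: location parameters mu are
#' drawn i.i.d. from a Normal(7.5, 2^2) truncated to \[2, 14\] on the log2
#' scale, the range typical of normalised single-channel arrays. The base
#' level only shifts features and carries no class signal, so its exact
#' distribution is immaterial to the benchmark.
#'
#' Uses the current R RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param p number of features (>= 1).
#' @return numeric vector of p log2 base expressions.
#' @export
sampleBaseExpressions <- function(p) {
  if (length(p) != 1L || is.na(p) || p < 1) stop("p must be a single integer >= 1")
  truncnorm::rtruncnorm(p, a = 2, b = 14, mean = 7.5, sd = 2)
}

# moments of the base-expression surrogate, for Monte-Carlo tests
.baseExpressionMoments <- function() {
  c(mean = truncnorm::etruncnorm(a = 2, b = 14, mean = 7.5, sd = 2),
    sd = sqrt(truncnorm::vtruncnorm(a = 2, b = 14, mean = 7.5, sd = 2)))
}

#' Simulate replicate-averaged uncorrelated expression values
#'
#' Random-effects model `x_ij = mu + b_i + eps_ij` per feature: a
#' between-subject effect `b_i ~ N(0, sigmaB^2)` shared by the r technical
#' replicates of subject i, plus replicate-level noise
#' `eps_ij ~ N(0, sigmaE^2)`. Replicates are then averaged, so each column j
#' of the returned matrix is marginally `N(mu_j, sigmaB^2 + sigmaE^2 / r)`
#' and columns are independent at this stage.
#'
#' @param config a [SimConfig] (gaussian family).
#' @param mu numeric vector of p base expressions.
#' @return n x p matrix of replicate-averaged values.
#' @export
simulateReplicateAverage <- function(config, mu) {
  stopifnot(is(config, "SimConfig"))
  if (config@family != "gaussian")
    stop("simulateReplicateAverage applies to the gaussian family")
  if (length(mu) != config@p) stop("mu must have length p")
  n <- config@n; p <- config@p; r <- config@r
  b <- matrix(rnorm(n * p, 0, config@sigmaB), n, p)
  epsBar <- matrix(rowMeans(matrix(rnorm(n * p * r, 0, config@sigmaE), ncol = r)),
                   n, p)
  sweep(b + epsBar, 2L, mu, `+`)
}

#' Random block partition of p features
#'
#' The number of blocks H is 1 for p < 5 and otherwise drawn uniformly from
#' `{1, ..., floor(p/3)}`. If H divides p all blocks have size p/H; otherwise
#' the first block absorbs the remainder: `d_1 = floor(p/H) + p mod H`,
#' `d_h = floor(p/H)` for h >= 2.
#'
#' @param p number of features.
#' @param H optional fixed number of blocks (overrides the random draw; used
#'   by tests and by the exchangeable structure).
#' @return integer vector of block sizes summing to p.
#' @export
makeBlockPartition <- function(p, H = NULL) {
  if (length(p) != 1L || is.na(p) || p < 1) stop("p must be a single integer >= 1")
  p <- as.integer(p)
  if (is.null(H)) {
    H <- if (p < 5L) 1L else sample.int(p %/% 3L, 1L)
  }
  H <- as.integer(H)
  if (H < 1L || H > p) stop("H out of range")
  base <- p %/% H
  sizes <- rep.int(base, H)
  sizes[1L] <- base + p %% H
  sizes
}

#' Hub-Toeplitz correlation block
#'
#' Symmetric Toeplitz block whose first row is `(1, rho_2, ..., rho_d)` with
#' the hub correlation decaying from `rhoMax` (adjacent to the hub) down to
#' `rhoMin` at the far end of the block:
#' `rho_l = rhoMax - ((l - 2) / (d - 2))^nu * (rhoMax - rhoMin)` for
#' `l = 2, ..., d`. `nu = 1` gives a linear decline. A 2 x 2 block has a
#' single off-diagonal lag, defined as `rhoMax`.
#'
#' @param d block dimension (>= 1).
#' @param rhoMax,rhoMin hub and tail correlations, `0 <= rhoMin <= rhoMax < 1`.
#' @param nu decline-rate exponent.
#' @return d x d correlation matrix.
#' @export
hubToeplitzBlock <- function(d, rhoMax, rhoMin, nu = 1) {
  if (length(d) != 1L || is.na(d) || d < 1) stop("d must be a single integer >= 1")
  if (rhoMin > rhoMax) stop("rhoMin must be <= rhoMax")
  if (rhoMax >= 1 || rhoMin < 0) stop("correlations must satisfy 0 <= rhoMin <= rhoMax < 1")
  d <- as.integer(d)
  firstRow <- c(1, hubRhoSequence(d, rhoMax, rhoMin, nu))
  toeplitz(firstRow)
}

# the sequence rho_{2..d}; exported logic kept separate so the assembled
# CorrelationModel can record it per block
hubRhoSequence <- function(d, rhoMax, rhoMin, nu = 1) {
  if (d < 2L) return(numeric())
  if (d == 2L) return(rhoMax)
  l <- 2:d
  rhoMax - (((l - 2) / (d - 2))^nu) * (rhoMax - rhoMin)
}

#' Assemble the inter-feature correlation model
#'
#' * `independent`: identity.
#' * `hub_toeplitz_blocks`: `rhoMax ~ U(rhoMaxRange)` and
#'   `rhoMin ~ U(rhoMinRange)` are drawn once per dataset, the feature set is
#'   partitioned by [makeBlockPartition()], and per-block hub-Toeplitz
#'   matrices are placed on the block diagonal (zero between blocks).
#' * `exchangeable_single_block`: constant off-diagonal `rhoFixed`.
#'
#' Positive definiteness is verified (minimum eigenvalue > 1e-10); a
#' degenerate draw is repaired by clipping eigenvalues at 1e-8,
#' reconstructing, and rescaling to unit diagonal, with the repair recorded.
#'
#' @param config a [SimConfig].
#' @return a [CorrelationModel].
#' @export
assembleCorrelation <- function(config) {
  stopifnot(is(config, "SimConfig"))
  p <- config@p
  kind <- config@corrKind
  if (kind == "independent") {
    return(new("CorrelationModel", blockSizes = p, rhoSequences = list(),
               R = diag(p), pdRepaired = FALSE))
  }
  if (kind == "exchangeable_single_block") {
    rho <- config@rhoFixed
    if (is.na(rho)) stop("exchangeable structure requires rhoFixed")
    if (rho >= 1 || (p > 1 && rho <= -1 / (p - 1)))
      stop("rhoFixed violates the exchangeable positive-definite bound")
    R <- matrix(rho, p, p); diag(R) <- 1
    return(new("CorrelationModel", blockSizes = p,
               rhoSequences = list(rep(rho, max(p - 1L, 0L))),
               R = R, pdRepaired = FALSE))
  }
  rhoMax <- runif(1, config@rhoMaxRange[1], config@rhoMaxRange[2])
  rhoMin <- runif(1, config@rhoMinRange[1], config@rhoMinRange[2])
  sizes <- makeBlockPartition(p)
  seqs <- lapply(sizes, hubRhoSequence, rhoMax = rhoMax, rhoMin = rhoMin,
                 nu = config@nu)
  R <- matrix(0, p, p)
  at <- 0L
  for (h in seq_along(sizes)) {
    d <- sizes[h]
    R[at + seq_len(d), at + seq_len(d)] <-
      hubToeplitzBlock(d, rhoMax, rhoMin, config@nu)
    at <- at + d
  }
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) <= 1e-10) {
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% (vals * t(ev$vectors))
    R <- stats::cov2cor((R + t(R)) / 2)
    repaired <- TRUE
  }
  new("CorrelationModel", blockSizes = as.integer(sizes), rhoSequences = seqs,
      R = R, pdRepaired = repaired)
}

#' Impose a correlation structure by Cholesky transformation
#'
#' Columns of the input are independent with means `mu` and common variance
#' `v = sigmaB^2 + sigmaE^2 / r`. The target covariance is
#' `V^{1/2} R V^{1/2} = v R` with `V = v I_p`. The transform is
#' variance-preserving: residuals are standardised, `Z = (X - mu) / sqrt(v)`,
#' multiplied by the upper Cholesky factor U with `U'U = R` (row-vector
#' convention, `Y = Z U`), rescaled by `sqrt(v)` and re-centred at `mu`. With
#' `R = I` the data pass through unchanged.
#'
#' @param Xbar n x p matrix with independent columns.
#' @param mu column means.
#' @param v common column variance.
#' @param R target correlation matrix (positive definite).
#' @return n x p matrix with row covariance `v * R` and means `mu`.
#' @export
imposeCorrelation <- function(Xbar, mu, v, R) {
  p <- ncol(Xbar)
  if (length(mu) != p || nrow(R) != p) stop("dimension mismatch")
  if (identical(R, diag(p)) || max(abs(R - diag(p))) == 0) return(Xbar)
  U <- tryCatch(chol(R), error = function(e)
    stop("internal error: R is not positive definite (repair should have run upstream)"))
  Z <- sweep(Xbar, 2L, mu, `-`) / sqrt(v)
  sweep(Z %*% U * sqrt(v), 2L, mu, `+`)
}

#' Mean of the lower-truncated normal effect distribution
#'
#' For delta ~ Normal(0, tau^2) truncated to `[alpha, Inf)`,
#' `E[delta | A] = tau * phi(alpha / tau) / (1 - Phi(alpha / tau))`, which at
#' tau = 1 reduces to `phi(alpha) / (1 - Phi(alpha))` and at alpha = 0 to the
#' half-normal mean `tau * sqrt(2 / pi)`.
#'
#' @param alpha truncation point (>= 0).
#' @param tau scale of the untruncated distribution (> 0).
#' @return expected effect size.
#' @seealso [averageFoldChange()]
#' @export
truncnormMean <- function(alpha, tau = 1) {
  if (any(alpha < 0)) stop("alpha must be >= 0")
  if (any(tau <= 0)) stop("tau must be > 0")
  tau * dnorm(alpha / tau) / (1 - pnorm(alpha / tau))
}

#' Average fold change implied by (thetaMin, tau)
#'
#' `theta = 2^{E[delta | delta >= alpha]}` with `alpha = log2(thetaMin)`.
#'
#' @param thetaMin minimum fold change (>= 1).
#' @param tau scale of the untruncated effect distribution.
#' @return the average fold change of retained biomarkers.
#' @export
averageFoldChange <- function(thetaMin, tau = 1) {
  if (any(thetaMin < 1)) stop("thetaMin must be >= 1")
  2^truncnormMean(log2(thetaMin), tau)
}

#' Sample per-feature effect sizes
#'
#' Draws p effects from the truncated normal of [truncnormMean()] with
#' `alpha = log2(thetaMin)`, sorts them in descending order (biomarkers are
#' added in descending order of effect size), and attaches i.i.d. uniform
#' signs z in \{-1, +1\}.
#'
#' @param p number of features.
#' @param thetaMin minimum fold change (>= 1).
#' @param tau scale of the untruncated distribution.
#' @return an [EffectModel].
#' @export
sampleEffectSizes <- function(p, thetaMin, tau = 1) {
  if (thetaMin < 1) stop("thetaMin must be >= 1 (alpha = log2(thetaMin) >= 0)")
  if (tau <= 0) stop("tau must be > 0")
  alpha <- log2(thetaMin)
  delta <- sort(truncnorm::rtruncnorm(p, a = alpha, b = Inf, mean = 0, sd = tau),
                decreasing = TRUE)
  z <- sample(c(-1L, 1L), p, replace = TRUE)
  new("EffectModel", alpha = alpha, tau = tau, delta = delta, z = z)
}

#' Shift the second group by its signed effects
#'
#' Adds `z_j * delta_j` to feature j in every G2 row (rows n1+1, ..., n);
#' G1 rows are untouched.
#'
#' @param Ybar n x p matrix.
#' @param effects an [EffectModel] with p entries.
#' @param n1 size of the first group, `n1 = floor(n / 2)` by convention.
#' @return list with the shifted matrix `X` and the label factor `y`.
#' @export
injectGroupEffect <- function(Ybar, effects, n1) {
  stopifnot(is(effects, "EffectModel"))
  n <- nrow(Ybar); p <- ncol(Ybar)
  if (length(effects@delta) != p)
    stop("effects length does not match the number of columns")
  if (n1 < 1 || n1 >= n) stop("n1 must leave both groups non-empty")
  shift <- effects@z * effects@delta
  g2 <- (n1 + 1L):n
  Ybar[g2, ] <- sweep(Ybar[g2, , drop = FALSE], 2L, shift, `+`)
  y <- factor(rep(.GROUPS, c(n1, n - n1)), levels = .GROUPS)
  list(X = Ybar, y = y)
}

.newSimulatedSet <- function(X, y, mu, v, config, corr, effects) {
  p <- ncol(X)
  featNames <- sprintf("f%03d", seq_len(p))
  dimnames(X) <- list(sprintf("s%03d", seq_len(nrow(X))), featNames)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = t(X)),
    colData = S4Vectors::DataFrame(group = y),
    rowData = S4Vectors::DataFrame(mu = mu, delta = effects@delta,
                                   z = effects@z, row.names = featNames),
    metadata = list(config = config, correlation = corr, effects = effects,
                    mu = mu, marginalVariance = v,
                    n1 = sum(y == "G1"), n2 = sum(y == "G2"))
  )
  as(se, "SimulatedSet")
}

#' Simulate one labelled dataset
#'
#' Full generative pipeline, reproducible from `config@seed`:
#' base expressions, replicate-averaged random-effects noise, block
#' correlation by Cholesky transformation, then injection of signed
#' truncated-normal group effects into G2 (`n1 = floor(n/2)` subjects in G1,
#' the remainder in G2). The Poisson family replaces the Gaussian noise
#' pipeline with correlated counts (see [simulatePoissonDataset()]).
#'
#' @param config a [SimConfig].
#' @return a [SimulatedSet].
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (config@family == "poisson") return(simulatePoissonDataset(config))
  set.seed(config@seed)
  n <- config@n; p <- config@p
  mu <- sampleBaseExpressions(p)
  Xbar <- simulateReplicateAverage(config, mu)
  v <- config@sigmaB^2 + config@sigmaE^2 / config@r
  corr <- assembleCorrelation(config)
  Ybar <- imposeCorrelation(Xbar, mu, v, corr@R)
  effects <- sampleEffectSizes(p, config@thetaMin, config@tau)
  lab <- injectGroupEffect(Ybar, effects, n1 = n %/% 2L)
  .newSimulatedSet(lab$X, lab$y, mu, v, config, corr, effects)
}

#' Simulate a correlated Poisson dataset
#'
#' Count-data sensitivity variant: a single replicate of each feature is
#' marginally Poisson(lambda). Inter-feature dependence targets the same
#' block-diagonal hub-Toeplitz correlation R via a Gaussian copula (NORTA):
#' a Gaussian vector with correlation R is pushed through the standard normal
#' CDF and then the Poisson(lambda) quantile function. The realised count
#' correlation is attenuated relative to R (see
#' [poissonCopulaCorrelation()]). The signed group effects `z * delta` are
#' added to the counts of G2 as real-valued shifts, exactly as in the
#' Gaussian pipeline. `sigmaB`, `sigmaE` and `r` are ignored for this family.
#'
#' @param config a [SimConfig] with `family = "poisson"`.
#' @return a [SimulatedSet]; pre-injection values are non-negative integers.
#' @export
simulatePoissonDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  if (config@family != "poisson") stop("config family must be poisson")
  if (config@lambdaRate <= 0) stop("lambdaRate must be > 0")
  set.seed(config@seed)
  n <- config@n; p <- config@p; lam <- config@lambdaRate
  corr <- assembleCorrelation(config)
  if (max(abs(corr@R - diag(p))) == 0) {
    counts <- matrix(rpois(n * p, lam), n, p)
  } else {
    Z <- imposeCorrelation(matrix(rnorm(n * p), n, p), rep(0, p), 1, corr@R)
    counts <- matrix(qpois(pmin(pnorm(Z), 1 - 1e-14), lam), n, p)
  }
  effects <- sampleEffectSizes(p, config@thetaMin, config@tau)
  lab <- injectGroupEffect(counts, effects, n1 = n %/% 2L)
  .newSimulatedSet(lab$X, lab$y, mu = rep(lam, p), v = lam,
                   config = config, corr = corr, effects = effects)
}

#' Realised count correlation under the Gaussian copula
#'
#' For a bivariate standard normal with correlation `rho` pushed through
#' `qpois(pnorm(.), lambda)`, computes the correlation of the resulting
#' counts by two-dimensional numerical integration on a dense Gauss grid.
#' Documents the NORTA attenuation: the returned value is slightly below
#' `rho` for moderate lambda.
#'
#' @param rho latent Gaussian correlation.
#' @param lambda Poisson intensity.
#' @param gridN quadrature grid size per dimension.
#' @return realised Pearson correlation of the count pair.
#' @export
poissonCopulaCorrelation <- function(rho, lambda, gridN = 400L) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  zs <- seq(-8, 8, length.out = gridN)
  w <- dnorm(zs); w <- w / sum(w)
  toCount <- function(z) qpois(pmin(pnorm(z), 1 - 1e-14), lambda)
  g <- toCount(zs)
  m <- sum(w * g)
  v <- sum(w * (g - m)^2)
  # E[g(Z1) g(Z2)] with Z2 = rho Z1 + sqrt(1-rho^2) Z0
  s <- sqrt(1 - rho^2)
  inner <- vapply(zs, function(z1) {
    sum(w * toCount(rho * z1 + s * zs))
  }, numeric(1))
  (sum(w * g * inner) - m^2) / v
}
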