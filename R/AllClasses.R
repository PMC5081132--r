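#' @import methods
#' @importFrom stats dnorm pnorm qnorm rnorm runif rpois qpois toeplitz pt
#'   setNames quantile
NULL

.CORR_KINDS <- c("independent", "hub_toeplitz_blocks", "exchangeable_single_block")
.FAMILIES <- c("gaussian", "poisson")
.METHODS <- c("rf", "svm_rbf", "lda", "knn")
.GROUPS <- c("G1", "G2")

#' Simulation configuration for one design cell
#'
#' Captures every factor of the two-group expression simulator: sample size,
#' dimensionality, the random-effects noise scales (between-subject `sigmaB`
#' and within-subject `sigmaE`, both on the log2 scale), technical replication
#' `r`, the minimum fold change `thetaMin` (truncation point of the
#' effect-size distribution, `alpha = log2(thetaMin)`), the scale `tau` of the
#' untruncated effect distribution, the distributional family, and the
#' inter-feature correlation structure.
#'
#' @slot n integer, subjects (>= 4).
#' @slot p integer, features (>= 1).
#' @slot sigmaB numeric, between-subject SD (log2 units, > 0).
#' @slot sigmaE numeric, within-subject SD (log2 units, > 0).
#' @slot r integer, technical replicates per subject (>= 1).
#' @slot thetaMin numeric, minimum fold change (>= 1).
#' @slot tau numeric, scale of the untruncated effect distribution (> 0).
#' @slot family `"gaussian"` or `"poisson"`.
#' @slot lambdaRate numeric, Poisson intensity (> 0); only used for the
#'   Poisson family, where `sigmaB`, `sigmaE` and `r` are ignored (a single
#'   Poisson replicate carries all the noise).
#' @slot corrKind one of `"independent"`, `"hub_toeplitz_blocks"`,
#'   `"exchangeable_single_block"`.
#' @slot rhoMaxRange numeric(2), uniform sampling interval for the hub
#'   correlation `rhoMax`.
#' @slot rhoMinRange numeric(2), uniform sampling interval for the tail
#'   correlation `rhoMin`; its upper bound must stay below the lower bound of
#'   `rhoMaxRange`.
#' @slot rhoFixed numeric, the single correlation for the exchangeable
#'   structure (NA unless used).
#' @slot nu numeric, decline-rate exponent of the hub-Toeplitz decay (1 =
#'   linear).
#' @slot seed integer, master seed for the dataset.
#' @export
setClass("SimConfig",
  slots = c(
    n = "integer", p = "integer", sigmaB = "numeric", sigmaE = "numeric",
    r = "integer", thetaMin = "numeric", tau = "numeric", family = "character",
    lambdaRate = "numeric", corrKind = "character", rhoMaxRange = "numeric",
    rhoMinRange = "numeric", rhoFixed = "numeric", nu = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@n) != 1L || is.na(object@n) || object@n < 4L)
    msg <- c(msg, "n must be a single integer >= 4")
  if (length(object@p) != 1L || is.na(object@p) || object@p < 1L)
    msg <- c(msg, "p must be a single integer >= 1")
  if (object@sigmaB <= 0) msg <- c(msg, "sigmaB must be > 0")
  if (object@sigmaE <= 0) msg <- c(msg, "sigmaE must be > 0")
  if (object@r < 1L) msg <- c(msg, "r must be >= 1")
  if (object@thetaMin < 1) msg <- c(msg, "thetaMin must be >= 1 (alpha = log2(thetaMin) >= 0)")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (!object@family %in% .FAMILIES) msg <- c(msg, "unknown family")
  if (object@lambdaRate <= 0) msg <- c(msg, "lambdaRate must be > 0")
  if (!object@corrKind %in% .CORR_KINDS) msg <- c(msg, "unknown corrKind")
  if (length(object@rhoMaxRange) != 2L || diff(object@rhoMaxRange) < 0)
    msg <- c(msg, "rhoMaxRange must be an ordered interval")
  if (length(object@rhoMinRange) != 2L || diff(object@rhoMinRange) < 0)
    msg <- c(msg, "rhoMinRange must be an ordered interval")
  if (object@rhoMinRange[2] >= object@rhoMaxRange[1])
    msg <- c(msg, "rhoMinRange upper bound must be < rhoMaxRange lower bound")
  if (object@corrKind == "exchangeable_single_block") {
    if (is.na(object@rhoFixed))
      msg <- c(msg, "exchangeable structure requires rhoFixed")
    else if (object@rhoFixed >= 1 || object@rhoFixed <= -1 / (max(object@p, 2L) - 1))
      msg <- c(msg, "rhoFixed outside the exchangeable positive-definite bound")
  }
  if (object@nu <= 0) msg <- c(msg, "nu must be > 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class Constructor. Defaults are the reference design
#'   of the simulation study: `sigmaB = 2.5`, `sigmaE = 1.5`, `thetaMin = 2`,
#'   `r = 3`, `tau = 1`, hub-Toeplitz blocks with `rhoMax ~ U(0.6, 0.8)`,
#'   `rhoMin ~ U(0.2, 0.4)`, `nu = 1`, and `lambda = 4` for the Poisson
#'   variant.
#' @param n,p,sigmaB,sigmaE,r,thetaMin,tau,family,lambdaRate,corrKind,rhoMaxRange,rhoMinRange,rhoFixed,nu,seed
#'   see the slot documentation.
#' @return A validated `SimConfig`.
#' @export
SimConfig <- function(n, p, sigmaB = 2.5, sigmaE = 1.5, r = 3L, thetaMin = 2,
                      tau = 1, family = "gaussian", lambdaRate = 4,
                      corrKind = "hub_toeplitz_blocks",
                      rhoMaxRange = c(0.6, 0.8), rhoMinRange = c(0.2, 0.4),
                      rhoFixed = NA_real_, nu = 1, seed = 1L) {
  new("SimConfig",
    n = as.integer(n), p = as.integer(p), sigmaB = as.numeric(sigmaB),
    sigmaE = as.numeric(sigmaE), r = as.integer(r),
    thetaMin = as.numeric(thetaMin), tau = as.numeric(tau),
    family = match.arg(family, .FAMILIES),
    lambdaRate = as.numeric(lambdaRate),
    corrKind = match.arg(corrKind, .CORR_KINDS),
    rhoMaxRange = as.numeric(rhoMaxRange),
    rhoMinRange = as.numeric(rhoMinRange), rhoFixed = as.numeric(rhoFixed),
    nu = as.numeric(nu), seed = as.integer(seed)
  )
}

#' Block partition and assembled correlation matrix
#'
#' @slot blockSizes integer vector of block dimensions summing to p.
#' @slot rhoSequences list; per block, the off-diagonal correlation sequence
#'   `rho[2..d_h]` (empty for degenerate 1x1 blocks).
#' @slot R p x p correlation matrix.
#' @slot pdRepaired logical; TRUE when an eigenvalue-clipping repair was
#'   needed to restore positive definiteness.
#' @export
setClass("CorrelationModel",
  slots = c(blockSizes = "integer", rhoSequences = "list", R = "matrix",
            pdRepaired = "logical")
)

setValidity("CorrelationModel", function(object) {
  R <- object@R
  msg <- character()
  if (nrow(R) != ncol(R)) msg <- c(msg, "R must be square")
  if (sum(object@blockSizes) != nrow(R))
    msg <- c(msg, "block sizes must sum to the dimension of R")
  if (max(abs(R - t(R))) > 1e-12) msg <- c(msg, "R must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-12) msg <- c(msg, "diag(R) must be 1")
  if (max(abs(R)) > 1 + 1e-12) msg <- c(msg, "|R_ij| must be <= 1")
  if (length(msg)) msg else TRUE
})

#' Truncated-normal effect-size model
#'
#' Per-feature unstandardised group differences delta (log2 fold changes),
#' drawn from a zero-mean normal of scale `tau` truncated to
#' `[alpha, Inf)` with `alpha = log2(thetaMin)`, sorted in descending order,
#' plus random signs z in {-1, +1} deciding up- or down-regulation.
#'
#' @slot alpha numeric truncation point (>= 0).
#' @slot tau numeric scale of the untruncated distribution.
#' @slot delta numeric vector, non-increasing, all >= alpha.
#' @slot z integer vector of +/- 1 signs.
#' @export
setClass("EffectModel",
  slots = c(alpha = "numeric", tau = "numeric", delta = "numeric",
            z = "integer")
)

setValidity("EffectModel", function(object) {
  msg <- character()
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (length(object@delta) != length(object@z))
    msg <- c(msg, "delta and z must have equal length")
  if (length(object@delta) && any(object@delta < object@alpha - 1e-12))
    msg <- c(msg, "all delta must be >= alpha")
  if (is.unsorted(rev(object@delta), strictly = FALSE))
    msg <- c(msg, "delta must be non-increasing")
  if (length(object@z) && !all(object@z %in% c(-1L, 1L)))
    msg <- c(msg, "z entries must be -1 or +1")
  if (length(msg)) msg else TRUE
})

#' Simulated labelled expression set
#'
#' A [SummarizedExperiment::SummarizedExperiment] (features x samples) whose
#' colData carries the two-group labels and whose metadata records the
#' generating `SimConfig`, the `CorrelationModel`, the `EffectModel`, the base
#' expressions mu and the marginal variance `v = sigmaB^2 + sigmaE^2 / r`.
#'
#' @export
setClass("SimulatedSet", contains = "SummarizedExperiment")

setValidity("SimulatedSet", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- object$group
    if (!all(levels(g) == .GROUPS)) msg <- c(msg, "group levels must be G1, G2")
  }
  for (nm in c("config", "effects", "mu", "marginalVariance"))
    if (is.null(md[[nm]])) msg <- c(msg, paste0("metadata$", nm, " missing"))
  if (length(msg)) msg else TRUE
})

#' Tuned hyperparameters for one classifier
#'
#' @slot method one of `"rf"`, `"svm_rbf"`, `"lda"`, `"knn"`.
#' @slot params named list of selected parameter values (empty for LDA).
#' @slot cvError numeric, 10-fold CV misclassification error at the optimum
#'   (NA for LDA, which has nothing to tune).
#' @export
setClass("TunedParams",
  slots = c(method = "character", params = "list", cvError = "numeric")
)

#' Cross-validated performance estimate
#'
#' @slot method classifier key.
#' @slot error,sensitivity,specificity proportions in \[0, 1\] (NA when
#'   missing); sensitivity is the true-positive rate with G2 (the
#'   effect-injected group) as the positive class, specificity the
#'   true-negative rate on G1.
#' @slot predictions character vector of per-sample hold-out predictions.
#' @slot nEval integer, number of evaluated samples.
#' @slot missing logical; TRUE when the estimate could not be computed (e.g.
#'   LDA with p >= n - 1 is degenerate).
#' @slot reason character, explanation when missing.
#' @export
setClass("PerformanceEstimate",
  slots = c(method = "character", error = "numeric", sensitivity = "numeric",
            specificity = "numeric", predictions = "character",
            nEval = "integer", missing = "logical", reason = "character")
)

#' Case/control feature table
#'
#' Plain samples x features numeric matrix with a binary class factor, used by
#' the real-data workflow (feature ranking, incremental top-k error curves,
#' data-characteristics summaries).
#'
#' @slot X numeric matrix, samples in rows, named feature columns.
#' @slot y factor with two levels; the second level plays the role of G2
#'   (positive class, delta-hat = mean(level 2) - mean(level 1)).
#' @slot sampleIds character vector of row identifiers.
#' @export
setClass("FeatureTable",
  slots = c(X = "matrix", y = "factor", sampleIds = "character")
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (nrow(object@X) != length(object@y))
    msg <- c(msg, "label length must match the number of rows")
  if (nlevels(object@y) != 2L) msg <- c(msg, "labels must have exactly two levels")
  if (is.null(colnames(object@X))) msg <- c(msg, "features must be named")
  if (length(msg)) msg else TRUE
})

#' Factorial simulation design
#'
#' @slot levels named list of factor levels; recognised names are `n`, `p`,
#'   `sigmaB`, `sigmaE`, `thetaMin`, `r` (numeric vectors) and `corr` (a list
#'   of correlation specs, each `list(kind =, rho =)`).
#' @slot methods character vector of classifier keys.
#' @slot nReps integer, replications per cell (the reference design uses 500;
#'   scaled-down runs record the value actually used here).
#' @slot masterSeed integer.
#' @slot workers integer, parallel workers (results are identical to a serial
#'   run by construction of the per-cell seeds).
#' @export
setClass("FactorGrid",
  slots = c(levels = "list", methods = "character", nReps = "integer",
            masterSeed = "integer", workers = "integer")
)

setValidity("FactorGrid", function(object) {
  msg <- character()
  if (!length(object@levels) || any(!lengths(object@levels)))
    msg <- c(msg, "all factor level lists must be non-empty")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (!all(object@methods %in% .METHODS)) msg <- c(msg, "unknown method key")
  if (length(msg)) msg else TRUE
})
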