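#' Write a simulated dataset to disk
#'
#' Writes a delimited table (TSV by default; samples as rows, features as
#' columns, final column `group`) plus a JSON sidecar `<path>.json` recording
#' the generating configuration, seed, effect sizes and signs, block sizes
#' and the positive-definiteness repair flag.
#'
#' @param x a [SimulatedSet].
#' @param path output file path (the sidecar gets `.json` appended).
#' @param sep field separator (`"\t"` or `","`).
#' @return `path`, invisibly.
#' @export
writeDataset <- function(x, path, sep = "\t") {
  stopifnot(is(x, "SimulatedSet"))
  df <- as.data.frame(datasetMatrix(x))
  df$group <- as.character(groupLabels(x))
  data.table::fwrite(df, path, sep = sep)
  cfg <- simConfig(x)
  eff <- effectModel(x)
  corr <- correlationModel(x)
  meta <- list(
    config = list(n = cfg@n, p = cfg@p, sigmaB = cfg@sigmaB,
                  sigmaE = cfg@sigmaE, r = cfg@r, thetaMin = cfg@thetaMin,
                  tau = cfg@tau, family = cfg@family,
                  lambdaRate = cfg@lambdaRate, corrKind = cfg@corrKind,
                  rhoMaxRange = cfg@rhoMaxRange,
                  rhoMinRange = cfg@rhoMinRange, rhoFixed = cfg@rhoFixed,
                  nu = cfg@nu, seed = cfg@seed),
    delta = eff@delta, z = eff@z, alpha = eff@alpha,
    blockSizes = if (!is.null(corr)) corr@blockSizes else integer(),
    pdRepaired = if (!is.null(corr)) corr@pdRepaired else FALSE,
    marginalVariance = marginalVariance(x))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a dataset written by [writeDataset()]
#'
#' Rebuilds a [SimulatedSet] from the delimited table and its JSON sidecar.
#' The correlation matrix itself is not stored; it is re-assembled
#' deterministically from the recorded configuration and seed.
#'
#' @param path path passed to [writeDataset()].
#' @return a [SimulatedSet].
#' @export
readDataset <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("sidecar metadata file not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  c0 <- meta$config
  cfg <- SimConfig(n = c0$n, p = c0$p, sigmaB = c0$sigmaB, sigmaE = c0$sigmaE,
                   r = c0$r, thetaMin = c0$thetaMin, tau = c0$tau,
                   family = c0$family, lambdaRate = c0$lambdaRate,
                   corrKind = c0$corrKind, rhoMaxRange = c0$rhoMaxRange,
                   rhoMinRange = c0$rhoMinRange,
                   rhoFixed = c0$rhoFixed %||% NA_real_, nu = c0$nu,
                   seed = c0$seed)
  dt <- as.data.frame(data.table::fread(path))
  y <- factor(dt$group, levels = .GROUPS)
  X <- as.matrix(dt[setdiff(names(dt), "group")])
  eff <- new("EffectModel", alpha = meta$alpha, tau = cfg@tau,
             delta = meta$delta, z = as.integer(meta$z))
  set.seed(cfg@seed)
  mu <- sampleBaseExpressions(cfg@p)
  corr <- new("CorrelationModel",
              blockSizes = as.integer(meta$blockSizes),
              rhoSequences = list(), R = diag(cfg@p),
              pdRepaired = isTRUE(meta$pdRepaired))
  .newSimulatedSet(X, y, mu = if (cfg@family == "poisson")
                     rep(cfg@lambdaRate, cfg@p) else mu,
                   v = meta$marginalVariance, config = cfg, corr = corr,
                   effects = eff)
}
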