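#' Derive a reproducible sub-seed
#'
#' Folds `(masterSeed, index, index, ...)` through a splitmix64 mixing
#' function into a 31-bit seed. Derivation depends only on the indices, never
#' on execution order, so parallel and serial sweeps produce identical
#' results.
#'
#' @param masterSeed integer.
#' @param ... further integer indices (cell index, replication index, ...).
#' @return a single integer seed in `[2, 2^31 - 1)`.
#' @export
deriveSeed <- function(masterSeed, ...) {
  parts <- as.integer(c(masterSeed, ...))
  if (anyNA(parts)) stop("seed components must be integers")
  .derive_seed_cpp(parts)
}

#' Construct a factorial simulation design
#'
#' @param n,p,sigmaB,sigmaE,thetaMin,r numeric vectors of factor levels.
#' @param corr list of correlation specs, each `list(kind =, rho =)` where
#'   `kind` is a `SimConfig` corrKind and `rho` is used by the exchangeable
#'   structure.
#' @param methods classifier keys to benchmark.
#' @param nReps replications per design cell (the reference design uses 500).
#' @param masterSeed integer master seed.
#' @param workers parallel workers for [runFactorial()].
#' @return a [FactorGrid].
#' @export
FactorGrid <- function(n, p, sigmaB = 2.5, sigmaE = 1.5, thetaMin = 2, r = 3,
                       corr = list(list(kind = "hub_toeplitz_blocks",
                                        rho = NA_real_)),
                       methods = .METHODS, nReps = 500L, masterSeed = 1L,
                       workers = 1L) {
  if (!is.list(corr[[1]])) corr <- list(corr)
  new("FactorGrid",
      levels = list(n = n, p = p, sigmaB = sigmaB, sigmaE = sigmaE,
                    thetaMin = thetaMin, r = r, corr = corr),
      methods = methods, nReps = as.integer(nReps),
      masterSeed = as.integer(masterSeed), workers = as.integer(workers))
}

.configForCell <- function(cell, seed) {
  SimConfig(n = cell$n, p = cell$p, sigmaB = cell$sigmaB, sigmaE = cell$sigmaE,
            r = cell$r, thetaMin = cell$thetaMin,
            corrKind = cell$corr$kind,
            rhoFixed = cell$corr$rho %||% NA_real_, seed = seed)
}

#' Run all replications of one design cell
#'
#' For every replication a fresh dataset is simulated from a derived seed
#' (re-drawing the random design elements H, rhoMax, rhoMin and the effect
#' signs), each method is tuned once on the full dataset by stratified
#' 10-fold CV, and its leave-one-out performance is recorded. Missing
#' estimates (e.g. LDA with p >= n - 1) are excluded from the aggregates and
#' counted. The standard error is the SD of the per-replication estimates
#' divided by the square root of the number of effective replications.
#'
#' @param config a [SimConfig]; its seed acts as the cell seed.
#' @param methods classifier keys.
#' @param nReps number of replications.
#' @param grids optional named list of tuning-grid overrides per method
#'   (see [defaultGrid()]); an entry may also be a `function(n, p)` building
#'   a grid, re-invoked for every replication (needed for randomized grids).
#'   `trimmedGrids = TRUE` is shorthand for the scaled-down grids.
#' @param trimmedGrids logical, use the trimmed grids of [defaultGrid()].
#' @return data.frame with one row per method: factor values, mean and SE of
#'   error/sensitivity/specificity, and `nEffectiveReps`.
#' @export
runCell <- function(config, methods = .METHODS, nReps = 10L, grids = NULL,
                    trimmedGrids = FALSE) {
  stopifnot(is(config, "SimConfig"))
  reps <- vector("list", nReps)
  for (rep in seq_len(nReps)) {
    repSeed <- deriveSeed(config@seed, rep)
    cfg <- config
    cfg@seed <- repSeed
    ds <- simulateDataset(cfg)
    set.seed(deriveSeed(repSeed, 1L))
    rows <- lapply(methods, function(m) {
      grid <- grids[[m]] %||%
        (if (trimmedGrids) defaultGrid(m, cfg@n, cfg@p, trimmed = TRUE) else NULL)
      # a function-valued override is re-invoked per replication, so grids
      # with random candidates (e.g. uniform cost/gamma draws) are re-drawn
      # for every simulated dataset
      if (is.function(grid)) grid <- grid(cfg@n, cfg@p)
      params <- tuneParams(m, ds, grid = grid)
      asRecord(loocv(m, params, ds))
    })
    reps[[rep]] <- do.call(rbind, rows)
  }
  all <- do.call(rbind, reps)
  agg <- lapply(methods, function(m) {
    sub <- all[all$method == m & !all$missing, , drop = FALSE]
    k <- nrow(sub)
    seOf <- function(x) if (k > 1L) sd(x) / sqrt(k) else NA_real_
    data.frame(
      n = config@n, p = config@p, sigmaB = config@sigmaB,
      sigmaE = config@sigmaE, thetaMin = config@thetaMin, r = config@r,
      corrKind = config@corrKind, rho = config@rhoFixed, method = m,
      meanError = if (k) mean(sub$error) else NA_real_,
      seError = if (k) seOf(sub$error) else NA_real_,
      meanSensitivity = if (k) mean(sub$sensitivity) else NA_real_,
      seSensitivity = if (k) seOf(sub$sensitivity) else NA_real_,
      meanSpecificity = if (k) mean(sub$specificity) else NA_real_,
      seSpecificity = if (k) seOf(sub$specificity) else NA_real_,
      nEffectiveReps = k, missing = k == 0L, stringsAsFactors = FALSE)
  })
  do.call(rbind, agg)
}

#' Run a full factorial sweep
#'
#' Expands the Cartesian product of the grid's factor levels, runs every cell
#' with [runCell()] under a per-cell seed derived from the master seed and
#' the cell index (so serial and parallel executions agree exactly), and
#' returns — and optionally writes — a long-format results table. With
#' `resume = TRUE` and an existing output file, completed cells are skipped.
#'
#' @param grid a [FactorGrid].
#' @param out optional CSV path; rows are appended per cell.
#' @param resume logical, skip cells already present in `out`.
#' @param trimmedGrids logical, passed to [runCell()].
#' @return data.frame of all cell results.
#' @export
runFactorial <- function(grid, out = NULL, resume = FALSE,
                         trimmedGrids = FALSE) {
  stopifnot(is(grid, "FactorGrid"))
  lv <- grid@levels
  cells <- expand.grid(n = lv$n, p = lv$p, sigmaB = lv$sigmaB,
                       sigmaE = lv$sigmaE, thetaMin = lv$thetaMin, r = lv$r,
                       corrIdx = seq_along(lv$corr), KEEP.OUT.ATTRS = FALSE)
  done <- character()
  if (resume && !is.null(out) && file.exists(out)) {
    prev <- as.data.frame(data.table::fread(out))
    done <- unique(prev$cellId)
  }
  cellKey <- function(cell) paste(cell$n, cell$p, cell$sigmaB, cell$sigmaE,
                                  cell$thetaMin, cell$r, cell$corrIdx,
                                  sep = "|")
  runOne <- function(i) {
    cell <- as.list(cells[i, ])
    cell$corr <- lv$corr[[cell$corrIdx]]
    key <- cellKey(cell)
    if (key %in% done) return(NULL)
    cfg <- .configForCell(cell, seed = deriveSeed(grid@masterSeed, i))
    t0 <- proc.time()[[3]]
    res <- runCell(cfg, methods = grid@methods, nReps = grid@nReps,
                   trimmedGrids = trimmedGrids)
    res$cellId <- key
    message(sprintf("[cell %d/%d] %s | %d reps x %d methods | %.1fs",
                    i, nrow(cells), key, grid@nReps, length(grid@methods),
                    proc.time()[[3]] - t0))
    res
  }
  results <- if (grid@workers > 1L) {
    parallel::mclapply(seq_len(nrow(cells)), runOne, mc.cores = grid@workers)
  } else {
    lapply(seq_len(nrow(cells)), runOne)
  }
  results <- do.call(rbind, results[!vapply(results, is.null, TRUE)])
  if (!is.null(out)) {
    if (!is.null(results))
      data.table::fwrite(results, out, append = resume && file.exists(out))
    if (file.exists(out))
      results <- as.data.frame(data.table::fread(out))
  }
  results
}

#' Order methods by mean error within one design cell
#'
#' Methods are sorted ascending by `meanError`; a method is flagged as tied
#' with its successor when the absolute difference is below twice the pooled
#' standard error.
#'
#' @param results a cell-results table from [runCell()]/[runFactorial()].
#' @param cell optional named list of factor values to filter on (e.g.
#'   `list(n = 100, p = 25)`); NULL uses the whole table (assumed one cell).
#' @return data.frame (method, meanError, seError, tiedWithNext).
#' @export
rankMethods <- function(results, cell = NULL) {
  sub <- results
  if (!is.null(cell))
    for (nm in names(cell)) sub <- sub[sub[[nm]] == cell[[nm]], , drop = FALSE]
  sub <- sub[!sub$missing, , drop = FALSE]
  if (!nrow(sub)) stop("no (non-missing) results for the requested cell")
  sub <- sub[order(sub$meanError), , drop = FALSE]
  tied <- rep(FALSE, nrow(sub))
  if (nrow(sub) > 1L) {
    for (i in seq_len(nrow(sub) - 1L)) {
      pooledSE <- sqrt(sum(c(sub$seError[i], sub$seError[i + 1L])^2, na.rm = TRUE))
      tied[i] <- abs(sub$meanError[i + 1L] - sub$meanError[i]) < 2 * pooledSE
    }
  }
  data.frame(method = sub$method, meanError = sub$meanError,
             seError = sub$seError, tiedWithNext = tied,
             stringsAsFactors = FALSE)
}
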