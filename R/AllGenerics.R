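#' @rdname SimulatedSet-class
#' @param x a `SimulatedSet`.
#' @export
setGeneric("datasetMatrix", function(x) standardGeneric("datasetMatrix"))

#' @rdname SimulatedSet-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname SimulatedSet-class
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname SimulatedSet-class
#' @export
setGeneric("effectModel", function(x) standardGeneric("effectModel"))

#' @rdname SimulatedSet-class
#' @export
setGeneric("correlationModel", function(x) standardGeneric("correlationModel"))

#' @rdname SimulatedSet-class
#' @export
setGeneric("baseExpressions", function(x) standardGeneric("baseExpressions"))

#' @rdname SimulatedSet-class
#' @export
setGeneric("marginalVariance", function(x) standardGeneric("marginalVariance"))

#' Samples-by-features matrix of a `SimulatedSet`
#'
#' The assay is stored features x samples (Bioconductor convention); the
#' learners consume samples x features, which is what this accessor returns.
#' @param x a `SimulatedSet`.
#' @rdname SimulatedSet-class
#' @aliases datasetMatrix,SimulatedSet-method
setMethod("datasetMatrix", "SimulatedSet", function(x)
  t(SummarizedExperiment::assay(x, "expr")))

#' @rdname SimulatedSet-class
#' @aliases groupLabels,SimulatedSet-method
setMethod("groupLabels", "SimulatedSet", function(x) x$group)

#' @rdname SimulatedSet-class
#' @aliases groupLabels,FeatureTable-method
setMethod("groupLabels", "FeatureTable", function(x) x@y)

#' @rdname SimulatedSet-class
#' @aliases datasetMatrix,FeatureTable-method
setMethod("datasetMatrix", "FeatureTable", function(x) x@X)

#' @rdname SimulatedSet-class
#' @aliases simConfig,SimulatedSet-method
setMethod("simConfig", "SimulatedSet", function(x)
  S4Vectors::metadata(x)$config)

#' @rdname SimulatedSet-class
#' @aliases effectModel,SimulatedSet-method
setMethod("effectModel", "SimulatedSet", function(x)
  S4Vectors::metadata(x)$effects)

#' @rdname SimulatedSet-class
#' @aliases correlationModel,SimulatedSet-method
setMethod("correlationModel", "SimulatedSet", function(x)
  S4Vectors::metadata(x)$correlation)

#' @rdname SimulatedSet-class
#' @aliases baseExpressions,SimulatedSet-method
setMethod("baseExpressions", "SimulatedSet", function(x)
  S4Vectors::metadata(x)$mu)

#' @rdname SimulatedSet-class
#' @aliases marginalVariance,SimulatedSet-method
setMethod("marginalVariance", "SimulatedSet", function(x)
  S4Vectors::metadata(x)$marginalVariance)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@family, "family\n")
  cat(sprintf("  n = %d, p = %d, sigmaB = %g, sigmaE = %g, r = %d\n",
              object@n, object@p, object@sigmaB, object@sigmaE, object@r))
  cat(sprintf("  thetaMin = %g (alpha = %.4f), tau = %g\n",
              object@thetaMin, log2(object@thetaMin), object@tau))
  cat("  correlation:", object@corrKind,
      if (object@corrKind == "exchangeable_single_block")
        sprintf("(rho = %g)", object@rhoFixed) else "", "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "CorrelationModel", function(object) {
  cat(sprintf("CorrelationModel: %d x %d, %d block(s)%s\n",
              nrow(object@R), ncol(object@R), length(object@blockSizes),
              if (object@pdRepaired) " [PD-repaired]" else ""))
  cat("  block sizes:", paste(object@blockSizes, collapse = ", "), "\n")
})

setMethod("show", "EffectModel", function(object) {
  cat(sprintf("EffectModel: %d effects, alpha = %.4f, tau = %g\n",
              length(object@delta), object@alpha, object@tau))
  if (length(object@delta))
    cat(sprintf("  delta range [%.3f, %.3f]; mean fold change 2^mean(delta) = %.3f\n",
                min(object@delta), max(object@delta), 2^mean(object@delta)))
})

setMethod("show", "TunedParams", function(object) {
  cat("TunedParams:", object@method, "\n")
  if (length(object@params))
    cat(" ", paste(names(object@params), unlist(object@params), sep = " = ",
                   collapse = ", "), "\n")
  else cat("  (no tuning parameters)\n")
  if (!is.na(object@cvError))
    cat(sprintf("  10-fold CV error at optimum: %.4f\n", object@cvError))
})

setMethod("show", "PerformanceEstimate", function(object) {
  if (object@missing) {
    cat(sprintf("PerformanceEstimate [%s]: missing (%s)\n",
                object@method, object@reason))
  } else {
    cat(sprintf("PerformanceEstimate [%s]: error %.4f, sensitivity %.4f, specificity %.4f (n = %d)\n",
                object@method, object@error, object@sensitivity,
                object@specificity, object@nEval))
  }
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d samples x %d features; groups %s\n",
              nrow(object@X), ncol(object@X),
              paste(sprintf("%s (%d)", levels(object@y), table(object@y)),
                    collapse = " vs ")))
})

setMethod("show", "FactorGrid", function(object) {
  cat("FactorGrid:", prod(lengths(object@levels)), "cells x",
      object@nReps, "replications\n")
  for (nm in names(object@levels)) {
    lv <- object@levels[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (nm == "corr") paste(vapply(lv, function(z)
                  if (is.na(z$rho %||% NA)) z$kind else
                    paste0(z$kind, "(", z$rho, ")"), ""), collapse = ", ")
                else paste(lv, collapse = ", ")))
  }
  cat("  methods:", paste(object@methods, collapse = ", "),
      "| master seed:", object@masterSeed, "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
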