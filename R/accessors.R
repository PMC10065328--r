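#' @rdname PredictorPanel-class
#' @export
setMethod("lineIds", "PredictorPanel", function(x) rownames(x@genotypes))

#' @rdname PredictorPanel-class
#' @export
setMethod("predictorIds", "PredictorPanel", function(x) colnames(x@genotypes))

#' @rdname PredictorPanel-class
#' @export
setMethod("genotypes", "PredictorPanel", function(x) x@genotypes)

#' @rdname PredictorPanel-class
#' @export
setMethod("panelKind", "PredictorPanel", function(x) x@kind)

#' @rdname PredictorPanel-class
#' @export
setMethod("dim", "PredictorPanel", function(x) dim(x@genotypes))

#' Subset a panel by lines and/or predictors
#'
#' @param x a [PredictorPanel-class]
#' @param i line selector, @param j predictor selector (as for a matrix)
#' @param ... ignored
#' @param drop ignored (always FALSE)
#' @export
setMethod("[", "PredictorPanel", function(x, i, j, ..., drop = FALSE) {
  g <- x@genotypes
  if (missing(i)) i <- seq_len(nrow(g))
  if (missing(j)) j <- seq_len(ncol(g))
  jj <- seq_len(ncol(g))[j]  # resolve names/logicals to positions once
  PredictorPanel(g[i, jj, drop = FALSE], kind = x@kind,
                 chrom = if (length(x@chrom)) x@chrom[jj] else character(),
                 pos   = if (length(x@pos)) x@pos[jj] else numeric())
})

setMethod("show", "PredictorPanel", function(object) {
  cat(sprintf("PredictorPanel: %d lines x %d %s predictors%s\n",
              nrow(object@genotypes), ncol(object@genotypes), object@kind,
              if (length(object@pos)) " (mapped)" else ""))
})

#' @rdname RelationshipKernel-class
#' @export
setMethod("lineIds", "RelationshipKernel", function(x) rownames(x@K))

#' @rdname RelationshipKernel-class
#' @export
setMethod("kernelMatrix", "RelationshipKernel", function(x) x@K)

#' @rdname RelationshipKernel-class
#' @export
setMethod("kernelKind", "RelationshipKernel", function(x) x@kind)

#' @rdname RelationshipKernel-class
#' @export
setMethod("scaleConstant", "RelationshipKernel", function(x) x@scaleC)

setMethod("show", "RelationshipKernel", function(object) {
  cat(sprintf("RelationshipKernel (%s): %d lines, %s terms, scale c = %.6g, ridge = %.3g\n",
              object@kind, nrow(object@K),
              format(object@nTerms, big.mark = ","), object@scaleC, object@ridge))
})

#' @rdname InteractionPairs-class
#' @export
setMethod("length", "InteractionPairs", function(x) length(x@i))

setMethod("show", "InteractionPairs", function(object) {
  cat(sprintf("InteractionPairs: %d unordered pairs over %d predictors\n",
              length(object@i), length(object@predictorIds)))
})

#' Pairs of an interaction set as a data.frame
#'
#' @param x an [InteractionPairs-class] or [EffectVarianceRanking-class]
#' @param ... ignored
#' @return data.frame with predictor ids, indices, frequency (and, for a
#'   ranking, alpha / varHat / rank).
#' @export
as.data.frame.InteractionPairs <- function(x, ...) {
  data.frame(
    j_id = x@predictorIds[x@i], k_id = x@predictorIds[x@j],
    i = x@i, j = x@j, frequency = x@freq, score = x@score,
    stringsAsFactors = FALSE
  )
}

#' @rdname as.data.frame.InteractionPairs
#' @export
as.data.frame.EffectVarianceRanking <- function(x, ...) {
  df <- as.data.frame(x@pairs)
  df$score <- NULL
  df$alpha_hat <- x@alpha
  df$var_hat <- x@varHat
  df$rank <- rank(-x@varHat, ties.method = "first")
  df
}

setMethod("show", "EffectVarianceRanking", function(object) {
  cat(sprintf("EffectVarianceRanking: %d pairs, varHat range [%.3g, %.3g]\n",
              length(object@pairs@i),
              suppressWarnings(min(object@varHat)),
              suppressWarnings(max(object@varHat))))
})

setMethod("show", "UnivariateFit", function(object) {
  cat(sprintf(paste0("UnivariateFit: sigma2_g = %.4g, sigma2_e = %.4g ",
                     "(h2 = %.3f), logL = %.4f, %s\n"),
              object@sigmaG, object@sigmaE,
              object@sigmaG / (object@sigmaG + object@sigmaE),
              object@logLik,
              if (object@converged) "converged" else "not converged"))
})

setMethod("show", "BivariateFit", function(object) {
  rg <- object@G0[1, 2] / sqrt(object@G0[1, 1] * object@G0[2, 2])
  cat(sprintf(paste0("BivariateFit (years %s/%s): sigma2_g = (%.4g, %.4g), ",
                     "sigma_g12 = %.4g (r_g = %.3f), sigma2_e = (%.4g, %.4g)\n",
                     "  logL = %.4f after %d iterations; %s%s\n"),
              object@years[1], object@years[2],
              object@G0[1, 1], object@G0[2, 2], object@G0[1, 2], rg,
              object@sigmaE[1], object@sigmaE[2],
              object@logLik, object@nIter,
              if (object@converged) "converged" else "not converged",
              if (object@fixedFallback) " (BLUPs at fixed initial components)" else ""))
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan: %d lines, %d folds x %d reps (seed %d)\n",
              nrow(object@assignment), object@folds, object@reps, object@seed))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(paste0("EvaluationResult [%s%s]: mean PA = %.4f over %d folds ",
                     "(%.0f%% converged%s)\n"),
              object@spec$model,
              if (!is.null(object@spec$q) && !is.na(object@spec$q))
                sprintf(", q = %g", object@spec$q) else "",
              object@paMean, length(object@paPerFold), object@pctConverged,
              if (object@foldsSkipped > 0L)
                sprintf(", %d skipped", object@foldsSkipped) else ""))
})
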