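#' Backsolve per-interaction effects from an ERRBLUP fit
#'
#' Given genetic-value BLUPs g_hat from a fit that used the full
#' pairwise-interaction kernel, recovers the implied per-pair random
#' regression effects via the kernel/marker-effect equivalence of random
#' regression BLUP: alpha = (1 / c) W' K^+ g_hat, with W the centered
#' interaction design, c the kernel scaling constant and K^+ the
#' Moore-Penrose pseudo-inverse of the unridged kernel.  Columns of W are
#' processed in batches, so the full design is never materialized, and the
#' result is independent of the batch size.
#'
#' @param panel the [PredictorPanel-class] the kernel was built from.
#' @param gHat named numeric of genetic-value BLUPs (one per kernel line),
#'   e.g. the `gHat` slot of a [UnivariateFit-class].
#' @param kernel the [RelationshipKernel-class] of kind `"errblup"` used in
#'   the fit.
#' @param batchSize maximum number of pair columns processed at once.
#' @param pinvTol relative singular-value cutoff for the pseudo-inverse.
#' @return an [EffectVarianceRanking-class] with `alpha` filled and `varHat`
#'   empty (fill it with [effectVariances()]).
#' @export
backsolveEffects <- function(panel, gHat, kernel, batchSize = 2^20,
                             pinvTol = 1e-10) {
  m <- genotypes(panel)
  if (kernel@kind != "errblup")
    stopf("backsolve requires an errblup kernel, got '%s'", kernel@kind)
  if (!identical(kernel@panelDigest, panelDigest(rownames(m), colnames(m), m)))
    stopf("kernel was not built from this panel")
  if (is.null(names(gHat)) || !setequal(names(gHat), rownames(m)) ||
      length(gHat) != nrow(m))
    stopf("gHat must be named with exactly the panel's line ids")
  gHat <- gHat[rownames(m)]
  K0 <- kernel@K - diag(kernel@ridge, nrow(kernel@K))
  e <- eigen(K0, symmetric = TRUE)
  keep <- e$values > pinvTol * max(e$values)
  v <- e$vectors[, keep, drop = FALSE] %*%
    ((crossprod(e$vectors[, keep, drop = FALSE], gHat)) / e$values[keep])
  v <- drop(v)
  pairs <- allPairs(panel)
  cc <- kernel@scaleC
  sv <- sum(v)
  nP <- length(pairs@i)
  alpha <- numeric(nP)
  .pairBatches(nP, batchSize, function(idx) {
    Tb <- m[, pairs@i[idx], drop = FALSE] * m[, pairs@j[idx], drop = FALSE]
    alpha[idx] <<- (crossprod(Tb, v) - pairs@freq[idx] * sv) / cc
  })
  new("EffectVarianceRanking", pairs = pairs, alpha = alpha,
      varHat = numeric(0))
}

#' Estimated effect variance per interaction pair
#'
#' The variance contributed by a centered 0/1 interaction column with
#' combination frequency f and effect alpha is alpha^2 f (1 - f); this is the
#' sERRBLUP selection criterion.
#'
#' @param ranking an [EffectVarianceRanking-class] with `alpha` filled.
#' @return the ranking with `varHat` filled.
#' @export
effectVariances <- function(ranking) {
  if (!length(ranking@alpha)) stopf("alpha is not filled")
  f <- ranking@pairs@freq
  ranking@varHat <- ranking@alpha^2 * f * (1 - f)
  validObject(ranking)
  ranking
}

#' Select the top fraction of interaction pairs by effect variance
#'
#' Returns the ceiling(q * P) pairs with the largest estimated effect
#' variance.  Ties are broken by lexicographic pair order (stable and
#' deterministic).  The returned set is sorted lexicographically; nestedness
#' holds: a larger q always yields a superset.
#'
#' @param ranking an [EffectVarianceRanking-class] with `varHat` filled.
#' @param q selection fraction in (0, 1].  The evaluation grid used for the
#'   reported tables is \{0.10, 0.05, 0.01, 0.001, 0.0001, 0.00001\}, but any
#'   fraction is accepted.
#' @return an [InteractionPairs-class] with `score` carrying varHat.
#' @export
selectTop <- function(ranking, q) {
  if (!length(ranking@varHat)) stopf("varHat is not filled; call effectVariances() first")
  if (q <= 0 || q > 1) stopf("q must lie in (0, 1]")
  P <- length(ranking@pairs@i)
  mTop <- ceiling(q * P)
  ord <- order(-ranking@varHat, seq_len(P))   # stable: ties keep pair order
  take <- sort(ord[seq_len(mTop)])            # back to lexicographic order
  p0 <- ranking@pairs
  InteractionPairs(p0@i[take], p0@j[take], freq = p0@freq[take],
                   predictorIds = p0@predictorIds,
                   score = ranking@varHat[take])
}
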