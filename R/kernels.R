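#' Number of unordered pairwise interactions
#'
#' All unordered predictor pairs including self-pairs: p (p + 1) / 2.  The
#' self-pair of a 0/1 predictor is the predictor itself, so the full
#' interaction design contains the additive columns as a subset.
#'
#' @param p number of predictors (>= 1).
#' @return the pair count as a double (pair counts overflow 32-bit integers
#'   for realistic SNP panels).
#' @examples
#' nInteractions(3330)   # 5546115 pairs for 3330 haplotype-block variants
#' @export
nInteractions <- function(p) {
  if (any(p <= 0) || any(p != floor(p))) stopf("p must be a positive integer")
  p * (p + 1) / 2
}

#' All unordered predictor pairs of a panel
#'
#' Enumerates pairs (j, k) with j <= k in lexicographic order and computes
#' each pair's combination frequency, the mean over lines of the product of
#' the two 0/1 predictor columns.
#'
#' @param panel a [PredictorPanel-class].
#' @return an [InteractionPairs-class].
#' @export
allPairs <- function(panel) {
  m <- genotypes(panel)
  p <- ncol(m)
  i <- rep.int(seq_len(p), times = p - seq_len(p) + 1L)
  j <- unlist(lapply(seq_len(p), function(a) a:p), use.names = FALSE)
  FF <- crossprod(m) / nrow(m)          # F[i, j] = frequency of combination (i, j)
  InteractionPairs(i, j, freq = FF[cbind(i, j)], predictorIds = colnames(m))
}

#' Materialize the pairwise-interaction design
#'
#' The column for pair (j, k) codes absence (0) or presence (1) of the marker
#' combination: the elementwise product of predictor columns j and k.  The
#' self-pair column (j, j) equals column j.  Only intended for small or
#' selected pair sets; the full ERRBLUP kernel never materializes this matrix
#' (see [errblupKernel()]).
#'
#' @param panel a [PredictorPanel-class].
#' @param pairs an [InteractionPairs-class], or `"all"`.
#' @return n x |pairs| 0/1 matrix, columns in `pairs` order.
#' @export
interactionDesign <- function(panel, pairs = "all") {
  m <- genotypes(panel)
  if (identical(pairs, "all")) pairs <- allPairs(panel)
  if (length(pairs@i) && (max(pairs@j) > ncol(m) || min(pairs@i) < 1L))
    stopf("pair index out of predictor range")
  TT <- m[, pairs@i, drop = FALSE] * m[, pairs@j, drop = FALSE]
  colnames(TT) <- paste(pairs@predictorIds[pairs@i],
                        pairs@predictorIds[pairs@j], sep = "x")
  TT
}

# Shared ridge guard: make the kernel numerically PSD with a strictly
# positive diagonal before it reaches REML.
.ridgeGuard <- function(K) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  delta <- max(0, -min(ev)) + 1e-8 * mean(diag(K))
  list(K = K + diag(delta, nrow(K)), ridge = delta)
}

#' Additive (VanRaden) genomic relationship kernel
#'
#' DH lines carry dosage 0 or 2 of the counted allele.  With X the dosage
#' matrix and column allele frequencies p_j, columns are centered by 2 p_j
#' and the cross-product is scaled by the sum of 2 p_j (1 - p_j):
#' K = Z Z' / sum_j 2 p_j q_j.
#'
#' @param panel a [PredictorPanel-class].
#' @return a [RelationshipKernel-class] of kind `"gblup"`.
#' @export
gblupKernel <- function(panel) {
  m <- genotypes(panel)
  if (nrow(m) < 2L) stopf("need at least 2 lines")
  p <- colMeans(m)                       # allele frequency (dosage / 2)
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stopf("all predictors are monomorphic: GBLUP denominator is zero")
  Z <- 2 * sweep(m, 2L, p, `-`)
  K <- tcrossprod(Z) / denom
  g <- .ridgeGuard(K)
  new("RelationshipKernel", K = g$K, kind = "gblup", scaleC = denom,
      nTerms = ncol(m), ridge = g$ridge,
      panelDigest = panelDigest(rownames(m), colnames(m), m))
}

#' Full pairwise-interaction (ERRBLUP) kernel
#'
#' The epistatic random regression kernel over all p (p + 1) / 2 unordered
#' marker combinations, with VanRaden-analogous column-frequency centering
#' and a sum-of-column-variances denominator: with T the interaction design,
#' f its column means and W = T - 1 f', K = W W' / c, c = sum_k f_k (1 - f_k).
#'
#' The computation never materializes T.  For 0/1 panels every required
#' quantity is a function of S = M M' and the row sums of M: if lines a and b
#' share s loci at value 1, they share s (s + 1) / 2 pair combinations, so
#' (T T')_ab = (S_ab^2 + S_ab) / 2, and the centering terms are row/column
#' means of that matrix.
#'
#' @param panel a [PredictorPanel-class].
#' @return a [RelationshipKernel-class] of kind `"errblup"`.
#' @export
errblupKernel <- function(panel) {
  m <- genotypes(panel)
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 lines")
  S <- tcrossprod(m)
  TT <- (S * S + S) / 2                  # uncentered T T'
  u <- rowSums(TT) / n                   # u_a = sum_k f_k T_ak
  sumf <- sum(diag(TT)) / n              # sum_k f_k   (diag TT = row pair counts)
  sumf2 <- sum(TT) / n^2                 # sum_k f_k^2
  cc <- sumf - sumf2
  if (cc <= 1e-12 * max(1, sumf))
    stopf("all interaction columns are constant (c = 0); are all lines identical?")
  K <- (TT - outer(u, rep(1, n)) - outer(rep(1, n), u) + sumf2) / cc
  dimnames(K) <- list(rownames(m), rownames(m))
  g <- .ridgeGuard(K)
  new("RelationshipKernel", K = g$K, kind = "errblup", scaleC = cc,
      nTerms = nInteractions(ncol(m)), ridge = g$ridge,
      panelDigest = panelDigest(rownames(m), colnames(m), m))
}

# iterate over pair batches, calling fn(idx) for index slices
.pairBatches <- function(nPairs, batchSize, fn) {
  starts <- seq.int(1L, nPairs, by = batchSize)
  for (s in starts) fn(s:min(s + batchSize - 1L, nPairs))
  invisible(NULL)
}

#' Selected-interaction (sERRBLUP) kernel
#'
#' Kernel over a selected subset of interaction pairs, centered by the pairs'
#' full-panel combination frequencies and scaled by
#' c_s = sum over selected pairs of f (1 - f).  Selected pair columns are
#' materialized in batches so peak memory is bounded by `batchSize` columns;
#' the result is identical for any batch size.
#'
#' @param panel a [PredictorPanel-class] (all lines; frequencies are computed
#'   on the full panel).
#' @param selected a non-empty [InteractionPairs-class] over the panel's
#'   predictors.
#' @param batchSize maximum number of pair columns held in memory at once.
#' @return a [RelationshipKernel-class] of kind `"serrblup"`.
#' @export
serrblupKernel <- function(panel, selected, batchSize = 2^20) {
  m <- genotypes(panel)
  n <- nrow(m)
  if (!is(selected, "InteractionPairs") || length(selected@i) == 0L)
    stopf("selected must be a non-empty InteractionPairs")
  if (!identical(selected@predictorIds, colnames(m)))
    stopf("selected pairs were built on a different predictor panel")
  nP <- length(selected@i)
  CP <- matrix(0, n, n)
  v <- numeric(n)
  sumf <- 0; sumf2 <- 0
  .pairBatches(nP, batchSize, function(idx) {
    Tb <- m[, selected@i[idx], drop = FALSE] * m[, selected@j[idx], drop = FALSE]
    fb <- colMeans(Tb)
    CP <<- CP + tcrossprod(Tb)
    v <<- v + drop(Tb %*% fb)
    sumf <<- sumf + sum(fb)
    sumf2 <<- sumf2 + sum(fb^2)
  })
  cs <- sumf - sumf2
  if (cs <= 1e-12 * max(1, sumf))
    stopf("all selected interaction columns are constant (c = 0)")
  K <- (CP - outer(v, rep(1, n)) - outer(rep(1, n), v) + sumf2) / cs
  dimnames(K) <- list(rownames(m), rownames(m))
  g <- .ridgeGuard(K)
  new("RelationshipKernel", K = g$K, kind = "serrblup", scaleC = cs,
      nTerms = nP, ridge = g$ridge,
      panelDigest = panelDigest(rownames(m), colnames(m), m))
}
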