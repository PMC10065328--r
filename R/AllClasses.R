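#' @import methods
NULL

#' Binary predictor panel for doubled-haploid lines
#'
#' Holds a lines-by-predictors matrix of 0/1 genotype codes.  Doubled-haploid
#' (DH) lines are fully homozygous, so a single bit per locus suffices: 0 and 1
#' are the two homozygous states.  Predictors are either SNPs (`kind = "snp"`)
#' or haplotype-block variants (`kind = "block"`), i.e. indicators that a line
#' carries a particular shared chromosomal segment.
#'
#' @slot genotypes numeric matrix, rows are lines, columns are predictors;
#'   all entries in \{0, 1\}; dimnames carry line and predictor identifiers.
#' @slot kind `"snp"` or `"block"`.
#' @slot chrom optional per-predictor chromosome labels (length 0 when no map).
#' @slot pos optional per-predictor 1-based map positions (length 0 when no map).
#'
#' @seealso [readPredictorPanel()], [simulateDhPanel()], [vifPrune()]
#' @export
setClass("PredictorPanel",
  representation(
    genotypes = "matrix",
    kind      = "character",
    chrom     = "character",
    pos       = "numeric"
  )
)

setValidity("PredictorPanel", function(object) {
  g <- object@genotypes
  msgs <- character()
  if (nrow(g) < 2L) msgs <- c(msgs, "panel needs at least 2 lines")
  if (ncol(g) < 1L) msgs <- c(msgs, "panel needs at least 1 predictor")
  if (is.null(rownames(g)) || is.null(colnames(g)))
    msgs <- c(msgs, "genotype matrix must carry line and predictor ids as dimnames")
  else {
    if (anyDuplicated(rownames(g))) msgs <- c(msgs, "line ids must be unique")
    if (anyDuplicated(colnames(g))) msgs <- c(msgs, "predictor ids must be unique")
  }
  if (anyNA(g)) msgs <- c(msgs, "genotypes must not contain missing values")
  else if (!all(g == 0 | g == 1)) msgs <- c(msgs, "all genotype entries must be 0 or 1")
  if (length(object@kind) != 1L || !object@kind %in% c("snp", "block"))
    msgs <- c(msgs, "kind must be \"snp\" or \"block\"")
  if (length(object@chrom) && length(object@chrom) != ncol(g))
    msgs <- c(msgs, "chrom must be empty or one entry per predictor")
  if (length(object@pos) && length(object@pos) != ncol(g))
    msgs <- c(msgs, "pos must be empty or one entry per predictor")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PredictorPanel
#'
#' @param genotypes lines x predictors matrix of 0/1 values with dimnames.
#' @param kind `"snp"` or `"block"`.
#' @param chrom,pos optional map coordinates (per predictor).
#' @return A [PredictorPanel-class] object.
#' @export
PredictorPanel <- function(genotypes, kind = c("snp", "block"),
                           chrom = character(), pos = numeric()) {
  kind <- match.arg(kind)
  storage.mode(genotypes) <- "double"
  new("PredictorPanel", genotypes = genotypes, kind = kind,
      chrom = as.character(chrom), pos = as.numeric(pos))
}

#' Genomic relationship kernel
#'
#' A symmetric lines-by-lines similarity matrix together with the model family
#' it encodes: additive VanRaden GBLUP, the full pairwise-interaction ERRBLUP
#' kernel, or the selected-interaction sERRBLUP kernel.  The scaling constant
#' (the denominator used to normalise the cross-product) and the number of
#' predictors or interaction pairs entering the kernel are recorded so the
#' per-term effect backsolve can be reproduced.
#'
#' @slot K symmetric numeric matrix with line ids as dimnames.
#' @slot kind `"gblup"`, `"errblup"` or `"serrblup"`.
#' @slot scaleC positive scaling denominator.
#' @slot nTerms number of predictors (gblup) or interaction pairs (errblup /
#'   serrblup) behind the kernel; numeric because pair counts can exceed
#'   the integer range.
#' @slot ridge diagonal ridge added to guarantee positive semi-definiteness.
#' @slot panelDigest internal fingerprint of the source panel (line and
#'   predictor ids) used to verify that downstream backsolves use the
#'   matching panel.
#' @export
setClass("RelationshipKernel",
  representation(
    K           = "matrix",
    kind        = "character",
    scaleC      = "numeric",
    nTerms      = "numeric",
    ridge       = "numeric",
    panelDigest = "character"
  )
)

setValidity("RelationshipKernel", function(object) {
  K <- object@K
  msgs <- character()
  if (nrow(K) != ncol(K)) msgs <- c(msgs, "kernel must be square")
  if (is.null(rownames(K))) msgs <- c(msgs, "kernel must carry line ids")
  if (max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K))))
    msgs <- c(msgs, "kernel must be symmetric")
  if (!object@kind %in% c("gblup", "errblup", "serrblup"))
    msgs <- c(msgs, "kind must be gblup, errblup or serrblup")
  if (object@scaleC <= 0) msgs <- c(msgs, "scaleC must be positive")
  if (any(diag(K) <= 0)) msgs <- c(msgs, "kernel diagonal must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' Set of unordered predictor pairs
#'
#' Pairs (j, k) with j <= k over the predictors of a panel, including
#' self-pairs (j, j); the self-pair column of the interaction design equals
#' the predictor column itself.  `freq` is the mean over lines of the pair's
#' 0/1 product indicator, computed on the panel the set was built from.
#'
#' @slot i,j 1-based predictor indices with i <= j.
#' @slot freq per-pair combination frequency in [0, 1].
#' @slot score optional per-pair score (NA when unset).
#' @slot predictorIds predictor identifiers of the source panel.
#' @export
setClass("InteractionPairs",
  representation(
    i = "integer",
    j = "integer",
    freq = "numeric",
    score = "numeric",
    predictorIds = "character"
  )
)

setValidity("InteractionPairs", function(object) {
  msgs <- character()
  n <- length(object@i)
  if (length(object@j) != n || length(object@freq) != n || length(object@score) != n)
    msgs <- c(msgs, "i, j, freq and score must have equal length")
  if (n) {
    if (any(object@i > object@j)) msgs <- c(msgs, "pairs must satisfy i <= j")
    p <- length(object@predictorIds)
    if (any(object@i < 1L) || any(object@j > p))
      msgs <- c(msgs, "pair indices out of predictor range")
    key <- (object@i - 1) * p + object@j
    if (anyDuplicated(key)) msgs <- c(msgs, "pairs must be unique")
    if (any(object@freq < 0 | object@freq > 1, na.rm = TRUE))
      msgs <- c(msgs, "freq must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

InteractionPairs <- function(i, j, freq, predictorIds,
                             score = rep(NA_real_, length(i))) {
  new("InteractionPairs", i = as.integer(i), j = as.integer(j),
      freq = as.numeric(freq), score = as.numeric(score),
      predictorIds = as.character(predictorIds))
}

#' Ranking of interaction pairs by estimated effect variance
#'
#' Carries backsolved per-pair effects (`alpha`) from an ERRBLUP fit and the
#' estimated effect variances `varHat = alpha^2 * f (1 - f)` used as the
#' sERRBLUP selection criterion.
#'
#' @slot pairs an [InteractionPairs-class] over the source panel.
#' @slot alpha backsolved effect per pair.
#' @slot varHat non-negative estimated effect variance per pair.
#' @export
setClass("EffectVarianceRanking",
  representation(
    pairs  = "InteractionPairs",
    alpha  = "numeric",
    varHat = "numeric"
  )
)

setValidity("EffectVarianceRanking", function(object) {
  n <- length(object@pairs@i)
  msgs <- character()
  if (length(object@alpha) != n)
    msgs <- c(msgs, "alpha must have one entry per pair")
  if (length(object@varHat) && length(object@varHat) != n)
    msgs <- c(msgs, "varHat must be empty or one entry per pair")
  if (length(object@varHat) && any(object@varHat < -1e-12, na.rm = TRUE))
    msgs <- c(msgs, "varHat must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Univariate REML fit
#'
#' @slot beta fixed-effect estimate (intercept).
#' @slot sigmaG,sigmaE genetic and residual variance components.
#' @slot lambda ratio sigmaG / sigmaE.
#' @slot logLik restricted log-likelihood at the optimum.
#' @slot gHat BLUP of the genetic value for every kernel line (named).
#' @slot converged,nIter convergence state of the variance search.
#' @export
setClass("UnivariateFit",
  representation(
    beta = "numeric", sigmaG = "numeric", sigmaE = "numeric",
    lambda = "numeric", logLik = "numeric", gHat = "numeric",
    converged = "logical", nIter = "integer"
  )
)

#' Bivariate (two-year) REML fit
#'
#' The same biological trait measured in two years is treated as two traits
#' with a common genomic kernel.  `G0` is the 2x2 genetic (co)variance matrix;
#' residuals are independent within and between years (separate field
#' seasons), so the residual covariance is structurally zero.
#'
#' @slot beta per-year intercepts (named by year).
#' @slot G0 2x2 symmetric genetic (co)variance matrix.
#' @slot sigmaE per-year residual variances.
#' @slot logLik restricted log-likelihood at the returned components.
#' @slot gHat kernel-lines x 2 matrix of genetic-value BLUPs (columns = years).
#' @slot converged,nIter convergence state.
#' @slot init the starting components (g11, g12, g22, e1, e2).
#' @slot fixedFallback TRUE when the fit did not converge and BLUPs were
#'   computed with the components fixed at `init`.
#' @slot years the two year labels.
#' @slot logLikTrace per-iteration restricted log-likelihood.
#' @export
setClass("BivariateFit",
  representation(
    beta = "numeric", G0 = "matrix", sigmaE = "numeric",
    logLik = "numeric", gHat = "matrix",
    converged = "logical", nIter = "integer",
    init = "numeric", fixedFallback = "logical",
    years = "numeric", logLikTrace = "numeric"
  )
)

#' Cross-validation plan
#'
#' Repeated k-fold partitions of the target-year phenotyped lines.  Each
#' replicate assigns every line to exactly one fold; fold sizes differ by at
#' most one.
#'
#' @slot folds,reps number of folds and replicates.
#' @slot seed the seed the partitions were drawn from.
#' @slot assignment lines x reps integer matrix of fold labels (1..folds).
#' @export
setClass("CVPlan",
  representation(
    folds = "integer", reps = "integer", seed = "integer",
    assignment = "matrix"
  )
)

setValidity("CVPlan", function(object) {
  a <- object@assignment
  msgs <- character()
  if (is.null(rownames(a))) msgs <- c(msgs, "assignment must carry line ids")
  if (ncol(a) != object@reps) msgs <- c(msgs, "assignment needs one column per rep")
  for (r in seq_len(ncol(a))) {
    sizes <- tabulate(a[, r], nbins = object@folds)
    if (sum(sizes) != nrow(a)) { msgs <- c(msgs, "every line must be in a fold"); break }
    if (max(sizes) - min(sizes) > 1L) { msgs <- c(msgs, "fold sizes must differ by <= 1"); break }
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of one cross-validated model evaluation
#'
#' @slot spec the model specification (list: model, q, predictorKind,
#'   environment, trait, targetYear, sourceYear).
#' @slot paPerFold predictive ability (Pearson correlation between predicted
#'   and observed test-set phenotypes) per computed fold x rep.
#' @slot paMean mean predictive ability over computed folds.
#' @slot paMeanConverged mean over converged folds only.
#' @slot accuracyMean paMean / sqrt(h2) when a heritability was supplied.
#' @slot rGFull genomic correlation from the full-data bivariate pre-fit
#'   (NA for univariate models).
#' @slot rP phenotypic correlation between years on common lines.
#' @slot pctConverged percentage of folds whose REML fit converged (fits that
#'   fell back to fixed initial components count as non-converged).
#' @slot foldConverged per-fold convergence flags.
#' @slot foldsSkipped number of degenerate folds skipped.
#' @export
setClass("EvaluationResult",
  representation(
    spec = "list",
    paPerFold = "numeric", paMean = "numeric", paMeanConverged = "numeric",
    accuracyMean = "numeric", rGFull = "numeric", rP = "numeric",
    pctConverged = "numeric", foldConverged = "logical",
    foldsSkipped = "integer"
  )
)
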