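#' Model specification for one evaluation
#'
#' @param model one of `"uni_gblup_within"` (univariate GBLUP trained on
#'   target-year training folds), `"uni_gblup_avg"` (univariate GBLUP trained
#'   on the per-line average of both years' phenotypes), `"bi_gblup"`,
#'   `"bi_errblup"`, `"bi_serrblup"`.
#' @param q selection fraction; required exactly when model is
#'   `"bi_serrblup"`.
#' @param predictorKind `"snp"` or `"block"`.
#' @param environment,trait which phenotype series to evaluate.
#' @param targetYear year predicted (test phenotypes come from it).
#' @param sourceYear previous year whose complete data are borrowed.
#' @return a validated list of class-free model spec.
#' @export
modelSpec <- function(model = c("uni_gblup_within", "uni_gblup_avg",
                                "bi_gblup", "bi_errblup", "bi_serrblup"),
                      q = NA_real_, predictorKind = c("snp", "block"),
                      environment, trait, targetYear, sourceYear) {
  model <- match.arg(model)
  predictorKind <- match.arg(predictorKind)
  if (model == "bi_serrblup") {
    if (is.na(q) || q <= 0 || q > 1)
      stopf("bi_serrblup requires a selection fraction q in (0, 1]")
  } else if (!is.na(q)) {
    stopf("q is only meaningful for bi_serrblup")
  }
  list(model = model, q = q, predictorKind = predictorKind,
       environment = environment, trait = trait,
       targetYear = targetYear, sourceYear = sourceYear)
}

#' Repeated k-fold cross-validation plan
#'
#' Randomly partitions the lines into `folds` subsets of as equal size as
#' possible (sizes differ by at most one), independently for each of `reps`
#' replicates.  Deterministic given the seed; the caller's RNG state is left
#' untouched.
#'
#' @param lines character vector of line ids (the target-year phenotyped
#'   lines).
#' @param folds,reps partition shape (default 5 x 5).
#' @param seed integer seed.
#' @return a [CVPlan-class].
#' @export
makeCvPlan <- function(lines, folds = 5, reps = 5, seed) {
  n <- length(lines)
  if (n < folds) stopf("fewer lines (%d) than folds (%d)", n, folds)
  if (anyDuplicated(lines)) stopf("line ids must be unique")
  base <- n %/% folds; rem <- n %% folds
  labels <- rep(seq_len(folds), times = c(rep(base + 1L, rem), rep(base, folds - rem)))
  assignment <- withSeed(as.integer(seed), {
    vapply(seq_len(reps), function(r) labels[order(runif(n))], integer(n))
  })
  rownames(assignment) <- lines
  new("CVPlan", folds = as.integer(folds), reps = as.integer(reps),
      seed = as.integer(seed), assignment = assignment)
}

#' Prediction accuracy from predictive ability
#'
#' Predictive ability (the Pearson correlation between predicted and
#' observed test-set phenotypes) divided by the square root of the trait
#' heritability.
#'
#' @param pa predictive ability.
#' @param h2 entry-mean heritability in (0, 1].
#' @return pa / sqrt(h2).
#' @export
predictionAccuracy <- function(pa, h2) {
  if (any(h2 <= 0 | h2 > 1)) stopf("h2 must lie in (0, 1]")
  pa / sqrt(h2)
}

#' Phenotypic correlation between two years
#'
#' Pearson correlation of the phenotype values of lines phenotyped in both
#' years for one (environment, trait).
#'
#' @param records phenotype records.
#' @param env,trait,year1,year2 series selectors.
#' @return the correlation.
#' @export
phenotypicCorrelation <- function(records, env, trait, year1, year2) {
  sel <- records$environment == env & records$trait == trait
  a <- records[sel & records$year == year1, c("line_id", "value")]
  b <- records[sel & records$year == year2, c("line_id", "value")]
  common <- intersect(a$line_id, b$line_id)
  if (length(common) < 3L)
    stopf("fewer than 3 lines phenotyped in both years (%d)", length(common))
  cor(a$value[match(common, a$line_id)], b$value[match(common, b$line_id)])
}

#' Regression of predictive-ability gain on a correlation
#'
#' Ordinary least squares of the absolute increase in predictive ability
#' (best model minus baseline) on the genomic or phenotypic correlation,
#' with the Pearson correlation and its two-sided t-test p-value.
#'
#' @param gain numeric vector of predictive-ability gains.
#' @param predictor numeric vector of correlations (same length, >= 3).
#' @return list(slope, intercept, r_squared, pearson_r, p_value).
#' @export
gainRegression <- function(gain, predictor) {
  if (length(gain) != length(predictor) || length(gain) < 3L)
    stopf("need at least 3 (gain, predictor) pairs of equal length")
  if (sd(predictor) == 0) stopf("predictor is constant")
  fit <- lm(gain ~ predictor)
  ct <- cor.test(gain, predictor)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       pearson_r = unname(ct$estimate), p_value = ct$p.value)
}

#' Best sERRBLUP over a selection-fraction grid
#'
#' The result with the highest mean predictive ability; ties go to the
#' larger q (the less aggressive selection).
#'
#' @param results list of [EvaluationResult-class] for bi_serrblup at
#'   different q.
#' @return list(q = best fraction, result = its EvaluationResult).
#' @export
bestSerrblup <- function(results) {
  if (!length(results)) stopf("no results supplied")
  pa <- vapply(results, function(r) r@paMean, numeric(1))
  qs <- vapply(results, function(r) r@spec$q, numeric(1))
  best <- which(pa == max(pa))
  pick <- best[which.max(qs[best])]
  list(q = qs[pick], result = results[[pick]])
}

# Pearson correlation guarded against degenerate inputs; NA means the fold
# must be skipped.
.safeCor <- function(a, b) {
  if (length(a) < 3L) return(NA_real_)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# Build the kernel prescribed by a model spec.  For sERRBLUP the interaction
# selection uses ONLY the complete source-year data of the target
# environment: a univariate fit with the full interaction kernel on the
# source year, backsolved to per-pair effect variances.  Target-year
# phenotypes never enter this step.
.kernelForSpec <- function(spec, panel, sourceRecords) {
  if (spec$model %in% c("uni_gblup_within", "uni_gblup_avg", "bi_gblup"))
    return(gblupKernel(panel))
  Ke <- errblupKernel(panel)
  if (spec$model == "bi_errblup") return(Ke)
  ySrc <- sourceRecords$value
  names(ySrc) <- sourceRecords$line_id
  fitSel <- remlUnivariate(ySrc, Ke)
  ranking <- effectVariances(backsolveEffects(panel, fitSel@gHat, Ke))
  selected <- selectTop(ranking, spec$q)
  serrblupKernel(panel, selected)
}

#' Cross-validated evaluation of one model specification
#'
#' Runs the across-year evaluation protocol for one (model, environment,
#' trait): the complete source-year data of the target environment drive
#' interaction selection (sERRBLUP) and enter every bivariate training set;
#' target-year lines are split by the cross-validation plan, and each fold's
#' test phenotypes are used only to compute the fold's predictive ability.
#' Bivariate fits follow the two-stage protocol: components are pre-fitted
#' on the full two-year data (100 iterations), each fold fit starts from the
#' prefit components (50 iterations) and falls back to the prefit components
#' as fixed values when it does not converge.
#'
#' Folds with fewer than 3 phenotyped test lines or zero-variance
#' predictions are skipped with a message.
#'
#' @param spec a [modelSpec()].
#' @param panel SNP [PredictorPanel-class].
#' @param phenotypes phenotype records covering both years of the
#'   environment / trait.
#' @param plan a [CVPlan-class] over target-year phenotyped lines.
#' @param blocks haplotype-block [PredictorPanel-class]; required when
#'   `spec$predictorKind == "block"`.
#' @param h2 optional entry-mean heritability for the accuracy conversion.
#' @return an [EvaluationResult-class].
#' @export
runEvaluation <- function(spec, panel, phenotypes, plan, blocks = NULL,
                          h2 = NULL) {
  usedPanel <- if (spec$predictorKind == "block") {
    if (is.null(blocks)) stopf("spec asks for blocks but no block panel was given")
    blocks
  } else panel
  sel <- phenotypes$environment == spec$environment &
    phenotypes$trait == spec$trait
  recs <- phenotypes[sel, c("line_id", "year", "value")]
  srcRecs <- recs[recs$year == spec$sourceYear, ]
  tgtRecs <- recs[recs$year == spec$targetYear, ]
  if (!nrow(srcRecs) || !nrow(tgtRecs))
    stopf("phenotypes lack year %s or %s for (%s, %s)",
          spec$sourceYear, spec$targetYear, spec$environment, spec$trait)
  planLines <- rownames(plan@assignment)
  if (!all(planLines %in% tgtRecs$line_id))
    stopf("cross-validation plan contains lines without target-year phenotypes")
  bivariate <- spec$model %in% c("bi_gblup", "bi_errblup", "bi_serrblup")

  kernel <- .kernelForSpec(spec, usedPanel, srcRecs)

  rP <- tryCatch(
    phenotypicCorrelation(phenotypes, spec$environment, spec$trait,
                          spec$sourceYear, spec$targetYear),
    error = function(e) NA_real_)

  rGFull <- NA_real_
  prefit <- NULL
  if (bivariate) {
    prefit <- fitWithProtocol(rbind(srcRecs, tgtRecs), kernel, stage = "prefit")
    rGFull <- tryCatch(suppressWarnings(genomicCorrelation(prefit)),
                       error = function(e) NA_real_)
  }

  tgtVal <- tgtRecs$value
  names(tgtVal) <- tgtRecs$line_id
  srcVal <- srcRecs$value
  names(srcVal) <- srcRecs$line_id

  pa <- numeric(0); convFlags <- logical(0); skipped <- 0L
  for (r in seq_len(plan@reps)) {
    for (f in seq_len(plan@folds)) {
      testLines <- planLines[plan@assignment[, r] == f]
      trainLines <- setdiff(planLines, testLines)
      yTest <- tgtVal[testLines]
      if (length(yTest) < 3L) {
        msgf("skipping rep %d fold %d: fewer than 3 test phenotypes", r, f)
        skipped <- skipped + 1L
        next
      }
      if (bivariate) {
        foldRecs <- rbind(srcRecs, tgtRecs[tgtRecs$line_id %in% trainLines, ])
        fit <- fitWithProtocol(foldRecs, kernel, stage = "cv_fold",
                               init = prefitComponents(prefit))
        pred <- predictBlup(fit, kernel, spec$targetYear, testLines)
        conv <- fit@converged && !fit@fixedFallback
      } else {
        if (spec$model == "uni_gblup_within") {
          yTrain <- tgtVal[trainLines]
        } else {  # uni_gblup_avg: per-line mean of the years' phenotypes
          yTrain <- vapply(trainLines, function(ln) {
            mean(c(srcVal[ln], tgtVal[ln]), na.rm = TRUE)
          }, numeric(1))
          names(yTrain) <- trainLines
        }
        fit <- suppressWarnings(remlUnivariate(yTrain, kernel))
        pred <- fit@gHat[testLines]
        conv <- fit@converged
      }
      paFold <- .safeCor(pred, yTest)
      if (is.na(paFold)) {
        msgf("skipping rep %d fold %d: degenerate predictions or phenotypes", r, f)
        skipped <- skipped + 1L
        next
      }
      pa <- c(pa, paFold)
      convFlags <- c(convFlags, conv)
    }
  }
  if (!length(pa)) stopf("all folds were skipped")
  paMean <- mean(pa)
  new("EvaluationResult", spec = spec,
      paPerFold = pa, paMean = paMean,
      paMeanConverged = if (any(convFlags)) mean(pa[convFlags]) else NA_real_,
      accuracyMean = if (!is.null(h2)) predictionAccuracy(paMean, h2) else NA_real_,
      rGFull = rGFull, rP = rP,
      pctConverged = 100 * mean(convFlags),
      foldConverged = convFlags, foldsSkipped = skipped)
}
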