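# ---- internal machinery for the two-year (bivariate) animal model ----
#
# Model: the same trait in two years is treated as two traits sharing one
# genomic kernel K.  Stacked observations y = X beta + Z u + e with
# u ~ N(0, G0 (x) K) over all kernel lines and independent residuals within
# and between years (separate field seasons: the residual covariance is
# structurally zero).  Components theta = (g11, g12, g22, e1, e2).

# Static problem description shared by all iterations.
.bivSetup <- function(records, kernel) {
  for (col in c("line_id", "year", "value"))
    if (is.null(records[[col]])) stopf("records lack column '%s'", col)
  if (!is.null(records$environment) && length(unique(records$environment)) > 1L)
    stopf("records span multiple environments; filter to one before fitting")
  if (!is.null(records$trait) && length(unique(records$trait)) > 1L)
    stopf("records span multiple traits; filter to one before fitting")
  years <- sort(unique(records$year))
  if (length(years) != 2L)
    stopf("bivariate fit needs exactly two years, got %d", length(years))
  allLines <- rownames(kernel@K)
  r1 <- records[records$year == years[1], ]
  r2 <- records[records$year == years[2], ]
  if (anyDuplicated(r1$line_id) || anyDuplicated(r2$line_id))
    stopf("at most one record per line per year")
  if (nrow(r1) < 10L || nrow(r2) < 10L)
    stopf("need at least 10 phenotyped lines per year (have %d / %d)",
          nrow(r1), nrow(r2))
  miss <- setdiff(c(r1$line_id, r2$line_id), allLines)
  if (length(miss))
    stopf("kernel is missing phenotyped line(s): %s",
          paste(utils::head(miss, 3), collapse = ", "))
  li1 <- match(r1$line_id, allLines)
  li2 <- match(r2$line_id, allLines)
  n1 <- nrow(r1); n2 <- nrow(r2); N <- n1 + n2
  X <- cbind(c(rep(1, n1), rep(0, n2)), c(rep(0, n1), rep(1, n2)))
  list(years = years, allLines = allLines, m = length(allLines),
       K = kernel@K, K11 = kernel@K[li1, li1], K12 = kernel@K[li1, li2],
       K22 = kernel@K[li2, li2], li1 = li1, li2 = li2,
       y = c(r1$value, r2$value), X = X, n1 = n1, n2 = n2, N = N,
       i1 = seq_len(n1), i2 = n1 + seq_len(n2),
       overlap = length(intersect(r1$line_id, r2$line_id)))
}

.bivV <- function(s, th) {
  V <- matrix(0, s$N, s$N)
  V[s$i1, s$i1] <- th[1] * s$K11
  V[s$i2, s$i2] <- th[3] * s$K22
  V[s$i1, s$i2] <- th[2] * s$K12
  V[s$i2, s$i1] <- th[2] * t(s$K12)
  diag(V) <- diag(V) + rep(c(th[4], th[5]), c(s$n1, s$n2))
  V
}

# Full REML state at components th: projection quantities and logL (constant
# -N/2 log 2pi dropped).
.bivState <- function(s, th, needP = TRUE) {
  V <- .bivV(s, th)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  XtVi <- crossprod(s$X, Vi)
  XtViX <- XtVi %*% s$X
  beta <- drop(solve(XtViX, XtVi %*% s$y))
  logL <- -0.5 * (2 * sum(log(diag(ch))) +
                    as.numeric(determinant(XtViX, logarithm = TRUE)$modulus) +
                    sum(s$y * (Vi %*% s$y - t(XtVi) %*% beta)))
  st <- list(logL = logL, beta = beta)
  if (needP) {
    P <- Vi - t(XtVi) %*% solve(XtViX, XtVi)
    st$P <- P
    st$Py <- drop(P %*% s$y)
  }
  st
}

.bivLogL <- function(s, th) {
  st <- .bivState(s, th, needP = FALSE)
  if (is.null(st)) -Inf else st$logL
}

# BLUPs for all kernel lines at components th given the projection of y.
.bivBlups <- function(s, th, Py) {
  a1 <- numeric(s$m); a2 <- numeric(s$m)
  a1[s$li1] <- a1[s$li1] + Py[s$i1]
  a2[s$li2] <- a2[s$li2] + Py[s$i2]
  Ka1 <- drop(s$K %*% a1); Ka2 <- drop(s$K %*% a2)
  cbind(th[1] * Ka1 + th[2] * Ka2, th[2] * Ka1 + th[3] * Ka2)
}

.emUpdate <- function(s, th, st, Ki) {
  v1 <- st$Py[s$i1]; v2 <- st$Py[s$i2]
  U <- .bivBlups(s, th, st$Py)
  UtKiU <- crossprod(U, Ki %*% U)
  P11 <- st$P[s$i1, s$i1]; P12 <- st$P[s$i1, s$i2]; P22 <- st$P[s$i2, s$i2]
  Tm <- matrix(c(sum(P11 * s$K11), sum(P12 * s$K12),
                 sum(P12 * s$K12), sum(P22 * s$K22)), 2, 2)
  G0 <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
  G0n <- (UtKiU + s$m * G0 - G0 %*% Tm %*% G0) / s$m
  G0n <- (G0n + t(G0n)) / 2
  e1 <- (sum((th[4] * v1)^2) + th[4] * (s$n1 - th[4] * sum(diag(P11)))) / s$n1
  e2 <- (sum((th[5] * v2)^2) + th[5] * (s$n2 - th[5] * sum(diag(P22)))) / s$n2
  c(G0n[1, 1], G0n[1, 2], G0n[2, 2], e1, e2)
}

.aiUpdate <- function(s, th, st) {
  v1 <- st$Py[s$i1]; v2 <- st$Py[s$i2]
  P11 <- st$P[s$i1, s$i1]; P12 <- st$P[s$i1, s$i2]; P22 <- st$P[s$i2, s$i2]
  t11 <- sum(P11 * s$K11); t12 <- sum(P12 * s$K12); t22 <- sum(P22 * s$K22)
  K11v1 <- drop(s$K11 %*% v1); K12v2 <- drop(s$K12 %*% v2)
  K21v1 <- drop(crossprod(s$K12, v1)); K22v2 <- drop(s$K22 %*% v2)
  score <- c(
    -0.5 * (t11 - sum(v1 * K11v1)),
    -0.5 * (2 * t12 - 2 * sum(v1 * K12v2)),
    -0.5 * (t22 - sum(v2 * K22v2)),
    -0.5 * (sum(diag(P11)) - sum(v1^2)),
    -0.5 * (sum(diag(P22)) - sum(v2^2))
  )
  z <- function(x1, x2) c(x1, x2)
  W <- cbind(z(K11v1, numeric(s$n2)),
             z(K12v2, K21v1),
             z(numeric(s$n1), K22v2),
             z(v1, numeric(s$n2)),
             z(numeric(s$n1), v2))
  AI <- 0.5 * crossprod(W, st$P %*% W)
  step <- tryCatch(solve(AI, score), error = function(e) NULL)
  if (is.null(step) || any(!is.finite(step))) return(NULL)
  th + step
}

# floor residuals, project G0 to PSD, honour a fixed-at-zero covariance
.sanitize <- function(th, floorVal, fixG12) {
  if (fixG12) th[2] <- 0
  G0 <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2)
  G0 <- projectPSD(G0)
  th <- c(G0[1, 1], G0[1, 2], G0[2, 2],
          max(th[4], floorVal), max(th[5], floorVal))
  if (fixG12) th[2] <- 0
  th[1] <- max(th[1], floorVal); th[3] <- max(th[3], floorVal)
  th
}

#' Bivariate (two-year) EM/AI REML fit
#'
#' Fits the two-year animal model by EM-REML with average-information (AI)
#' acceleration: each iteration takes the AI step when it keeps the
#' components admissible and does not decrease the restricted likelihood,
#' and the (monotone) EM step otherwise.  The 2x2 genetic (co)variance
#' matrix is projected to the nearest positive semi-definite matrix after
#' each step and residual variances are floored at 1e-10 times the
#' phenotypic variance.  Convergence requires both the maximum relative
#' component change below `tol` and a restricted log-likelihood change below
#' 1e-6.  Unbalanced line sets are allowed: a line may be phenotyped in one
#' year only, and BLUPs are returned for every kernel line in both years.
#'
#' When the two years share no phenotyped line and no initial values are
#' given, the genetic covariance is not identifiable; it is then fixed at
#' zero with a warning.
#'
#' @param records phenotype records (columns line_id, year, value; an
#'   environment / trait column, if present, must be constant) covering
#'   exactly two years with >= 10 phenotyped lines each.
#' @param kernel a [RelationshipKernel-class] containing all phenotyped lines.
#' @param init optional starting components c(g11, g12, g22, e1, e2).
#' @param maxIter iteration cap.
#' @param tol relative component-change tolerance.
#' @param fixG12 force the genetic covariance to zero throughout.
#' @param evaluateOnly do not iterate: compute BLUPs and likelihood at
#'   `init` (used for the fixed-component fallback).
#' @return a [BivariateFit-class].
#' @export
remlBivariate <- function(records, kernel, init = NULL, maxIter = 100,
                          tol = 1e-6, fixG12 = FALSE, evaluateOnly = FALSE) {
  s <- .bivSetup(records, kernel)
  if (s$overlap == 0L && is.null(init) && !fixG12) {
    warnf("years share no phenotyped line and no initial values were given: genetic covariance fixed at 0")
    fixG12 <- TRUE
  }
  floorVal <- 1e-10 * var(s$y)
  if (is.null(init)) {
    s1 <- var(s$y[s$i1]); s2 <- var(s$y[s$i2])
    init <- c(s1 / 2, if (fixG12) 0 else 0.25 * sqrt(s1 * s2), s2 / 2,
              s1 / 2, s2 / 2)
  }
  if (length(init) != 5L) stopf("init must be c(g11, g12, g22, e1, e2)")
  th <- .sanitize(init, floorVal, fixG12)
  Ki <- chol2inv(chol(s$K))
  trace <- numeric(0)
  converged <- FALSE
  nIter <- 0L
  prevLogL <- -Inf
  if (!evaluateOnly) {
    for (it in seq_len(maxIter)) {
      nIter <- it
      st <- .bivState(s, th)
      if (is.null(st)) stopf("covariance matrix not positive definite at iteration %d", it)
      trace <- c(trace, st$logL)
      thEM <- .sanitize(.emUpdate(s, th, st, Ki), floorVal, fixG12)
      thAI <- .aiUpdate(s, th, st)
      thNew <- thEM
      if (!is.null(thAI)) {
        thAI <- .sanitize(thAI, floorVal, fixG12)
        if (.bivLogL(s, thAI) >= st$logL - 1e-10) thNew <- thAI
      }
      relChange <- max(abs(thNew - th) / pmax(abs(th), sqrt(floorVal)))
      dLogL <- st$logL - prevLogL
      prevLogL <- st$logL
      th <- thNew
      if (relChange < tol && abs(dLogL) < 1e-6) { converged <- TRUE; break }
    }
  }
  stFinal <- .bivState(s, th)
  if (is.null(stFinal)) stopf("covariance matrix not positive definite at the returned components")
  gHat <- .bivBlups(s, th, stFinal$Py)
  dimnames(gHat) <- list(s$allLines, as.character(s$years))
  G0 <- matrix(c(th[1], th[2], th[2], th[3]), 2, 2,
               dimnames = rep(list(as.character(s$years)), 2))
  beta <- stFinal$beta
  names(beta) <- as.character(s$years)
  new("BivariateFit", beta = beta, G0 = G0, sigmaE = c(th[4], th[5]),
      logLik = stFinal$logL, gHat = gHat,
      converged = converged, nIter = nIter,
      init = init, fixedFallback = evaluateOnly,
      years = as.numeric(s$years),
      logLikTrace = c(trace, stFinal$logL))
}

#' Two-stage fitting protocol for cross-validation
#'
#' Stage `"prefit"` estimates components from the full two-year dataset with
#' an iteration cap of 100 and returns them whether or not the fit converged;
#' the components at the final iteration serve as initial values for the
#' cross-validation fits.  Stage `"cv_fold"` starts from the supplied
#' initial components and runs at most 50 iterations; if it does not
#' converge, the initial components are taken as fixed values and the BLUPs
#' are recomputed at them (`fixedFallback` is set).
#'
#' @param records,kernel as in [remlBivariate()].
#' @param stage `"prefit"` or `"cv_fold"`.
#' @param init starting components; ignored for `"prefit"`, required for
#'   `"cv_fold"`.
#' @param tol convergence tolerance passed on to [remlBivariate()].
#' @param maxIter iteration cap override; defaults to the protocol's
#'   100 (prefit) / 50 (cv_fold).
#' @return a [BivariateFit-class].
#' @export
fitWithProtocol <- function(records, kernel, stage = c("prefit", "cv_fold"),
                            init = NULL, tol = 1e-6, maxIter = NULL) {
  stage <- match.arg(stage)
  if (stage == "prefit")
    return(remlBivariate(records, kernel, init = NULL,
                         maxIter = maxIter %||% 100, tol = tol))
  if (is.null(init)) stopf("cv_fold stage requires initial components from the prefit")
  fit <- remlBivariate(records, kernel, init = init,
                       maxIter = maxIter %||% 50, tol = tol)
  if (!fit@converged) {
    fit <- remlBivariate(records, kernel, init = init, evaluateOnly = TRUE)
  }
  fit
}

#' Extract the prefit components used as cross-validation initial values
#'
#' @param fit a [BivariateFit-class] from the prefit stage.
#' @return numeric c(g11, g12, g22, e1, e2).
#' @export
prefitComponents <- function(fit) {
  c(fit@G0[1, 1], fit@G0[1, 2], fit@G0[2, 2], fit@sigmaE)
}

#' @rdname genomicCorrelation
#' @export
setMethod("genomicCorrelation", "BivariateFit", function(fit) {
  g1 <- fit@G0[1, 1]; g2 <- fit@G0[2, 2]
  if (g1 <= 0 || g2 <= 0)
    stopf("genomic correlation undefined: a genetic variance is zero")
  r <- fit@G0[1, 2] / sqrt(g1 * g2)
  if (abs(r) > 1) {
    warnf("genomic correlation %.4f clipped to [-1, 1]", r)
    r <- max(-1, min(1, r))
  }
  r
})

#' Predict genetic values for target lines in a target year
#'
#' Returns the BLUPs of the target-year genetic values of the requested
#' lines from a bivariate fit.  Information reaches unphenotyped lines
#' through the kernel and through their other-year phenotypes via the mixed
#' model equations.
#'
#' @param fit a [BivariateFit-class].
#' @param kernel the kernel the fit used (consistency check).
#' @param targetYear one of the fit's two years.
#' @param targetLines character vector of kernel line ids.
#' @return named numeric of predicted genetic values.
#' @export
predictBlup <- function(fit, kernel, targetYear, targetLines) {
  if (!as.character(targetYear) %in% colnames(fit@gHat))
    stopf("targetYear %s is not one of the fit's years", targetYear)
  miss <- setdiff(targetLines, rownames(fit@gHat))
  if (length(miss))
    stopf("target line(s) absent from the kernel: %s",
          paste(utils::head(miss, 3), collapse = ", "))
  fit@gHat[targetLines, as.character(targetYear)]
}
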