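# Profiled restricted log-likelihood at variance ratio lambda = s2g / s2e,
# evaluated through a one-time eigendecomposition of the observed kernel
# block.  X is the intercept; sigma2_e is profiled out.
.remlProfile <- function(lambda, d, yt, xt, n) {
  w <- 1 / (lambda * d + 1)
  a <- sum(xt^2 * w)
  b <- sum(xt * yt * w)
  mu <- b / a
  rt <- yt - mu * xt
  q <- sum(rt^2 * w)
  s2e <- q / (n - 1)
  list(logLik = -0.5 * ((n - 1) * (log(2 * pi * s2e) + 1) +
                          sum(log(lambda * d + 1)) + log(a)),
       mu = mu, s2e = s2e)
}

#' Univariate REML fit of the animal model y = 1 mu + g + e
#'
#' g ~ N(0, sigma2_g K), e ~ N(0, sigma2_e I).  The restricted likelihood is
#' maximized exactly over the variance ratio lambda = sigma2_g / sigma2_e by
#' one-dimensional optimization on an eigendecomposition of the observed
#' kernel block, which is deterministic and free of iteration-count
#' concerns.  BLUPs are returned for every kernel line, including
#' unphenotyped ones, through the kernel cross-block:
#' g_all = sigma2_g K[, obs] V_obs^-1 (y - 1 mu).
#'
#' When the kernel carries no information to separate g from e (e.g. K
#' proportional to the identity), the profile is flat in lambda; the fit is
#' still returned, with a warning.
#'
#' @param y named numeric of phenotypes; names must be kernel line ids
#'   (>= 10 observations).
#' @param kernel a [RelationshipKernel-class] containing all phenotyped lines.
#' @param logLambdaRange search interval for log(lambda).
#' @return a [UnivariateFit-class].
#' @export
remlUnivariate <- function(y, kernel, logLambdaRange = c(-20, 20)) {
  if (is.null(names(y))) stopf("y must be named with line ids")
  obs <- names(y)
  if (length(obs) < 10L) stopf("need at least 10 phenotyped lines, got %d", length(obs))
  allLines <- rownames(kernel@K)
  missing <- setdiff(obs, allLines)
  if (length(missing))
    stopf("kernel is missing phenotyped line(s): %s",
          paste(utils::head(missing, 3), collapse = ", "))
  Kobs <- kernel@K[obs, obs]
  n <- length(y)
  e <- eigen(Kobs, symmetric = TRUE)
  d <- pmax(e$values, 0)
  yt <- drop(crossprod(e$vectors, y))
  xt <- drop(crossprod(e$vectors, rep(1, n)))
  f <- function(ll) .remlProfile(exp(ll), d, yt, xt, n)$logLik
  # flat-profile guard (g and e not separately identifiable)
  probe <- vapply(c(logLambdaRange[1], 0, logLambdaRange[2]), f, numeric(1))
  flat <- diff(range(probe)) < 1e-6
  if (flat)
    warnf("restricted likelihood is flat in lambda: genetic and residual variance are not separately identifiable with this kernel")
  opt <- optimize(f, interval = logLambdaRange, maximum = TRUE, tol = 1e-10)
  lambda <- exp(opt$maximum)
  atEdge <- min(abs(opt$maximum - logLambdaRange)) < 1e-3
  if (atEdge && !flat)
    warnf("lambda optimum at the search boundary (log lambda = %.2f)", opt$maximum)
  prof <- .remlProfile(lambda, d, yt, xt, n)
  s2e <- prof$s2e
  s2g <- lambda * s2e
  mu <- prof$mu
  # BLUPs for all kernel lines via the cross-block
  Vinv_r <- e$vectors %*% ((yt - mu * xt) / (lambda * d + 1)) / s2e
  gAll <- drop(s2g * kernel@K[, obs] %*% Vinv_r)
  names(gAll) <- allLines
  new("UnivariateFit", beta = c(intercept = mu), sigmaG = s2g, sigmaE = s2e,
      lambda = lambda, logLik = opt$objective, gHat = gAll,
      converged = TRUE, nIter = 1L)
}
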