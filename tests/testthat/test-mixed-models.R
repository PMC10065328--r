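test_that("eigendecomposition REML profile matches a dense from-scratch evaluation", {
  d <- simDataset(301, n = 40, p = 60)
  K <- gblupKernel(d$sim$snp)
  y <- yearVector(d$recs, 2018)
  Kmat <- kernelMatrix(K)[names(y), names(y)]
  e <- eigen(Kmat, symmetric = TRUE)
  yt <- drop(crossprod(e$vectors, y))
  xt <- drop(crossprod(e$vectors, rep(1, length(y))))
  for (lambda in c(0.01, 0.1, 1, 5, 50)) {
    fast <- epiblup:::.remlProfile(lambda, pmax(e$values, 0), yt, xt, length(y))$logLik
    expect_equal(fast, denseRemlLogLik(lambda, y, Kmat), tolerance = 1e-8)
  }
})

test_that("univariate REML recovers heritability on simulated data", {
  h2hat <- vapply(1:20, function(s) {
    d <- simDataset(400 + s, n = 200, p = 300, h2Year2 = 0.6)
    K <- gblupKernel(d$sim$snp)
    fit <- remlUnivariate(yearVector(d$recs, 2018), K)
    heritability(fit, K)
  }, numeric(1))
  expect_lt(abs(mean(h2hat) - 0.6), 0.10)
})

test_that("in the noiseless limit the BLUPs reproduce the centered phenotypes", {
  d <- simDataset(311, n = 60, p = 120, h2Year1 = 1, h2Year2 = 1,
                  nEpiPairs = 0, epiVarFraction = 0)
  K <- gblupKernel(d$sim$snp)
  y <- yearVector(d$recs, 2018)
  fit <- suppressWarnings(remlUnivariate(y, K))
  expect_lt(max(abs(fit@gHat[names(y)] - (y - fit@beta))), 1e-6)
})

test_that("an identity-like kernel triggers the identifiability warning but still fits", {
  Kmat <- diag(1 + 1e-8, 20)
  dimnames(Kmat) <- list(sprintf("L%02d", 1:20), sprintf("L%02d", 1:20))
  K <- new("RelationshipKernel", K = Kmat,
           kind = "gblup", scaleC = 1, nTerms = 20, ridge = 1e-8,
           panelDigest = "")
  y <- withr::with_seed(1, setNames(rnorm(20), rownames(K@K)))
  expect_warning(fit <- remlUnivariate(y, K), "identifiable")
  expect_true(is.finite(fit@logLik))
})

test_that("bivariate REML recovers a strong genetic correlation and the near-duplicate limit", {
  d <- simDataset(321, n = 250, p = 300, rGTarget = 0.9)
  K <- gblupKernel(d$sim$snp)
  fit <- remlBivariate(d$recs, K)
  expect_true(fit@converged)
  expect_lt(abs(genomicCorrelation(fit) - cor(d$ph$truth$g[, 1], d$ph$truth$g[, 2])), 0.12)

  # same trait twice with tiny independent noise: r_g near 1
  y <- yearVector(d$recs, 2018)
  noise <- withr::with_seed(2, rnorm(length(y), 0, 0.01 * sd(y)))
  recs2 <- rbind(
    data.frame(line_id = names(y), year = 2017, value = unname(y)),
    data.frame(line_id = names(y), year = 2018, value = unname(y) + noise))
  fit2 <- remlBivariate(recs2, K)
  expect_gte(suppressWarnings(genomicCorrelation(fit2)), 0.95)
})

test_that("restricted log-likelihood never decreases along the iteration trace", {
  for (s in c(331, 332)) {
    d <- simDataset(s, n = 120, p = 150, rGTarget = 0.6, h2Year1 = 0.4)
    K <- gblupKernel(d$sim$snp)
    fit <- remlBivariate(d$recs, K)
    expect_true(all(diff(fit@logLikTrace) > -1e-6))
  }
})

test_that("with zero genetic covariance the bivariate fit reproduces the univariate components", {
  d <- simDataset(341, n = 120, p = 150)
  K <- gblupKernel(d$sim$snp)
  bf <- remlBivariate(d$recs, K, fixG12 = TRUE, maxIter = 500, tol = 1e-10)
  uf <- remlUnivariate(yearVector(d$recs, 2017), K)
  expect_equal(bf@G0[1, 1], uf@sigmaG, tolerance = 1e-6)
  expect_equal(bf@sigmaE[1], uf@sigmaE, tolerance = 1e-6)
})

test_that("estimates are invariant to permuting the line order", {
  d <- simDataset(351, n = 80, p = 100)
  K <- gblupKernel(d$sim$snp)
  fit <- remlBivariate(d$recs, K)
  perm <- withr::with_seed(3, sample(nrow(kernelMatrix(K))))
  Kp <- new("RelationshipKernel", K = kernelMatrix(K)[perm, perm],
            kind = "gblup", scaleC = K@scaleC, nTerms = K@nTerms,
            ridge = K@ridge, panelDigest = "")
  recsPerm <- d$recs[withr::with_seed(4, sample(nrow(d$recs))), ]
  fitP <- remlBivariate(recsPerm, Kp)
  expect_equal(fitP@G0, fit@G0, tolerance = 1e-6)
  expect_equal(fitP@sigmaE, fit@sigmaE, tolerance = 1e-6)
  expect_equal(fitP@gHat[rownames(fit@gHat), ], fit@gHat, tolerance = 1e-6)
})

test_that("disjoint year line sets without init fix the genetic covariance at zero", {
  d <- simDataset(361, n = 60, p = 80)
  K <- gblupKernel(d$sim$snp)
  lines <- lineIds(d$sim$snp)
  recs <- rbind(
    data.frame(line_id = lines[1:30], year = 2017,
               value = d$ph$truth$g[1:30, 1]),
    data.frame(line_id = lines[31:60], year = 2018,
               value = d$ph$truth$g[31:60, 2]))
  expect_warning(fit <- remlBivariate(recs, K), "covariance fixed at 0")
  expect_identical(fit@G0[1, 2], 0)
})

test_that("the prefit/cv protocol converges on well-conditioned data and falls back otherwise", {
  d <- simDataset(371, n = 120, p = 150)
  K <- gblupKernel(d$sim$snp)
  pre <- fitWithProtocol(d$recs, K, stage = "prefit")
  expect_true(pre@converged)
  expect_lt(pre@nIter, 100)
  cv <- fitWithProtocol(d$recs, K, stage = "cv_fold", init = prefitComponents(pre))
  expect_true(cv@converged)
  expect_lt(cv@nIter, 50)
  expect_false(cv@fixedFallback)

  # adversarial init with a single permitted iteration: fixed-value fallback
  badInit <- c(1e-4, 0, 1e-4, 100, 100)
  fb <- fitWithProtocol(d$recs, K, stage = "cv_fold", init = badInit, maxIter = 1)
  expect_true(fb@fixedFallback)
  expect_false(fb@converged)
  atInit <- remlBivariate(d$recs, K, init = badInit, evaluateOnly = TRUE)
  expect_equal(fb@gHat, atInit@gHat)
  expect_equal(fb@G0[1, 1], badInit[1])

  expect_error(fitWithProtocol(d$recs, K, stage = "cv_fold"), "requires initial")
})

test_that("genomic correlation follows sigma_g12 / sqrt(g1 g2) with boundary handling", {
  base <- remlBivariate(simDataset(381, n = 60, p = 80)$recs,
                        gblupKernel(simDataset(381, n = 60, p = 80)$sim$snp))
  fit <- base
  fit@G0 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(genomicCorrelation(fit), 0.5)
  fit@G0 <- matrix(c(4, -2, -2, 1), 2)
  expect_equal(genomicCorrelation(fit), -1.0)
  fit@G0 <- matrix(c(0, 0, 0, 1), 2)
  expect_error(genomicCorrelation(fit), "zero")
})

test_that("BLUP prediction shrinks unrelated and no-information lines to zero", {
  # kernel with an unrelated line (block-diagonal) built directly
  withr::with_seed(5, {
    A <- matrix(rnorm(30 * 40), 30, 40)
  })
  K0 <- tcrossprod(A) / 40
  Kfull <- rbind(cbind(K0, 0), 0)
  Kfull[31, 31] <- 1
  ids <- sprintf("L%02d", 1:31)
  dimnames(Kfull) <- list(ids, ids)
  K <- new("RelationshipKernel", K = Kfull + diag(1e-8, 31), kind = "gblup",
           scaleC = 1, nTerms = 40, ridge = 1e-8, panelDigest = "")
  withr::with_seed(6, {
    g <- drop(chol(Kfull[1:30, 1:30] + diag(1e-6, 30)) %*% rnorm(30))
  })
  recs <- rbind(
    data.frame(line_id = ids[1:30], year = 2017, value = g + rnorm(30, 0, 0.3)),
    data.frame(line_id = ids[1:30], year = 2018, value = g + rnorm(30, 0, 0.3)))
  fit <- remlBivariate(recs, K)
  expect_lt(abs(predictBlup(fit, K, 2018, "L31")), 1e-6)

  # vanishing genetic variance: everything shrinks to zero
  tiny <- remlBivariate(recs, K, init = c(1e-10, 0, 1e-10, 1, 1),
                        evaluateOnly = TRUE)
  expect_lt(max(abs(tiny@gHat)), 1e-6)
})

test_that("a clone of a training line (identical kernel rows) gets the same BLUP", {
  withr::with_seed(7, {
    A <- matrix(rnorm(25 * 60), 25, 60)
  })
  A <- rbind(A, A[25, ])                      # line 26 clones line 25
  K0 <- tcrossprod(A) / 60
  ids <- sprintf("L%02d", 1:26)
  dimnames(K0) <- list(ids, ids)
  K <- new("RelationshipKernel", K = K0, kind = "gblup", scaleC = 1,
           nTerms = 60, ridge = 0, panelDigest = "")
  withr::with_seed(8, {
    y <- drop(A[1:25, ] %*% rnorm(60, 0, 0.2)) + rnorm(25, 0, 0.3)
  })
  fit <- suppressWarnings(remlUnivariate(setNames(y, ids[1:25]), K))
  expect_lt(abs(fit@gHat["L26"] - fit@gHat["L25"]), 1e-8)
})
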