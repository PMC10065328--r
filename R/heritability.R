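#' Genomic heritability implied by a REML fit
#'
#' The genetic variance of a line under the kernel model is
#' sigma2_g * K_ii, so the heritability on the phenotype scale uses the mean
#' kernel diagonal kbar: h2 = sigma2_g kbar / (sigma2_g kbar + sigma2_e).
#' For DH panels the VanRaden kernel diagonal averages about 2 (fully
#' inbred lines), so ignoring kbar would roughly halve the genetic share.
#'
#' @param fit a [UnivariateFit-class] or [BivariateFit-class].
#' @param kernel the [RelationshipKernel-class] used in the fit.
#' @return heritability (univariate) or per-year heritabilities (bivariate).
#' @export
heritability <- function(fit, kernel) {
  kbar <- mean(diag(kernel@K))
  if (is(fit, "UnivariateFit")) {
    vg <- fit@sigmaG * kbar
    return(vg / (vg + fit@sigmaE))
  }
  if (is(fit, "BivariateFit")) {
    vg <- c(fit@G0[1, 1], fit@G0[2, 2]) * kbar
    h <- vg / (vg + fit@sigmaE)
    names(h) <- as.character(fit@years)
    return(h)
  }
  stopf("unsupported fit class '%s'", class(fit)[1])
}
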