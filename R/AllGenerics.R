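#' @rdname PredictorPanel-class
#' @param object,x a package object
#' @export
setGeneric("lineIds", function(x) standardGeneric("lineIds"))

#' @rdname PredictorPanel-class
#' @export
setGeneric("predictorIds", function(x) standardGeneric("predictorIds"))

#' @rdname PredictorPanel-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname PredictorPanel-class
#' @export
setGeneric("panelKind", function(x) standardGeneric("panelKind"))

#' @rdname RelationshipKernel-class
#' @param x a package object
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname RelationshipKernel-class
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))

#' @rdname RelationshipKernel-class
#' @export
setGeneric("scaleConstant", function(x) standardGeneric("scaleConstant"))

#' Genomic correlation between the two years of a bivariate fit
#'
#' r_g = sigma_g12 / sqrt(sigma2_g1 * sigma2_g2), clipped to [-1, 1]
#' (a clip is reported with a warning).
#'
#' @param fit a [BivariateFit-class].
#' @return The genomic correlation, a single number in [-1, 1].
#' @export
setGeneric("genomicCorrelation", function(fit) standardGeneric("genomicCorrelation"))
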