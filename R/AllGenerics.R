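#' @import methods
#' @importFrom stats coef dnorm lm median pnorm predict qnorm residuals rnorm
#'   runif sd uniroot var
#' @importFrom signal sgolayfilt
#' @importFrom randomForest randomForest
NULL

#' Accessor generics
#'
#' Accessors for the core data containers: the wavenumber axis, the absorbance
#' block, sample identifiers, region labels and the chemistry table.
#'
#' @param x an object of one of the package's classes.
#' @return \code{wavenumbers}: numeric vector in ascending order (cm-1);
#'   \code{absorbance}: numeric matrix, samples in rows; \code{sampleIds}:
#'   character vector; \code{regions}: factor with levels YN, XQ, DBM;
#'   \code{chemistry}: data.frame of per-sample reference concentrations;
#'   \code{nSamples}: integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("chemistry", function(x) standardGeneric("chemistry"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Split accessors
#'
#' @param x a \linkS4class{SplitResult}.
#' @return character vectors of sample identifiers.
#' @name split-accessors
NULL

#' @rdname split-accessors
#' @export
setGeneric("calibrationIds", function(x) standardGeneric("calibrationIds"))

#' @rdname split-accessors
#' @export
setGeneric("validationIds", function(x) standardGeneric("validationIds"))

#' Flagged outlier accessor
#'
#' @param x an \linkS4class{OutlierReport}.
#' @return character vector of flagged sample identifiers.
#' @export
setGeneric("flaggedIds", function(x) standardGeneric("flaggedIds"))

#' Classification accuracy accessor
#'
#' @param x a \linkS4class{ClassificationReport}.
#' @return fraction of correctly classified samples (0..1).
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
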