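## Core S4 containers for the NIR chemometrics pipeline.

#' Region labels, in tie-break order
#'
#' The three cultivation regions: Yunnan (YN), Xiangqian (XQ) and the Dabie
#' Mountains (DBM). The order of this vector is the documented tie-break
#' order for classification votes.
#'
#' @export
REGION_LEVELS <- c("YN", "XQ", "DBM")

#' Quality-parameter and triterpene-acid column names
#'
#' PSC (polysaccharides), WSE (water-soluble extract), ASE (alcohol-soluble
#' extract), the five triterpene acids (DTUA, PAA, PAC, DPA, DTRA) and their
#' sum SFT, all in mg per g.
#'
#' @export
CHEM_COLUMNS <- c("psc", "wse", "ase", "dtua", "paa", "pac", "dpa", "dtra",
                  "sft")

ACID_COLUMNS <- c("dtua", "paa", "pac", "dpa", "dtra")

## ---------------------------------------------------------------------------
## SpectraMatrix
## ---------------------------------------------------------------------------

#' SpectraMatrix: samples-by-wavenumbers absorbance block
#'
#' Holds a set of NIR spectra on a common wavenumber axis: the independent
#' variable block of all downstream models. The axis is stored strictly
#' ascending (in cm-1); constructors re-sort descending input.
#'
#' @slot wavenumbers numeric, strictly ascending spectral positions (cm-1).
#' @slot absorbance numeric matrix, \code{length(sampleIds)} rows by
#'   \code{length(wavenumbers)} columns, all values finite.
#' @slot sampleIds character, unique sample identifiers.
#'
#' @seealso \code{\link{readSpectra}}, \code{\link{simulateDataset}}
#' @export
setClass("SpectraMatrix",
         representation(wavenumbers = "numeric",
                        absorbance  = "matrix",
                        sampleIds   = "character"))

setValidity("SpectraMatrix", function(object) {
    wn <- object@wavenumbers
    ab <- object@absorbance
    ids <- object@sampleIds
    msg <- character()
    if (length(wn) < 1L)
        msg <- c(msg, "at least one wavenumber is required")
    if (length(wn) > 1L && any(diff(wn) <= 0))
        msg <- c(msg, "wavenumbers must be strictly ascending")
    if (!is.numeric(ab))
        msg <- c(msg, "absorbance must be numeric")
    if (nrow(ab) != length(ids))
        msg <- c(msg, sprintf("absorbance has %d rows but %d sample ids",
                              nrow(ab), length(ids)))
    if (ncol(ab) != length(wn))
        msg <- c(msg, sprintf("absorbance has %d columns but %d wavenumbers",
                              ncol(ab), length(wn)))
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate sample id(s): %s",
                              paste(unique(ids[duplicated(ids)]),
                                    collapse = ", ")))
    if (is.numeric(ab) && !all(is.finite(ab)))
        msg <- c(msg, "absorbance values must all be finite")
    if (length(msg)) msg else TRUE
})

#' Construct a SpectraMatrix
#'
#' @param absorbance numeric matrix, samples in rows, wavenumbers in columns.
#' @param wavenumbers numeric spectral axis (cm-1); may be supplied in
#'   descending order, in which case columns are permuted to ascending.
#' @param sampleIds character vector of unique identifiers; defaults to
#'   rownames of \code{absorbance} or \code{S1..Sn}.
#' @return a validated \linkS4class{SpectraMatrix}.
#' @examples
#' sm <- SpectraMatrix(matrix(rnorm(15), 3, 5), seq(4000, 4032, by = 8))
#' wavenumbers(sm)
#' @export
SpectraMatrix <- function(absorbance, wavenumbers,
                          sampleIds = NULL) {
    absorbance <- as.matrix(absorbance)
    storage.mode(absorbance) <- "double"
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(absorbance))) rownames(absorbance)
                     else paste0("S", seq_len(nrow(absorbance)))
    ord <- order(wavenumbers)
    wavenumbers <- as.numeric(wavenumbers[ord])
    absorbance <- absorbance[, ord, drop = FALSE]
    dimnames(absorbance) <- list(sampleIds, NULL)
    new("SpectraMatrix", wavenumbers = wavenumbers, absorbance = absorbance,
        sampleIds = as.character(sampleIds))
}

#' @rdname accessors
#' @export
setMethod("wavenumbers", "SpectraMatrix", function(x) x@wavenumbers)

#' @rdname accessors
#' @export
setMethod("absorbance", "SpectraMatrix", function(x) x@absorbance)

#' @rdname accessors
#' @export
setMethod("sampleIds", "SpectraMatrix", function(x) x@sampleIds)

#' @rdname accessors
#' @export
setMethod("nSamples", "SpectraMatrix", function(x) length(x@sampleIds))

#' @describeIn SpectraMatrix subset samples (rows, by index, id or logical)
#'   and/or wavenumber positions (columns, by index).
#' @param x,i,j,...,drop see \code{\link[base]{Extract}}; \code{drop} ignored.
#' @export
setMethod("[", "SpectraMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nSamples(x))
    if (is.character(i)) i <- match(i, x@sampleIds)
    if (anyNA(i)) stop("unknown sample id in subset")
    if (missing(j)) j <- seq_along(x@wavenumbers)
    SpectraMatrix(x@absorbance[i, j, drop = FALSE],
                  x@wavenumbers[j],
                  x@sampleIds[i])
})

setMethod("show", "SpectraMatrix", function(object) {
    wn <- wavenumbers(object)
    cat(sprintf("SpectraMatrix: %d sample(s) x %d wavenumber(s), %g..%g cm-1\n",
                nSamples(object), length(wn), min(wn), max(wn)))
})

## ---------------------------------------------------------------------------
## SampleTable
## ---------------------------------------------------------------------------

#' SampleTable: per-sample region labels and reference chemistry
#'
#' The dependent-variable block: region of origin and wet-lab reference
#' concentrations (mg/g) for the quality parameters. Any concentration may be
#' missing; when the five triterpene acids are all present, SFT must equal
#' their sum (recomputed on construction when absent).
#'
#' @slot data data.frame with columns \code{sample_id}, \code{region}
#'   (factor YN/XQ/DBM) and the nine concentration columns of
#'   \code{\link{CHEM_COLUMNS}}.
#' @seealso \code{\link{readSampleTable}}
#' @export
setClass("SampleTable", representation(data = "data.frame"))

setValidity("SampleTable", function(object) {
    d <- object@data
    msg <- character()
    need <- c("sample_id", "region", CHEM_COLUMNS)
    if (!all(need %in% names(d)))
        return(paste("missing column(s):",
                     paste(setdiff(need, names(d)), collapse = ", ")))
    if (anyDuplicated(d$sample_id))
        msg <- c(msg, sprintf("duplicate sample id(s): %s",
                              paste(unique(d$sample_id[duplicated(d$sample_id)]),
                                    collapse = ", ")))
    if (!is.factor(d$region) || !identical(levels(d$region), REGION_LEVELS))
        msg <- c(msg, "region must be a factor with levels YN, XQ, DBM")
    if (anyNA(d$region))
        msg <- c(msg, "region labels may not be missing")
    for (cc in CHEM_COLUMNS) {
        v <- d[[cc]]
        if (!is.numeric(v))
            msg <- c(msg, sprintf("column %s must be numeric", cc))
        else if (any(v < 0, na.rm = TRUE))
            msg <- c(msg, sprintf("column %s has negative concentration(s)", cc))
    }
    ok <- stats::complete.cases(d[, c(ACID_COLUMNS, "sft")])
    if (any(ok)) {
        tot <- rowSums(d[ok, ACID_COLUMNS, drop = FALSE])
        if (any(abs(tot - d$sft[ok]) > 1e-9))
            msg <- c(msg, "sft must equal the sum of the five acids (1e-9)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SampleTable
#'
#' @param data data.frame with at least \code{sample_id} and \code{region};
#'   missing chemistry columns are created as all-NA. \code{sft} is recomputed
#'   as the sum of the five acids when absent and all five are present.
#' @return a validated \linkS4class{SampleTable}.
#' @export
SampleTable <- function(data) {
    data <- as.data.frame(data)
    if (!all(c("sample_id", "region") %in% names(data)))
        stop("sample table needs columns 'sample_id' and 'region'")
    bad <- setdiff(unique(as.character(data$region)), REGION_LEVELS)
    if (length(bad))
        stop(sprintf("unknown region label(s) %s; allowed: %s",
                     paste(bad, collapse = ", "),
                     paste(REGION_LEVELS, collapse = ", ")))
    data$sample_id <- as.character(data$sample_id)
    data$region <- factor(as.character(data$region), levels = REGION_LEVELS)
    for (cc in CHEM_COLUMNS)
        data[[cc]] <- if (cc %in% names(data)) as.numeric(data[[cc]])
                      else NA_real_
    acid_ok <- stats::complete.cases(data[, ACID_COLUMNS])
    fill <- acid_ok & is.na(data$sft)
    if (any(fill))
        data$sft[fill] <- rowSums(data[fill, ACID_COLUMNS, drop = FALSE])
    data <- data[, c("sample_id", "region", CHEM_COLUMNS)]
    rownames(data) <- NULL
    new("SampleTable", data = data)
}

#' @rdname accessors
#' @export
setMethod("sampleIds", "SampleTable", function(x) x@data$sample_id)

#' @rdname accessors
#' @export
setMethod("regions", "SampleTable", function(x) x@data$region)

#' @rdname accessors
#' @export
setMethod("chemistry", "SampleTable",
          function(x) x@data[, CHEM_COLUMNS, drop = FALSE])

#' @rdname accessors
#' @export
setMethod("nSamples", "SampleTable", function(x) nrow(x@data))

#' @describeIn SampleTable coerce to the underlying data.frame.
#' @param x a SampleTable.
#' @param ... unused.
#' @export
as.data.frame.SampleTable <- function(x, ...) x@data

#' @describeIn SampleTable subset samples by index, id or logical.
#' @param i,j,drop see \code{\link[base]{Extract}}; \code{j}, \code{drop}
#'   ignored.
#' @export
setMethod("[", "SampleTable", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@data$sample_id)
    if (anyNA(i)) stop("unknown sample id in subset")
    d <- x@data[i, , drop = FALSE]
    rownames(d) <- NULL
    new("SampleTable", data = d)
})

setMethod("show", "SampleTable", function(object) {
    cat(sprintf("SampleTable: %d sample(s); regions: %s\n", nSamples(object),
                paste(sprintf("%s=%d", REGION_LEVELS,
                              as.integer(table(regions(object)))),
                      collapse = " ")))
})

## ---------------------------------------------------------------------------
## PretreatmentSpec
## ---------------------------------------------------------------------------

PRETREATMENT_NAMES <- c("Raw", "MSC", "SNV", "Smooth", "Smooth+SNV",
                        "Smooth+MSC", "SG-1D")

#' PretreatmentSpec: a named spectral pretreatment
#'
#' One of the seven pretreatments compared in the calibration study:
#' \code{Raw}, \code{MSC}, \code{SNV}, \code{Smooth} (Savitzky-Golay
#' smoothing), \code{Smooth+SNV}, \code{Smooth+MSC} and \code{SG-1D}
#' (Savitzky-Golay first derivative). Composed names apply smoothing first.
#'
#' @slot name one of the seven names above (matched case-insensitively by the
#'   constructor).
#' @slot window odd integer window (points) for Smooth / SG-1D.
#' @slot polyorder polynomial order, >= 1 and < window.
#' @seealso \code{\link{applyPretreatment}}
#' @export
setClass("PretreatmentSpec",
         representation(name = "character", window = "integer",
                        polyorder = "integer"))

setValidity("PretreatmentSpec", function(object) {
    msg <- character()
    if (!(object@name %in% PRETREATMENT_NAMES))
        msg <- c(msg, sprintf("unknown pretreatment '%s'; valid names: %s",
                              object@name,
                              paste(PRETREATMENT_NAMES, collapse = ", ")))
    if (object@window < 3L || object@window %% 2L == 0L)
        msg <- c(msg, "window must be an odd integer >= 3")
    if (object@polyorder < 1L || object@polyorder >= object@window)
        msg <- c(msg, "polyorder must be >= 1 and < window")
    if (length(msg)) msg else TRUE
})

#' Construct a PretreatmentSpec
#'
#' @param name pretreatment name (case-insensitive): Raw, MSC, SNV, Smooth,
#'   Smooth+SNV, Smooth+MSC or SG-1D.
#' @param window odd Savitzky-Golay window in points (default 11).
#' @param polyorder Savitzky-Golay polynomial order (default 2).
#' @return a validated \linkS4class{PretreatmentSpec}.
#' @examples
#' PretreatmentSpec("sg-1d")
#' @export
PretreatmentSpec <- function(name = "Raw", window = 11L, polyorder = 2L) {
    hit <- match(tolower(name), tolower(PRETREATMENT_NAMES))
    if (is.na(hit))
        stop(sprintf("unknown pretreatment '%s'; valid names: %s", name,
                     paste(PRETREATMENT_NAMES, collapse = ", ")))
    new("PretreatmentSpec", name = PRETREATMENT_NAMES[hit],
        window = as.integer(window), polyorder = as.integer(polyorder))
}

setMethod("show", "PretreatmentSpec", function(object) {
    cat(sprintf("PretreatmentSpec: %s (window %d, polyorder %d)\n",
                object@name, object@window, object@polyorder))
})

## ---------------------------------------------------------------------------
## SplitResult / OutlierReport
## ---------------------------------------------------------------------------

#' SplitResult: a calibration/validation partition
#'
#' @slot calibrationIds,validationIds disjoint character id sets whose union
#'   is the full sample set.
#' @slot ratio target calibration:validation proportion (e.g. 4 for 4:1).
#' @seealso \code{\link{kennardStoneSplit}}
#' @export
setClass("SplitResult",
         representation(calibrationIds = "character",
                        validationIds = "character", ratio = "numeric"))

setValidity("SplitResult", function(object) {
    if (length(intersect(object@calibrationIds, object@validationIds)))
        return("calibration and validation ids overlap")
    if (object@ratio <= 0) return("ratio must be positive")
    TRUE
})

#' @rdname split-accessors
#' @export
setMethod("calibrationIds", "SplitResult", function(x) x@calibrationIds)

#' @rdname split-accessors
#' @export
setMethod("validationIds", "SplitResult", function(x) x@validationIds)

setMethod("show", "SplitResult", function(object) {
    cat(sprintf("SplitResult: %d calibration / %d validation (ratio %g:1)\n",
                length(object@calibrationIds), length(object@validationIds),
                object@ratio))
})

#' OutlierReport: Monte-Carlo cross-validation residual diagnostics
#'
#' Per-sample mean and standard deviation of absolute held-out prediction
#' residuals across Monte-Carlo rounds, with the identifiers flagged by the
#' mean/SD thresholds.
#'
#' @slot stats data.frame: sample_id, residual_mean, residual_sd, n_heldout,
#'   flagged.
#' @slot flaggedIds character, flagged sample ids.
#' @slot params list of the MCCV parameters used (n_rounds, cal_fraction,
#'   n_factors, mean_k, sd_k, seed).
#' @seealso \code{\link{detectOutliersMCCV}}
#' @export
setClass("OutlierReport",
         representation(stats = "data.frame", flaggedIds = "character",
                        params = "list"))

setValidity("OutlierReport", function(object) {
    s <- object@stats
    msg <- character()
    if (!all(object@flaggedIds %in% s$sample_id))
        msg <- c(msg, "flagged ids must be a subset of sample ids")
    if (any(!is.finite(s$residual_mean)) || any(s$residual_mean < 0) ||
        any(!is.finite(s$residual_sd)) || any(s$residual_sd < 0))
        msg <- c(msg, "residual statistics must be finite and >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname flaggedIds
#' @export
setMethod("flaggedIds", "OutlierReport", function(x) x@flaggedIds)

setMethod("show", "OutlierReport", function(object) {
    cat(sprintf("OutlierReport: %d round(s), %d flagged of %d sample(s)%s\n",
                object@params$n_rounds, length(object@flaggedIds),
                nrow(object@stats),
                if (length(object@flaggedIds))
                    paste0(" (", paste(object@flaggedIds, collapse = ", "), ")")
                else ""))
})

## ---------------------------------------------------------------------------
## PLSRModel / RegressionEvaluation
## ---------------------------------------------------------------------------

#' PLSRModel: a fitted single-response partial least squares regression
#'
#' NIPALS PLS1 state: latent-variable weights/loadings and the collapsed
#' regression vector, plus the centering vectors and the pretreatment (with
#' its fitted state) applied to spectra before regression.
#'
#' @slot nFactors number of latent variables.
#' @slot xWeights,xLoadings p-by-A weight and loading matrices.
#' @slot yLoadings length-A response loadings.
#' @slot xMean,yMean centering vectors (length p / 1).
#' @slot coefficients length-p regression vector mapping centered pretreated
#'   spectra to the centered response.
#' @slot wavenumbers training axis (prediction validates against it).
#' @slot pretreatment \linkS4class{PretreatmentSpec} applied internally.
#' @slot pretreatmentState fitted pretreatment state (e.g. the MSC reference),
#'   learned on calibration data only.
#' @slot response name of the modelled response.
#' @seealso \code{\link{fitPLSR}}, \code{\link{predict,PLSRModel-method}}
#' @export
setClass("PLSRModel",
         representation(nFactors = "integer", xWeights = "matrix",
                        xLoadings = "matrix", yLoadings = "numeric",
                        xMean = "numeric", yMean = "numeric",
                        coefficients = "numeric", wavenumbers = "numeric",
                        pretreatment = "PretreatmentSpec",
                        pretreatmentState = "list", response = "character"))

setValidity("PLSRModel", function(object) {
    p <- length(object@wavenumbers)
    msg <- character()
    if (length(object@coefficients) != p)
        msg <- c(msg, "coefficient length must equal the number of wavenumbers")
    if (object@nFactors < 1L)
        msg <- c(msg, "nFactors must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn PLSRModel the collapsed regression coefficient vector.
#' @param object a PLSRModel.
#' @param ... unused.
#' @export
setMethod("coef", "PLSRModel", function(object, ...) object@coefficients)

setMethod("show", "PLSRModel", function(object) {
    cat(sprintf("PLSRModel for '%s': %d factor(s), %d wavenumber(s), pretreatment %s\n",
                object@response, object@nFactors, length(object@wavenumbers),
                object@pretreatment@name))
})

#' RegressionEvaluation: calibration/prediction error summary
#'
#' Root mean square errors of calibration and prediction, coefficients of
#' determination for both sets, and the mean relative error (percent) over
#' the validation samples.
#'
#' @slot rmsec,rmsep root mean square error, calibration / prediction set.
#' @slot r2cal,r2pre coefficients of determination (each set uses its own
#'   measured mean by default).
#' @slot rePercent mean of per-sample |yhat - y| / y * 100 over validation.
#' @slot nCal,nVal set sizes.
#' @seealso \code{\link{evaluateRegression}}
#' @export
setClass("RegressionEvaluation",
         representation(rmsec = "numeric", rmsep = "numeric",
                        r2cal = "numeric", r2pre = "numeric",
                        rePercent = "numeric", nCal = "integer",
                        nVal = "integer"))

setValidity("RegressionEvaluation", function(object) {
    msg <- character()
    if (object@rmsec < 0 || object@rmsep < 0)
        msg <- c(msg, "rmsec and rmsep must be >= 0")
    if (object@r2cal > 1 || object@r2pre > 1)
        msg <- c(msg, "r2 values cannot exceed 1")
    if (!is.na(object@rePercent) && object@rePercent < 0)
        msg <- c(msg, "rePercent must be >= 0")
    if (object@nCal < 1L || object@nVal < 1L)
        msg <- c(msg, "set sizes must be >= 1")
    if (length(msg)) msg else TRUE
})

setMethod("show", "RegressionEvaluation", function(object) {
    cat(sprintf(
        "RegressionEvaluation: RMSEC %.4g R2cal %.4g | RMSEP %.4g R2pre %.4g | RE %.3g%% (n=%d/%d)\n",
        object@rmsec, object@r2cal, object@rmsep, object@r2pre,
        object@rePercent, object@nCal, object@nVal))
})

## ---------------------------------------------------------------------------
## RegionForest / ClassificationReport
## ---------------------------------------------------------------------------

#' RegionForest: random-forest discriminator of cultivation regions
#'
#' Wraps a bagged classification forest trained on pretreated spectra,
#' together with the pretreatment state so validation spectra are transformed
#' identically at prediction time.
#'
#' @slot forest the fitted \code{randomForest} object.
#' @slot pretreatment,pretreatmentState pretreatment applied to spectra before
#'   the forest, with state learned on calibration data.
#' @slot wavenumbers training axis.
#' @slot classLevels class labels in tie-break order.
#' @slot seed integer seed used for training.
#' @seealso \code{\link{fitRegionForest}}
#' @export
setClass("RegionForest",
         representation(forest = "ANY", pretreatment = "PretreatmentSpec",
                        pretreatmentState = "list", wavenumbers = "numeric",
                        classLevels = "character", seed = "integer"))

setMethod("show", "RegionForest", function(object) {
    cat(sprintf("RegionForest: %d tree(s), classes %s, pretreatment %s\n",
                object@forest$ntree,
                paste(object@classLevels, collapse = "/"),
                object@pretreatment@name))
})

#' ClassificationReport: per-sample classification outcomes
#'
#' @slot table data.frame: sample_id, reference, predicted, correct.
#' @slot confusion contingency matrix (reference rows, predicted columns).
#' @slot accuracy fraction correct.
#' @seealso \code{\link{classificationReport}}
#' @export
setClass("ClassificationReport",
         representation(table = "data.frame", confusion = "matrix",
                        accuracy = "numeric"))

setValidity("ClassificationReport", function(object) {
    n <- nrow(object@table)
    msg <- character()
    if (sum(object@confusion) != n)
        msg <- c(msg, "confusion counts must sum to the number of samples")
    if (abs(object@accuracy - sum(object@table$correct) / n) > 1e-12)
        msg <- c(msg, "accuracy must equal correct/total")
    if (length(msg)) msg else TRUE
})

#' @rdname accuracy
#' @export
setMethod("accuracy", "ClassificationReport", function(x) x@accuracy)

setMethod("show", "ClassificationReport", function(object) {
    cat(sprintf("ClassificationReport: accuracy %.2f%% (%d/%d correct)\n",
                100 * object@accuracy, sum(object@table$correct),
                nrow(object@table)))
})

## ---------------------------------------------------------------------------
## StandardCurve
## ---------------------------------------------------------------------------

#' StandardCurve: a linear calibration curve
#'
#' Ordinary least-squares line response = slope * concentration + intercept,
#' with goodness-of-fit and optional detection/quantification limits.
#'
#' @slot slope,intercept line parameters (response per concentration unit /
#'   response units).
#' @slot r2 squared Pearson correlation of the fit.
#' @slot residualSd residual standard deviation (n - 2 denominator).
#' @slot lod,loq limits of detection/quantification (concentration units),
#'   NA until computed by \code{\link{lodLoq}}.
#' @seealso \code{\link{fitStandardCurve}}
#' @export
setClass("StandardCurve",
         representation(slope = "numeric", intercept = "numeric",
                        r2 = "numeric", residualSd = "numeric",
                        lod = "numeric", loq = "numeric"))

setValidity("StandardCurve", function(object) {
    msg <- character()
    if (object@r2 > 1 + 1e-12) msg <- c(msg, "r2 cannot exceed 1")
    if (!is.na(object@lod) && !is.na(object@loq) && object@lod > object@loq)
        msg <- c(msg, "lod must not exceed loq")
    if (length(msg)) msg else TRUE
})

setMethod("show", "StandardCurve", function(object) {
    cat(sprintf("StandardCurve: y = %.6g x %+.6g (R2 %.4f, residual sd %.3g)\n",
                object@slope, object@intercept, object@r2, object@residualSd))
    if (!is.na(object@lod))
        cat(sprintf("  LOD %.4g, LOQ %.4g\n", object@lod, object@loq))
})
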