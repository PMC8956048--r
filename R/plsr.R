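## Single-response partial least squares regression (PLS1) by NIPALS, 10-fold
## cross-validated factor selection, calibration/prediction evaluation and the
## pretreatment grid search.

## NIPALS PLS1 on plain matrices. Returns centering vectors, weight/loading
## matrices and the collapsed coefficient vector for every factor count
## 1..A (column a of `B` is the regression vector using a factors).
.nipalsPLS1 <- function(X, y, A, strict = TRUE) {
    n <- nrow(X); p <- ncol(X)
    if (length(y) != n) stop("y length must match the number of rows of X")
    if (var(y) == 0) stop("y has zero variance")
    A <- as.integer(A)
    if (A < 1L) stop("nFactors must be >= 1")
    if (A > min(n - 1L, p))
        stop(sprintf("nFactors %d exceeds the rank bound min(n-1, p) = %d",
                     A, min(n - 1L, p)))
    xMean <- colMeans(X)
    yMean <- mean(y)
    Xc <- sweep(X, 2L, xMean)
    yc <- y - yMean
    W <- matrix(0, p, A); P <- matrix(0, p, A); R <- matrix(0, p, A)
    q <- numeric(A)
    B <- matrix(0, p, A)
    b <- numeric(p)
    for (a in seq_len(A)) {
        w <- crossprod(Xc, yc)[, 1]
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12 * max(1, sqrt(sum(y^2)))) {
            ## X (or the covariance with y) is exhausted: no further factors
            if (strict)
                stop(sprintf("X exhausted after %d factor(s); nFactors %d exceeds the effective rank",
                             a - 1L, A))
            if (a == 1L) stop("X carries no covariance with y")
            A <- a - 1L
            W <- W[, seq_len(A), drop = FALSE]
            P <- P[, seq_len(A), drop = FALSE]
            R <- R[, seq_len(A), drop = FALSE]
            q <- q[seq_len(A)]; B <- B[, seq_len(A), drop = FALSE]
            break
        }
        w <- w / nw
        t_ <- Xc %*% w
        tt <- sum(t_^2)
        pv <- crossprod(Xc, t_)[, 1] / tt
        qa <- sum(yc * t_) / tt
        Xc <- Xc - tcrossprod(t_, pv)
        yc <- yc - qa * t_[, 1]
        ## r_a: weight mapped back to the original (undeflated) X space
        r <- w
        if (a > 1L)
            r <- as.vector(w - R[, seq_len(a - 1L), drop = FALSE] %*%
                               crossprod(P[, seq_len(a - 1L), drop = FALSE],
                                         w))
        W[, a] <- w; P[, a] <- pv; q[a] <- qa; R[, a] <- r
        b <- b + qa * r
        B[, a] <- b
    }
    list(xMean = xMean, yMean = yMean, W = W, P = P, q = q, B = B,
         coefficients = b, nFactors = A)
}

.nipalsPredict <- function(fit, X, nFactors = fit$nFactors) {
    as.vector(sweep(X, 2L, fit$xMean) %*% fit$B[, nFactors]) + fit$yMean
}

#' Fit a PLSR calibration model
#'
#' Mean-centers spectra and response and extracts latent variables by the
#' NIPALS sequence (weight along the covariance of X with y, score, rank-one
#' deflation); the latent regression is collapsed to a single coefficient
#' vector. The named pretreatment is fitted on the calibration spectra and
#' stored, so \code{\link{predict,PLSRModel-method}} transforms new spectra
#' identically.
#'
#' @param spectra calibration \linkS4class{SpectraMatrix}.
#' @param y numeric response, one value per sample, no missing values,
#'   nonzero variance.
#' @param nFactors number of latent variables, within the rank bound
#'   \code{min(n - 1, n_wavenumbers)}.
#' @param pretreatment a \linkS4class{PretreatmentSpec} or name; default Raw.
#' @param response a label for the modelled response.
#' @return a \linkS4class{PLSRModel}.
#' @examples
#' sim <- simulateDataset(SyntheticConfig(nPerRegion = c(8, 6, 6), seed = 3))
#' m <- fitPLSR(sim$spectra, chemistry(sim$samples)$psc, nFactors = 4,
#'              pretreatment = "SNV", response = "psc")
#' @export
fitPLSR <- function(spectra, y, nFactors, pretreatment = "Raw",
                    response = "y") {
    stopifnot(is(spectra, "SpectraMatrix"))
    if (anyNA(y)) stop("y must have no missing values")
    if (is.character(pretreatment))
        pretreatment <- PretreatmentSpec(pretreatment)
    pre <- applyPretreatment(spectra, pretreatment)
    fit <- .nipalsPLS1(absorbance(pre$spectra), y, nFactors)
    new("PLSRModel", nFactors = fit$nFactors, xWeights = fit$W,
        xLoadings = fit$P, yLoadings = fit$q, xMean = fit$xMean,
        yMean = fit$yMean, coefficients = fit$coefficients,
        wavenumbers = wavenumbers(spectra), pretreatment = pretreatment,
        pretreatmentState = pre$state, response = response)
}

#' Predict responses from spectra
#'
#' Applies the model's stored pretreatment (with the state fitted on
#' calibration data) and evaluates
#' \code{yhat = yMean + (X_pretreated - xMean) \%*\% coefficients}.
#'
#' @param object a \linkS4class{PLSRModel}.
#' @param newdata a \linkS4class{SpectraMatrix} on the model's wavenumber
#'   axis.
#' @param ... unused.
#' @return numeric vector of predicted responses, named by sample id.
#' @export
setMethod("predict", "PLSRModel", function(object, newdata, ...) {
    stopifnot(is(newdata, "SpectraMatrix"))
    if (length(wavenumbers(newdata)) != length(object@wavenumbers) ||
        max(abs(wavenumbers(newdata) - object@wavenumbers)) > 1e-9)
        stop("wavenumber axis of newdata does not match the model")
    pre <- applyPretreatment(newdata, object@pretreatment,
                             state = if (length(object@pretreatmentState))
                                         object@pretreatmentState else NULL)
    yhat <- as.vector(sweep(absorbance(pre$spectra), 2L, object@xMean) %*%
                          object@coefficients) + object@yMean
    names(yhat) <- sampleIds(newdata)
    yhat
})

#' Select the number of PLSR factors by k-fold cross-validation
#'
#' Partitions the calibration samples into \code{k} folds (seeded shuffle),
#' computes the root mean square error of cross-validation (RMSECV, pooled
#' held-out residuals) for each candidate factor count, and returns the
#' smallest count whose RMSECV is within \code{margin} of the global minimum
#' (parsimony rule; \code{margin = 0} recovers the strict argmin).
#'
#' @param spectra calibration \linkS4class{SpectraMatrix}, already pretreated.
#' @param y numeric response.
#' @param maxFactors largest candidate factor count.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle; result is deterministic
#'   given it.
#' @param margin relative parsimony margin on RMSECV (default 0.02).
#' @return the selected factor count (integer) with attribute
#'   \code{"rmsecv"}: the RMSECV per candidate count.
#' @export
selectNFactors <- function(spectra, y, maxFactors, k = 10L, seed = 1L,
                           margin = 0.02) {
    stopifnot(is(spectra, "SpectraMatrix"))
    X <- absorbance(spectra)
    n <- nrow(X)
    if (k > n) stop(sprintf("k = %d folds exceed n = %d samples", k, n))
    if (maxFactors < 1L) stop("maxFactors must be >= 1")
    set.seed(seed)
    fold <- sample(rep(seq_len(k), length.out = n))
    A <- min(maxFactors,
             min(vapply(seq_len(k), function(f) sum(fold != f) - 1L,
                        integer(1))),
             ncol(X))
    sse <- numeric(A)
    for (f in seq_len(k)) {
        tr <- fold != f
        fit <- .nipalsPLS1(X[tr, , drop = FALSE], y[tr], A, strict = FALSE)
        Xo <- sweep(X[!tr, , drop = FALSE], 2L, fit$xMean)
        pred <- Xo %*% fit$B + fit$yMean       # n_out x A_fit, all counts at once
        if (fit$nFactors < A)                  # rank exhausted: error is flat beyond
            pred <- pred[, c(seq_len(fit$nFactors),
                             rep(fit$nFactors, A - fit$nFactors)),
                         drop = FALSE]
        sse <- sse + colSums((pred - y[!tr])^2)
    }
    rmsecv <- sqrt(sse / n)
    best <- min(rmsecv)
    sel <- which(rmsecv <= best * (1 + margin))[1]
    structure(as.integer(sel), rmsecv = rmsecv)
}

#' Evaluate a regression model on calibration and validation sets
#'
#' RMSEC and RMSEP are the roots of the mean squared residual over the
#' calibration and prediction sets; R2cal and R2pre are 1 - SSres/SStot with
#' the mean of the measured values of the respective set (switchable to the
#' calibration mean); RE is the mean over validation samples of
#' \code{|yhat - y| / y * 100}.
#'
#' @param model a \linkS4class{PLSRModel}.
#' @param calSpectra,yCal calibration spectra and measured values.
#' @param valSpectra,yVal validation spectra and measured values (no zeros:
#'   relative error is undefined at y = 0).
#' @param yBar which measured mean anchors SStot in R2pre: \code{"own"}
#'   (validation mean, default) or \code{"calibration"}.
#' @return a \linkS4class{RegressionEvaluation}.
#' @examples
#' # yVal = c(10, 20), predictions c(11, 18): RMSEP = sqrt(5/2), RE = 10%
#' @export
evaluateRegression <- function(model, calSpectra, yCal, valSpectra, yVal,
                               yBar = c("own", "calibration")) {
    yBar <- match.arg(yBar)
    if (!length(yCal) || !length(yVal)) stop("both sets must be non-empty")
    if (anyNA(yCal) || anyNA(yVal)) stop("measured values must not be missing")
    if (any(yVal == 0))
        stop("relative error undefined: validation set contains y = 0")
    predCal <- predict(model, calSpectra)
    predVal <- predict(model, valSpectra)
    rmsec <- sqrt(mean((predCal - yCal)^2))
    rmsep <- sqrt(mean((predVal - yVal)^2))
    r2cal <- 1 - sum((predCal - yCal)^2) / sum((yCal - mean(yCal))^2)
    mPre <- if (yBar == "own") mean(yVal) else mean(yCal)
    r2pre <- 1 - sum((predVal - yVal)^2) / sum((yVal - mPre)^2)
    re <- mean(abs(predVal - yVal) / yVal) * 100
    new("RegressionEvaluation", rmsec = rmsec, rmsep = rmsep, r2cal = r2cal,
        r2pre = r2pre, rePercent = re, nCal = length(yCal),
        nVal = length(yVal))
}

#' Pretreatment grid search
#'
#' For each candidate pretreatment: fit the pretreatment state on the
#' calibration set only, select the factor count by 10-fold cross-validation,
#' fit the PLSR model and evaluate on both sets. The selected method minimizes
#' RMSEP (ties: higher R2pre, then first listed).
#'
#' @param spectra full \linkS4class{SpectraMatrix}.
#' @param y numeric response for all samples.
#' @param split a \linkS4class{SplitResult} over the sample ids.
#' @param methods character vector of pretreatment names or list of
#'   \linkS4class{PretreatmentSpec}; defaults to all seven.
#' @param maxFactors candidate ceiling for factor selection.
#' @param cvSeed seed for the fold shuffle.
#' @param margin parsimony margin for \code{\link{selectNFactors}}.
#' @param response label for the modelled response.
#' @return list with \code{grid} (data.frame: method, n_factors, rmsec,
#'   r2cal, rmsep, r2pre, re_percent), \code{selected} (method name),
#'   \code{models} and \code{evaluations} (named lists).
#' @export
pretreatmentGrid <- function(spectra, y, split,
                             methods = PRETREATMENT_NAMES,
                             maxFactors = 15L, cvSeed = 1L, margin = 0.02,
                             response = "y") {
    stopifnot(is(spectra, "SpectraMatrix"), is(split, "SplitResult"))
    if (!length(methods)) stop("methods must be non-empty")
    specs <- lapply(methods, function(m)
        if (is(m, "PretreatmentSpec")) m else PretreatmentSpec(m))
    ids <- sampleIds(spectra)
    calIdx <- match(calibrationIds(split), ids)
    valIdx <- match(validationIds(split), ids)
    if (anyNA(calIdx) || anyNA(valIdx))
        stop("split ids not found among the spectra")
    calS <- spectra[calIdx, ]
    valS <- spectra[valIdx, ]
    yc <- y[calIdx]; yv <- y[valIdx]
    rows <- vector("list", length(specs))
    models <- list(); evals <- list()
    for (i in seq_along(specs)) {
        sp <- specs[[i]]
        res <- tryCatch({
            pre <- applyPretreatment(calS, sp)
            nf <- selectNFactors(pre$spectra, yc, maxFactors, seed = cvSeed,
                                 margin = margin)
            model <- fitPLSR(calS, yc, nFactors = nf, pretreatment = sp,
                             response = response)
            ev <- evaluateRegression(model, calS, yc, valS, yv)
            list(model = model, ev = ev, nf = nf)
        }, error = function(e)
            stop(sprintf("pretreatment '%s' failed: %s", sp@name,
                         conditionMessage(e)), call. = FALSE))
        models[[sp@name]] <- res$model
        evals[[sp@name]] <- res$ev
        rows[[i]] <- data.frame(method = sp@name,
                                n_factors = as.integer(res$nf),
                                rmsec = res$ev@rmsec, r2cal = res$ev@r2cal,
                                rmsep = res$ev@rmsep, r2pre = res$ev@r2pre,
                                re_percent = res$ev@rePercent,
                                stringsAsFactors = FALSE)
    }
    grid <- do.call(rbind, rows)
    ord <- order(grid$rmsep, -grid$r2pre, seq_len(nrow(grid)))
    selected <- grid$method[ord[1]]
    list(grid = grid, selected = selected, models = models,
         evaluations = evals)
}

#' Write a pretreatment grid as a delimited table
#'
#' One row per evaluation statistic, one column per method, mirroring the
#' usual pretreatment-comparison layout.
#'
#' @param gridResult result of \code{\link{pretreatmentGrid}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGrid <- function(gridResult, path) {
    g <- gridResult$grid
    stats <- c(rmsec = "RMSEC", r2cal = "R2cal", rmsep = "RMSEP",
               r2pre = "R2pre")
    lines <- c(paste(c("evaluation", g$method), collapse = ","),
               vapply(names(stats), function(s)
                   paste(c(stats[[s]], sprintf("%.6g", g[[s]])),
                         collapse = ","), character(1)))
    writeLines(c(sprintf("# selected method: %s", gridResult$selected),
                 lines), path)
    invisible(path)
}
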