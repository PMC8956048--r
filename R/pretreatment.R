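## Spectral pretreatment operators: SNV, MSC, Savitzky-Golay smoothing and
## first derivative, and their named compositions. All operators preserve the
## matrix shape; SNV/MSC are row-local (MSC relative to a stored reference).

#' Standard normal variate transform
#'
#' Each spectrum is centered and scaled to unit standard deviation
#' (\code{(x - mean(x)) / sd(x)}, sample n-1 standard deviation), removing
#' per-sample multiplicative scatter and offset.
#'
#' @param spectra a \linkS4class{SpectraMatrix} (rows need >= 2 points and
#'   nonzero standard deviation).
#' @return the transformed \linkS4class{SpectraMatrix}: every row has mean 0
#'   and standard deviation 1.
#' @examples
#' sm <- SpectraMatrix(matrix(c(1, 2, 3), 1), c(1, 2, 3), "a")
#' absorbance(snv(sm))  # -1 0 1
#' @export
snv <- function(spectra) {
    stopifnot(is(spectra, "SpectraMatrix"))
    ab <- absorbance(spectra)
    if (ncol(ab) < 2L) stop("SNV needs at least 2 points per spectrum")
    mu <- rowMeans(ab)
    sdv <- apply(ab, 1L, sd)
    zero <- sdv == 0
    if (any(zero))
        stop(sprintf("SNV undefined for constant spectrum (zero sd): %s",
                     paste(sampleIds(spectra)[zero], collapse = ", ")))
    SpectraMatrix((ab - mu) / sdv, wavenumbers(spectra), sampleIds(spectra))
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, \code{x = a + b * reference}, and replaced by \code{(x - a) / b}.
#' The reference defaults to the column-wise mean spectrum of the input; pass
#' the returned reference back in to correct validation spectra against the
#' calibration reference (no information leakage).
#'
#' @param spectra a \linkS4class{SpectraMatrix} (>= 2 samples when
#'   \code{reference} is omitted).
#' @param reference optional numeric reference spectrum of matching length.
#' @return a list with \code{spectra} (corrected \linkS4class{SpectraMatrix})
#'   and \code{reference} (the reference used).
#' @export
msc <- function(spectra, reference = NULL) {
    stopifnot(is(spectra, "SpectraMatrix"))
    ab <- absorbance(spectra)
    if (is.null(reference)) {
        if (nrow(ab) < 2L)
            stop("MSC needs >= 2 samples to form a mean reference")
        reference <- colMeans(ab)
    }
    if (length(reference) != ncol(ab))
        stop(sprintf("reference length %d does not match %d wavenumbers",
                     length(reference), ncol(ab)))
    rc <- reference - mean(reference)
    denom <- sum(rc^2)
    if (denom == 0) stop("MSC reference is constant")
    b <- as.vector(ab %*% rc) / denom            # OLS slope per row
    a <- rowMeans(ab) - b * mean(reference)      # OLS intercept per row
    if (any(b == 0))
        stop(sprintf("MSC slope of 0 for sample(s): %s",
                     paste(sampleIds(spectra)[b == 0], collapse = ", ")))
    out <- (ab - a) / b
    list(spectra = SpectraMatrix(out, wavenumbers(spectra),
                                 sampleIds(spectra)),
         reference = as.numeric(reference))
}

#' Savitzky-Golay filtering
#'
#' Local least-squares polynomial smoothing (\code{deriv = 0}) or first
#' derivative (\code{deriv = 1}) of each spectrum. Edges are handled by the
#' polynomial fit over the one-sided window, so output shape equals input
#' shape. The derivative is scaled by the (uniform) wavenumber step, so its
#' units are absorbance per cm-1.
#'
#' @param spectra a \linkS4class{SpectraMatrix}.
#' @param window odd window length in points, 3 <= window <= n_wavenumbers.
#' @param polyorder polynomial order, < window.
#' @param deriv 0 (smoothing) or 1 (first derivative).
#' @return the filtered \linkS4class{SpectraMatrix}.
#' @examples
#' sm <- SpectraMatrix(matrix(3 * (1:20) + 7, 1), 1:20, "a")
#' absorbance(savitzkyGolay(sm, 7, 2, deriv = 1))  # constant 3
#' @export
savitzkyGolay <- function(spectra, window = 11L, polyorder = 2L, deriv = 0L) {
    stopifnot(is(spectra, "SpectraMatrix"))
    window <- as.integer(window); polyorder <- as.integer(polyorder)
    deriv <- as.integer(deriv)
    wn <- wavenumbers(spectra)
    if (window %% 2L == 0L) stop("window must be odd")
    if (window < 3L || window > length(wn))
        stop(sprintf("window must be in [3, %d]", length(wn)))
    if (polyorder >= window) stop("polyorder must be < window")
    if (!deriv %in% c(0L, 1L)) stop("deriv must be 0 or 1")
    if (deriv < 0L || deriv > polyorder) stop("deriv must be <= polyorder")
    step <- 1
    if (deriv == 1L) {
        d <- diff(wn)
        if (max(abs(d - d[1])) > 1e-6 * abs(d[1]))
            stop("first derivative needs a uniformly spaced wavenumber axis")
        step <- d[1]
    }
    ab <- absorbance(spectra)
    ## sgolay projection matrix handles the edge rows as one-sided fits
    out <- t(apply(ab, 1L, signal::sgolayfilt, p = polyorder, n = window,
                   m = deriv, ts = step))
    if (nrow(ab) == 1L) out <- matrix(out, nrow = 1L)
    SpectraMatrix(out, wn, sampleIds(spectra))
}

#' Apply a named pretreatment
#'
#' Dispatches to the operator(s) named by a \linkS4class{PretreatmentSpec}.
#' Composed names (\code{Smooth+SNV}, \code{Smooth+MSC}) smooth first. Any
#' data-dependent state -- the MSC reference -- is learned from the data only
#' when \code{state} is \code{NULL} (i.e. on calibration data) and re-applied
#' unchanged when the returned \code{state} is passed back in (validation
#' data).
#'
#' @param spectra a \linkS4class{SpectraMatrix}.
#' @param spec a \linkS4class{PretreatmentSpec} (or a name passed to
#'   \code{\link{PretreatmentSpec}}).
#' @param state fitted state returned by a previous call on calibration data,
#'   or \code{NULL} to fit.
#' @return list with \code{spectra} (transformed) and \code{state} (to reuse
#'   on validation data).
#' @examples
#' sm <- simulateDataset(SyntheticConfig(nPerRegion = c(3, 3, 3), seed = 1))
#' out <- applyPretreatment(sm$spectra, PretreatmentSpec("Smooth+SNV"))
#' @export
applyPretreatment <- function(spectra, spec, state = NULL) {
    if (is.character(spec)) spec <- PretreatmentSpec(spec)
    stopifnot(is(spectra, "SpectraMatrix"), is(spec, "PretreatmentSpec"))
    validObject(spec)
    x <- spectra
    name <- spec@name
    if (name %in% c("Smooth", "Smooth+SNV", "Smooth+MSC"))
        x <- savitzkyGolay(x, spec@window, spec@polyorder, deriv = 0L)
    if (name == "SG-1D")
        x <- savitzkyGolay(x, spec@window, spec@polyorder, deriv = 1L)
    if (name %in% c("SNV", "Smooth+SNV"))
        x <- snv(x)
    if (name %in% c("MSC", "Smooth+MSC")) {
        res <- msc(x, reference = state$mscReference)
        x <- res$spectra
        state <- list(mscReference = res$reference)
    }
    if (is.null(state)) state <- list()
    list(spectra = x, state = state)
}
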