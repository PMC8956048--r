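## Region-stratified synthetic NIR dataset generator. Spectra are linear
## mixtures of Gaussian-band constituent profiles (Beer-Lambert), degraded by
## per-sample baseline offset, multiplicative scatter and white noise;
## concentrations follow the per-region summary moments of the reference
## dataset (58/28/52 samples from Yunnan, Xiangqian and the Dabie Mountains).

CONSTITUENTS <- c("psc", "wse", "ase", "sft")

#' Per-region concentration parameters
#'
#' The (mean, sd, min, max) of the four quality parameters in each region,
#' mg/g, as reported for the reference sample set.
#'
#' @return data.frame with columns region, constituent, mean, sd, min, max.
#' @export
defaultRegionParams <- function() {
    d <- rbind(
        c("YN",  "psc",  6.81,  5.62,  1.24, 31.16),
        c("YN",  "wse", 25.22, 12.81,  8.80, 73.95),
        c("YN",  "ase", 37.85, 14.31, 16.29, 90.00),
        c("YN",  "sft",  1.26,  1.00,  0.51,  5.68),
        c("XQ",  "psc",  5.67,  4.59,  1.20, 22.66),
        c("XQ",  "wse", 23.95, 12.18, 15.52, 73.76),
        c("XQ",  "ase", 33.60,  7.53, 24.20, 53.88),
        c("XQ",  "sft",  1.36,  0.80,  0.64,  4.82),
        c("DBM", "psc",  4.59,  1.89,  1.40,  8.96),
        c("DBM", "wse", 19.57,  7.40,  5.68, 57.58),
        c("DBM", "ase", 31.24,  5.83, 17.01, 48.70),
        c("DBM", "sft",  1.13,  0.47,  0.52,  2.77))
    out <- data.frame(region = d[, 1], constituent = d[, 2],
                      mean = as.numeric(d[, 3]), sd = as.numeric(d[, 4]),
                      min = as.numeric(d[, 5]), max = as.numeric(d[, 6]),
                      stringsAsFactors = FALSE)
    out
}

## Five triterpene acids as fixed proportions of SFT (from the reference
## region means 0.15/0.06/0.13/0.18/0.73 over their 1.25 total).
ACID_PROPORTIONS <- c(dtua = 0.15, paa = 0.06, pac = 0.13, dpa = 0.18,
                      dtra = 0.73) / 1.25

.defaultLoadings <- function() {
    ## rows: constituents; columns: bands at 8256/6880/5610/5180/4800 cm-1.
    ## Row scales balance each constituent's mean contribution (~0.3 AU)
    ## despite very different concentration scales; patterns are linearly
    ## independent so the mixture is identifiable. Declared fiction: real
    ## constituent cross-sections are not published.
    rbind(psc = 0.050 * c(0.20, 0.50, 0.30, 1.00, 0.60),
          wse = 0.012 * c(0.10, 0.30, 0.60, 1.00, 0.40),
          ase = 0.010 * c(0.60, 0.40, 0.90, 0.70, 0.30),
          sft = 0.250 * c(0.90, 0.20, 0.50, 0.40, 0.80))
}

.defaultCorrelation <- function() {
    ## extracts co-vary positively; high SFT tends with low PSC
    m <- matrix(c(1.00, 0.50, 0.50, -0.30,
                  0.50, 1.00, 0.50, -0.15,
                  0.50, 0.50, 1.00, -0.15,
                 -0.30, -0.15, -0.15, 1.00), 4, 4,
                dimnames = list(CONSTITUENTS, CONSTITUENTS))
    m
}

#' SyntheticConfig: parameters of the synthetic dataset generator
#'
#' @slot nPerRegion named integer counts for YN/XQ/DBM (default 58/28/52).
#' @slot axis wavenumber grid, cm-1 (default 4000..12000 step 8).
#' @slot bandCenters absorption band positions, cm-1 (default 8256, 6880,
#'   5610, 5180, 4800: the five observed peaks, strongest near 5180).
#' @slot bandWidths Gaussian band SDs, cm-1.
#' @slot componentLoadings 4 x n_bands matrix mapping constituents (psc, wse,
#'   ase, sft) to band amplitudes.
#' @slot backgroundWeights per-band weights of the fixed dry-matter
#'   background spectrum common to all samples (the bulk sclerotium powder
#'   absorbs at the same bands regardless of extractable content).
#' @slot backgroundAmplitude peak scale of that background (absorbance
#'   units); 0 disables it.
#' @slot regionParams data.frame of per-region truncated-normal parameters,
#'   see \code{\link{defaultRegionParams}}.
#' @slot correlation 4 x 4 constituent correlation (Gaussian copula).
#' @slot scatterSlopeSd,scatterOffsetSd,baselineSd,noiseSd degradation SDs:
#'   multiplicative slope, additive scatter offset, pre-scatter baseline
#'   offset, white noise (absorbance units).
#' @slot seed integer RNG seed.
#' @seealso \code{\link{simulateDataset}}, \code{\link{componentProfiles}}
#' @export
setClass("SyntheticConfig",
         representation(nPerRegion = "integer", axis = "numeric",
                        bandCenters = "numeric", bandWidths = "numeric",
                        componentLoadings = "matrix",
                        backgroundWeights = "numeric",
                        backgroundAmplitude = "numeric",
                        regionParams = "data.frame", correlation = "matrix",
                        scatterSlopeSd = "numeric",
                        scatterOffsetSd = "numeric", baselineSd = "numeric",
                        noiseSd = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (length(object@nPerRegion) != 3L || any(object@nPerRegion < 2L))
        msg <- c(msg, "nPerRegion must give >= 2 samples for each of the 3 regions")
    if (any(diff(object@axis) <= 0))
        msg <- c(msg, "axis must be strictly ascending")
    if (any(object@bandCenters < min(object@axis)) ||
        any(object@bandCenters > max(object@axis)))
        msg <- c(msg, "band centers must lie within the axis")
    if (any(object@bandWidths <= 0))
        msg <- c(msg, "band widths must be positive")
    if (nrow(object@componentLoadings) != 4L ||
        ncol(object@componentLoadings) != length(object@bandCenters))
        msg <- c(msg, "componentLoadings must be 4 x n_bands")
    if (any(object@componentLoadings < 0))
        msg <- c(msg, "componentLoadings must be non-negative")
    if (length(object@backgroundWeights) != length(object@bandCenters) ||
        any(object@backgroundWeights < 0))
        msg <- c(msg, "backgroundWeights must be non-negative, one per band")
    if (object@backgroundAmplitude < 0)
        msg <- c(msg, "backgroundAmplitude must be >= 0")
    rp <- object@regionParams
    if (!all(c("region", "constituent", "mean", "sd", "min", "max") %in%
             names(rp)))
        msg <- c(msg, "regionParams must have region/constituent/mean/sd/min/max")
    else {
        if (any(rp$sd < 0)) msg <- c(msg, "regionParams sd must be >= 0")
        if (any(rp$mean < rp$min | rp$mean > rp$max))
            msg <- c(msg, "regionParams means must lie within [min, max]")
        need <- expand.grid(region = REGION_LEVELS,
                            constituent = CONSTITUENTS,
                            stringsAsFactors = FALSE)
        have <- paste(rp$region, rp$constituent)
        if (!all(paste(need$region, need$constituent) %in% have))
            msg <- c(msg, "regionParams must cover all region x constituent pairs")
    }
    if (any(c(object@scatterSlopeSd, object@scatterOffsetSd,
              object@baselineSd, object@noiseSd) < 0))
        msg <- c(msg, "all noise/scatter sds must be >= 0")
    ev <- tryCatch(eigen(object@correlation, symmetric = TRUE,
                         only.values = TRUE)$values,
                   error = function(e) -1)
    if (any(ev <= 0))
        msg <- c(msg, "correlation matrix must be positive definite")
    if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' All arguments default to the study conditions the generator emulates:
#' 58/28/52 samples per region, a 4000-12000 cm-1 axis at 8 cm-1 steps, five
#' absorption bands with the strongest near 5180 cm-1, per-region
#' concentration moments from the reference tables, mild multiplicative
#' scatter and 0.005 AU white noise.
#'
#' @param nPerRegion counts for YN, XQ, DBM.
#' @param axis wavenumber grid (cm-1).
#' @param bandCenters,bandWidths Gaussian band positions and SDs (cm-1).
#' @param componentLoadings 4 x n_bands non-negative amplitude matrix.
#' @param backgroundWeights,backgroundAmplitude shape (per band) and peak
#'   scale of the fixed dry-matter background spectrum.
#' @param regionParams per-region truncated-normal parameters.
#' @param correlation 4 x 4 constituent correlation matrix.
#' @param scatterSlopeSd,scatterOffsetSd,baselineSd,noiseSd degradation SDs.
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @export
SyntheticConfig <- function(nPerRegion = c(YN = 58L, XQ = 28L, DBM = 52L),
                            axis = seq(4000, 12000, by = 8),
                            bandCenters = c(8256, 6880, 5610, 5180, 4800),
                            bandWidths = c(160, 140, 100, 90, 110),
                            componentLoadings = .defaultLoadings(),
                            backgroundWeights = c(0.50, 0.70, 0.80, 1.00,
                                                  0.85),
                            backgroundAmplitude = 1.0,
                            regionParams = defaultRegionParams(),
                            correlation = .defaultCorrelation(),
                            scatterSlopeSd = 0.05, scatterOffsetSd = 0.02,
                            baselineSd = 0.01, noiseSd = 0.005,
                            seed = 1L) {
    nPerRegion <- as.integer(nPerRegion)
    names(nPerRegion) <- REGION_LEVELS
    new("SyntheticConfig", nPerRegion = nPerRegion, axis = as.numeric(axis),
        bandCenters = as.numeric(bandCenters),
        bandWidths = as.numeric(bandWidths),
        componentLoadings = componentLoadings,
        backgroundWeights = as.numeric(backgroundWeights),
        backgroundAmplitude = backgroundAmplitude,
        regionParams = regionParams, correlation = correlation,
        scatterSlopeSd = scatterSlopeSd, scatterOffsetSd = scatterOffsetSd,
        baselineSd = baselineSd, noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf("SyntheticConfig: n=%s, axis %g..%g cm-1 (%d points), noise sd %g, seed %d\n",
                paste(object@nPerRegion, collapse = "/"), min(object@axis),
                max(object@axis), length(object@axis), object@noiseSd,
                object@seed))
})

#' Pure-component spectral profiles
#'
#' Each constituent's profile is the non-negative weighted sum of Gaussian
#' bands at the configured centers; with the default loadings, the strongest
#' feature of the mean mixture lies at the 5180 cm-1 combination band.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return 4 x n_wavenumbers matrix, rows psc/wse/ase/sft.
#' @export
componentProfiles <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    bands <- vapply(seq_along(config@bandCenters), function(b)
        exp(-(config@axis - config@bandCenters[b])^2 /
                (2 * config@bandWidths[b]^2)),
        numeric(length(config@axis)))         # n_wn x n_bands
    profiles <- config@componentLoadings %*% t(bands)
    rownames(profiles) <- CONSTITUENTS
    profiles
}

#' Fixed dry-matter background spectrum
#'
#' The bulk powder absorbs at the same bands in every sample, regardless of
#' extractable content; this common background (normalized to peak at
#' \code{backgroundAmplitude}) is what per-sample multiplicative scatter
#' mostly acts on, and what scatter-corrective pretreatments anchor to.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return numeric background spectrum over the axis.
#' @export
backgroundSpectrum <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    if (config@backgroundAmplitude == 0)
        return(numeric(length(config@axis)))
    bands <- vapply(seq_along(config@bandCenters), function(b)
        exp(-(config@axis - config@bandCenters[b])^2 /
                (2 * config@bandWidths[b]^2)),
        numeric(length(config@axis)))
    bg <- as.vector(bands %*% config@backgroundWeights)
    bg / max(bg) * config@backgroundAmplitude
}

## Mean of a normal(m, s) clipped to [a, b], closed form.
.clippedMean <- function(m, s, a, b) {
    if (s == 0) return(min(max(m, a), b))
    al <- (a - m) / s; be <- (b - m) / s
    a * pnorm(al) + b * (1 - pnorm(be)) + m * (pnorm(be) - pnorm(al)) +
        s * (dnorm(al) - dnorm(be))
}

## Latent mean such that the clipped-normal mean equals `target`
## (moment matching, so region sample means track the published means).
.matchedMean <- function(target, s, a, b) {
    if (s == 0) return(target)
    uniroot(function(m) .clippedMean(m, s, a, b) - target,
            lower = a - 10 * s, upper = b + 10 * s, tol = 1e-10)$root
}

#' Simulate a region-stratified NIR dataset
#'
#' Per sample: constituent concentrations are drawn from region-specific
#' clipped normals (Gaussian copula across constituents; the latent mean is
#' moment-matched so each region's expected sample mean equals the configured
#' mean); the spectrum is the Beer-Lambert mixture of the component profiles
#' on top of the fixed dry-matter background, plus a baseline offset,
#' multiplied by a random scatter slope (1 + s),
#' plus a scatter offset and white noise. Fully reproducible given the
#' config seed.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{spectra} (\linkS4class{SpectraMatrix}) and
#'   \code{samples} (\linkS4class{SampleTable}; the five acids are fixed
#'   proportions of SFT).
#' @examples
#' sim <- simulateDataset(SyntheticConfig(nPerRegion = c(4, 3, 3), seed = 7))
#' sim$spectra
#' @export
simulateDataset <- function(config = SyntheticConfig()) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    n <- sum(config@nPerRegion)
    region <- rep(REGION_LEVELS, times = config@nPerRegion)
    profiles <- componentProfiles(config)
    rp <- config@regionParams
    set.seed(config@seed)
    ## fixed draw order: copula normals, baseline, slope, offset, noise
    Z <- matrix(rnorm(n * 4L), n, 4L) %*% chol(config@correlation)
    conc <- matrix(NA_real_, n, 4L, dimnames = list(NULL, CONSTITUENTS))
    for (r in REGION_LEVELS) {
        rows <- region == r
        for (k in seq_along(CONSTITUENTS)) {
            p <- rp[rp$region == r & rp$constituent == CONSTITUENTS[k], ]
            mAdj <- .matchedMean(p$mean, p$sd, p$min, p$max)
            v <- mAdj + p$sd * Z[rows, k]
            conc[rows, k] <- pmin(pmax(v, p$min), p$max)
        }
    }
    baseline <- rnorm(n, 0, config@baselineSd)
    slope <- rnorm(n, 0, config@scatterSlopeSd)
    offset <- rnorm(n, 0, config@scatterOffsetSd)
    p <- length(config@axis)
    noise <- matrix(rnorm(n * p, 0, config@noiseSd), n, p)
    mix <- conc %*% profiles
    bg <- backgroundSpectrum(config)
    spectraMat <- sweep(mix + baseline, 2L, bg, "+") * (1 + slope) +
        offset + noise
    ids <- paste0("S", seq_len(n))
    acids <- outer(conc[, "sft"], ACID_PROPORTIONS)
    tab <- data.frame(sample_id = ids, region = region,
                      psc = conc[, "psc"], wse = conc[, "wse"],
                      ase = conc[, "ase"], acids,
                      sft = conc[, "sft"], stringsAsFactors = FALSE)
    list(spectra = SpectraMatrix(spectraMat, config@axis, ids),
         samples = SampleTable(tab))
}

#' Inject gross spectral outliers
#'
#' Adds a smooth random broad artifact (a mixture of three wide Gaussian
#' bumps, normalized to unit peak) to the listed samples, scaled to
#' \code{magnitude} times the mean band amplitude of the input (the mean
#' over samples of the maximum absolute absorbance). All other rows are
#' returned bit-identical.
#'
#' @param spectra a \linkS4class{SpectraMatrix}.
#' @param ids sample ids to perturb (empty = no-op).
#' @param magnitude artifact size as a multiple of the mean band amplitude,
#'   > 0.
#' @param seed integer seed for the artifact shapes.
#' @return the perturbed \linkS4class{SpectraMatrix}.
#' @export
injectOutliers <- function(spectra, ids, magnitude = 10, seed = 1L) {
    stopifnot(is(spectra, "SpectraMatrix"))
    if (!length(ids)) return(spectra)
    if (magnitude <= 0) stop("magnitude must be > 0")
    idx <- match(ids, sampleIds(spectra))
    if (anyNA(idx))
        stop(sprintf("unknown sample id(s): %s",
                     paste(ids[is.na(idx)], collapse = ", ")))
    ab <- absorbance(spectra)
    wn <- wavenumbers(spectra)
    scale <- magnitude * mean(apply(abs(ab), 1L, max))
    set.seed(seed)
    for (i in idx) {
        centers <- runif(3L, min(wn), max(wn))
        widths <- runif(3L, diff(range(wn)) / 10, diff(range(wn)) / 4)
        amps <- runif(3L, 0.3, 1) * sample(c(-1, 1), 3L, replace = TRUE)
        art <- rowSums(vapply(1:3, function(b)
            amps[b] * exp(-(wn - centers[b])^2 / (2 * widths[b]^2)),
            numeric(length(wn))))
        ab[i, ] <- ab[i, ] + art / max(abs(art)) * scale
    }
    SpectraMatrix(ab, wn, sampleIds(spectra))
}
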