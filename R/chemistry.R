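## Wet-lab reference arithmetic: gravimetric extract content, standard-curve
## quantification (phenol-sulfuric polysaccharide assay, HPLC calibration of
## the triterpene acids), detection limits, and region summary tables.

#' Gravimetric extract content
#'
#' Water- or ethanol-soluble extract content of a powder sample:
#' \code{(W1 - W0) * aliquotFactor / S * 100} percent, where the aliquot
#' factor accounts for evaporating a fraction of the extraction volume
#' (2 when 25 of 50 mL are taken).
#'
#' @param S sample mass (g), > 0.
#' @param W0 evaporating-dish mass (g).
#' @param W1 dish plus residue mass after drying (g), >= W0.
#' @param aliquotFactor unitless multiplier (default 2).
#' @return extract content in percent.
#' @examples
#' extractContent(S = 2.5, W0 = 50.000, W1 = 50.250)  # 20
#' @export
extractContent <- function(S, W0, W1, aliquotFactor = 2) {
    if (any(S <= 0)) stop("sample mass S must be > 0")
    if (any(W1 < W0)) stop("W1 must be >= W0")
    (W1 - W0) * aliquotFactor / S * 100
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of instrument response on analyte concentration;
#' r2 is the squared Pearson correlation and the residual standard deviation
#' uses the n - 2 denominator.
#'
#' @param concentrations numeric, >= 3 distinct values.
#' @param responses numeric of equal length.
#' @return a \linkS4class{StandardCurve} (LOD/LOQ unset; see
#'   \code{\link{lodLoq}}).
#' @examples
#' fitStandardCurve(1:4, 2 * (1:4) + 1)  # slope 2, intercept 1, r2 = 1
#' @export
fitStandardCurve <- function(concentrations, responses) {
    if (length(concentrations) != length(responses))
        stop("concentrations and responses must have equal length")
    if (length(concentrations) < 3L)
        stop("at least 3 calibration points are required")
    if (var(concentrations) == 0)
        stop("concentrations are all equal: cannot fit a line")
    fit <- lm(responses ~ concentrations)
    res <- residuals(fit)
    r2 <- if (var(responses) == 0) 1
          else suppressWarnings(stats::cor(concentrations, responses))^2
    new("StandardCurve", slope = unname(coef(fit)[2]),
        intercept = unname(coef(fit)[1]), r2 = r2,
        residualSd = sqrt(sum(res^2) / (length(res) - 2L)),
        lod = NA_real_, loq = NA_real_)
}

#' Concentration from instrument response
#'
#' Inverts the standard curve: \code{(response - intercept) / slope} times
#' the dilution factor.
#'
#' @param curve a \linkS4class{StandardCurve} with nonzero slope.
#' @param response measured response(s).
#' @param dilutionFactor unitless multiplier (default 1).
#' @return concentration(s) in the curve's concentration units.
#' @export
concentrationFromResponse <- function(curve, response, dilutionFactor = 1) {
    stopifnot(is(curve, "StandardCurve"))
    if (curve@slope == 0) stop("curve slope is zero: cannot invert")
    (response - curve@intercept) / curve@slope * dilutionFactor
}

#' Detection and quantification limits of a standard curve
#'
#' ICH convention based on the calibration residual standard deviation:
#' LOD = 3.3 sigma / slope, LOQ = 10 sigma / slope.
#'
#' @param curve a \linkS4class{StandardCurve} with slope > 0.
#' @return the curve with \code{lod} and \code{loq} filled in (concentration
#'   units).
#' @export
lodLoq <- function(curve) {
    stopifnot(is(curve, "StandardCurve"))
    if (curve@slope <= 0) stop("LOD/LOQ require a positive slope")
    curve@lod <- 3.3 * curve@residualSd / curve@slope
    curve@loq <- 10 * curve@residualSd / curve@slope
    validObject(curve)
    curve
}

#' Per-region summary of a constituent
#'
#' Count, minimum, maximum, arithmetic mean and sample (n-1) standard
#' deviation per region; display values rounded to two decimals (full
#' precision kept in the \code{*_full} columns).
#'
#' @param values numeric per-sample concentrations (missing values dropped
#'   per region).
#' @param regionLabels region labels of equal length.
#' @return data.frame: region, n, min, max, mean, sd (2-decimal display) and
#'   mean_full, sd_full. Regions with one sample report sd as NA; regions
#'   empty after filtering are omitted with a warning.
#' @export
regionSummary <- function(values, regionLabels) {
    if (length(values) != length(regionLabels))
        stop("values and regionLabels must have equal length")
    regionLabels <- as.character(regionLabels)
    regs <- REGION_LEVELS[REGION_LEVELS %in% regionLabels]
    rows <- list()
    for (r in regs) {
        v <- values[regionLabels == r]
        v <- v[!is.na(v)]
        if (!length(v)) {
            warning(sprintf("region %s empty after filtering; omitted", r))
            next
        }
        s <- if (length(v) > 1L) sd(v) else NA_real_
        rows[[r]] <- data.frame(region = r, n = length(v),
                                min = round(min(v), 2), max = round(max(v), 2),
                                mean = round(mean(v), 2), sd = round(s, 2),
                                mean_full = mean(v), sd_full = s,
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
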