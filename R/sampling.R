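## Sample management: Kennard-Stone calibration/validation splitting and
## Monte-Carlo cross-validation (MCCV) outlier elimination.

#' Kennard-Stone calibration/validation split
#'
#' Deterministic max-min-distance selection of a representative calibration
#' subset: the first two calibration members are the pair at maximal pairwise
#' distance; each subsequent member maximizes its minimum distance to the
#' already-selected set. Remaining samples form the validation group. Ties
#' are broken by lowest sample index. The algorithm is unsupervised: only the
#' spectra are used.
#'
#' @param spectra a \linkS4class{SpectraMatrix} (finite, n >= 3).
#' @param ratio target calibration:validation proportion; 4 means 4:1, giving
#'   \code{round(n * ratio / (ratio + 1))} calibration samples.
#' @param distance distance metric, currently \code{"euclidean"}.
#' @return a \linkS4class{SplitResult}.
#' @examples
#' sm <- SpectraMatrix(cbind(0:9, 0:9), c(5000, 5008), paste0("S", 0:9))
#' kennardStoneSplit(sm, ratio = 4)
#' @export
kennardStoneSplit <- function(spectra, ratio = 4, distance = "euclidean") {
    stopifnot(is(spectra, "SpectraMatrix"))
    distance <- match.arg(distance, "euclidean")
    n <- nSamples(spectra)
    if (n < 3L) stop("Kennard-Stone needs at least 3 samples")
    nCal <- round(n * ratio / (ratio + 1))
    if (nCal < 2L) stop(sprintf("requested calibration size %d < 2", nCal))
    D <- as.matrix(stats::dist(absorbance(spectra), method = distance))
    ## seed pair: maximal pairwise distance, ties -> lowest (i, j) indices
    upper <- D
    upper[lower.tri(upper, diag = TRUE)] <- -Inf
    best <- which(upper == max(upper), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    sel <- sort(c(best[1], best[2]))
    mind <- pmin(D[, sel[1]], D[, sel[2]])
    while (length(sel) < nCal) {
        mind[sel] <- -Inf
        nxt <- which.max(mind)   # which.max returns the first (lowest index) tie
        sel <- c(sel, nxt)
        mind <- pmin(mind, D[, nxt])
    }
    ids <- sampleIds(spectra)
    new("SplitResult", calibrationIds = ids[sel],
        validationIds = ids[-sel], ratio = ratio)
}

#' Monte-Carlo cross-validation outlier detection
#'
#' Repeatedly (n_rounds times) draws a random calibration subset, fits an
#' inner PLSR model on it and records absolute prediction residuals for the
#' held-out samples. A sample is flagged when its residual mean (or residual
#' standard deviation) exceeds a \code{mean + meanK * sd} (resp. \code{sdK})
#' threshold over all samples, computed on the log scale -- residual
#' magnitudes are positive with multiplicative dispersion, so log-scale
#' thresholds separate gross outliers without flagging the benign
#' high-concentration tail. Thresholds are re-estimated on the unflagged
#' population until a fixed point (sequential rejection), preventing one
#' extreme outlier from masking others.
#'
#' @param spectra a \linkS4class{SpectraMatrix} (pretreat beforehand if
#'   desired).
#' @param y numeric reference values, one per sample, no missing values.
#' @param nRounds number of Monte-Carlo rounds (>= 100 recommended).
#' @param calFraction fraction of samples in each random calibration subset.
#' @param nFactors latent variables of the inner PLSR model.
#' @param meanK,sdK flag thresholds in SD units on the residual-mean /
#'   residual-SD plane.
#' @param seed integer seed; the procedure is fully reproducible given it.
#' @return an \linkS4class{OutlierReport}.
#' @seealso \code{\link{fitPLSR}}
#' @export
detectOutliersMCCV <- function(spectra, y, nRounds = 500L, calFraction = 0.8,
                               nFactors = 5L, meanK = 3, sdK = 3,
                               seed = 1L) {
    stopifnot(is(spectra, "SpectraMatrix"))
    n <- nSamples(spectra)
    if (length(y) != n) stop("y must have one value per sample")
    if (anyNA(y)) stop("y must be present for all samples")
    if (nRounds < 1L) stop("nRounds must be >= 1")
    if (calFraction <= 0 || calFraction >= 1)
        stop("calFraction must be in (0, 1)")
    nCal <- max(2L, round(calFraction * n))
    if (nCal >= n) stop("calFraction leaves no held-out samples")
    if (nFactors > min(nCal - 1L, ncol(absorbance(spectra))))
        stop("nFactors exceeds the rank bound of the calibration subsets")
    ab <- absorbance(spectra)
    resids <- vector("list", n)           # collected |residuals| per sample
    for (i in seq_len(n)) resids[[i]] <- numeric(0)
    set.seed(seed)
    for (r in seq_len(nRounds)) {
        cal <- sample.int(n, nCal)
        out <- setdiff(seq_len(n), cal)
        fit <- .nipalsPLS1(ab[cal, , drop = FALSE], y[cal], nFactors)
        pred <- .nipalsPredict(fit, ab[out, , drop = FALSE])
        err <- abs(pred - y[out])
        for (k in seq_along(out))
            resids[[out[k]]] <- c(resids[[out[k]]], err[k])
    }
    nHeld <- lengths(resids)
    if (any(nHeld == 0L))
        stop(sprintf("sample(s) never held out across %d rounds (%s); increase nRounds",
                     nRounds,
                     paste(sampleIds(spectra)[nHeld == 0], collapse = ", ")))
    rm_ <- vapply(resids, mean, numeric(1))
    rs_ <- vapply(resids, function(v) if (length(v) > 1L) sd(v) else 0,
                  numeric(1))
    ## Thresholds act on the log scale: residual magnitudes are positive
    ## with multiplicative dispersion, so the benign high-concentration tail
    ## is compressed while gross outliers stay orders of magnitude out.
    ## Sequential rejection (thresholds recomputed on the not-yet-flagged
    ## population until a fixed point) stops one extreme outlier from
    ## inflating the SD and masking the others.
    lm_ <- log(pmax(rm_, .Machine$double.xmin))
    ls_ <- log(pmax(rs_, .Machine$double.xmin))
    flag <- rep(FALSE, n)
    repeat {
        keep <- !flag
        thrM <- mean(lm_[keep]) + meanK * sd(lm_[keep])
        thrS <- mean(ls_[keep]) + sdK * sd(ls_[keep])
        newflag <- flag | lm_ > thrM | ls_ > thrS
        if (identical(newflag, flag)) break
        flag <- newflag
    }
    stats <- data.frame(sample_id = sampleIds(spectra),
                        residual_mean = rm_, residual_sd = rs_,
                        n_heldout = nHeld, flagged = flag,
                        stringsAsFactors = FALSE)
    new("OutlierReport", stats = stats,
        flaggedIds = stats$sample_id[flag],
        params = list(n_rounds = as.integer(nRounds),
                      cal_fraction = calFraction,
                      n_factors = as.integer(nFactors),
                      mean_k = meanK, sd_k = sdK, seed = as.integer(seed)))
}

#' Write a split or outlier report as delimited text
#'
#' Serializes with a \code{#}-prefixed header comment recording the
#' parameters (and seed, for MCCV reports).
#'
#' @param x a \linkS4class{SplitResult} or \linkS4class{OutlierReport}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(x, path) {
    if (is(x, "SplitResult")) {
        hdr <- sprintf("# kennard-stone split, ratio %g:1, %d calibration / %d validation",
                       x@ratio, length(x@calibrationIds),
                       length(x@validationIds))
        body <- c("sample_id,set",
                  paste(x@calibrationIds, "calibration", sep = ","),
                  paste(x@validationIds, "validation", sep = ","))
    } else if (is(x, "OutlierReport")) {
        p <- x@params
        hdr <- sprintf("# mccv outlier report: n_rounds=%d cal_fraction=%g n_factors=%d mean_k=%g sd_k=%g seed=%d",
                       p$n_rounds, p$cal_fraction, p$n_factors, p$mean_k,
                       p$sd_k, p$seed)
        body <- c("sample_id,residual_mean,residual_sd,n_heldout,flagged",
                  sprintf("%s,%.17g,%.17g,%d,%s", x@stats$sample_id,
                          x@stats$residual_mean, x@stats$residual_sd,
                          x@stats$n_heldout, x@stats$flagged))
    } else stop("writeReport handles SplitResult and OutlierReport objects")
    writeLines(c(hdr, body), path)
    invisible(path)
}
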