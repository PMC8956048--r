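## Random-forest discrimination of the three cultivation regions from
## pretreated spectra, with per-sample reporting.

#' Fit a random-forest region classifier
#'
#' Grows a bagged ensemble of classification trees on pretreated spectra:
#' each tree is trained on a bootstrap resample (with replacement, size n)
#' using Gini-impurity splits over a random subset of columns at each node
#' (the canonical Breiman forest, via the \pkg{randomForest} package). The
#' pretreatment state is fitted on the training spectra and stored, so
#' prediction transforms new spectra identically. Deterministic given
#' \code{seed}.
#'
#' @param spectra training \linkS4class{SpectraMatrix}.
#' @param labels region labels (character or factor with levels among
#'   YN/XQ/DBM); at least two classes must be present.
#' @param nTrees number of trees (default 500).
#' @param featuresPerSplit columns tried at each split; default
#'   \code{floor(sqrt(n_wavenumbers))}.
#' @param minLeaf minimum terminal-node size (default 1).
#' @param pretreatment \linkS4class{PretreatmentSpec} or name applied to the
#'   spectra before the forest (default SNV).
#' @param seed integer training seed.
#' @return a \linkS4class{RegionForest}.
#' @export
fitRegionForest <- function(spectra, labels, nTrees = 500L,
                            featuresPerSplit = NULL, minLeaf = 1L,
                            pretreatment = "SNV", seed = 1L) {
    stopifnot(is(spectra, "SpectraMatrix"))
    labels <- as.character(labels)
    if (length(labels) != nSamples(spectra))
        stop("one label per sample is required")
    bad <- setdiff(unique(labels), REGION_LEVELS)
    if (length(bad))
        stop(sprintf("unknown region label(s): %s", paste(bad, collapse = ", ")))
    present <- REGION_LEVELS[REGION_LEVELS %in% labels]
    if (length(present) < 2L)
        stop("at least two classes must be present")
    if (nTrees < 1L) stop("nTrees must be >= 1")
    p <- length(wavenumbers(spectra))
    if (is.null(featuresPerSplit)) featuresPerSplit <- floor(sqrt(p))
    if (featuresPerSplit > p)
        stop(sprintf("featuresPerSplit %d exceeds %d spectral columns",
                     featuresPerSplit, p))
    if (is.character(pretreatment))
        pretreatment <- PretreatmentSpec(pretreatment)
    pre <- applyPretreatment(spectra, pretreatment)
    X <- absorbance(pre$spectra)
    colnames(X) <- paste0("wn", seq_len(ncol(X)))
    yf <- factor(labels, levels = present)
    set.seed(seed)
    rf <- randomForest::randomForest(x = X, y = yf, ntree = as.integer(nTrees),
                                     mtry = as.integer(featuresPerSplit),
                                     nodesize = as.integer(minLeaf))
    new("RegionForest", forest = rf, pretreatment = pretreatment,
        pretreatmentState = pre$state, wavenumbers = wavenumbers(spectra),
        classLevels = present, seed = as.integer(seed))
}

#' Predict cultivation regions
#'
#' Majority vote across the trees; exact vote ties are broken by the
#' documented class order YN < XQ < DBM.
#'
#' @param object a \linkS4class{RegionForest}.
#' @param newdata a \linkS4class{SpectraMatrix} on the training axis.
#' @param ... unused.
#' @return factor of predicted regions, named by sample id.
#' @export
setMethod("predict", "RegionForest", function(object, newdata, ...) {
    stopifnot(is(newdata, "SpectraMatrix"))
    if (length(wavenumbers(newdata)) != length(object@wavenumbers) ||
        max(abs(wavenumbers(newdata) - object@wavenumbers)) > 1e-9)
        stop("wavenumber axis of newdata does not match the training axis")
    pre <- applyPretreatment(newdata, object@pretreatment,
                             state = if (length(object@pretreatmentState))
                                         object@pretreatmentState else NULL)
    X <- absorbance(pre$spectra)
    colnames(X) <- paste0("wn", seq_len(ncol(X)))
    votes <- predict(object@forest, X, type = "vote", norm.votes = FALSE)
    out <- .voteLabels(votes, object@classLevels)
    names(out) <- sampleIds(newdata)
    out
})

## Majority vote over a samples-by-classes vote-count matrix; exact ties go
## to the earliest label in `levels` (the documented YN < XQ < DBM order).
.voteLabels <- function(votes, levels) {
    pick <- apply(votes[, levels, drop = FALSE], 1L,
                  function(v) levels[which.max(v)])
    factor(pick, levels = levels)
}

#' Per-sample classification report
#'
#' Tabulates reference against predicted labels per sample, the confusion
#' matrix and the overall accuracy (fraction correct; shown as a percentage
#' to two decimal places).
#'
#' @param reference,predicted label vectors of equal length (>= 1).
#' @param ids optional sample identifiers (default S1..Sn).
#' @return a \linkS4class{ClassificationReport}.
#' @examples
#' classificationReport(c("YN", "XQ"), c("YN", "DBM"), c("S1", "S2"))
#' @export
classificationReport <- function(reference, predicted, ids = NULL) {
    reference <- as.character(reference)
    predicted <- as.character(predicted)
    if (length(reference) != length(predicted))
        stop("reference and predicted must have equal length")
    n <- length(reference)
    if (n < 1L) stop("at least one sample is required")
    if (is.null(ids)) ids <- paste0("S", seq_len(n))
    levs <- union(REGION_LEVELS, union(reference, predicted))
    levs <- levs[levs %in% c(reference, predicted) | levs %in% REGION_LEVELS]
    conf <- table(reference = factor(reference, levels = levs),
                  predicted = factor(predicted, levels = levs))
    tab <- data.frame(sample_id = as.character(ids), reference = reference,
                      predicted = predicted,
                      correct = reference == predicted,
                      stringsAsFactors = FALSE)
    new("ClassificationReport", table = tab,
        confusion = unclass(conf), accuracy = sum(tab$correct) / n)
}

#' Write a classification report as delimited text
#'
#' Columns Sample, Reference, Predicted, Result; the accuracy is recorded in
#' a header comment as a percentage with two decimals.
#'
#' @param report a \linkS4class{ClassificationReport}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeClassificationReport <- function(report, path) {
    stopifnot(is(report, "ClassificationReport"))
    t <- report@table
    writeLines(c(sprintf("# accuracy: %.2f%% (%d/%d)", 100 * report@accuracy,
                         sum(t$correct), nrow(t)),
                 "sample,reference,predicted,result",
                 sprintf("%s,%s,%s,%s", t$sample_id, t$reference, t$predicted,
                         ifelse(t$correct, "Correct", "False"))), path)
    invisible(path)
}
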