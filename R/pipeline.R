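## End-to-end orchestration: input (or simulation) -> replicate averaging ->
## MCCV outlier removal -> Kennard-Stone split -> per-response pretreatment
## grid + PLSR models -> random-forest region classification -> reports.

RESPONSES <- c("psc", "wse", "ase", "sft")

#' Run the full chemometrics pipeline
#'
#' Executes the study workflow in fixed stage order: (1) load or simulate the
#' dataset, (2) optionally average replicate scans, (3) flag and remove
#' outliers by Monte-Carlo cross-validation (a sample flagged for any
#' response is excluded globally), (4) split calibration/validation by
#' Kennard-Stone on the spectra, (5) for each response run the pretreatment
#' grid and keep the selected model, (6) classify regions with a random
#' forest on the same split, (7) optionally write the report files. The
#' single \code{seed} fans out to fixed per-stage offsets (simulation
#' \code{seed}, MCCV \code{seed + 1000}, factor-selection CV
#' \code{seed + 2000}, forest \code{seed + 3000}), so disabling one stage
#' does not shift another's random stream. Identical inputs and seed give
#' identical manifests.
#'
#' @param spectra,samples a \linkS4class{SpectraMatrix} and matching
#'   \linkS4class{SampleTable}; supply either these or \code{config}.
#' @param config a \linkS4class{SyntheticConfig} to simulate from (its seed is
#'   overridden by \code{seed}).
#' @param replicateOf optional sample-to-specimen map for
#'   \code{\link{averageReplicates}}.
#' @param responses responses to model (default psc, wse, ase, sft).
#' @param methods pretreatment candidates for the grid (default all seven).
#' @param removeOutliers run the MCCV outlier stage (default TRUE).
#' @param mccv list of MCCV parameters (nRounds, calFraction, nFactors,
#'   meanK, sdK) overriding the defaults of
#'   \code{\link{detectOutliersMCCV}}.
#' @param splitRatio Kennard-Stone calibration:validation ratio (default 4).
#' @param maxFactors candidate ceiling for factor selection.
#' @param classifierPretreatment pretreatment fed to the forest (default SNV).
#' @param nTrees forest size.
#' @param outDir optional output directory for report files.
#' @param seed global integer seed.
#' @return the run manifest: a list with sample accounting (\code{nInput},
#'   \code{flagged}, \code{nKept}), the split, the per-response
#'   \code{regression} summary table, full \code{grids}, fitted
#'   \code{models}, the \code{classification} report, \code{seeds},
#'   and \code{files} written (if any).
#' @examples
#' \donttest{
#' man <- runPipeline(config = SyntheticConfig(), removeOutliers = FALSE,
#'                    seed = 1)
#' man$regression
#' }
#' @export
runPipeline <- function(spectra = NULL, samples = NULL, config = NULL,
                        replicateOf = NULL, responses = RESPONSES,
                        methods = PRETREATMENT_NAMES, removeOutliers = TRUE,
                        mccv = list(), splitRatio = 4, maxFactors = 15L,
                        classifierPretreatment = "SNV", nTrees = 500L,
                        outDir = NULL, seed = 1L) {
    hasData <- !is.null(spectra) || !is.null(samples)
    if (hasData == !is.null(config))
        stop("supply exactly one of (spectra + samples) or config")
    seed <- as.integer(seed)
    seeds <- list(simulation = seed, mccv = seed + 1000L, cv = seed + 2000L,
                  forest = seed + 3000L)
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    if (!is.null(config)) {
        cfg <- config
        cfg@seed <- seeds$simulation
        sim <- stage("simulate", simulateDataset(cfg))
        spectra <- sim$spectra
        samples <- sim$samples
    }
    stopifnot(is(spectra, "SpectraMatrix"), is(samples, "SampleTable"))
    if (!is.null(replicateOf))
        spectra <- stage("average-replicates",
                         averageReplicates(spectra, replicateOf))
    if (!setequal(sampleIds(spectra), sampleIds(samples)))
        stop("spectra and sample table cover different sample ids")
    samples <- samples[sampleIds(spectra)]
    nInput <- nSamples(spectra)
    chem <- chemistry(samples)
    missing <- setdiff(responses, names(chem))
    if (length(missing))
        stop(sprintf("unknown response(s): %s", paste(missing, collapse = ", ")))

    flagged <- character(0)
    outlierReports <- list()
    if (removeOutliers) {
        args <- utils::modifyList(list(nRounds = 500L, calFraction = 0.8,
                                       nFactors = 5L, meanK = 3, sdK = 3),
                                  mccv)
        for (resp in responses) {
            rep_ <- stage(paste0("outliers-", resp),
                          detectOutliersMCCV(spectra, chem[[resp]],
                                             nRounds = args$nRounds,
                                             calFraction = args$calFraction,
                                             nFactors = args$nFactors,
                                             meanK = args$meanK,
                                             sdK = args$sdK,
                                             seed = seeds$mccv))
            outlierReports[[resp]] <- rep_
            flagged <- union(flagged, flaggedIds(rep_))
        }
        if (length(flagged)) {
            keep <- setdiff(sampleIds(spectra), flagged)
            spectra <- spectra[keep, ]
            samples <- samples[keep]
            chem <- chemistry(samples)
        }
    }

    split <- stage("split", kennardStoneSplit(spectra, ratio = splitRatio))

    grids <- list(); models <- list(); rows <- list()
    for (resp in responses) {
        g <- stage(paste0("grid-", resp),
                   pretreatmentGrid(spectra, chem[[resp]], split,
                                    methods = methods,
                                    maxFactors = maxFactors,
                                    cvSeed = seeds$cv, response = resp))
        grids[[resp]] <- g$grid
        models[[resp]] <- g$models[[g$selected]]
        sel <- g$grid[g$grid$method == g$selected, ]
        rows[[resp]] <- cbind(data.frame(response = resp,
                                         stringsAsFactors = FALSE), sel)
    }
    regression <- do.call(rbind, rows)
    rownames(regression) <- NULL

    ids <- sampleIds(spectra)
    calIdx <- match(calibrationIds(split), ids)
    valIdx <- match(validationIds(split), ids)
    forest <- stage("classify",
                    fitRegionForest(spectra[calIdx, ],
                                    regions(samples)[calIdx],
                                    nTrees = nTrees,
                                    pretreatment = classifierPretreatment,
                                    seed = seeds$forest))
    predVal <- predict(forest, spectra[valIdx, ])
    classification <- classificationReport(
        as.character(regions(samples)[valIdx]), as.character(predVal),
        ids = ids[valIdx])

    files <- character(0)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        wf <- function(fun, x, name) {
            path <- file.path(outDir, name)
            fun(x, path)
            path
        }
        files <- c(files, wf(writeReport, split, "split.csv"))
        for (resp in names(outlierReports))
            files <- c(files, wf(writeReport, outlierReports[[resp]],
                                 sprintf("outliers_%s.csv", resp)))
        for (resp in responses)
            files <- c(files,
                       wf(writeGrid,
                          list(grid = grids[[resp]],
                               selected = regression$method[
                                   regression$response == resp]),
                          sprintf("grid_%s.csv", resp)))
        files <- c(files, wf(writeClassificationReport, classification,
                             "classification.csv"))
        manifestPath <- file.path(outDir, "manifest.txt")
        writeLines(c(sprintf("poriaNIR %s",
                             as.character(utils::packageVersion("poriaNIR"))),
                     sprintf("seed: %d", seed),
                     sprintf("n_input: %d", nInput),
                     sprintf("flagged: %s",
                             if (length(flagged))
                                 paste(flagged, collapse = ",") else "-"),
                     sprintf("n_kept: %d", nSamples(spectra)),
                     sprintf("split: %d/%d", length(calibrationIds(split)),
                             length(validationIds(split))),
                     sprintf("classification_accuracy: %.4f",
                             accuracy(classification)),
                     sprintf("regression: %s=%s(RMSEP %.4g)",
                             regression$response, regression$method,
                             regression$rmsep)),
                   manifestPath)
        files <- c(files, manifestPath)
    }

    list(nInput = nInput, flagged = flagged, nKept = nSamples(spectra),
         split = split, outlierReports = outlierReports,
         regression = regression, grids = grids, models = models,
         forest = forest, classification = classification, seeds = seeds,
         files = files)
}
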