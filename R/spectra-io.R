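## Reading, writing and replicate handling for spectra and sample metadata.
##
## Native on-disk format is a delimited matrix: header "sample_id,<wn1>,...",
## one row per sample. JCAMP-DX is supported read-only for single spectra
## (XYDATA with AFFN numbers).

#' Read spectra from disk
#'
#' @param path file path.
#' @param dialect \code{"matrix-csv"} (default): comma-delimited, header
#'   \code{sample_id,<wn1>,<wn2>,...}, one sample per row; or
#'   \code{"jcamp-dx"}: a single-spectrum JCAMP-DX file
#'   (\code{##XYDATA=(X++(Y..Y))}, AFFN numerics).
#' @return a \linkS4class{SpectraMatrix}; wavenumbers are re-sorted ascending
#'   with columns permuted consistently, whatever the file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeSpectra(SpectraMatrix(matrix(1:6 / 2, 2, 3), c(4000, 4008, 4016)), f)
#' readSpectra(f)
#' @seealso \code{\link{writeSpectra}}
#' @export
readSpectra <- function(path, dialect = c("matrix-csv", "jcamp-dx")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    if (dialect == "jcamp-dx") return(.readJcamp(path))
    header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
    if (length(header) < 2L || header[1] != "sample_id")
        stop(sprintf("parse error in %s, line 1: expected header 'sample_id,<wn>,...'",
                     path))
    wn <- suppressWarnings(as.numeric(header[-1]))
    if (anyNA(wn))
        stop(sprintf("parse error in %s, line 1: non-numeric wavenumber '%s'",
                     path, header[-1][which(is.na(wn))[1]]))
    d <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (ncol(d) != length(wn) + 1L)
        stop(sprintf("parse error in %s: ragged rows", path))
    if (anyDuplicated(d$sample_id))
        stop(sprintf("duplicate sample id(s) in %s: %s", path,
                     paste(unique(d$sample_id[duplicated(d$sample_id)]),
                           collapse = ", ")))
    m <- suppressWarnings(
        matrix(as.numeric(as.matrix(d[, -1, drop = FALSE])), nrow = nrow(d)))
    if (anyNA(m)) {
        bad <- which(is.na(m), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric or missing absorbance in %s: sample '%s', wavenumber %g",
                     path, d$sample_id[bad[1]], wn[bad[2]]))
    }
    SpectraMatrix(m, wn, d$sample_id)
}

## Minimal JCAMP-DX reader: single spectrum, XYDATA=(X++(Y..Y)), AFFN.
.readJcamp <- function(path) {
    lines <- readLines(path)
    lab <- function(name) {
        hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE)
        if (!length(hit)) return(NA_character_)
        sub(paste0("^##", name, "=\\s*"), "", lines[hit[1]], ignore.case = TRUE)
    }
    start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
    if (!length(start))
        stop(sprintf("parse error in %s: no ##XYDATA record", path))
    form <- toupper(gsub("\\s", "", sub("^##XYDATA=", "", lines[start[1]],
                                        ignore.case = TRUE)))
    if (form != "(X++(Y..Y))")
        stop(sprintf("parse error in %s, line %d: unsupported XYDATA form '%s'",
                     path, start[1], form))
    xfac <- as.numeric(lab("XFACTOR")); if (is.na(xfac)) xfac <- 1
    yfac <- as.numeric(lab("YFACTOR")); if (is.na(yfac)) yfac <- 1
    title <- lab("TITLE"); if (is.na(title)) title <- "jcamp"
    end <- grep("^##", lines)
    end <- end[end > start[1]]
    stop_at <- if (length(end)) min(end) - 1L else length(lines)
    body <- lines[(start[1] + 1L):stop_at]
    x <- numeric(); y <- numeric()
    for (k in seq_along(body)) {
        if (!nzchar(trimws(body[k]))) next
        tok <- strsplit(trimws(body[k]), "[[:space:],]+")[[1]]
        num <- suppressWarnings(as.numeric(tok))
        if (anyNA(num))
            stop(sprintf("parse error in %s, line %d: non-numeric token '%s'",
                         path, start[1] + k, tok[which(is.na(num))[1]]))
        if (length(num) < 2L)
            stop(sprintf("parse error in %s, line %d: X with no Y values",
                         path, start[1] + k))
        xs <- num[1]
        ys <- num[-1]
        ## successive Y values advance X by the implied even step
        step <- .jcampStep(lines, start[1], length(ys))
        x <- c(x, xs + step * (seq_along(ys) - 1L))
        y <- c(y, ys)
    }
    SpectraMatrix(matrix(y * yfac, nrow = 1L), x * xfac, title)
}

.jcampStep <- function(lines, start, nper) {
    getnum <- function(name) {
        hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE)
        if (!length(hit)) return(NA_real_)
        as.numeric(sub(paste0("^##", name, "=\\s*"), "", lines[hit[1]],
                       ignore.case = TRUE))
    }
    first <- getnum("FIRSTX"); last <- getnum("LASTX"); np <- getnum("NPOINTS")
    if (!is.na(first) && !is.na(last) && !is.na(np) && np > 1)
        return((last - first) / (np - 1))
    if (nper <= 1L) return(0)
    stop("cannot infer JCAMP-DX X step: FIRSTX/LASTX/NPOINTS missing")
}

#' Write spectra as a delimited matrix
#'
#' Writes the native matrix-csv format at full double precision (17
#' significant digits), so write-then-read round-trips exactly.
#'
#' @param spectra a \linkS4class{SpectraMatrix}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpectra <- function(spectra, path) {
    stopifnot(is(spectra, "SpectraMatrix"))
    header <- paste(c("sample_id",
                      sprintf("%.17g", wavenumbers(spectra))), collapse = ",")
    ab <- absorbance(spectra)
    rows <- vapply(seq_len(nrow(ab)), function(i)
        paste(c(sampleIds(spectra)[i], sprintf("%.17g", ab[i, ])),
              collapse = ","), character(1))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Read a sample metadata table
#'
#' Comma-delimited with header naming at least \code{sample_id} and
#' \code{region}; the nine concentration columns (\code{psc, wse, ase, dtua,
#' paa, pac, dpa, dtra, sft}, mg/g) are optional and may contain missing
#' values. When all five triterpene acids are present and \code{sft} is
#' absent, \code{sft} is recomputed as their sum.
#'
#' @param path file path.
#' @return a validated \linkS4class{SampleTable}.
#' @seealso \code{\link{writeSampleTable}}
#' @export
readSampleTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    d <- utils::read.csv(path, check.names = TRUE,
                         colClasses = "character")
    names(d) <- tolower(names(d))
    for (cc in intersect(CHEM_COLUMNS, names(d))) {
        v <- suppressWarnings(as.numeric(d[[cc]]))
        bad <- !is.na(d[[cc]]) & nzchar(trimws(d[[cc]])) &
            toupper(trimws(d[[cc]])) != "NA" & is.na(v)
        if (any(bad))
            stop(sprintf("non-numeric value '%s' in column %s of %s",
                         d[[cc]][which(bad)[1]], cc, path))
        d[[cc]] <- v
    }
    SampleTable(d)
}

#' Write a sample metadata table
#'
#' @param samples a \linkS4class{SampleTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSampleTable <- function(samples, path) {
    stopifnot(is(samples, "SampleTable"))
    utils::write.csv(as.data.frame(samples), path, row.names = FALSE,
                     quote = FALSE)
    invisible(path)
}

#' Average replicate spectra
#'
#' Each specimen was scanned several times; the per-specimen spectrum used in
#' all downstream analysis is the arithmetic mean of its replicate scans.
#'
#' @param spectra a \linkS4class{SpectraMatrix} of replicate scans.
#' @param replicateOf named character vector or list mapping every sample id
#'   in \code{spectra} to its specimen id.
#' @return a \linkS4class{SpectraMatrix} with one row per specimen, ordered by
#'   first appearance of the specimen among the input samples.
#' @examples
#' sm <- SpectraMatrix(rbind(c(0, 0), c(2, 2), c(4, 4)), c(5000, 5008),
#'                     c("a1", "a2", "a3"))
#' averageReplicates(sm, c(a1 = "A", a2 = "A", a3 = "A"))
#' @export
averageReplicates <- function(spectra, replicateOf) {
    stopifnot(is(spectra, "SpectraMatrix"))
    replicateOf <- unlist(replicateOf)
    ids <- sampleIds(spectra)
    if (!all(ids %in% names(replicateOf)))
        stop(sprintf("no specimen mapping for sample(s): %s",
                     paste(setdiff(ids, names(replicateOf)), collapse = ", ")))
    spec <- as.character(replicateOf[ids])
    specimens <- unique(spec)
    ab <- absorbance(spectra)
    out <- matrix(0, length(specimens), ncol(ab))
    for (k in seq_along(specimens)) {
        rows <- which(spec == specimens[k])
        out[k, ] <- colMeans(ab[rows, , drop = FALSE])
    }
    SpectraMatrix(out, wavenumbers(spectra), specimens)
}

#' Convert between nanometers and wavenumbers
#'
#' Unit helper: wavenumber (cm-1) = 1e7 / wavelength (nm). The package itself
#' never converts axes; this exists for users comparing instrument ranges
#' quoted in different units.
#'
#' @param nm wavelength(s) in nanometers.
#' @param wavenumber wavenumber(s) in cm-1.
#' @return the converted values.
#' @export
nmToWavenumber <- function(nm) 1e7 / nm

#' @rdname nmToWavenumber
#' @export
wavenumberToNm <- function(wavenumber) 1e7 / wavenumber
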