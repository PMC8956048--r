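# Spectra and sample-table I/O, replicate averaging.

test_that("SpectraMatrix enforces its invariants and sorts the axis", {
    sm <- SpectraMatrix(matrix(1:6, 2, 3), c(4016, 4000, 4008))
    expect_equal(wavenumbers(sm), c(4000, 4008, 4016))
    # columns permuted along with the axis
    expect_equal(absorbance(sm)[, 3], c(1, 2), ignore_attr = TRUE)
    expect_error(SpectraMatrix(matrix(c(1, NA, 3, 4), 2, 2), c(1, 2)),
                 "finite")
    expect_error(SpectraMatrix(matrix(1:4, 2, 2), c(1, 2), c("a", "a")),
                 "duplicate")
    expect_error(SpectraMatrix(matrix(1:4, 2, 2), c(1, 1)), "ascending")
})

test_that("write-then-read round-trips at full stored precision", {
    sm <- tinySpectra(4, 9)
    f <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(sm, f)
    back <- readSpectra(f)
    expect_identical(absorbance(back), absorbance(sm))
    expect_identical(wavenumbers(back), wavenumbers(sm))
    expect_identical(sampleIds(back), sampleIds(sm))
})

test_that("loading is order-invariant over columns and rows", {
    sm <- tinySpectra(3, 5)
    f1 <- withr::local_tempfile(fileext = ".csv")
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(sm, f1)
    # rewrite with wavenumber columns descending and rows permuted
    lines <- readLines(f1)
    hdr <- strsplit(lines[1], ",")[[1]]
    perm <- c(1, 6:2)
    relines <- vapply(lines, function(l)
        paste(strsplit(l, ",")[[1]][perm], collapse = ","), character(1))
    dataRows <- relines[-1]
    writeLines(c(relines[1], dataRows[c(2, 3, 1)]), f2)
    back <- readSpectra(f2)
    expect_equal(wavenumbers(back), wavenumbers(sm))
    expect_equal(absorbance(back)[match(sampleIds(sm), sampleIds(back)), ],
                 absorbance(sm), ignore_attr = TRUE)
})

test_that("malformed spectra files are rejected with informative errors", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,4000,4008", "a,1.0,NA", "b,2.0,3.0"), f)
    expect_error(readSpectra(f), "absorbance.*'a'|sample 'a'")
    writeLines(c("sample_id,4000,4008", "a,1.0,2.0", "a,2.0,3.0"), f)
    expect_error(readSpectra(f), "duplicate")
    writeLines(c("wn,4000,4008", "a,1,2"), f)
    expect_error(readSpectra(f), "header")
    expect_error(readSpectra(file.path(tempdir(), "no-such-file.csv")),
                 "not found")
})

test_that("a minimal JCAMP-DX spectrum is read correctly", {
    f <- withr::local_tempfile(fileext = ".jdx")
    writeLines(c("##TITLE=demo", "##JCAMP-DX=4.24", "##XUNITS=1/CM",
                 "##FIRSTX=4000", "##LASTX=4040", "##NPOINTS=6",
                 "##XFACTOR=1", "##YFACTOR=0.5",
                 "##XYDATA=(X++(Y..Y))",
                 "4000 2 4 6", "4024 8 10 12", "##END="), f)
    sm <- readSpectra(f, dialect = "jcamp-dx")
    expect_equal(wavenumbers(sm), seq(4000, 4040, by = 8))
    expect_equal(as.vector(absorbance(sm)), seq(1, 6))
    expect_identical(sampleIds(sm), "demo")
})

test_that("sample tables recompute SFT and validate labels", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("sample_id,region,psc,wse,ase,dtua,paa,pac,dpa,dtra",
                 "a,YN,6.81,25.22,37.85,0.15,0.06,0.13,0.18,0.73"), f)
    st <- readSampleTable(f)
    expect_equal(chemistry(st)$sft, 1.25)
    writeLines(c("sample_id,region", "a,EU"), f)
    expect_error(readSampleTable(f), "YN, XQ, DBM")
    writeLines(c("sample_id,region", "a,YN", "a,XQ"), f)
    expect_error(readSampleTable(f), "duplicate")
    # chemistry entirely absent is fine, values stay missing
    writeLines(c("sample_id,region", "a,YN", "b,DBM"), f)
    st <- readSampleTable(f)
    expect_true(all(is.na(as.matrix(chemistry(st)))))
    expect_equal(as.character(regions(st)), c("YN", "DBM"))
})

test_that("sample table round-trips through write/read", {
    st <- smallSim(seed = 5)$samples
    f <- withr::local_tempfile(fileext = ".csv")
    writeSampleTable(st, f)
    back <- readSampleTable(f)
    expect_equal(chemistry(back)$psc, chemistry(st)$psc, tolerance = 1e-12)
    expect_identical(as.character(regions(back)), as.character(regions(st)))
})

test_that("replicate averaging is the arithmetic mean in first-appearance order", {
    wn <- c(5000, 5008)
    sm <- SpectraMatrix(rbind(c(0, 0), c(2, 2), c(4, 4)), wn,
                        c("a1", "a2", "a3"))
    avg <- averageReplicates(sm, c(a1 = "A", a2 = "A", a3 = "A"))
    expect_equal(as.vector(absorbance(avg)), c(2, 2))
    expect_identical(sampleIds(avg), "A")

    # 9 rows in 3 groups -> 3 rows; identical replicates average to themselves
    sm9 <- tinySpectra(9, 4, seed = 2)
    map <- setNames(rep(c("X", "Y", "Z"), each = 3), sampleIds(sm9))
    avg9 <- averageReplicates(sm9, map)
    expect_equal(nSamples(avg9), 3)
    expect_identical(sampleIds(avg9), c("X", "Y", "Z"))
    expect_equal(absorbance(avg9)[1, ],
                 colMeans(absorbance(sm9)[1:3, ]), ignore_attr = TRUE)

    # idempotent on groups of size one
    again <- averageReplicates(avg9, setNames(sampleIds(avg9),
                                              sampleIds(avg9)))
    expect_identical(absorbance(again), absorbance(avg9))

    expect_error(averageReplicates(sm9, map[-1]), "no specimen mapping")
})
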