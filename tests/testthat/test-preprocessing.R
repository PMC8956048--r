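# Pretreatment operators: SNV, MSC, Savitzky-Golay, named compositions.

test_that("SNV centers and scales every spectrum to mean 0, sd 1", {
    sm <- SpectraMatrix(matrix(c(1, 2, 3), 1), c(1, 2, 3), "a")
    expect_equal(as.vector(absorbance(snv(sm))), c(-1, 0, 1))

    rnd <- tinySpectra(6, 50, seed = 11)
    out <- absorbance(snv(rnd))
    expect_lt(max(abs(rowMeans(out))), 1e-10)
    expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-10)

    # idempotence
    expect_lt(max(abs(absorbance(snv(snv(rnd))) - out)), 1e-10)

    flat <- SpectraMatrix(rbind(c(1, 2), c(5, 5)), c(1, 2), c("ok", "bad"))
    expect_error(snv(flat), "bad")
})

test_that("MSC inverts affine scatter against its reference", {
    ref <- sin(seq(0, 3, length.out = 40)) + 2
    sm <- SpectraMatrix(rbind(ref, 2 * ref + 5), c(seq_len(40)),
                        c("same", "affine"))
    out <- msc(sm, reference = ref)
    expect_equal(absorbance(out$spectra)[1, ], ref, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(absorbance(out$spectra)[2, ], ref, ignore_attr = TRUE,
                 tolerance = 1e-12)

    # corrected rows re-regressed on the reference: slope 1, intercept 0
    rnd <- tinySpectra(5, 40, seed = 3)
    res <- msc(rnd)
    for (i in 1:5) {
        fit <- lm(absorbance(res$spectra)[i, ] ~ res$reference)
        expect_equal(unname(coef(fit)), c(0, 1), tolerance = 1e-8)
    }
    expect_error(msc(rnd, reference = 1:3), "length")
})

test_that("Savitzky-Golay is exact on polynomials and scales derivatives by the axis step", {
    x <- seq_len(41)
    poly2 <- 0.5 * x^2 - 3 * x + 7
    sm <- SpectraMatrix(matrix(poly2, 1), x, "p2")
    sm0 <- savitzkyGolay(sm, window = 9, polyorder = 2, deriv = 0)
    expect_lt(max(abs(absorbance(sm0) - poly2)), 1e-9)

    line <- SpectraMatrix(matrix(3 * x + 7, 1), x, "line")
    d1 <- savitzkyGolay(line, window = 7, polyorder = 2, deriv = 1)
    expect_lt(max(abs(absorbance(d1) - 3)), 1e-9)

    # physical-unit scaling: same line over a step-8 axis
    wn <- seq(4000, by = 8, length.out = 41)
    line8 <- SpectraMatrix(matrix(3 * wn + 7, 1), wn, "line8")
    d8 <- savitzkyGolay(line8, window = 7, polyorder = 2, deriv = 1)
    expect_lt(max(abs(absorbance(d8) - 3)), 1e-9)

    # analytic-derivative oracle on a cubic, interior points
    cub <- x^3 - 5 * x^2 + 2 * x
    dcub <- 3 * x^2 - 10 * x + 2
    d3 <- savitzkyGolay(SpectraMatrix(matrix(cub, 1), x, "c"),
                        window = 7, polyorder = 3, deriv = 1)
    interior <- 4:38
    expect_lt(max(abs(absorbance(d3)[interior] - dcub[interior])), 1e-8)

    # polyorder = window - 1 smoothing is the identity
    rnd <- tinySpectra(2, 30, seed = 4)
    ident <- savitzkyGolay(rnd, window = 5, polyorder = 4, deriv = 0)
    expect_lt(max(abs(absorbance(ident) - absorbance(rnd))), 1e-9)

    expect_error(savitzkyGolay(rnd, window = 6), "odd")
    expect_error(savitzkyGolay(rnd, window = 5, polyorder = 5), "polyorder")
    uneven <- SpectraMatrix(matrix(rnorm(10), 1), c(1:9, 11), "u")
    expect_error(savitzkyGolay(uneven, 5, 2, deriv = 1), "uniform")
    expect_silent(savitzkyGolay(uneven, 5, 2, deriv = 0))
})

test_that("named pretreatments dispatch, compose and freeze fitted state", {
    rnd <- tinySpectra(6, 40, seed = 9)
    expect_identical(
        absorbance(applyPretreatment(rnd, "Raw")$spectra), absorbance(rnd))

    spec <- PretreatmentSpec("Smooth+SNV", window = 7, polyorder = 2)
    comp <- applyPretreatment(rnd, spec)$spectra
    oracle <- snv(savitzkyGolay(rnd, 7, 2, deriv = 0))
    expect_equal(absorbance(comp), absorbance(oracle), tolerance = 1e-12)

    expect_error(PretreatmentSpec("detrend"), "Raw, MSC, SNV")

    # MSC state learned on calibration is reused verbatim on validation
    cal <- tinySpectra(5, 40, seed = 1)
    val <- tinySpectra(4, 40, seed = 2)
    fitted <- applyPretreatment(cal, "MSC")
    valOut <- applyPretreatment(val, "MSC", state = fitted$state)
    twoStep <- msc(val, reference = colMeans(absorbance(cal)))
    expect_equal(absorbance(valOut$spectra), absorbance(twoStep$spectra),
                 tolerance = 1e-12)
    # and differs from refitting on validation data alone
    refit <- applyPretreatment(val, "MSC")
    expect_false(isTRUE(all.equal(absorbance(valOut$spectra),
                                  absorbance(refit$spectra))))
})

test_that("all operators preserve shape and are row-local under permutation", {
    rnd <- tinySpectra(7, 45, seed = 21)
    perm <- c(3, 1, 7, 5, 2, 6, 4)
    for (name in c("Raw", "MSC", "SNV", "Smooth", "Smooth+SNV", "Smooth+MSC",
                   "SG-1D")) {
        out <- applyPretreatment(rnd, PretreatmentSpec(name, window = 7))
        expect_identical(dim(absorbance(out$spectra)), dim(absorbance(rnd)))
        # permuting samples permutes outputs identically (state from the
        # unpermuted data, so MSC sees the same reference)
        permOut <- applyPretreatment(rnd[perm, ],
                                     PretreatmentSpec(name, window = 7),
                                     state = out$state)
        expect_equal(absorbance(permOut$spectra),
                     absorbance(out$spectra)[perm, ], ignore_attr = TRUE,
                     tolerance = 1e-12)
    }
})
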