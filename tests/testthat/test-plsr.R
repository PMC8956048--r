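# NIPALS PLSR, factor selection, evaluation statistics, grid search.

test_that("one latent variable suffices when a single direction carries y", {
    # the informative column is orthogonal (after centering) to the rest,
    # so the first covariance-direction weight isolates it exactly
    set.seed(31)
    B <- scale(matrix(rnorm(12 * 5), 12, 5), scale = FALSE)
    a <- unname(residuals(lm(rnorm(12) ~ B)))
    X <- cbind(B[, 1:3], a, B[, 4:5])
    y <- 2.5 * a + 1
    sm <- SpectraMatrix(X, 1:6, paste0("S", 1:12))
    m <- fitPLSR(sm, y, nFactors = 1)
    expect_equal(unname(predict(m, sm)), unname(y), tolerance = 1e-8)
})

test_that("PLSR at full rank equals ordinary least squares", {
    set.seed(41)
    X <- matrix(rnorm(8 * 5), 8, 5)
    beta <- c(1, -2, 0.5, 3, -1)
    y <- as.vector(X %*% beta) + rnorm(8, sd = 0.1)
    sm <- SpectraMatrix(X, 1:5, paste0("S", 1:8))
    m <- fitPLSR(sm, y, nFactors = 5)
    ols <- lm(y ~ X)
    expect_equal(unname(predict(m, sm)), unname(fitted(ols)),
                 tolerance = 1e-6)
})

test_that("PLSR matches an independent PLS1 implementation", {
    skip_if_not_installed("mixOmics")
    set.seed(17)
    X <- matrix(rnorm(20 * 12), 20, 12,
                dimnames = list(NULL, paste0("V", 1:12)))
    y <- as.vector(X[, 1] - 2 * X[, 5]) + rnorm(20, sd = 0.3)
    sm <- SpectraMatrix(X, 1:12, paste0("S", 1:20))
    m <- fitPLSR(sm, y, nFactors = 3)
    mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
    moPred <- predict(mo, X)$predict[, 1, 3]
    expect_equal(unname(predict(m, sm)), unname(moPred), tolerance = 1e-6)
})

test_that("degenerate fits are rejected", {
    sm <- tinySpectra(6, 4, seed = 2)
    expect_error(fitPLSR(sm, rep(1, 6), nFactors = 1), "variance")
    expect_error(fitPLSR(sm, rnorm(6), nFactors = 6), "rank")
})

test_that("prediction honors centering, batching and shift equivariance", {
    sm <- tinySpectra(10, 8, seed = 13)
    y <- rnorm(10) + 3
    m <- fitPLSR(sm, y, nFactors = 3)
    # the mean spectrum predicts the mean response
    center <- SpectraMatrix(matrix(m@xMean, 2, 8, byrow = TRUE),
                            wavenumbers(sm), c("c1", "c2"))
    expect_equal(unname(predict(m, center)), rep(m@yMean, 2),
                 tolerance = 1e-10)
    # single-sample prediction equals the batch row
    batch <- predict(m, sm)
    one <- predict(m, sm[3, ])
    expect_equal(one, batch[3])
    # adding a constant to y shifts predictions by that constant
    m2 <- fitPLSR(sm, y + 100, nFactors = 3)
    expect_equal(unname(predict(m2, sm)), unname(batch) + 100,
                 tolerance = 1e-8)
    # axis mismatch is an error
    other <- tinySpectra(2, 8, seed = 1, wn = seq(9000, by = 8,
                                                  length.out = 8))
    expect_error(predict(m, other), "axis")
})

test_that("cross-validated factor selection finds low-rank structure", {
    set.seed(23)
    scores <- matrix(rnorm(40 * 2), 40, 2)
    load <- matrix(rnorm(2 * 30), 2, 30)
    X <- scores %*% load
    y <- as.vector(scores %*% c(2, -1))
    sm <- SpectraMatrix(X, 1:30, paste0("S", 1:40))
    expect_equal(as.integer(selectNFactors(sm, y, maxFactors = 8, seed = 3)),
                 2L)
    expect_equal(as.integer(selectNFactors(sm, y, maxFactors = 1, seed = 3)),
                 1L)
    s1 <- selectNFactors(sm, y, maxFactors = 8, seed = 5)
    s2 <- selectNFactors(sm, y, maxFactors = 8, seed = 5)
    expect_identical(s1, s2)
    expect_error(selectNFactors(sm, y, maxFactors = 3, k = 50), "folds")
    # the parsimony rule never returns a count above 1.02x the minimum
    rmsecv <- attr(s1, "rmsecv")
    expect_lte(rmsecv[as.integer(s1)], 1.02 * min(rmsecv))
})

test_that("evaluation statistics match hand values and a loop oracle", {
    sm <- tinySpectra(12, 6, seed = 51)
    y <- 2 * absorbance(sm)[, 2] + 5
    m <- fitPLSR(sm, y, nFactors = 6)   # y in the column span: exact fit
    # perfect predictions
    ev <- evaluateRegression(m, sm[1:8, ], y[1:8], sm[9:12, ], y[9:12])
    expect_equal(ev@rmsec, 0, tolerance = 1e-8)
    expect_equal(ev@rmsep, 0, tolerance = 1e-8)
    expect_equal(ev@r2cal, 1, tolerance = 1e-8)
    expect_equal(ev@r2pre, 1, tolerance = 1e-8)
    expect_equal(ev@rePercent, 0, tolerance = 1e-6)

    # hand-computed: yVal = (10, 20), predictions (11, 18)
    expect_equal(sqrt(mean(c(11 - 10, 18 - 20)^2)), sqrt(5 / 2))
    expect_equal(mean(abs(c(11 - 10, 18 - 20)) / c(10, 20)) * 100, 10)

    # loop oracle on a noisy model
    set.seed(6)
    yn <- y + rnorm(12, sd = 0.5)
    mn <- fitPLSR(sm[1:8, ], yn[1:8], nFactors = 2)
    ev <- evaluateRegression(mn, sm[1:8, ], yn[1:8], sm[9:12, ], yn[9:12])
    pc <- predict(mn, sm[1:8, ]); pv <- predict(mn, sm[9:12, ])
    rmsecLoop <- 0
    for (i in 1:8) rmsecLoop <- rmsecLoop + (pc[i] - yn[i])^2
    rmsecLoop <- sqrt(rmsecLoop / 8)
    expect_equal(ev@rmsec, unname(rmsecLoop), tolerance = 1e-10)
    sse <- sst <- 0
    for (i in 1:4) {
        sse <- sse + (pv[i] - yn[8 + i])^2
        sst <- sst + (yn[8 + i] - mean(yn[9:12]))^2
    }
    expect_equal(ev@rmsep, unname(sqrt(sse / 4)), tolerance = 1e-10)
    expect_equal(ev@r2pre, unname(1 - sse / sst), tolerance = 1e-10)
    reLoop <- mean(abs(pv - yn[9:12]) / yn[9:12]) * 100
    expect_equal(ev@rePercent, unname(reLoop), tolerance = 1e-10)

    # predicting the mean gives r2 = 0; zero measured values are rejected
    yv <- yn[9:12]
    expect_equal(1 - sum((mean(yv) - yv)^2) / sum((yv - mean(yv))^2), 0)
    expect_error(evaluateRegression(mn, sm[1:8, ], yn[1:8], sm[9:12, ],
                                    c(0, yv[-1])), "undefined")
})

test_that("the pretreatment grid evaluates, selects and is order-invariant", {
    sim <- smallSim(seed = 61, n = c(12, 10, 10))
    y <- chemistry(sim$samples)$wse
    sp <- kennardStoneSplit(sim$spectra, 4)
    g1 <- pretreatmentGrid(sim$spectra, y, sp, methods = "Raw",
                           maxFactors = 6, cvSeed = 7)
    expect_identical(g1$selected, "Raw")
    expect_identical(nrow(g1$grid), 1L)

    g3 <- pretreatmentGrid(sim$spectra, y, sp,
                           methods = c("SNV", "Raw", "MSC"),
                           maxFactors = 6, cvSeed = 7)
    g3r <- pretreatmentGrid(sim$spectra, y, sp,
                            methods = c("Raw", "MSC", "SNV"),
                            maxFactors = 6, cvSeed = 7)
    a <- g3$grid[order(g3$grid$method), ]
    b <- g3r$grid[order(g3r$grid$method), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
    expect_identical(g3$selected,
                     g3$grid$method[which.min(g3$grid$rmsep)])
    expect_error(pretreatmentGrid(sim$spectra, y, sp, methods = list()),
                 "non-empty")
})

test_that("scatter-corrective methods beat Raw under strong multiplicative scatter", {
    cfg <- coarseConfig(seed = 71, scatterSlopeSd = 0.3,
                        scatterOffsetSd = 0.1)
    sim <- simulateDataset(cfg)
    y <- chemistry(sim$samples)$wse
    sp <- kennardStoneSplit(sim$spectra, 4)
    g <- pretreatmentGrid(sim$spectra, y, sp,
                          methods = c("Raw", "SNV", "MSC"),
                          maxFactors = 12, cvSeed = 5)
    raw <- g$grid$rmsep[g$grid$method == "Raw"]
    corrected <- min(g$grid$rmsep[g$grid$method != "Raw"])
    expect_lt(corrected, raw)
})
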