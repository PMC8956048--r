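# Synthetic dataset generator.

test_that("component profiles are Gaussian band mixtures peaking where configured", {
    cfg <- SyntheticConfig(bandCenters = 6000, bandWidths = 150,
                           componentLoadings = matrix(c(1, 0, 0, 0), 4, 1),
                           backgroundWeights = 1)
    pr <- componentProfiles(cfg)
    expect_equal(cfg@axis[which.max(pr["psc", ])], 6000)
    expect_true(all(pr[c("wse", "ase", "sft"), ] == 0))

    zero <- SyntheticConfig(componentLoadings = matrix(0, 4, 5))
    expect_true(all(componentProfiles(zero) == 0))

    # the strongest feature of the default mean spectrum sits near 5180
    cfg <- SyntheticConfig(seed = 4)
    sim <- simulateDataset(cfg)
    meanConc <- colMeans(as.matrix(
        chemistry(sim$samples)[, c("psc", "wse", "ase", "sft")]))
    mixture <- as.vector(meanConc %*% componentProfiles(cfg)) +
        backgroundSpectrum(cfg)
    expect_lte(abs(cfg@axis[which.max(mixture)] - 5180), 50)
    expect_lte(abs(cfg@axis[which.max(colMeans(absorbance(sim$spectra)))] -
                   5180), 50)
})

test_that("spectra are exactly linear in concentrations when degradations are off", {
    cfg <- coarseConfig(seed = 5, nPerRegion = c(4, 3, 3),
                        scatterSlopeSd = 0, scatterOffsetSd = 0,
                        baselineSd = 0, noiseSd = 0)
    sim <- simulateDataset(cfg)
    conc <- as.matrix(chemistry(sim$samples)[, c("psc", "wse", "ase", "sft")])
    expected <- conc %*% componentProfiles(cfg)
    expected <- sweep(expected, 2, backgroundSpectrum(cfg), "+")
    expect_equal(absorbance(sim$spectra), expected, ignore_attr = TRUE,
                 tolerance = 1e-12)
})

test_that("the generator is seed-reproducible with exact region marginals", {
    cfg <- coarseConfig(seed = 99, nPerRegion = c(6, 4, 5))
    s1 <- simulateDataset(cfg)
    s2 <- simulateDataset(cfg)
    expect_identical(absorbance(s1$spectra), absorbance(s2$spectra))
    expect_identical(chemistry(s1$samples), chemistry(s2$samples))
    expect_equal(as.integer(table(regions(s1$samples))), c(6L, 4L, 5L))
})

test_that("region concentration means track the configured summary moments", {
    sim <- simulateDataset(SyntheticConfig(seed = 1))
    psc <- chemistry(sim$samples)$psc
    reg <- regions(sim$samples)
    targets <- c(YN = 6.81, XQ = 5.67, DBM = 4.59)
    for (r in names(targets)) {
        v <- psc[reg == r]
        se <- sd(v) / sqrt(length(v))
        expect_lte(abs(mean(v) - targets[[r]]), 2 * se)
    }
    # concentrations respect the configured ranges
    rp <- defaultRegionParams()
    for (cc in c("psc", "wse", "ase", "sft")) {
        v <- chemistry(sim$samples)[[cc]]
        for (r in names(targets)) {
            p <- rp[rp$region == r & rp$constituent == cc, ]
            expect_true(all(v[reg == r] >= p$min & v[reg == r] <= p$max))
        }
    }
    # the five acids sum to SFT
    acids <- as.matrix(chemistry(sim$samples)[, c("dtua", "paa", "pac",
                                                  "dpa", "dtra")])
    expect_equal(rowSums(acids), chemistry(sim$samples)$sft,
                 tolerance = 1e-12)
})

test_that("outlier injection is local, scaled and validated", {
    sim <- smallSim(seed = 33)
    expect_identical(injectOutliers(sim$spectra, character(0)), sim$spectra)
    out <- injectOutliers(sim$spectra, c("S2", "S5"), magnitude = 10,
                          seed = 3)
    untouched <- setdiff(seq_len(nSamples(sim$spectra)), c(2, 5))
    expect_identical(absorbance(out)[untouched, ],
                     absorbance(sim$spectra)[untouched, ])
    # perturbed rows are farther from the mean spectrum than any clean row
    center <- colMeans(absorbance(sim$spectra))
    d <- sqrt(rowSums(sweep(absorbance(out), 2, center)^2))
    expect_gt(min(d[c(2, 5)]), max(d[untouched]))
    expect_error(injectOutliers(sim$spectra, "nope"), "unknown")
    expect_error(injectOutliers(sim$spectra, "S2", magnitude = 0),
                 "magnitude")
})

test_that("rising noise degrades downstream prediction accuracy", {
    r2At <- function(noise) {
        mean(vapply(1:5, function(s) {
            sim <- simulateDataset(coarseConfig(seed = 500 + s,
                                                noiseSd = noise))
            y <- chemistry(sim$samples)$psc
            sp <- kennardStoneSplit(sim$spectra, 4)
            ids <- sampleIds(sim$spectra)
            cal <- match(calibrationIds(sp), ids)
            val <- match(validationIds(sp), ids)
            m <- fitPLSR(sim$spectra[cal, ], y[cal], nFactors = 8)
            ev <- evaluateRegression(m, sim$spectra[cal, ], y[cal],
                                     sim$spectra[val, ], y[val])
            ev@r2pre
        }, numeric(1)))
    }
    levels <- c(0.005, 0.1, 0.4)
    r2 <- vapply(levels, r2At, numeric(1))
    expect_true(all(diff(r2) < 0))
})

test_that("invalid generator configurations are rejected before sampling", {
    expect_error(SyntheticConfig(nPerRegion = c(5, 1, 5)), ">= 2")
    expect_error(SyntheticConfig(bandCenters = c(100, 6880, 5610, 5180,
                                                 4800)), "within the axis")
    expect_error(SyntheticConfig(bandWidths = c(-1, 1, 1, 1, 1)), "positive")
    expect_error(SyntheticConfig(noiseSd = -0.1), ">= 0")
    rp <- defaultRegionParams()
    rp$mean[1] <- 100
    expect_error(SyntheticConfig(regionParams = rp), "within \\[min, max\\]")
    badCor <- matrix(0.99, 4, 4); diag(badCor) <- c(1, 1, 1, -1)
    expect_error(SyntheticConfig(correlation = badCor), "positive definite")
})
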