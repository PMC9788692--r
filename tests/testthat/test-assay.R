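test_that("relative intensity change is anchored at the no-ligand lane", {
    tab <- data.frame(
        lane_id = c("neg", "l1", "l2"),
        conc_molar = c(NA, 1e-6, 1e-5),
        modulated = c(10, 10, 5),
        constant = c(10, 10, 10))
    ric <- relativeIntensityChange(tab)
    expect_equal(ric$concs, c(1e-6, 1e-5))
    expect_equal(ric$relChange, c(0, -0.5))

    # identical lanes: no modulation anywhere
    tab$modulated <- 10
    expect_equal(relativeIntensityChange(tab)$relChange, c(0, 0))

    tab$conc_molar <- c(1e-7, 1e-6, 1e-5)
    expect_error(relativeIntensityChange(tab), "no-ligand")
    tab$conc_molar <- c(NA, 1e-6, 1e-5)
    tab$constant[2] <- 0
    expect_error(relativeIntensityChange(tab), "l1")
})

test_that("series normalization is idempotent and scale invariant", {
    expect_equal(normalizeSeries(c(0.1, 0.2, 0.4)), c(0.25, 0.5, 1))
    expect_equal(normalizeSeries(c(-0.2, -0.5)), c(-0.4, -1))
    x <- c(0.25, 0.5, 1)
    expect_equal(normalizeSeries(x), x)
    set.seed(1)
    v <- rnorm(10)
    expect_equal(normalizeSeries(3.7 * v), normalizeSeries(v))
    expect_equal(normalizeSeries(normalizeSeries(v)), normalizeSeries(v))
    expect_error(normalizeSeries(c(0, 0, 0)), "all-zero")
})

test_that("dilution series reproduces the printed assay range", {
    s <- dilutionSeries(20e-3, 2, 16)
    expect_length(s, 16L)
    expect_equal(s[1], 20e-3)
    expect_equal(s[16], 20e-3 / 2^15)       # ~0.61 uM
    expect_equal(s[16] * 1e6, 0.61, tolerance = 0.01)
    expect_equal(dilutionSeries(1, 10, 3), c(1, 0.1, 0.01))
    expect_equal(dilutionSeries(5, 2, 1), 5)
})

test_that("noiseless binding data recover the true Kd", {
    concs <- dilutionSeries(20e-3, 2, 16)
    tab <- generateProbingTable(kd = 50e-6, hillN = 1, fMax = 0.5,
        concs = concs, noiseSd = 0, seed = 1)
    ric <- relativeIntensityChange(tab)
    curve <- fitBindingCurve(ric$concs, ric$relChange)
    expect_true(curve@saturated)
    expect_equal(curve@kd, 50e-6, tolerance = 0.05)
    expect_equal(curve@hillN, 1, tolerance = 0.05)
    expect_equal(max(abs(curve@normalized)), 1)
})

test_that("a far-above-range Kd yields no apparent Kd", {
    concs <- dilutionSeries(20e-3, 2, 16)
    tab <- generateProbingTable(kd = 200e-3, hillN = 1, fMax = 0.5,
        concs = concs, noiseSd = 0.02, seed = 2)
    ric <- relativeIntensityChange(tab)
    curve <- suppressWarnings(fitBindingCurve(ric$concs, ric$relChange))
    expect_false(curve@saturated)
    expect_true(is.na(curve@kd))
    # normalized magnitudes stay capped at 1 even without saturation
    expect_equal(max(abs(curve@normalized)), 1)
    # and in the noiseless case the anchor is the top-concentration value
    tab0 <- generateProbingTable(kd = 200e-3, hillN = 1, fMax = 0.5,
        concs = concs, noiseSd = 0, seed = 2)
    ric0 <- relativeIntensityChange(tab0)
    curve0 <- suppressWarnings(fitBindingCurve(ric0$concs,
        ric0$relChange))
    expect_false(curve0@saturated)
    expect_equal(abs(curve0@normalized[length(curve0@normalized)]), 1)
})

test_that("a constant response is flagged as degenerate", {
    concs <- dilutionSeries(1e-3, 2, 8)
    expect_warning(curve <- fitBindingCurve(concs, rep(0.4, 8)),
        "degenerate")
    expect_true("degenerate" %in% curve@flags)
    expect_true(is.na(curve@kd))
})

test_that("fit input contracts are enforced", {
    expect_error(fitBindingCurve(c(1, 2, 3), c(1, 2, 3)), "at least 5")
    expect_error(fitBindingCurve(seq(1, 2, length.out = 6), rep(1, 6)),
        "orders of magnitude")
})

test_that("terminated fraction applies the A-count correction", {
    r <- terminatedFraction(100, 100, aTerm = 30, aFull = 60)
    expect_equal(r$fracTerminated, 2 / 3)
    # absent full-length product: complete termination
    expect_equal(terminatedFraction(500, 0, 30, 60)$fracTerminated, 1.0)
    # symmetric case
    expect_equal(terminatedFraction(80, 80, 45, 45)$fracTerminated, 0.5)
    # invariance under joint rescaling
    r1 <- terminatedFraction(120, 40, 30, 60)
    r2 <- terminatedFraction(120 * 7.5, 40 * 7.5, 30, 60)
    expect_equal(r1$fracTerminated, r2$fracTerminated)
    # correction can be disabled
    expect_equal(terminatedFraction(100, 100, 30, 60,
        correctA = FALSE)$fracTerminated, 0.5)
    expect_error(terminatedFraction(0, 0, 30, 60), "zero")
})

test_that("DTNB calibration recovers a perfect line exactly", {
    concs <- c(0, 1e-4, 2e-4, 3e-4, 4e-4)
    cal <- dtnbCalibrate(concs, 0.05 + 2000 * concs)
    expect_equal(cal@slope, 2000)
    expect_equal(cal@intercept, 0.05)
    expect_equal(cal@rSquared, 1)
    expect_equal(activityFromAbsorbance(0.45, cal), 2e-4)
    expect_warning(neg <- activityFromAbsorbance(0.01, cal), "negative")
    expect_equal(neg, 0)
    expect_error(dtnbCalibrate(c(1e-4, 2e-4), c(0.1, 0.2)), "3")
    expect_error(dtnbCalibrate(rep(1e-4, 4), c(0.1, 0.2, 0.3, 0.4)),
        "variance")
})

test_that("noisy calibrations recover the slope within tolerance", {
    tab <- generateCalibrationTable(slope = 2000, intercept = 0.05,
        noiseSd = 0.01, seed = 31)
    cal <- dtnbCalibrate(tab$conc_molar, tab$absorbance)
    expect_equal(cal@slope, 2000, tolerance = 0.05)
    expect_gt(cal@rSquared, 0.99)
})

test_that("reporter fluorescence is normalized by OD", {
    expect_equal(normalizedFluorescence(1000, 0.5), 2000)
    expect_equal(normalizedFluorescence(0, 1), 0)
    expect_error(normalizedFluorescence(100, 0), "positive")
})
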