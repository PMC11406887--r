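# analytic spectrum builders on a grid hitting round wavelengths
flat_spec <- function(level = 10, from = 640, to = 700, step = 0.02) {
    wl <- seq(from, to, by = step)
    data.frame(wavelength = wl, intensity = rep(level, length(wl)))
}
add_gauss <- function(spec, center, amp, fwhm = 0.15) {
    sd <- fwhm / (2 * sqrt(2 * log(2)))
    spec$intensity <- spec$intensity +
        amp * exp(-0.5 * ((spec$wavelength - center) / sd)^2)
    spec
}

test_that("baseline estimation recovers flat and linear continua", {
    cfg <- peakConfig()
    expect_equal(estimateBaseline(flat_spec(level = 3.7), 670), 3.7)
    # linear continuum: interpolated flank medians land on the true line
    sp <- flat_spec(level = 0)
    sp$intensity <- 2 + 0.5 * sp$wavelength
    expect_equal(estimateBaseline(sp, 670), 2 + 0.5 * 670, tolerance = 1e-9)
    # an isolated peak far outside both flanks leaves the baseline untouched
    sp2 <- add_gauss(flat_spec(level = 5), 650, amp = 1000)
    expect_equal(estimateBaseline(sp2, 670), 5, tolerance = 1e-9)
    expect_error(estimateBaseline(flat_spec(from = 660, to = 680), 660.1),
                 "off-grid")
})

test_that("extraction returns the background-corrected Gaussian amplitude", {
    cfg <- peakConfig()
    # center off-grid: oracle = closed-form Gaussian at the nearest grid point
    sp <- add_gauss(flat_spec(level = 10, step = 0.1), 656.28, amp = 50)
    sd <- 0.15 / (2 * sqrt(2 * log(2)))
    grid_pt <- sp$wavelength[which.min(abs(sp$wavelength - 656.28))]
    oracle <- 50 * exp(-0.5 * ((grid_pt - 656.28) / sd)^2)
    expect_equal(extractIntensity(sp, 656.28, cfg), oracle,
                 tolerance = 1e-6)
    # pure continuum extracts zero (floored)
    expect_equal(extractIntensity(flat_spec(), 656.28, cfg), 0)
    # additivity of co-added spectra at a shared argmax
    sp2 <- sp
    sp2$intensity <- 2 * sp$intensity
    expect_equal(extractIntensity(sp2, 656.28, cfg),
                 2 * extractIntensity(sp, 656.28, cfg), tolerance = 1e-9)
    expect_error(extractIntensity(sp, 500, cfg), "outside")
})

test_that("extraction is invariant to a constant offset", {
    sp <- add_gauss(flat_spec(level = 4), 670.78, amp = 25)
    off <- sp
    off$intensity <- off$intensity + 123
    expect_equal(extractIntensity(off, 670.78), extractIntensity(sp, 670.78),
                 tolerance = 1e-9)
})

test_that("extracted intensities are proportional to planted concentrations", {
    concs <- seq(10, 100, length.out = 10)
    vals <- vapply(concs, function(cc) {
        shot <- simulateShot(onlyFeature("Li", cc),
                             instrument = tinyInstrument(),
                             noise = exactNoise())
        extractIntensity(shot, 670.78)
    }, numeric(1))
    expect_gt(cor(concs, vals), 0.999)
})

test_that("multi-line features use the strongest extracted line", {
    # populate only the secondary Zn line at 334.50 nm
    wl <- seq(190, 900, by = 0.1)
    sp <- data.frame(wavelength = wl, intensity = rep(5, length(wl)))
    sp <- add_gauss(sp, 334.50, amp = 40)
    x <- SpectraSet(matrix(sp$intensity, ncol = 1), wl,
                    data.frame(sample_id = "s", species = "Hf",
                               medium = "PDB", bio_rep = 1, tech_rep = 1,
                               shot = 1))
    tab <- buildIntensityTable(x)
    expect_equal(unname(spectraMatrix(tab)["Zn", 1]), 40, tolerance = 1e-3)
    # all-zero spectra give an all-zero table
    zero <- x
    assay(zero, "intensity")[] <- 0
    expect_true(all(spectraMatrix(buildIntensityTable(zero)) == 0))
})

test_that("element identification finds planted elements and nothing else", {
    inst <- tinyInstrument()  # covers H 656.28 and Li 670.78
    shot <- simulateShot(onlyFeature("Li", 50), instrument = inst,
                         noise = exactNoise())
    expect_identical(identifyElements(shot), "Li")
    # pure continuum: empty set
    expect_identical(identifyElements(flat_spec()), character(0))
})

test_that("identification is monotone in the SNR threshold", {
    set.seed(42)
    shot <- simulateShot(c(Li = 12, H = 40), instrument = tinyInstrument(),
                         noise = noiseConfig(noise_a = 1, noise_b = 0,
                                             continuum_decay = Inf))
    sets <- lapply(c(1, 3, 10, 100), function(thr)
        identifyElements(shot, cfg = peakConfig(snr_threshold = thr)))
    for (i in seq_len(length(sets) - 1))
        expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})
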