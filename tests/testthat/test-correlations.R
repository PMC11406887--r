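meta_rows <- function(n) {
    data.frame(sample_id = sprintf("s%d", seq_len(n)),
               species = rep(c("Hf", "Mh"), length.out = n),
               medium = rep(c("PDB", "PDB", "GMM", "GMM"), length.out = n),
               bio_rep = seq_len(n), tech_rep = 1)
}

# tiny table: features in rows, spectra in columns
tiny_table <- function(values) {
    IntensityTable(t(as.matrix(values)), meta_rows(nrow(values)))
}

test_that("pearson matrix matches the hand-computed coefficient", {
    tab <- tiny_table(data.frame(C = c(1, 2, 3, 4), Zn = c(1, 3, 2, 4)))
    r <- pearsonMatrix(tab)
    # oracle: direct covariance / sd formula
    x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(oracle, 0.8)
    expect_equal(unname(r["C", "Zn"]), 0.8)
    expect_equal(unname(diag(r)), c(1, 1))
    # anti-correlated column
    tab2 <- tiny_table(data.frame(C = c(1, 2, 3, 4), Zn = c(4, 3, 2, 1)))
    expect_equal(unname(pearsonMatrix(tab2)["C", "Zn"]), -1)
})

test_that("pearson matrix is symmetric, bounded, unit-diagonal, scale-invariant", {
    set.seed(7)
    vals <- matrix(rexp(16 * 12), nrow = 16,
                   dimnames = list(libsionome:::.FEATURE_ORDER, NULL))
    tab <- IntensityTable(vals, meta_rows(12))
    r <- pearsonMatrix(tab)
    expect_equal(r, t(r))
    expect_true(all(abs(r) <= 1 + 1e-12))
    expect_equal(unname(diag(r)), rep(1, 16))
    # invariance to positive affine rescaling of one feature
    vals2 <- vals
    vals2["Fe", ] <- 5 * vals2["Fe", ] + 3
    expect_equal(pearsonMatrix(IntensityTable(vals2, meta_rows(12))), r,
                 ignore_attr = TRUE)
})

test_that("zero-variance features are reported as undefined, not imputed", {
    tab <- tiny_table(data.frame(C = c(1, 2, 3, 4), Zn = rep(2, 4)))
    r <- pearsonMatrix(tab)
    expect_true(is.na(r["C", "Zn"]))
    expect_identical(attr(r, "undefined"), "Zn")
    expect_error(pearsonMatrix(tiny_table(data.frame(C = 1:2, Zn = 2:1))),
                 "at least 3")
})

test_that("correlation categories follow the standard magnitude bins", {
    cc <- categorizeCorrelation(c(0.05, 0.1, 0.29, 0.3, -0.4, 0.5, 1.0, -1.0,
                                  0))
    expect_identical(cc$magnitude,
                     c("none", "small", "small", "medium", "medium", "large",
                       "large", "large", "none"))
    expect_identical(cc$sign[c(1, 5, 7, 8, 9)],
                     c("positive", "negative", "positive", "negative",
                       "zero"))
    expect_error(categorizeCorrelation(1.2), "outside")
    expect_true(is.na(categorizeCorrelation(NA)$magnitude))
    lab <- correlationCategoryMatrix(matrix(c(1, -0.4, -0.4, 1), 2,
                                            dimnames = list(c("a", "b"),
                                                            c("a", "b"))))
    expect_identical(lab["a", "b"], "medium-")
    expect_identical(lab["a", "a"], "large+")
})

test_that("group means recover planted fold changes exactly at zero noise", {
    # identical rows: every fold change is 1
    same <- IntensityTable(matrix(3, nrow = 16, ncol = 4,
                                  dimnames = list(libsionome:::.FEATURE_ORDER,
                                                  NULL)),
                           meta_rows(4))
    gm <- groupMeanProfile(same, "species")
    expect_true(all(abs(gm$fold_changes[[1]] - 1) < 1e-12))

    # planted 2x species effect, zero noise, no normalization
    shots <- smallStudy(noise = exactNoise())
    spectra <- preprocessSpectra(shots,
                                 aggregationConfig(normalization = "none"))
    tab <- buildIntensityTable(spectra)
    gm <- groupMeanProfile(tab, "species")
    fc <- gm$fold_changes[["Hf/Mh"]]
    expect_equal(unname(fc["Zn"]), 2, tolerance = 1e-8)
    expect_equal(unname(fc["P"]), 2, tolerance = 1e-8)
    # Li is higher in Mh
    expect_equal(unname(fc["Li"]), 0.5, tolerance = 1e-8)
})

test_that("feature-PC correlations align rows and flag misalignment", {
    set.seed(3)
    vals <- matrix(rexp(16 * 12), nrow = 16,
                   dimnames = list(libsionome:::.FEATURE_ORDER,
                                   sprintf("s%d", 1:12)))
    tab <- IntensityTable(vals, meta_rows(12))
    pca <- fitSpectralPCA(t(vals), pcaConfig(n_components = 3,
                                             input_mode = "intensity_table"))
    pc <- pcCorrelations(tab, pca)
    expect_identical(dim(pc), c(16L, 3L))
    expect_true(all(abs(pc) <= 1 + 1e-12))
    # a synthetic score column equal to a feature column correlates at 1
    fake <- pca
    fake@scores[, 1] <- vals["Fe", ]
    expect_equal(unname(pcCorrelations(tab, fake)["Fe", 1]), 1)
    short <- fitSpectralPCA(t(vals)[1:10, ],
                            pcaConfig(n_components = 2,
                                      input_mode = "intensity_table"))
    expect_error(pcCorrelations(tab, short), "not aligned")
})

test_that("essential elements form a large-positive correlation block", {
    shots <- generateStudy(studyDesign("paper_n80", seed = 2))
    tab <- buildIntensityTable(preprocessSpectra(shots))
    ess <- c("Zn", "P", "Mn", "Mg")
    cd <- colData(tab)
    for (sp in c("Hf", "Mh")) {
        # Zn, P, Mn, Mg co-vary through the shared biological-replicate
        # multiplier in every species subset (media pooled)
        r <- pearsonMatrix(tab, subset = cd$species == sp)[ess, ess]
        cc <- categorizeCorrelation(r[upper.tri(r)])
        expect_true(all(cc$magnitude == "large" & cc$sign == "positive"))
        # carbon joins the essential block once the medium is fixed (its
        # planted 2x media fold otherwise dominates its variance)
        r5 <- pearsonMatrix(tab, subset = cd$species == sp &
                                     cd$medium == "PDB")[c("C", ess),
                                                         c("C", ess)]
        cc5 <- categorizeCorrelation(r5[upper.tri(r5)])
        expect_true(all(cc5$magnitude == "large" & cc5$sign == "positive"))
    }
})

test_that("a medium-driven PC correlates oppositely with Ca and C", {
    # media factor pushes Ca (and Al) up in PDB and C up in GMM by design;
    # on zero-noise data the PC separating media must show opposite signs
    shots <- smallStudy(n_biological = 3, noise = exactNoise())
    spectra <- preprocessSpectra(shots)
    tab <- buildIntensityTable(spectra)
    pca <- fitSpectralPCA(spectra, pcaConfig(n_components = 3))
    med <- as.integer(factor(classLabels(spectra, "media")))
    pcMedia <- which.max(abs(cor(pcScores(pca), med)))
    pc <- pcCorrelations(tab, pca)
    expect_lt(pc["Ca", pcMedia] * pc["C", pcMedia], 0)
})
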