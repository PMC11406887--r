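test_that("PCA satisfies its spectral-decomposition contracts", {
    # rank-1 data: all rows on a line through the mean
    base <- c(1, 2, 3, 4, 5)
    mat <- outer(seq(0, 2, length.out = 10), base)
    pca <- fitSpectralPCA(mat, pcaConfig(n_components = 2))
    evr <- explainedVariance(pca)
    expect_equal(evr[1], 1, tolerance = 1e-12)
    expect_true(all(evr[-1] < 1e-12))

    # orthonormal loadings, non-increasing ratios summing to 1 at full rank
    set.seed(5)
    x <- matrix(rnorm(30 * 8), 30, 8)
    pca <- fitSpectralPCA(x, pcaConfig(n_components = 8))
    L <- pcLoadings(pca)
    expect_equal(crossprod(L), diag(8), tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(explainedVariance(pca)) <= 1e-10))
    expect_equal(sum(explainedVariance(pca)), 1, tolerance = 1e-8)
    # sign convention: largest-magnitude loading element is positive
    for (j in 1:8)
        expect_gt(L[which.max(abs(L[, j])), j], 0)
    expect_error(fitSpectralPCA(x, pcaConfig(n_components = 50)),
                 "exceeds the maximum rank")
})

test_that("PCA recovers a planted two-factor subspace at zero noise", {
    set.seed(9)
    p <- 40
    u <- rnorm(p); u <- u / sqrt(sum(u^2))
    v <- rnorm(p); v <- v - sum(v * u) * u; v <- v / sqrt(sum(v^2))
    a <- rnorm(60, sd = 4); b <- rnorm(60, sd = 1.5)
    x <- outer(a, u) + outer(b, v)
    pca <- fitSpectralPCA(x, pcaConfig(n_components = 2))
    # principal angles between fitted and planted subspaces
    sv <- svd(crossprod(cbind(u, v), pcLoadings(pca)))$d
    expect_true(all(acos(pmin(sv, 1)) < 1e-6))
})

test_that("stratified thirds split is balanced, disjoint and reproducible", {
    labels <- rep(c("a", "b", "c", "d"), each = 20)
    sp <- splitThirds(labels, seed = 4)
    expect_length(sp$train, 28)   # round(20/3) = 7 per class
    expect_length(sp$test, 52)
    expect_true(all(table(labels[sp$train]) == 7))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_along(labels))
    expect_identical(splitThirds(labels, seed = 4), sp)
    expect_false(identical(splitThirds(labels, seed = 5)$train, sp$train))
    # a class of three: one train, two test
    tiny <- splitThirds(rep("a", 3), seed = 1)
    expect_length(tiny$train, 1)
    expect_length(tiny$test, 2)
    expect_error(splitThirds(c("a", "a", "b"), seed = 1), "fewer than 3")
})

test_that("linear discriminant places the two-class boundary at the midpoint", {
    # 1-D equal-variance two-class toy: closed-form boundary = midpoint of means
    train <- matrix(c(-1.2, -1, -0.8, 0.8, 1, 1.2), ncol = 1)
    labels <- rep(c("lo", "hi"), each = 3)
    clf <- trainLinearClassifier(train, labels, task = "species")
    expect_identical(predictClasses(clf, matrix(c(-0.01, 0.01), ncol = 1)),
                     c("lo", "hi"))
    # far-separated classes are fit perfectly
    expect_equal(mean(predictClasses(clf, train) == labels), 1)
})

test_that("discriminant predictions agree with an independent LDA oracle", {
    skip_if_not_installed("MASS")
    set.seed(21)
    n <- 30
    train <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
                   matrix(rnorm(n * 2, 1.5), ncol = 2),
                   matrix(rnorm(n * 2, c(3, -1)), ncol = 2))
    labels <- rep(c("a", "b", "c"), each = n)
    test <- matrix(rnorm(200 * 2, 1), ncol = 2)
    clf <- trainLinearClassifier(train, labels)
    fit <- MASS::lda(train, grouping = labels,
                     prior = rep(1 / 3, 3))  # equal priors, as in the model
    agree <- mean(predictClasses(clf, test) ==
                  as.character(predict(fit, test)$class))
    expect_gt(agree, 0.99)
})

test_that("classification with no signal stays at chance", {
    set.seed(33)
    train <- matrix(rnorm(200 * 3), ncol = 3)
    labels <- rep(c("a", "b"), each = 100)
    clf <- trainLinearClassifier(train, labels)
    test <- matrix(rnorm(2000 * 3), ncol = 3)
    acc <- mean(predictClasses(clf, test) == rep(c("a", "b"), 1000))
    expect_gt(acc, 0.4)
    expect_lt(acc, 0.6)
})

test_that("evaluation reports confusion counts, accuracy and misfits", {
    clf <- trainLinearClassifier(matrix(c(-1, -1.1, -0.9, 1, 1.1, 0.9),
                                        ncol = 1),
                                 rep(c("lo", "hi"), each = 3))
    rep1 <- evaluateClassifier(clf, matrix(c(-2, 2), ncol = 1), c("lo", "hi"))
    expect_equal(accuracy(rep1), 1)
    expect_equal(sum(diag(confusionMatrix(rep1))), 2)
    rep0 <- evaluateClassifier(clf, matrix(c(-2, 2), ncol = 1), c("hi", "lo"))
    expect_equal(accuracy(rep0), 0)
    expect_identical(nrow(rep0@misclassified), 2L)
    expect_warning(
        evaluateClassifier(clf, matrix(0, 1, 1), "unknown_class"),
        "never seen")
})

test_that("accuracy is invariant to a joint orthogonal rotation of scores", {
    set.seed(12)
    train <- rbind(matrix(rnorm(40 * 3, 0), ncol = 3),
                   matrix(rnorm(40 * 3, 1), ncol = 3))
    labels <- rep(c("a", "b"), each = 40)
    test <- matrix(rnorm(100 * 3, 0.5), ncol = 3)
    test_labels <- rep(c("a", "b"), 50)
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    a1 <- accuracy(evaluateClassifier(trainLinearClassifier(train, labels),
                                      test, test_labels))
    a2 <- accuracy(evaluateClassifier(
        trainLinearClassifier(train %*% q, labels), test %*% q, test_labels))
    expect_equal(a1, a2)
})

test_that("singular pooled covariance engages the ridge fallback", {
    train <- matrix(c(0, 0, 1, 1, 0, 0, 1, 1), ncol = 2)  # duplicated column
    labels <- c("a", "a", "b", "b")
    expect_warning(clf <- trainLinearClassifier(train, labels), "ridge")
    expect_gt(clf@ridge, 0)
    expect_identical(predictClasses(clf, matrix(c(0, 0), 1)), "a")
})

test_that("shot-averaging ablation halves spectra and stays perfect at zero noise", {
    shots <- smallStudy(n_biological = 3, noise = exactNoise(),
                        instrument = instrumentConfig(wavelength_min = 190,
                                                      wavelength_max = 450,
                                                      grid_step = 0.1))
    # zero within-class variance makes the pooled covariance singular, so the
    # declared ridge fallback engages (with a warning) by construction
    reports <- suppressWarnings(
        averagingAblation(shots, k_values = c(4, 8, 16),
                          agg = aggregationConfig(crop_min = 190,
                                                  crop_max = 450)))
    n4 <- sum(lengths(list(reports$k4@trainIndex, reports$k4@testIndex)))
    n8 <- sum(lengths(list(reports$k8@trainIndex, reports$k8@testIndex)))
    expect_identical(n4, 2L * n8)
    for (r in reports)
        expect_equal(accuracy(r), 1)
})

test_that("classifier accuracy does not decrease with larger planted effects", {
    inst <- instrumentConfig(wavelength_min = 190, wavelength_max = 450,
                             grid_step = 0.1)
    agg <- aggregationConfig(crop_min = 190, crop_max = 450)
    noisy <- noiseConfig(noise_a = 25, noise_b = 0.05)
    run_acc <- function(fold, seed) {
        shots <- generateStudy(studyDesign("custom", n_biological = 3,
                                           n_technical = 1, seed = seed),
                               effects = defaultEffectDirections(fold),
                               instrument = inst, noise = noisy)
        spectra <- preprocessSpectra(shots, agg)
        pca <- fitSpectralPCA(spectra)
        accuracy(classifyTask(pca, classLabels(spectra, "combined"),
                              seed = seed))
    }
    seeds <- 1:10
    lo <- vapply(seeds, function(s) run_acc(1.15, s), numeric(1))
    hi <- vapply(seeds, function(s) run_acc(2.5, s), numeric(1))
    expect_gte(mean(hi), mean(lo))
})

test_that("species and media tasks recover the planted factors across seeds", {
    perfect <- 0L
    for (s in 1:20) {
        shots <- generateStudy(studyDesign("paper_n80", seed = s))
        spectra <- preprocessSpectra(shots)
        pca <- fitSpectralPCA(spectra)
        accs <- vapply(c("media", "species"), function(task)
            accuracy(classifyTask(pca, classLabels(spectra, task),
                                  task = task, seed = s)), numeric(1))
        perfect <- perfect + as.integer(all(accs == 1))
    }
    expect_gte(perfect, 19L)  # 100% accuracy in at least 95% of runs
})
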