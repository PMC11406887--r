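#' PCA configuration
#'
#' @param n_components number of principal components to retain (5 by
#'   default, the number needed to explain essentially all signal variance of
#'   the LIBS spectra).
#' @param input_mode \code{"full_spectrum"} (decompose the preprocessed
#'   wavelength x spectrum matrix) or \code{"intensity_table"} (decompose the
#'   16-feature intensity table).
#' @param center,scale column centering / unit-variance scaling before the
#'   decomposition.
#' @return A validated list of class \code{"PCAConfig"}.
#' @export
pcaConfig <- function(n_components = 5,
                      input_mode = c("full_spectrum", "intensity_table"),
                      center = TRUE, scale = FALSE) {
    input_mode <- match.arg(input_mode)
    stopifnot(n_components >= 1)
    structure(list(n_components = as.integer(n_components),
                   input_mode = input_mode, center = center, scale = scale),
              class = "PCAConfig")
}

## Fix loading signs so the largest-magnitude element of each PC is positive;
## scores flip with their loadings.
.fixSigns <- function(loadings, scores) {
    for (j in seq_len(ncol(loadings))) {
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    list(loadings = loadings, scores = scores)
}

#' Fit a principal component decomposition
#'
#' Mean-centered (optionally scaled) eigendecomposition of the sample
#' covariance via singular values (\code{stats::prcomp}). Explained-variance
#' ratios are reported for the full decomposition so they sum to 1 over full
#' rank; scores and loadings are retained for the first
#' \code{cfg$n_components} components. Loading signs follow the
#' largest-element-positive convention, making results reproducible across
#' linear-algebra backends.
#'
#' @param x a \linkS4class{SpectraSet}, an \linkS4class{IntensityTable}, or a
#'   plain samples x features matrix.
#' @param cfg a \code{PCAConfig}; \code{input_mode} is only consulted to pick
#'   the assay orientation when \code{x} is a container.
#' @return A \linkS4class{SpectralPCA}.
#' @examples
#' spectra <- preprocessSpectra(generateStudy(studyDesign(seed = 1)))
#' pca <- fitSpectralPCA(spectra)
#' sum(explainedVariance(pca)[1:5])
#' @export
fitSpectralPCA <- function(x, cfg = pcaConfig()) {
    if (is(x, "SpectraSet") || is(x, "IntensityTable")) {
        mode <- if (is(x, "SpectraSet")) "full_spectrum" else "intensity_table"
        mat <- t(spectraMatrix(x))
    } else {
        mode <- cfg$input_mode
        mat <- as.matrix(x)
    }
    if (nrow(mat) < 2)
        stop("need at least 2 rows for PCA")
    if (any(!is.finite(mat)))
        stop("PCA input must be finite")
    maxk <- min(nrow(mat) - 1L, ncol(mat))
    if (cfg$n_components > maxk)
        stop("n_components = ", cfg$n_components,
             " exceeds the maximum rank ", maxk)
    pr <- stats::prcomp(mat, center = cfg$center, scale. = cfg$scale)
    ev <- pr$sdev^2
    evr <- ev / sum(ev)
    k <- cfg$n_components
    fx <- .fixSigns(pr$rotation[, seq_len(k), drop = FALSE],
                    pr$x[, seq_len(k), drop = FALSE])
    new("SpectralPCA", scores = fx$scores, loadings = fx$loadings,
        explainedVariance = evr,
        center = if (isTRUE(cfg$center)) pr$center else numeric(ncol(mat)),
        scale = pr$scale, inputMode = mode)
}

#' @rdname SpectralPCA-accessors
#' @param x a \linkS4class{SpectralPCA}.
#' @export
setMethod("pcScores", "SpectralPCA", function(x) x@scores)

#' @rdname SpectralPCA-accessors
#' @export
setMethod("pcLoadings", "SpectralPCA", function(x) x@loadings)

#' Accessors for SpectralPCA objects
#'
#' \code{pcScores} returns the samples x PCs score matrix, \code{pcLoadings}
#' the feature x PCs loading matrix, and \code{explainedVariance} the full
#' vector of explained-variance ratios.
#'
#' @rdname SpectralPCA-accessors
#' @export
setMethod("explainedVariance", "SpectralPCA",
          function(x) x@explainedVariance)

setMethod("show", "SpectralPCA", function(object) {
    k <- ncol(object@scores)
    cat("SpectralPCA (", object@inputMode, "): ", nrow(object@scores),
        " samples, ", k, " retained PCs\n", sep = "")
    evr <- object@explainedVariance[seq_len(k)]
    cat("explained variance:",
        paste(sprintf("PC%d %.2f%%", seq_len(k), 100 * evr),
              collapse = ", "), "\n")
    cat(sprintf("cumulative over %d PCs: %.2f%%\n", k, 100 * sum(evr)))
})

#' Stratified thirds train/test split
#'
#' Randomly assigns, within every class, \code{round(count/3)} rows (at least
#' one) to the training set and the remainder to the test set — the
#' one-third-train / two-thirds-test protocol of the classification
#' experiment. The split is reproducible for a given seed.
#'
#' @param labels class label per row.
#' @param seed integer seed for the split.
#' @param train_fraction fraction assigned to training (default 1/3).
#' @param stratified keep class proportions (default TRUE); every class then
#'   needs at least 3 members.
#' @return List with integer \code{train} and \code{test} indices (disjoint,
#'   exhaustive).
#' @export
splitThirds <- function(labels, seed = 1, train_fraction = 1 / 3,
                        stratified = TRUE) {
    stopifnot(train_fraction > 0, train_fraction < 1)
    n <- length(labels)
    set.seed(seed)
    if (stratified) {
        small <- names(which(table(labels) < 3))
        if (length(small) > 0)
            stop("class(es) with fewer than 3 members under stratification: ",
                 paste(small, collapse = ", "))
        train <- unlist(lapply(split(seq_len(n), labels), function(idx) {
            k <- max(1L, round(length(idx) * train_fraction))
            sample(idx, k)
        }), use.names = FALSE)
    } else {
        k <- max(1L, round(n * train_fraction))
        train <- sample(seq_len(n), k)
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
}

#' Train the equal-covariance linear discriminant
#'
#' The canonical linear classifier on PCA scores: class means with a pooled
#' within-class covariance and equal priors; the decision rule assigns the
#' class maximizing the linear discriminant score
#' \code{x' S^-1 mu_c - mu_c' S^-1 mu_c / 2}. If the pooled covariance is
#' singular (or near-singular) a small ridge is added to its diagonal and a
#' warning is raised; with no usable covariance the rule degrades to nearest
#' class mean.
#'
#' @param scores numeric matrix of training rows (samples x PC dimensions).
#' @param labels class label per training row; at least 2 classes.
#' @param task task name recorded in the model (\code{"media"},
#'   \code{"species"}, \code{"combined"}).
#' @return A \linkS4class{LinearClassifier}.
#' @export
trainLinearClassifier <- function(scores, labels, task = "combined") {
    scores <- as.matrix(scores)
    labels <- as.character(labels)
    classes <- sort(unique(labels))
    if (length(classes) < 2)
        stop("need at least 2 classes in training data")
    p <- ncol(scores)
    means <- do.call(rbind, lapply(classes, function(cl)
        colMeans(scores[labels == cl, , drop = FALSE])))
    rownames(means) <- classes
    centered <- scores - means[labels, , drop = FALSE]
    df <- nrow(scores) - length(classes)
    S <- if (df > 0) crossprod(centered) / df else
        diag(1, p)
    ridge <- 0
    covInv <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(covInv) || kappa(S) > 1e12) {
        ridge <- 1e-8 * mean(diag(S))
        if (ridge <= 0) ridge <- 1e-8
        warning("pooled within-class covariance is singular; ",
                "adding ridge ", format(ridge))
        covInv <- solve(S + diag(ridge, p))
    }
    new("LinearClassifier", task = task, classes = classes,
        means = means, covInv = covInv, ridge = ridge)
}

#' Predict class labels with a linear discriminant
#'
#' @param classifier a \linkS4class{LinearClassifier}.
#' @param scores samples x dimensions matrix.
#' @return Character vector of predicted class labels.
#' @export
predictClasses <- function(classifier, scores) {
    scores <- as.matrix(scores)
    M <- classifier@means
    W <- classifier@covInv
    disc <- scores %*% W %*% t(M) -
        matrix(rowSums((M %*% W) * M) / 2, nrow(scores), nrow(M),
               byrow = TRUE)
    classifier@classes[max.col(disc, ties.method = "first")]
}

#' Evaluate a classifier on held-out spectra
#'
#' @param classifier a \linkS4class{LinearClassifier}.
#' @param scores test rows (samples x dimensions).
#' @param labels true class label per test row; labels never seen in training
#'   are kept as extra confusion rows and flagged with a warning.
#' @param meta optional data.frame of test-row metadata, carried into the
#'   misclassified listing.
#' @param trainIndex,testIndex optional indices recorded in the report.
#' @return A \linkS4class{ClassifierReport}.
#' @export
evaluateClassifier <- function(classifier, scores, labels, meta = NULL,
                               trainIndex = integer(0),
                               testIndex = integer(0)) {
    labels <- as.character(labels)
    if (length(labels) == 0)
        stop("test set is empty")
    unseen <- setdiff(unique(labels), classifier@classes)
    if (length(unseen) > 0)
        warning("test labels never seen in training: ",
                paste(unseen, collapse = ", "))
    pred <- predictClasses(classifier, scores)
    lev_true <- sort(unique(c(classifier@classes, labels)))
    conf <- table(factor(labels, levels = lev_true),
                  factor(pred, levels = classifier@classes))
    conf <- unclass(conf)
    acc <- mean(pred == labels)
    bad <- which(pred != labels)
    mis <- data.frame(index = bad, true = labels[bad], predicted = pred[bad])
    if (!is.null(meta) && length(bad) > 0)
        mis <- cbind(mis, as.data.frame(meta)[bad, , drop = FALSE])
    new("ClassifierReport", task = classifier@task,
        trainIndex = as.integer(trainIndex), testIndex = as.integer(testIndex),
        confusion = conf, accuracy = acc, misclassified = mis)
}

#' @rdname ClassifierReport-accessors
#' @param x a \linkS4class{ClassifierReport}.
#' @export
setMethod("accuracy", "ClassifierReport", function(x) x@accuracy)

#' Accessors for ClassifierReport objects
#'
#' \code{accuracy} returns the test accuracy in [0, 1];
#' \code{confusionMatrix} the true x predicted count matrix.
#'
#' @rdname ClassifierReport-accessors
#' @export
setMethod("confusionMatrix", "ClassifierReport", function(x) x@confusion)

setMethod("show", "ClassifierReport", function(object) {
    cat(sprintf("ClassifierReport [%s]: accuracy %.1f%% (n_test = %d)\n",
                object@task, 100 * object@accuracy, sum(object@confusion)))
    print(object@confusion)
    if (nrow(object@misclassified) > 0) {
        cat("misclassified:\n")
        print(object@misclassified)
    }
})

#' One classification task end to end
#'
#' Splits the PC scores into stratified thirds, trains the linear
#' discriminant on the training third and evaluates on the remaining
#' two-thirds.
#'
#' @param pca a \linkS4class{SpectralPCA} fitted on all analysis spectra.
#' @param labels class label per spectrum.
#' @param task task name for the report.
#' @param seed split seed.
#' @param meta optional per-spectrum metadata for the misclassified listing.
#' @return A \linkS4class{ClassifierReport}.
#' @export
classifyTask <- function(pca, labels, task = "combined", seed = 1,
                         meta = NULL) {
    sc <- pcScores(pca)
    sp <- splitThirds(labels, seed = seed)
    clf <- trainLinearClassifier(sc[sp$train, , drop = FALSE],
                                 labels[sp$train], task = task)
    evaluateClassifier(clf, sc[sp$test, , drop = FALSE], labels[sp$test],
                       meta = if (is.null(meta)) NULL else
                           meta[sp$test, , drop = FALSE],
                       trainIndex = sp$train, testIndex = sp$test)
}

#' Shot-averaging ablation
#'
#' Reruns preprocess -> PCA -> combined classification on the same raw shots
#' for each aggregation factor k (4 and 8 by default), with the same split
#' seed policy, and reports the per-k classifier performance. Averaging more
#' shots trades spectra count for signal-to-noise.
#'
#' @param shots a raw \linkS4class{SpectraSet}; every mount's shot count must
#'   be divisible by each k.
#' @param k_values aggregation factors to compare.
#' @param task classification task (default \code{"combined"}).
#' @param split_seed seed of the stratified thirds split.
#' @param agg template \code{AggregationConfig} (its \code{shots_per_average}
#'   is overridden per k).
#' @param pca a \code{PCAConfig}.
#' @return Named list (\code{"k4"}, \code{"k8"}, ...) of
#'   \linkS4class{ClassifierReport}s.
#' @export
averagingAblation <- function(shots, k_values = c(4, 8), task = "combined",
                              split_seed = 1, agg = aggregationConfig(),
                              pca = pcaConfig()) {
    out <- list()
    for (k in k_values) {
        cfg <- agg
        cfg$shots_per_average <- as.integer(k)
        spectra <- preprocessSpectra(shots, cfg)
        fit <- fitSpectralPCA(spectra, pca)
        labels <- classLabels(spectra, if (task == "media") "media" else
                              if (task == "species") "species" else "combined")
        out[[paste0("k", k)]] <- classifyTask(
            fit, labels, task = task, seed = split_seed,
            meta = as.data.frame(colData(spectra)))
    }
    out
}
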