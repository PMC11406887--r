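#' Pearson correlation matrix over spectral features
#'
#' Computes the Pearson coefficient for every pair of feature columns of an
#' intensity table (optionally row-filtered, e.g. one species at a time as in
#' the per-species correlation profiles). Zero-variance features yield an
#' undefined coefficient, recorded as \code{NA} and listed in the
#' \code{"undefined"} attribute rather than silently imputed.
#'
#' @param table an \linkS4class{IntensityTable}.
#' @param subset logical or integer vector selecting spectra (columns of the
#'   table); default all.
#' @return Symmetric numeric matrix with unit diagonal (for defined
#'   features), feature labels as dimnames, and attribute \code{undefined}
#'   naming any zero-variance features.
#' @examples
#' tab <- buildIntensityTable(
#'     preprocessSpectra(generateStudy(studyDesign(seed = 1))))
#' rmat <- pearsonMatrix(tab, subset = colData(tab)$species == "Mh")
#' @export
pearsonMatrix <- function(table, subset = NULL) {
    stopifnot(is(table, "IntensityTable"))
    x <- t(spectraMatrix(table))
    if (!is.null(subset))
        x <- x[subset, , drop = FALSE]
    if (nrow(x) < 3)
        stop("need at least 3 spectra after filtering, got ", nrow(x))
    sds <- apply(x, 2, stats::sd)
    undef <- colnames(x)[sds == 0]
    r <- suppressWarnings(stats::cor(x, method = "pearson"))
    attr(r, "undefined") <- undef
    r
}

#' Categorize a Pearson coefficient
#'
#' Applies the conventional magnitude bins: |r| < 0.1 means no linear
#' correlation; [0.1, 0.3) small; [0.3, 0.5) medium; [0.5, 1.0] large
#' (half-open bins, with 1 included in "large"). The sign is reported
#' separately.
#'
#' @param r numeric vector of coefficients in [-1, 1] (NA allowed, propagated).
#' @return data.frame with columns \code{r}, \code{sign} (\code{"positive"},
#'   \code{"negative"} or \code{"zero"}) and \code{magnitude} (\code{"none"},
#'   \code{"small"}, \code{"medium"}, \code{"large"}).
#' @examples
#' categorizeCorrelation(c(0.05, -0.4, 1.0))
#' @export
categorizeCorrelation <- function(r) {
    if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
        stop("correlation coefficient outside [-1, 1]")
    sgn <- ifelse(is.na(r), NA_character_,
           ifelse(r > 0, "positive", ifelse(r < 0, "negative", "zero")))
    mag <- cut(pmin(abs(r), 1), breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
               labels = c("none", "small", "medium", "large"), right = FALSE)
    data.frame(r = r, sign = sgn, magnitude = as.character(mag),
               stringsAsFactors = FALSE)
}

#' Compact category labels for a correlation matrix
#'
#' @param r numeric matrix of coefficients.
#' @return Character matrix of labels like \code{"large+"}, \code{"none"},
#'   \code{"medium-"}.
#' @export
correlationCategoryMatrix <- function(r) {
    cc <- categorizeCorrelation(as.numeric(r))
    lab <- ifelse(is.na(cc$r), "undefined",
           ifelse(cc$magnitude == "none", "none",
                  paste0(cc$magnitude,
                         ifelse(cc$sign == "negative", "-", "+"))))
    matrix(lab, nrow = nrow(r), dimnames = dimnames(r))
}

#' Group-mean intensity profiles and fold changes
#'
#' Arithmetic mean intensity of every feature within each group (species,
#' medium, or species x medium class), plus pairwise fold-change matrices
#' between groups — the numeric counterpart of comparing average relative
#' emission intensities between sample classes.
#'
#' @param table an \linkS4class{IntensityTable}.
#' @param group_by \code{"species"}, \code{"medium"} or \code{"combined"}.
#' @return List of class \code{"GroupMeanProfile"} with \code{means} (groups
#'   x features matrix) and \code{fold_changes} (named list of per-feature
#'   fold-change vectors, \code{"A/B"} = mean_A / mean_B).
#' @export
groupMeanProfile <- function(table, group_by = c("species", "medium",
                                                 "combined")) {
    group_by <- match.arg(group_by)
    stopifnot(is(table, "IntensityTable"))
    g <- switch(group_by,
                species = as.character(colData(table)$species),
                medium = as.character(colData(table)$medium),
                combined = classLabels(table, "combined"))
    if (any(table(g) == 0) || length(unique(g)) < 1)
        stop("every group must be nonempty")
    x <- t(spectraMatrix(table))
    means <- do.call(rbind, lapply(split(seq_len(nrow(x)), g), function(i)
        colMeans(x[i, , drop = FALSE])))
    groups <- rownames(means)
    fc <- list()
    if (length(groups) > 1) {
        pairs <- utils::combn(groups, 2, simplify = FALSE)
        for (p in pairs)
            fc[[paste(p[1], p[2], sep = "/")]] <- means[p[1], ] / means[p[2], ]
    }
    structure(list(group_by = group_by, means = means, fold_changes = fc),
              class = "GroupMeanProfile")
}

#' Correlate spectral features with PC scores
#'
#' Appends the per-spectrum PCA scores to the intensity table and reports the
#' Pearson coefficient of every feature with every retained principal
#' component, exposing which emission intensities drive each PC.
#'
#' @param table an \linkS4class{IntensityTable}.
#' @param pca a \linkS4class{SpectralPCA} whose score rows align with the
#'   table's spectra (same order, same count).
#' @return Numeric matrix, features x PCs.
#' @export
pcCorrelations <- function(table, pca) {
    stopifnot(is(table, "IntensityTable"), is(pca, "SpectralPCA"))
    sc <- pcScores(pca)
    if (nrow(sc) != ncol(table))
        stop("PC scores (", nrow(sc), " rows) are not aligned with the ",
             "intensity table (", ncol(table), " spectra)")
    if (!is.null(rownames(sc)) &&
        !identical(rownames(sc), colnames(table)))
        stop("PC score rows and intensity-table spectra are ordered ",
             "differently")
    suppressWarnings(stats::cor(t(spectraMatrix(table)), sc,
                                method = "pearson"))
}
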