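#' Aggregation / preprocessing configuration
#'
#' @param shots_per_average number of consecutive shots averaged into one
#'   analysis spectrum (4 in the standard pipeline, 8 in the ablation).
#' @param normalization \code{"total_area"} (per-spectrum intensities sum to 1
#'   over the cropped grid), \code{"max_peak"} (maximum equals 1) or
#'   \code{"none"}.
#' @param crop_min,crop_max analysed wavelength window, nm (190-900 by
#'   default, the window within which all element signatures are parsed).
#' @return A validated list of class \code{"AggregationConfig"}.
#' @export
aggregationConfig <- function(shots_per_average = 4,
                              normalization = c("total_area", "max_peak",
                                                "none"),
                              crop_min = 190, crop_max = 900) {
    normalization <- match.arg(normalization)
    stopifnot(shots_per_average >= 1, crop_min < crop_max)
    structure(list(shots_per_average = as.integer(shots_per_average),
                   normalization = normalization,
                   crop_min = crop_min, crop_max = crop_max),
              class = "AggregationConfig")
}

#' Crop spectra to a wavelength window
#'
#' Keeps grid points with \code{crop_min <= wavelength <= crop_max} (closed
#' interval); all metadata is preserved.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param crop_min,crop_max window bounds in nm.
#' @return The cropped \linkS4class{SpectraSet}.
#' @export
cropSpectra <- function(x, crop_min = 190, crop_max = 900) {
    stopifnot(is(x, "SpectraSet"), crop_min < crop_max)
    keep <- wavelengths(x) >= crop_min & wavelengths(x) <= crop_max
    if (!any(keep))
        stop(sprintf("crop [%g, %g] nm excludes all grid points", crop_min,
                     crop_max))
    x[keep, ]
}

#' Average consecutive shots within each mount
#'
#' Within every mount (unique \code{sample_id}), shots are taken in
#' acquisition order and consecutive disjoint groups of \code{k} are averaged
#' pointwise, turning \code{shots_per_mount} raw shots into
#' \code{shots_per_mount / k} analysis spectra. The group index is recorded in
#' the \code{group} metadata column.
#'
#' @param x a \linkS4class{SpectraSet} of raw shots (colData column
#'   \code{shot} required).
#' @param k shots per average; the shot count of every mount must be
#'   divisible by \code{k}.
#' @return A \linkS4class{SpectraSet} of averaged spectra.
#' @export
aggregateShots <- function(x, k = 4) {
    stopifnot(is(x, "SpectraSet"), k >= 1)
    cd <- as.data.frame(colData(x))
    if (!"shot" %in% names(cd))
        stop("aggregateShots needs raw shots with a 'shot' column")
    mounts <- unique(cd$sample_id)
    mat <- spectraMatrix(x)
    outCols <- list(); outMeta <- list(); idx <- 0L
    for (mid in mounts) {
        cols <- which(cd$sample_id == mid)
        cols <- cols[order(cd$shot[cols])]
        if (length(cols) %% k != 0)
            stop(sprintf(
                "mount '%s' has %d shots, not divisible by k = %d",
                mid, length(cols), k))
        ngroup <- length(cols) %/% k
        for (g in seq_len(ngroup)) {
            idx <- idx + 1L
            gc <- cols[((g - 1L) * k + 1L):(g * k)]
            outCols[[idx]] <- rowMeans(mat[, gc, drop = FALSE])
            m <- cd[gc[1], c("sample_id", "species", "medium", "bio_rep",
                             "tech_rep")]
            m$group <- g
            outMeta[[idx]] <- m
        }
    }
    avg <- do.call(cbind, outCols)
    meta <- do.call(rbind, outMeta)
    colnames(avg) <- sprintf("%s_g%d", meta$sample_id, meta$group)
    rownames(meta) <- colnames(avg)
    out <- SpectraSet(avg, wavelengths(x), meta, stage = "averaged")
    metadata(out) <- c(metadata(x)[setdiff(names(metadata(x)), "stage")],
                       metadata(out)["stage"])
    metadata(out)$shots_per_average <- as.integer(k)
    out
}

#' Normalize spectra
#'
#' \code{"total_area"} rescales each spectrum so its intensities sum to 1 over
#' the current (cropped) grid, removing shot-to-shot laser-energy variation;
#' \code{"max_peak"} rescales so the maximum equals 1; \code{"none"} is the
#' identity. Both rescalings are scale invariant and idempotent.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param mode normalization mode.
#' @return The normalized \linkS4class{SpectraSet}.
#' @export
normalizeSpectra <- function(x, mode = c("total_area", "max_peak", "none")) {
    mode <- match.arg(mode)
    stopifnot(is(x, "SpectraSet"))
    if (mode == "none")
        return(x)
    mat <- spectraMatrix(x)
    denom <- switch(mode,
                    total_area = colSums(mat),
                    max_peak = apply(mat, 2, max))
    if (any(denom <= 0))
        stop("cannot normalize all-zero spectrum (column ",
             which(denom <= 0)[1], ")")
    assay(x, "intensity") <- sweep(mat, 2, denom, "/")
    metadata(x)$normalization <- mode
    x
}

#' Standard preprocessing: crop, average, normalize
#'
#' Applies the fixed pipeline order crop -> aggregate -> normalize exactly
#' once; raw detector counts are averaged before any rescaling. Refuses to
#' preprocess an already-preprocessed set.
#'
#' @param x a \linkS4class{SpectraSet} of raw shots.
#' @param cfg an \code{AggregationConfig}.
#' @return A \linkS4class{SpectraSet} of analysis spectra (stage
#'   \code{"preprocessed"}).
#' @examples
#' shots <- generateStudy(studyDesign("paper_n80", seed = 1))
#' spectra <- preprocessSpectra(shots)  # 80 analysis spectra
#' @export
preprocessSpectra <- function(x, cfg = aggregationConfig()) {
    stopifnot(is(x, "SpectraSet"))
    if (identical(metadata(x)$stage, "preprocessed"))
        stop("SpectraSet is already preprocessed; the crop -> aggregate -> ",
             "normalize pipeline is applied exactly once")
    out <- cropSpectra(x, cfg$crop_min, cfg$crop_max)
    out <- aggregateShots(out, cfg$shots_per_average)
    out <- normalizeSpectra(out, cfg$normalization)
    metadata(out)$stage <- "preprocessed"
    metadata(out)$aggregation <- cfg
    out
}
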