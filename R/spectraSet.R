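#' Construct a SpectraSet
#'
#' @param intensity numeric matrix, wavelength grid points in rows, spectra in
#'   columns; nonnegative.
#' @param wavelength strictly increasing numeric vector (nm), one entry per
#'   row of \code{intensity}.
#' @param colData data.frame or DataFrame of per-spectrum labels with at least
#'   \code{sample_id}, \code{species}, \code{medium}, \code{bio_rep},
#'   \code{tech_rep}, and \code{shot} (raw shots) or \code{group} (averaged
#'   spectra).
#' @param stage character tag recorded in \code{metadata()} describing the
#'   processing stage (\code{"raw"}, \code{"preprocessed"}, ...).
#' @return A \linkS4class{SpectraSet}.
#' @export
SpectraSet <- function(intensity, wavelength, colData, stage = "raw") {
    intensity <- as.matrix(intensity)
    if (nrow(intensity) != length(wavelength))
        stop("nrow(intensity) must equal length(wavelength)")
    cd <- S4Vectors::DataFrame(colData)
    if (is.null(colnames(intensity)))
        colnames(intensity) <- sprintf("spec%03d", seq_len(ncol(intensity)))
    rownames(cd) <- colnames(intensity)
    se <- SummarizedExperiment(
        assays = list(intensity = intensity),
        rowData = S4Vectors::DataFrame(wavelength = as.numeric(wavelength)),
        colData = cd)
    out <- new("SpectraSet", se)
    metadata(out)$stage <- stage
    out
}

#' Construct an IntensityTable
#'
#' Mainly useful for assembling a table from externally extracted
#' intensities; \code{\link{buildIntensityTable}} is the usual route.
#'
#' @param intensity numeric matrix, features in rows (canonical order),
#'   analysis spectra in columns; nonnegative, no missing cells.
#' @param colData per-spectrum metadata (sample_id, species, medium,
#'   bio_rep, tech_rep, ...).
#' @return An \linkS4class{IntensityTable}.
#' @export
IntensityTable <- function(intensity, colData) {
    intensity <- as.matrix(intensity)
    cd <- S4Vectors::DataFrame(colData)
    if (is.null(colnames(intensity)))
        colnames(intensity) <- sprintf("spec%03d", seq_len(ncol(intensity)))
    rownames(cd) <- colnames(intensity)
    new("IntensityTable",
        SummarizedExperiment(assays = list(intensity = intensity),
                             colData = cd))
}

#' Wavelength grid of a SpectraSet
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric vector of wavelengths in nm.
#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) rowData(x)$wavelength)

#' Intensity matrix of a SpectraSet
#'
#' @param x a \linkS4class{SpectraSet} or \linkS4class{IntensityTable}.
#' @return For a \code{SpectraSet}, the wavelength x spectrum intensity
#'   matrix; for an \code{IntensityTable}, the feature x spectrum matrix.
#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x) assay(x, "intensity"))

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "IntensityTable", function(x) assay(x, "intensity"))

setMethod("show", "SpectraSet", function(object) {
    wl <- wavelengths(object)
    cat("SpectraSet:", ncol(object), "spectra x", nrow(object),
        "grid points\n")
    cat(sprintf("grid: %.1f-%.1f nm; stage: %s\n", min(wl), max(wl),
                metadata(object)$stage %||% "unknown"))
    cd <- colData(object)
    if (all(c("species", "medium") %in% names(cd)))
        print(table(species = cd$species, medium = cd$medium))
})

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Combined species x medium class label per spectrum
#'
#' @param x a SpectraSet or IntensityTable.
#' @param task one of \code{"media"}, \code{"species"}, \code{"combined"}.
#' @return Character vector of class labels, one per spectrum.
#' @export
classLabels <- function(x, task = c("combined", "species", "media")) {
    task <- match.arg(task)
    cd <- colData(x)
    switch(task,
           media = as.character(cd$medium),
           species = as.character(cd$species),
           combined = paste(cd$species, cd$medium, sep = "_"))
}
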