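#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## Canonical feature order: the 15 elements identified in fungal biomass by
## LIBS, in the order they are reported, followed by the CN molecular band.
.FEATURE_ORDER <- c("C", "Zn", "P", "Mn", "Mg", "Si", "Fe", "Ca", "Al",
                    "Na", "H", "Li", "K", "O", "N", "CN")

## Instrument hard limits of the 8-channel spectrometer (nm).
.INSTRUMENT_RANGE <- c(178, 1022)

#' Reference emission-line library
#'
#' Holds the reference emission lines (element or molecular-band label,
#' center wavelength in nm, within-feature relative strength) shared by the
#' spectrum simulator and the peak-extraction stage, together with the
#' canonical ordering of the 16 spectral features (15 elements plus the CN
#' molecular band).
#'
#' @slot lines data.frame with columns \code{feature_label},
#'   \code{center_wavelength} (nm), \code{relative_strength} (in (0, 1]) and
#'   \code{is_molecular_band} (logical).
#' @slot featureOrder character vector giving the canonical order of the 16
#'   feature labels.
#' @exportClass LineLibrary
setClass("LineLibrary",
         slots = c(lines = "data.frame", featureOrder = "character"))

setValidity("LineLibrary", function(object) {
    req <- c("feature_label", "center_wavelength", "relative_strength",
             "is_molecular_band")
    miss <- setdiff(req, names(object@lines))
    if (length(miss) > 0)
        return(paste0("missing line column(s): ", paste(miss, collapse = ", ")))
    ln <- object@lines
    if (nrow(ln) == 0)
        return("no lines")
    bad <- which(ln$center_wavelength < .INSTRUMENT_RANGE[1] |
                 ln$center_wavelength > .INSTRUMENT_RANGE[2])
    if (length(bad) > 0)
        return(sprintf(
            "line %d (%s at %.2f nm) outside instrument range [%g, %g] nm",
            bad[1], ln$feature_label[bad[1]], ln$center_wavelength[bad[1]],
            .INSTRUMENT_RANGE[1], .INSTRUMENT_RANGE[2]))
    if (any(!is.finite(ln$relative_strength)) ||
        any(ln$relative_strength <= 0))
        return("relative_strength must be > 0 for every line")
    key <- paste(ln$feature_label, ln$center_wavelength)
    if (anyDuplicated(key))
        return(sprintf("duplicate (label, wavelength) pair in row %d",
                       which(duplicated(key))[1]))
    elems <- setdiff(unique(ln$feature_label), "CN")
    if (length(elems) != 15L)
        return(sprintf("expected 15 distinct element labels plus CN, found %d",
                       length(elems)))
    if (!"CN" %in% ln$feature_label)
        return("CN molecular band missing from library")
    if (!setequal(object@featureOrder, unique(ln$feature_label)))
        return("featureOrder does not match the set of line labels")
    TRUE
})

#' Collection of LIBS spectra on a shared wavelength grid
#'
#' A \linkS4class{SummarizedExperiment} whose rows are wavelength grid points
#' and whose columns are individual spectra (raw shots or averaged analysis
#' spectra). \code{rowData} holds the wavelength grid; \code{colData} carries
#' the acquisition labels (\code{sample_id}, \code{species}, \code{medium},
#' \code{bio_rep}, \code{tech_rep}, and \code{shot} for raw shots or
#' \code{group} for shot-averaged spectra).
#'
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
    if (!"intensity" %in% assayNames(object))
        return("assay 'intensity' is required")
    if (!"wavelength" %in% names(rowData(object)))
        return("rowData column 'wavelength' is required")
    wl <- rowData(object)$wavelength
    if (any(diff(wl) <= 0))
        return("wavelength grid must be strictly increasing")
    req <- c("sample_id", "species", "medium", "bio_rep", "tech_rep")
    miss <- setdiff(req, names(colData(object)))
    if (length(miss) > 0)
        return(paste0("missing colData column(s): ",
                      paste(miss, collapse = ", ")))
    if (!any(c("shot", "group") %in% names(colData(object))))
        return("colData needs a 'shot' (raw) or 'group' (averaged) column")
    x <- assay(object, "intensity")
    if (any(!is.finite(x)))
        return("intensities must be finite")
    if (any(x < 0))
        return("intensities must be nonnegative")
    TRUE
})

#' Background-corrected peak-intensity table
#'
#' A \linkS4class{SummarizedExperiment} with one row per spectral feature (the
#' 15 elements plus CN, in canonical order) and one column per analysis
#' spectrum; the \code{intensity} assay holds background-corrected peak
#' intensities floored at zero, in the same arbitrary detector units as the
#' spectra they were extracted from. \code{colData} carries the full sample
#' metadata of the source spectra.
#'
#' @exportClass IntensityTable
setClass("IntensityTable", contains = "SummarizedExperiment")

setValidity("IntensityTable", function(object) {
    if (!"intensity" %in% assayNames(object))
        return("assay 'intensity' is required")
    x <- assay(object, "intensity")
    if (anyNA(x))
        return("intensity table must have no missing cells")
    if (any(x < 0))
        return("intensities must be >= 0")
    req <- c("sample_id", "species", "medium", "bio_rep", "tech_rep")
    miss <- setdiff(req, names(colData(object)))
    if (length(miss) > 0)
        return(paste0("missing colData column(s): ",
                      paste(miss, collapse = ", ")))
    TRUE
})

#' Principal component decomposition of a spectral matrix
#'
#' @slot scores matrix, samples x retained PCs.
#' @slot loadings matrix, input features (wavelengths or intensity features) x
#'   retained PCs; columns orthonormal, sign fixed so the largest-magnitude
#'   loading element of each PC is positive.
#' @slot explainedVariance numeric, variance ratio of every component of the
#'   full decomposition (sums to 1 over full rank), not just the retained ones.
#' @slot center numeric, the column means removed before decomposition.
#' @slot scale numeric or FALSE, column scales if scaling was requested.
#' @slot inputMode character, \code{"full_spectrum"} or
#'   \code{"intensity_table"}.
#' @exportClass SpectralPCA
setClass("SpectralPCA",
         slots = c(scores = "matrix", loadings = "matrix",
                   explainedVariance = "numeric", center = "numeric",
                   scale = "ANY", inputMode = "character"))

setValidity("SpectralPCA", function(object) {
    k <- ncol(object@scores)
    if (ncol(object@loadings) != k)
        return("scores and loadings disagree on the number of components")
    ev <- object@explainedVariance
    if (any(ev < -1e-12) || any(ev > 1 + 1e-12))
        return("explained-variance ratios must lie in [0, 1]")
    if (any(diff(ev) > 1e-8))
        return("explained-variance ratios must be non-increasing")
    if (sum(ev) > 1 + 1e-8)
        return("explained-variance ratios must sum to at most 1")
    TRUE
})

#' Equal-covariance linear discriminant classifier in PC space
#'
#' Class means with a shared (pooled) within-class covariance and equal
#' priors; prediction assigns the class with the largest linear discriminant
#' score. When the pooled covariance is singular a ridge term is added and
#' recorded in \code{ridge}.
#'
#' @slot task character, one of \code{"media"}, \code{"species"},
#'   \code{"combined"}.
#' @slot classes character vector of class labels seen in training.
#' @slot means matrix, classes x dimensions.
#' @slot covInv matrix, inverse of the (possibly ridge-regularized) pooled
#'   within-class covariance.
#' @slot ridge numeric, ridge value added to the covariance diagonal (0 if
#'   none was needed).
#' @exportClass LinearClassifier
setClass("LinearClassifier",
         slots = c(task = "character", classes = "character",
                   means = "matrix", covInv = "matrix", ridge = "numeric"))

#' Classification report for one task
#'
#' @slot task character, the classification task.
#' @slot trainIndex,testIndex integer indices of the train/test partition.
#' @slot confusion matrix of counts, true classes in rows, predicted in
#'   columns.
#' @slot accuracy numeric in [0, 1], \code{trace(confusion)/sum(confusion)}.
#' @slot misclassified data.frame of metadata for the misclassified test rows.
#' @exportClass ClassifierReport
setClass("ClassifierReport",
         slots = c(task = "character", trainIndex = "integer",
                   testIndex = "integer", confusion = "matrix",
                   accuracy = "numeric", misclassified = "data.frame"))

setValidity("ClassifierReport", function(object) {
    if (length(intersect(object@trainIndex, object@testIndex)) > 0)
        return("train and test indices must be disjoint")
    shared <- intersect(rownames(object@confusion),
                        colnames(object@confusion))
    tr <- sum(diag(object@confusion[shared, shared, drop = FALSE]))
    if (abs(object@accuracy - tr / sum(object@confusion)) > 1e-12)
        return("accuracy must equal trace(confusion)/sum(confusion)")
    TRUE
})
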