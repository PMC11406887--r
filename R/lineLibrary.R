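#' Construct a reference line library
#'
#' @param lines data.frame with columns \code{feature_label},
#'   \code{center_wavelength} (nm, within the 178-1022 nm spectrometer range),
#'   \code{relative_strength} (> 0) and \code{is_molecular_band}.
#' @param featureOrder canonical feature ordering; defaults to the order of
#'   first appearance in \code{lines}.
#' @return A \linkS4class{LineLibrary}.
#' @export
LineLibrary <- function(lines, featureOrder = unique(lines$feature_label)) {
    lines <- as.data.frame(lines)
    if (nrow(lines) > 0) {
        lines$feature_label <- as.character(lines$feature_label)
        lines$center_wavelength <- as.numeric(lines$center_wavelength)
        lines$relative_strength <- as.numeric(lines$relative_strength)
        lines$is_molecular_band <- as.logical(lines$is_molecular_band)
    }
    new("LineLibrary", lines = lines, featureOrder = as.character(featureOrder))
}

#' Default reference emission-line library
#'
#' Returns the line library shipped with the package: one to three strong
#' persistent NIST lines for each of the 15 elements detectable in fungal
#' biomass by LIBS (C, Zn, P, Mn, Mg, Si, Fe, Ca, Al, Na, H, Li, K, O, N),
#' plus the CN violet-system band head at 388.34 nm treated as a single
#' molecular pseudo-line. All primary lines lie within the analysed 190-900 nm
#' window. The call is deterministic and side-effect free.
#'
#' @return A \linkS4class{LineLibrary} with 16 features.
#' @examples
#' lib <- defaultLineLibrary()
#' featureOrder(lib)
#' @export
defaultLineLibrary <- function() {
    path <- system.file("extdata", "nist_strong_lines.tsv",
                        package = "libsionome", mustWork = TRUE)
    readLineLibrary(path, featureOrder = .FEATURE_ORDER)
}

#' Read / write a line library as tab-separated text
#'
#' The on-disk format is a tab-separated table with a header row and columns
#' \code{feature_label}, \code{center_wavelength}, \code{relative_strength},
#' \code{is_molecular_band}; lines starting with \code{#} are comments.
#' \code{readLineLibrary(writeLineLibrary(lib, path))} is the identity for
#' text-representable values.
#'
#' @param path file path.
#' @param featureOrder optional canonical feature order; defaults to order of
#'   first appearance.
#' @return \code{readLineLibrary} returns a \linkS4class{LineLibrary};
#'   \code{writeLineLibrary} returns \code{path} invisibly.
#' @export
readLineLibrary <- function(path, featureOrder = NULL) {
    tab <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    if (nrow(tab) == 0)
        stop("no lines in library file '", path, "'")
    req <- c("feature_label", "center_wavelength", "relative_strength",
             "is_molecular_band")
    miss <- setdiff(req, names(tab))
    if (length(miss) > 0)
        stop("line library file is missing column(s): ",
             paste(miss, collapse = ", "))
    if (is.null(featureOrder))
        featureOrder <- unique(tab$feature_label)
    LineLibrary(tab, featureOrder = featureOrder)
}

#' @rdname readLineLibrary
#' @param lib a \linkS4class{LineLibrary}.
#' @export
writeLineLibrary <- function(lib, path) {
    stopifnot(is(lib, "LineLibrary"))
    ## keep canonical order on disk so round trips are exact
    ord <- order(match(lib@lines$feature_label, lib@featureOrder),
                 -lib@lines$relative_strength, lib@lines$center_wavelength)
    utils::write.table(lib@lines[ord, , drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Canonical feature order of a line library
#'
#' @param x a \linkS4class{LineLibrary}.
#' @return Character vector of the 16 feature labels in canonical order.
#' @rdname featureOrder
#' @export
setMethod("featureOrder", "LineLibrary", function(x) x@featureOrder)

#' Line table of a library
#'
#' @param x a \linkS4class{LineLibrary}.
#' @return The underlying data.frame of reference lines.
#' @rdname lineTable
#' @export
setMethod("lineTable", "LineLibrary", function(x) x@lines)

#' Lines belonging to one feature, strongest first
#' @keywords internal
.featureLines <- function(lib, feature) {
    ln <- lib@lines[lib@lines$feature_label == feature, , drop = FALSE]
    ln[order(-ln$relative_strength), , drop = FALSE]
}

setMethod("show", "LineLibrary", function(object) {
    cat("LineLibrary with", nrow(object@lines), "lines over",
        length(object@featureOrder), "features\n")
    cat("features:", paste(object@featureOrder, collapse = " "), "\n")
    rng <- range(object@lines$center_wavelength)
    cat(sprintf("wavelengths: %.2f-%.2f nm\n", rng[1], rng[2]))
})
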