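#' Peak-extraction configuration
#'
#' @param match_tolerance half-width (nm) of the search window around a
#'   reference line center within which the peak maximum is located.
#' @param baseline_flank width (nm) of the two flanking baseline windows on
#'   each side of the exclusion zone.
#' @param exclusion_halfwidth half-width (nm) of the region around the line
#'   center excluded from baseline estimation; must be at least
#'   \code{match_tolerance}.
#' @param snr_threshold detection threshold for element identification, in
#'   units of the local noise sigma.
#' @return A validated list of class \code{"PeakConfig"}.
#' @export
peakConfig <- function(match_tolerance = 0.3, baseline_flank = 1.0,
                       exclusion_halfwidth = 0.45, snr_threshold = 3.0) {
    stopifnot(exclusion_halfwidth >= match_tolerance, baseline_flank > 0,
              match_tolerance > 0, snr_threshold > 0)
    structure(list(match_tolerance = match_tolerance,
                   baseline_flank = baseline_flank,
                   exclusion_halfwidth = exclusion_halfwidth,
                   snr_threshold = snr_threshold),
              class = "PeakConfig")
}

## Coerce the accepted spectrum representations (two-column data.frame or a
## single-spectrum SpectraSet) to wavelength/intensity vectors.
.asSpectrum <- function(spectrum) {
    if (is(spectrum, "SpectraSet")) {
        if (ncol(spectrum) != 1)
            stop("expected a single spectrum; got ", ncol(spectrum))
        list(wavelength = wavelengths(spectrum),
             intensity = as.numeric(spectraMatrix(spectrum)[, 1]))
    } else if (is.data.frame(spectrum) &&
               all(c("wavelength", "intensity") %in% names(spectrum))) {
        list(wavelength = spectrum$wavelength, intensity = spectrum$intensity)
    } else {
        stop("spectrum must be a wavelength/intensity data.frame or a ",
             "single-column SpectraSet")
    }
}

## Flank window indices and the two (position, median) anchors used for the
## local linear baseline around `center`.
.baselineAnchors <- function(wl, y, center, cfg) {
    exL <- center - cfg$exclusion_halfwidth
    exR <- center + cfg$exclusion_halfwidth
    li <- which(wl >= exL - cfg$baseline_flank & wl <= exL)
    ri <- which(wl >= exR & wl <= exR + cfg$baseline_flank)
    if (length(li) == 0 || length(ri) == 0)
        stop(sprintf(
            paste0("baseline window off-grid for center %.2f nm ",
                   "(left [%.2f, %.2f], right [%.2f, %.2f])"),
            center, exL - cfg$baseline_flank, exL, exR,
            exR + cfg$baseline_flank))
    list(left = li, right = ri,
         xL = stats::median(wl[li]), mL = stats::median(y[li]),
         xR = stats::median(wl[ri]), mR = stats::median(y[ri]))
}

#' Estimate the local spectral baseline under a line
#'
#' Linearly interpolates, at \code{center}, between the medians of the two
#' flanking windows \code{[center - exclusion - flank, center - exclusion]}
#' and \code{[center + exclusion, center + exclusion + flank]}. The median
#' makes the estimate robust to neighboring emission lines falling inside a
#' flank.
#'
#' @param spectrum a wavelength/intensity data.frame or single-column
#'   \linkS4class{SpectraSet}.
#' @param center wavelength (nm) at which the baseline is wanted.
#' @param cfg a \code{PeakConfig}.
#' @return Baseline intensity at \code{center}.
#' @export
estimateBaseline <- function(spectrum, center, cfg = peakConfig()) {
    s <- .asSpectrum(spectrum)
    a <- .baselineAnchors(s$wavelength, s$intensity, center, cfg)
    if (a$xR == a$xL)
        return((a$mL + a$mR) / 2)
    a$mL + (a$mR - a$mL) * (center - a$xL) / (a$xR - a$xL)
}

#' Background-corrected peak intensity of one reference line
#'
#' Takes the maximum intensity within \code{center +/- match_tolerance},
#' subtracts the local baseline estimated at the argmax wavelength, and
#' floors the result at zero.
#'
#' @param spectrum a wavelength/intensity data.frame or single-column
#'   \linkS4class{SpectraSet}.
#' @param line one row of a line table (list or data.frame row with
#'   \code{center_wavelength}), or a numeric center wavelength.
#' @param cfg a \code{PeakConfig}.
#' @return Nonnegative background-corrected intensity.
#' @export
extractIntensity <- function(spectrum, line, cfg = peakConfig()) {
    s <- .asSpectrum(spectrum)
    center <- if (is.numeric(line)) line[1] else line$center_wavelength
    win <- which(abs(s$wavelength - center) <= cfg$match_tolerance)
    if (length(win) == 0)
        stop(sprintf("line at %.2f nm falls outside the spectrum grid",
                     center))
    peak <- win[which.max(s$intensity[win])]
    base <- estimateBaseline(spectrum, s$wavelength[peak], cfg)
    max(s$intensity[peak] - base, 0)
}

## Robust local noise sigma: scaled MAD of the flank residuals around the
## interpolated baseline line.
.localNoiseSigma <- function(wl, y, center, cfg) {
    a <- .baselineAnchors(wl, y, center, cfg)
    idx <- c(a$left, a$right)
    slope <- if (a$xR == a$xL) 0 else (a$mR - a$mL) / (a$xR - a$xL)
    fit <- a$mL + slope * (wl[idx] - a$xL)
    1.4826 * stats::median(abs(y[idx] - fit))
}

#' Build the background-corrected intensity table
#'
#' Extracts, for every analysis spectrum and every feature of the library,
#' the background-corrected peak intensity; features with several reference
#' lines take the strongest extracted line (max rule).
#'
#' @param x a \linkS4class{SpectraSet} of analysis spectra sharing one grid.
#' @param library a \linkS4class{LineLibrary}.
#' @param cfg a \code{PeakConfig}.
#' @return An \linkS4class{IntensityTable} (features x spectra) whose rows
#'   follow the library's canonical feature order.
#' @examples
#' spectra <- preprocessSpectra(generateStudy(studyDesign(seed = 1)))
#' tab <- buildIntensityTable(spectra)
#' dim(tab)  # 16 features x 80 spectra
#' @export
buildIntensityTable <- function(x, library = defaultLineLibrary(),
                                cfg = peakConfig()) {
    stopifnot(is(x, "SpectraSet"))
    wl <- wavelengths(x)
    mat <- spectraMatrix(x)
    feats <- library@featureOrder
    out <- matrix(0, nrow = length(feats), ncol = ncol(mat),
                  dimnames = list(feats, colnames(mat)))
    for (f in feats) {
        ln <- .featureLines(library, f)
        vals <- matrix(0, nrow = nrow(ln), ncol = ncol(mat))
        for (i in seq_len(nrow(ln))) {
            center <- ln$center_wavelength[i]
            win <- which(abs(wl - center) <= cfg$match_tolerance)
            if (length(win) == 0)
                stop(sprintf("line %s at %.2f nm outside the cropped range",
                             f, center))
            for (j in seq_len(ncol(mat))) {
                y <- mat[, j]
                peak <- win[which.max(y[win])]
                a <- .baselineAnchors(wl, y, wl[peak], cfg)
                base <- if (a$xR == a$xL) (a$mL + a$mR) / 2 else
                    a$mL + (a$mR - a$mL) * (wl[peak] - a$xL) / (a$xR - a$xL)
                vals[i, j] <- max(y[peak] - base, 0)
            }
        }
        out[f, ] <- apply(vals, 2, max)
    }
    se <- SummarizedExperiment(assays = list(intensity = out),
                               colData = colData(x))
    res <- new("IntensityTable", se)
    metadata(res) <- metadata(x)
    metadata(res)$peak_config <- cfg
    res
}

#' Identify elements present in a spectrum
#'
#' A feature is reported when the background-corrected intensity of at least
#' one of its reference lines exceeds \code{snr_threshold} times the local
#' noise sigma (scaled median absolute deviation of the baseline-flank
#' residuals). With an exactly noise-free flat baseline (sigma = 0) any
#' strictly positive corrected intensity counts as detected. Raising the
#' threshold can only shrink the reported set.
#'
#' @param spectrum a wavelength/intensity data.frame or single-column
#'   \linkS4class{SpectraSet} (cropped to the analysis window).
#' @param library a \linkS4class{LineLibrary}.
#' @param cfg a \code{PeakConfig}.
#' @param include_molecular report molecular-band features (CN) as well;
#'   default TRUE.
#' @return Character vector of detected feature labels, in canonical order.
#' @export
identifyElements <- function(spectrum, library = defaultLineLibrary(),
                             cfg = peakConfig(), include_molecular = TRUE) {
    s <- .asSpectrum(spectrum)
    found <- character(0)
    for (f in library@featureOrder) {
        ln <- .featureLines(library, f)
        if (!include_molecular && any(ln$is_molecular_band)) next
        for (i in seq_len(nrow(ln))) {
            center <- ln$center_wavelength[i]
            win <- which(abs(s$wavelength - center) <= cfg$match_tolerance)
            if (length(win) == 0) next
            peak <- win[which.max(s$intensity[win])]
            ok <- tryCatch({
                base <- estimateBaseline(spectrum, s$wavelength[peak], cfg)
                sig <- max(s$intensity[peak] - base, 0)
                nz <- .localNoiseSigma(s$wavelength, s$intensity,
                                       s$wavelength[peak], cfg)
                sig > cfg$snr_threshold * nz && sig > 0
            }, error = function(e) FALSE)
            if (ok) { found <- c(found, f); break }
        }
    }
    found
}
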