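#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname featureOrder
#' @export
setGeneric("featureOrder", function(x) standardGeneric("featureOrder"))

#' @rdname lineTable
#' @export
setGeneric("lineTable", function(x) standardGeneric("lineTable"))

#' @rdname spectraMatrix
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @rdname SpectralPCA-accessors
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname SpectralPCA-accessors
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname SpectralPCA-accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname ClassifierReport-accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname ClassifierReport-accessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
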