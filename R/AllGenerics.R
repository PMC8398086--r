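#' @include AllClasses.R
NULL

#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))

#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @export
setGeneric("quencherConc", function(object) standardGeneric("quencherConc"))

#' @export
setGeneric("temperatureK", function(object) standardGeneric("temperatureK"))

#' @export
setGeneric("pHValue", function(object) standardGeneric("pHValue"))

#' @export
setGeneric("spectra", function(object) standardGeneric("spectra"))

#' @export
setGeneric("blankSpectrum", function(object) standardGeneric("blankSpectrum"))

#' @export
setGeneric("subtractBlank", function(object, ...) standardGeneric("subtractBlank"))

#' @export
setGeneric("peakIntensities", function(object, ...) standardGeneric("peakIntensities"))

#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @export
setGeneric("mechanism", function(object) standardGeneric("mechanism"))

#' @export
setGeneric("drivingForce", function(object) standardGeneric("drivingForce"))
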