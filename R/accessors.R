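#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for spectra and titration series
#'
#' `wavelengths()` and `intensities()` return the grid and signal of a
#' spectrum; `quencherConc()` the concentration(s) in mol/L;
#' `temperatureK()` and `pHValue()` the shared conditions; `spectra()` and
#' `blankSpectrum()` the components of a [TitrationSeries-class].
#'
#' @param object an [EmissionSpectrum-class] or [TitrationSeries-class].
#' @name spectra-accessors
#' @aliases wavelengths intensities quencherConc temperatureK pHValue
#'   spectra blankSpectrum
NULL

#' @rdname spectra-accessors
#' @export
setMethod("wavelengths", "EmissionSpectrum", function(object) object@wavelength)

#' @rdname spectra-accessors
#' @export
setMethod("intensities", "EmissionSpectrum", function(object) object@intensity)

#' @rdname spectra-accessors
#' @export
setMethod("quencherConc", "EmissionSpectrum",
          function(object) object@quencherConc)

#' @rdname spectra-accessors
#' @export
setMethod("temperatureK", "EmissionSpectrum",
          function(object) object@temperature)

#' @rdname spectra-accessors
#' @export
setMethod("pHValue", "EmissionSpectrum", function(object) object@pH)

#' @rdname spectra-accessors
#' @export
setMethod("spectra", "TitrationSeries", function(object) object@spectra)

#' @rdname spectra-accessors
#' @export
setMethod("blankSpectrum", "TitrationSeries", function(object) object@blank)

#' @rdname spectra-accessors
#' @export
setMethod("quencherConc", "TitrationSeries", function(object)
  vapply(object@spectra, function(s) s@quencherConc, numeric(1)))

#' @rdname spectra-accessors
#' @export
setMethod("temperatureK", "TitrationSeries", function(object)
  object@spectra[[1]]@temperature)

#' @rdname spectra-accessors
#' @export
setMethod("pHValue", "TitrationSeries", function(object)
  object@spectra[[1]]@pH)

#' Accessors for structures and ensembles
#'
#' @param object a [ProteinStructure-class] or [StructureEnsemble-class].
#' @name structure-accessors
#' @aliases atoms frames frameTimes nFrames
NULL

#' @rdname structure-accessors
#' @export
setMethod("atoms", "ProteinStructure", function(object) object@atoms)

#' @rdname structure-accessors
#' @export
setMethod("frames", "StructureEnsemble", function(object) object@frames)

#' @rdname structure-accessors
#' @export
setMethod("frameTimes", "StructureEnsemble", function(object) object@times)

#' @rdname structure-accessors
#' @export
setMethod("nFrames", "StructureEnsemble",
          function(object) length(object@frames))

#' Accessors for fit results
#'
#' @param object a [QuenchingFit-class] or [VantHoffFit-class].
#' @name fit-accessors
#' @aliases mechanism drivingForce
NULL

#' @rdname fit-accessors
#' @export
setMethod("mechanism", "QuenchingFit", function(object) object@mechanism)

#' @rdname fit-accessors
#' @export
setMethod("drivingForce", "VantHoffFit", function(object) object@drivingForce)
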