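## S4 containers for titration spectroscopy, fit results, and structures.

#' EmissionSpectrum: a single emission or absorbance scan
#'
#' Holds one spectrum recorded at a fixed temperature, pH and quencher
#' concentration. Wavelengths are in nm (strictly increasing), intensities in
#' arbitrary fluorescence units (or absorbance units when `kind =
#' "absorbance"`), quencher concentration in mol/L.
#'
#' @slot wavelength numeric, nm, strictly increasing.
#' @slot intensity numeric, same length as `wavelength`, finite.
#' @slot temperature numeric(1), K.
#' @slot pH numeric(1).
#' @slot quencherConc numeric(1), mol/L, `>= 0`.
#' @slot kind `"emission"` or `"absorbance"`.
#'
#' @examples
#' s <- EmissionSpectrum(seq(300, 450), dnorm(seq(300, 450), 337, 25),
#'                       temperature = 298, pH = 7.4, quencherConc = 0)
#' wavelengths(s)[1:3]
#' @export EmissionSpectrum
#' @exportClass EmissionSpectrum
.EmissionSpectrum <- setClass("EmissionSpectrum",
  representation(
    wavelength   = "numeric",
    intensity    = "numeric",
    temperature  = "numeric",
    pH           = "numeric",
    quencherConc = "numeric",
    kind         = "character"
  ),
  prototype(kind = "emission")
)

setValidity("EmissionSpectrum", function(object) {
  msg <- character()
  if (length(object@wavelength) != length(object@intensity))
    msg <- c(msg, "wavelength and intensity must have equal length")
  if (length(object@wavelength) >= 2 && any(diff(object@wavelength) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensities must be finite")
  if (length(object@quencherConc) != 1 || is.na(object@quencherConc) ||
      object@quencherConc < 0)
    msg <- c(msg, "quencherConc must be a single value >= 0")
  if (length(object@temperature) != 1 || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive value (K)")
  if (length(object@pH) != 1)
    msg <- c(msg, "pH must be a single value")
  if (!object@kind %in% c("emission", "absorbance"))
    msg <- c(msg, "kind must be 'emission' or 'absorbance'")
  if (length(msg)) msg else TRUE
})

setClassUnion("EmissionSpectrumOrNULL", c("EmissionSpectrum", "NULL"))

#' @rdname EmissionSpectrum-class
#' @param wavelength,intensity numeric vectors of equal length.
#' @param temperature temperature in K.
#' @param pH solution pH.
#' @param quencherConc quencher concentration in mol/L.
#' @param kind `"emission"` (default) or `"absorbance"`.
#' @return an `EmissionSpectrum`.
EmissionSpectrum <- function(wavelength, intensity, temperature, pH,
                             quencherConc, kind = "emission") {
  .EmissionSpectrum(wavelength = as.numeric(wavelength),
                    intensity = as.numeric(intensity),
                    temperature = as.numeric(temperature),
                    pH = as.numeric(pH),
                    quencherConc = as.numeric(quencherConc),
                    kind = kind)
}

#' TitrationSeries: spectra across a quencher titration
#'
#' An ordered set of [EmissionSpectrum-class] objects recorded at the same
#' temperature, pH and wavelength grid but distinct, ascending quencher
#' concentrations. The first spectrum must be the quencher-free scan (it
#' supplies F0). An optional buffer blank can be attached and subtracted.
#'
#' @slot spectra list of `EmissionSpectrum`, >= 3, ascending distinct
#'   quencher concentrations, first at 0.
#' @slot blank optional `EmissionSpectrum` of the buffer alone (or `NULL`).
#' @slot proteinConc numeric(1), protein concentration in g/L (may be `NA`).
#'
#' @export TitrationSeries
#' @exportClass TitrationSeries
.TitrationSeries <- setClass("TitrationSeries",
  representation(
    spectra     = "list",
    blank       = "EmissionSpectrumOrNULL",
    proteinConc = "numeric"
  ),
  prototype(blank = NULL, proteinConc = NA_real_)
)

setValidity("TitrationSeries", function(object) {
  msg <- character()
  sp <- object@spectra
  if (length(sp) < 3)
    msg <- c(msg, "a titration needs at least 3 spectra")
  if (!all(vapply(sp, is, logical(1), class2 = "EmissionSpectrum")))
    return("all elements of spectra must be EmissionSpectrum objects")
  conc <- vapply(sp, function(s) s@quencherConc, numeric(1))
  if (length(conc) && conc[1] != 0)
    msg <- c(msg, "first spectrum must have quencherConc = 0 (supplies F0)")
  if (length(conc) >= 2 && any(diff(conc) <= 0))
    msg <- c(msg, "quencher concentrations must be distinct and ascending")
  tK <- vapply(sp, function(s) s@temperature, numeric(1))
  pH <- vapply(sp, function(s) s@pH, numeric(1))
  if (length(unique(tK)) > 1)
    msg <- c(msg, "all spectra must share one temperature")
  if (length(unique(pH)) > 1)
    msg <- c(msg, "all spectra must share one pH")
  if (length(sp) >= 2) {
    wl <- sp[[1]]@wavelength
    same <- vapply(sp[-1], function(s)
      length(s@wavelength) == length(wl) && all(s@wavelength == wl),
      logical(1))
    if (!all(same))
      msg <- c(msg, "all spectra must share one wavelength grid")
    if (!is.null(object@blank) &&
        !(length(object@blank@wavelength) == length(wl) &&
          all(object@blank@wavelength == wl)))
      msg <- c(msg, "blank must share the series wavelength grid")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname TitrationSeries-class
#' @param spectra list of [EmissionSpectrum-class] objects.
#' @param blank optional buffer-only spectrum.
#' @param proteinConc protein concentration in g/L.
#' @return a `TitrationSeries`.
TitrationSeries <- function(spectra, blank = NULL, proteinConc = NA_real_) {
  .TitrationSeries(spectra = spectra, blank = blank,
                   proteinConc = as.numeric(proteinConc))
}

#' PeakReading: located emission maximum
#'
#' Result of [extractPeak()]: the wavelength of the (smoothed,
#' parabolically refined) maximum and its interpolated intensity.
#'
#' @slot lambdaMax numeric(1), nm.
#' @slot intensity numeric(1), a.u., `> 0`.
#' @slot atBoundary logical(1), `TRUE` when the maximum sat on the grid edge
#'   and no parabolic refinement was applied.
#' @export PeakReading
#' @exportClass PeakReading
.PeakReading <- setClass("PeakReading",
  representation(lambdaMax = "numeric", intensity = "numeric",
                 atBoundary = "logical"),
  prototype(atBoundary = FALSE)
)

setValidity("PeakReading", function(object) {
  msg <- character()
  if (length(object@lambdaMax) != 1 || !is.finite(object@lambdaMax))
    msg <- c(msg, "lambdaMax must be a single finite value")
  if (length(object@intensity) != 1 || !is.finite(object@intensity) ||
      object@intensity <= 0)
    msg <- c(msg, "peak intensity must be a single positive value")
  if (length(msg)) msg else TRUE
})

#' @rdname PeakReading-class
#' @param lambdaMax peak wavelength, nm.
#' @param intensity peak intensity, a.u.
#' @param atBoundary was the maximum on the grid edge?
PeakReading <- function(lambdaMax, intensity, atBoundary = FALSE) {
  .PeakReading(lambdaMax = as.numeric(lambdaMax),
               intensity = as.numeric(intensity),
               atBoundary = atBoundary)
}

#' QuenchingFit: Stern-Volmer analysis result
#'
#' Ordinary least-squares fit of F0/F against quencher concentration.
#' `ksv` (L/mol) is the slope, `kq = ksv / tau0` the bimolecular quenching
#' rate constant, `intercept` a diagnostic expected near 1.
#'
#' @slot ksv,ksvSE numeric(1), Stern-Volmer constant and its SE, L/mol.
#' @slot kq numeric(1), L/(mol s); always exactly `ksv / tau0`.
#' @slot tau0 numeric(1), unquenched fluorophore lifetime, s.
#' @slot intercept numeric(1), fitted intercept (1 when constrained).
#' @slot r2 numeric(1) in \[0, 1\].
#' @slot mechanism `"static"`, `"dynamic"` or `"indeterminate"`.

#' @exportClass QuenchingFit
.QuenchingFit <- setClass("QuenchingFit",
  representation(ksv = "numeric", ksvSE = "numeric", kq = "numeric",
                 tau0 = "numeric", intercept = "numeric", r2 = "numeric",
                 mechanism = "character")
)

setValidity("QuenchingFit", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@kq, object@ksv / object@tau0)))
    msg <- c(msg, "kq must equal ksv / tau0")
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1 + 1e-12))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (!object@mechanism %in% c("static", "dynamic", "indeterminate"))
    msg <- c(msg, "mechanism must be static, dynamic or indeterminate")
  if (length(msg)) msg else TRUE
})

#' BindingFit: double-logarithmic binding analysis result
#'
#' Fit of log10((F0 - F)/F) against log10\[Q\]: the slope is the apparent
#' number of binding sites `n`, the intercept log10 of the binding constant
#' `kb` (L/mol). `stoichiometry` is `round(n)`.
#'
#' @slot kb numeric(1), binding constant, L/mol, `> 0`.
#' @slot n numeric(1), apparent binding-site number.
#' @slot log10KbSE,nSE numeric(1), regression SEs.
#' @slot r2 numeric(1) in \[0, 1\].
#' @slot stoichiometry integer(1), `round(n)`.

#' @exportClass BindingFit
.BindingFit <- setClass("BindingFit",
  representation(kb = "numeric", n = "numeric", log10KbSE = "numeric",
                 nSE = "numeric", r2 = "numeric", stoichiometry = "integer")
)

setValidity("BindingFit", function(object) {
  msg <- character()
  if (object@kb <= 0) msg <- c(msg, "kb must be positive")
  if (object@stoichiometry != as.integer(round(object@n)))
    msg <- c(msg, "stoichiometry must equal round(n)")
  if (!is.na(object@r2) && (object@r2 < 0 || object@r2 > 1 + 1e-12))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' VantHoffFit: van't Hoff thermodynamic analysis result
#'
#' From a regression of ln Kb on 1/T: enthalpy change `dH = -R * slope`
#' (kJ/mol), entropy change `dS = R * intercept` (J/(mol K)), and per-
#' temperature Gibbs energies `dG = dH - T * dS / 1000` (kJ/mol). The
#' `drivingForce` class follows the sign heuristic of Ross & Subramanian:
#' (dH<0, dS>0) electrostatic; (dH>0, dS>0) hydrophobic; (dH<0, dS<0)
#' hydrogen bond / van der Waals; anything touching zero unclassified.
#'
#' @slot dH,dHSE numeric(1), kJ/mol.
#' @slot dS,dSSE numeric(1), J/(mol K).
#' @slot dG named numeric, kJ/mol, names are temperatures in K.
#' @slot r2 numeric(1) in \[0, 1\] (NA for a 2-point fit).
#' @slot drivingForce one of `"electrostatic"`, `"hydrophobic"`,
#'   `"hbond_vdw"`, `"unclassified"`.

#' @exportClass VantHoffFit
.VantHoffFit <- setClass("VantHoffFit",
  representation(dH = "numeric", dS = "numeric", dHSE = "numeric",
                 dSSE = "numeric", dG = "numeric", r2 = "numeric",
                 drivingForce = "character")
)

setValidity("VantHoffFit", function(object) {
  msg <- character()
  if (length(object@dG)) {
    tK <- as.numeric(names(object@dG))
    expect <- object@dH - tK * object@dS / 1000
    if (any(abs(expect - object@dG) > 1e-9 * pmax(1, abs(expect))))
      msg <- c(msg, "dG entries must equal dH - T * dS/1000")
  }
  if (!object@drivingForce %in%
      c("electrostatic", "hydrophobic", "hbond_vdw", "unclassified"))
    msg <- c(msg, "unknown drivingForce class")
  if (length(msg)) msg else TRUE
})

#' ProteinStructure: atoms of one model
#'
#' A flat atom table (one row per atom) with Angstrom coordinates.
#' `elety` is the PDB atom name (N, CA, C, O, ...), `resid` the residue
#' name, `resno` the residue number, `het` flags non-protein (HETATM)
#' records.
#'
#' @slot atoms data.frame with columns `elety`, `elesy`, `resid`, `chain`,
#'   `resno`, `x`, `y`, `z`, `het`.
#' @export ProteinStructure
#' @exportClass ProteinStructure
.ProteinStructure <- setClass("ProteinStructure",
  representation(atoms = "data.frame")
)

setValidity("ProteinStructure", function(object) {
  need <- c("elety", "elesy", "resid", "chain", "resno", "x", "y", "z", "het")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    return(paste("atom table lacks columns:", paste(miss, collapse = ", ")))
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && any(!is.finite(xyz)))
    return("coordinates must be finite")
  TRUE
})

#' @rdname ProteinStructure-class
#' @param atoms atom data.frame (see slots).
ProteinStructure <- function(atoms) {
  atoms$resno <- as.integer(atoms$resno)
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$elesy))
    atoms$elesy <- substr(trimws(atoms$elety), 1, 1)
  rownames(atoms) <- NULL
  .ProteinStructure(atoms = atoms)
}

#' StructureEnsemble: ordered frames of one structure
#'
#' A trajectory: frames share an identical atom roster; `times` (ps) are
#' strictly increasing.
#'
#' @slot frames list of [ProteinStructure-class] with identical rosters.
#' @slot times numeric, ps, strictly increasing, same length as frames.
#' @export StructureEnsemble
#' @exportClass StructureEnsemble
.StructureEnsemble <- setClass("StructureEnsemble",
  representation(frames = "list", times = "numeric")
)

setValidity("StructureEnsemble", function(object) {
  msg <- character()
  if (length(object@frames) != length(object@times))
    msg <- c(msg, "times must match frames in length")
  if (length(object@times) >= 2 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@frames) >= 2) {
    ref <- object@frames[[1]]@atoms
    key <- function(at) paste(at$chain, at$resno, at$elety)
    ok <- vapply(object@frames[-1], function(f)
      identical(key(f@atoms), key(ref)), logical(1))
    if (!all(ok)) msg <- c(msg, "frames must share one atom roster")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname StructureEnsemble-class
#' @param frames list of [ProteinStructure-class] objects.
#' @param times frame times in ps; defaults to 0, 1, 2, ...
StructureEnsemble <- function(frames, times = seq_along(frames) - 1) {
  .StructureEnsemble(frames = frames, times = as.numeric(times))
}

## ---- show methods -------------------------------------------------------

setMethod("show", "EmissionSpectrum", function(object) {
  cat(sprintf("%s spectrum: %d points, %.0f-%.0f nm, T=%g K, pH=%g, [Q]=%g M\n",
              object@kind, length(object@wavelength),
              min(object@wavelength), max(object@wavelength),
              object@temperature, object@pH, object@quencherConc))
})

setMethod("show", "TitrationSeries", function(object) {
  conc <- vapply(object@spectra, function(s) s@quencherConc, numeric(1))
  cat(sprintf("TitrationSeries: %d spectra, T=%g K, pH=%g\n",
              length(object@spectra), object@spectra[[1]]@temperature,
              object@spectra[[1]]@pH))
  cat("  [Q] (mol/L):", paste(signif(conc, 3), collapse = ", "), "\n")
  cat("  blank:", if (is.null(object@blank)) "none" else "present", "\n")
})

setMethod("show", "QuenchingFit", function(object) {
  cat(sprintf("Stern-Volmer fit: Ksv = %.4g +/- %.2g L/mol (R2 = %.4f)\n",
              object@ksv, object@ksvSE, object@r2))
  cat(sprintf("  Kq = %.4g L/(mol s) at tau0 = %g s; mechanism: %s\n",
              object@kq, object@tau0, object@mechanism))
})

setMethod("show", "BindingFit", function(object) {
  cat(sprintf("Double-log binding fit: Kb = %.4g L/mol, n = %.3f (R2 = %.4f)\n",
              object@kb, object@n, object@r2))
  cat(sprintf("  stoichiometry (round(n)) = %d\n", object@stoichiometry))
})

setMethod("show", "VantHoffFit", function(object) {
  cat(sprintf("van't Hoff fit: dH = %.3f kJ/mol, dS = %.3f J/(mol K)\n",
              object@dH, object@dS))
  for (tn in names(object@dG))
    cat(sprintf("  dG(%s K) = %.3f kJ/mol\n", tn, object@dG[[tn]]))
  cat("  driving force:", object@drivingForce, "\n")
})

setMethod("show", "ProteinStructure", function(object) {
  at <- object@atoms
  cat(sprintf("ProteinStructure: %d atoms, %d residues, chains: %s\n",
              nrow(at), length(unique(paste(at$chain, at$resno))),
              paste(unique(at$chain), collapse = ",")))
})

setMethod("show", "StructureEnsemble", function(object) {
  cat(sprintf("StructureEnsemble: %d frames x %d atoms, t = %g..%g ps\n",
              length(object@frames),
              if (length(object@frames)) nrow(object@frames[[1]]@atoms) else 0,
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA))
})
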