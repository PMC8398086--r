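## Seeded generators for titration spectra and van't Hoff Kb series with
## known ground truth. Every generator is a pure function of (truth, seed):
## RNG state of the session is saved and restored around each call.

#' QuenchTruth: ground truth for a synthetic titration
#'
#' Exactly one quenching law is active: Stern-Volmer mode (`ksv` set,
#' peak amplitude F = F0 / (1 + Ksv \[Q\])) or binding mode (`kb` and `n`
#' set, F = F0 / (1 + Kb \[Q\]^n)). The two coincide when n = 1.
#'
#' @slot f0Peak numeric(1), unquenched peak amplitude, a.u., > 0.
#' @slot ksv numeric, L/mol (length 0 when binding mode is active).
#' @slot kb numeric, L/mol (length 0 when Stern-Volmer mode is active).
#' @slot n numeric, binding-site number (with `kb`).
#' @slot lambdaCenter numeric(1), emission peak centre, nm.
#' @slot sigma numeric(1), Gaussian band width, nm, > 0.
#' @slot noiseSD numeric(1), additive Gaussian noise SD, a.u., >= 0.

#' @exportClass QuenchTruth
.QuenchTruth <- setClass("QuenchTruth",
  representation(f0Peak = "numeric", ksv = "numeric", kb = "numeric",
                 n = "numeric", lambdaCenter = "numeric", sigma = "numeric",
                 noiseSD = "numeric")
)

setValidity("QuenchTruth", function(object) {
  msg <- character()
  svMode <- length(object@ksv) == 1
  kbMode <- length(object@kb) == 1 && length(object@n) == 1
  if (svMode == kbMode)
    msg <- c(msg, "exactly one of ksv-mode or (kb, n)-mode must be active")
  if (object@f0Peak <= 0) msg <- c(msg, "f0Peak must be positive")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname QuenchTruth-class
#' @param f0Peak unquenched peak amplitude (a.u.).
#' @param ksv Stern-Volmer constant, L/mol (exclusive with `kb`/`n`).
#' @param kb,n binding constant (L/mol) and site number.
#' @param lambdaCenter emission peak centre, nm (337 is typical of casein
#'   tryptophan emission at pH 7.4; 334 at pH 2.0).
#' @param sigma Gaussian band width, nm.
#' @param noiseSD additive noise SD, a.u.
#' @return a `QuenchTruth`.
#' @export
quenchTruth <- function(f0Peak = 1000, ksv = NULL, kb = NULL, n = NULL,
                        lambdaCenter = 337, sigma = 25, noiseSD = 0) {
  .QuenchTruth(f0Peak = as.numeric(f0Peak),
               ksv = as.numeric(ksv %||% numeric()),
               kb = as.numeric(kb %||% numeric()),
               n = as.numeric(n %||% numeric()),
               lambdaCenter = as.numeric(lambdaCenter),
               sigma = as.numeric(sigma), noiseSD = as.numeric(noiseSD))
}

#' ThermoTruth: ground truth for a van't Hoff series
#'
#' @slot dH numeric(1), kJ/mol.
#' @slot dS numeric(1), J/(mol K).
#' @slot temperatures numeric, K, >= 2 distinct values.

#' @exportClass ThermoTruth
.ThermoTruth <- setClass("ThermoTruth",
  representation(dH = "numeric", dS = "numeric", temperatures = "numeric")
)

setValidity("ThermoTruth", function(object) {
  if (length(unique(object@temperatures)) < 2)
    return("need at least 2 distinct temperatures")
  TRUE
})

#' @rdname ThermoTruth-class
#' @param dH enthalpy change, kJ/mol.
#' @param dS entropy change, J/(mol K).
#' @param temperatures temperatures, K.
#' @export
thermoTruth <- function(dH, dS, temperatures = c(298, 305, 312)) {
  .ThermoTruth(dH = as.numeric(dH), dS = as.numeric(dS),
               temperatures = as.numeric(temperatures))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## run expr under a private seeded RNG stream, restoring session state
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Generate a synthetic emission titration
#'
#' Builds one Gaussian emission band per quencher concentration. The peak
#' amplitude follows the active quenching law of `truth` exactly, so the
#' downstream Stern-Volmer or double-log fit recovers the ground truth to
#' numerical precision when `noiseSD = 0`. Noise is additive Gaussian under
#' the given seed; with `noiseSD = 0` the output is bit-reproducible and
#' independent of the seed.
#'
#' Defaults mirror a casein-curcumin style titration: concentrations
#' \{0, 2, 4, 6, 8, 10\} x 1e-6 mol/L on a 300-450 nm grid at 1 nm steps.
#'
#' @param truth a [QuenchTruth-class].
#' @param concs ascending quencher concentrations, mol/L, first must be 0.
#' @param temperature K.
#' @param pH solution pH.
#' @param grid wavelength grid, nm.
#' @param seed integer seed for the noise stream (required; unused when
#'   `noiseSD = 0`).
#' @param blankLevel constant buffer baseline; when > 0 a flat blank
#'   spectrum at this level is attached and added to every scan.
#' @return a [TitrationSeries-class].
#' @examples
#' tr <- quenchTruth(ksv = 6.28e4)
#' ser <- generateEmissionTitration(tr, seed = 1)
#' f <- peakIntensities(ser)
#' f[1] / f[6]   # 1 + Ksv * 1e-5 = 1.628
#' @export
generateEmissionTitration <- function(truth,
                                      concs = c(0, 2, 4, 6, 8, 10) * 1e-6,
                                      temperature = 298, pH = 7.4,
                                      grid = seq(300, 450, by = 1),
                                      seed, blankLevel = 0) {
  stopifnot(is(truth, "QuenchTruth"))
  if (concs[1] != 0) stop("first concentration must be 0 (supplies F0)")
  if (any(diff(concs) <= 0)) stop("concentrations must be ascending")
  amp <- function(q) {
    if (length(truth@ksv) == 1) truth@f0Peak / (1 + truth@ksv * q)
    else truth@f0Peak / (1 + truth@kb * q^truth@n)
  }
  shape <- exp(-(grid - truth@lambdaCenter)^2 / (2 * truth@sigma^2))
  .with_seed(seed, {
    sp <- lapply(concs, function(q) {
      y <- amp(q) * shape + blankLevel
      if (truth@noiseSD > 0)
        y <- y + stats::rnorm(length(grid), sd = truth@noiseSD)
      EmissionSpectrum(grid, y, temperature, pH, q)
    })
    blank <- NULL
    if (blankLevel > 0)
      blank <- EmissionSpectrum(grid, rep(blankLevel, length(grid)),
                                temperature, pH, 0)
    TitrationSeries(sp, blank = blank)
  })
}

#' Generate a binding-constant series from thermodynamic ground truth
#'
#' Forward van't Hoff law: Kb(T) = exp(-dH/(R T) + dS/R), with R = 8.314
#' J/(mol K) and dH converted from kJ/mol to J/mol internally. Feeding the
#' result to [fitVantHoff()] recovers (dH, dS) exactly (the law is
#' log-linear).
#'
#' @param truth a [ThermoTruth-class].
#' @return data.frame with columns `temperature_K` and `Kb`.
#' @examples
#' generateKbSeries(thermoTruth(dH = -8.43, dS = 59.93))
#' @export
generateKbSeries <- function(truth) {
  stopifnot(is(truth, "ThermoTruth"))
  R <- 8.314
  tK <- truth@temperatures
  kb <- exp(-truth@dH * 1000 / (R * tK) + truth@dS / R)
  data.frame(temperature_K = tK, Kb = kb)
}
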