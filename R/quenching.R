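## Stage 1 of the inference chain: Stern-Volmer quenching analysis,
## quenching-mechanism classification, and the double-logarithmic binding
## fit. Both fits are ordinary least squares on linearised laws, so
## noiseless synthetic input is recovered to numerical precision.

#' Stern-Volmer quenching fit
#'
#' Extracts the peak intensity F of every spectrum, forms F0/F, and
#' regresses it on quencher concentration: F0/F = 1 + Ksv \[Q\]. By default
#' the intercept is left free as a normalisation diagnostic (it should come
#' out near 1); `constrainedIntercept = TRUE` forces the literal law by
#' regressing F0/F - 1 on \[Q\] without an intercept. The bimolecular
#' quenching rate constant is Kq = Ksv / tau0; values far above the
#' diffusion-controlled limit (about 2e10 L/(mol s)) indicate static
#' (ground-state complex) rather than collisional quenching.
#'
#' @param series a [TitrationSeries-class] with >= 3 concentrations
#'   including 0.
#' @param tau0 unquenched fluorophore lifetime, s (default 1e-8).
#' @param threshold diffusion-limit threshold for mechanism
#'   classification, L/(mol s).
#' @param constrainedIntercept force the intercept to 1?
#' @param window peak-smoothing half-width, nm (see [extractPeak()]).
#' @return a [QuenchingFit-class].
#' @examples
#' ser <- generateEmissionTitration(quenchTruth(ksv = 6.28e4), seed = 1)
#' fitSternVolmer(ser)
#' @export
fitSternVolmer <- function(series, tau0 = 1e-8, threshold = 2.0e10,
                           constrainedIntercept = FALSE, window = 2) {
  stopifnot(is(series, "TitrationSeries"))
  f <- peakIntensities(series, window = window)
  q <- quencherConc(series)
  if (length(q) < 3) stop("need at least 3 concentrations")
  y <- f[1] / f
  if (constrainedIntercept) {
    fit <- stats::lm(I(y - 1) ~ q - 1)
    sfit <- suppressWarnings(summary(fit))   # noiseless input: perfect fit
    slope <- stats::coef(fit)[[1]]
    se <- sfit$coefficients[1, 2]
    intercept <- 1
    r2 <- sfit$r.squared
  } else {
    fit <- stats::lm(y ~ q)
    sfit <- suppressWarnings(summary(fit))
    cf <- sfit$coefficients
    slope <- cf[2, 1]
    se <- cf[2, 2]
    intercept <- cf[1, 1]
    r2 <- sfit$r.squared
  }
  if (is.nan(se)) se <- 0
  if (slope + 2 * se <= 0)
    stop("no quenching detected: Stern-Volmer slope is not positive")
  kq <- slope / tau0
  mech <- .classify_mechanism(kq, se / tau0, threshold)
  .QuenchingFit(ksv = slope, ksvSE = se, kq = kq, tau0 = tau0,
                intercept = intercept, r2 = min(max(r2, 0), 1),
                mechanism = mech)
}

.classify_mechanism <- function(kq, kqSE, threshold) {
  if (abs(kq - threshold) <= kqSE || kq == threshold) "indeterminate"
  else if (kq > threshold) "static"
  else "dynamic"
}

#' Classify the quenching mechanism
#'
#' Compares Kq with the maximum diffusion-collision quenching constant
#' (default 2.0e10 L/(mol s)): above it the quenching must be static
#' (ground-state complex), below it dynamic (collisional). Within one
#' standard error of the threshold the call is "indeterminate".
#'
#' @param fit a [QuenchingFit-class].
#' @param threshold diffusion limit, L/(mol s).
#' @return `"static"`, `"dynamic"` or `"indeterminate"`.
#' @export
classifyMechanism <- function(fit, threshold = 2.0e10) {
  stopifnot(is(fit, "QuenchingFit"))
  .classify_mechanism(fit@kq, fit@ksvSE / fit@tau0, threshold)
}

#' Double-logarithmic binding fit
#'
#' Regresses log10((F0 - F)/F) on log10\[Q\] over the nonzero
#' concentrations: the slope is the apparent binding-site number n, the
#' intercept log10 of the binding constant Kb. Requires F < F0 at every
#' nonzero concentration (otherwise the offending concentration is named).
#'
#' @param series a [TitrationSeries-class].
#' @param window peak-smoothing half-width, nm.
#' @return a [BindingFit-class].
#' @examples
#' ser <- generateEmissionTitration(quenchTruth(kb = 6.48e4, n = 1.13),
#'                                  seed = 1)
#' fitDoubleLog(ser)
#' @export
fitDoubleLog <- function(series, window = 2) {
  stopifnot(is(series, "TitrationSeries"))
  f <- peakIntensities(series, window = window)
  q <- quencherConc(series)
  f0 <- f[[1]]
  nz <- which(q > 0)
  if (length(nz) < 3) stop("need at least 3 nonzero concentrations")
  bad <- nz[f[nz] >= f0]
  if (length(bad))
    stop("no quenching at [Q] = ",
         paste(format(q[bad], digits = 4), collapse = ", "),
         " mol/L: F >= F0 there")
  x <- log10(q[nz])
  y <- log10((f0 - f[nz]) / f[nz])
  fit <- stats::lm(y ~ x)
  sfit <- suppressWarnings(summary(fit))
  cf <- sfit$coefficients
  n <- cf[2, 1]
  .BindingFit(kb = 10^cf[1, 1], n = n, log10KbSE = cf[1, 2], nSE = cf[2, 2],
              r2 = min(max(sfit$r.squared, 0), 1),
              stoichiometry = as.integer(round(n)))
}

#' Analyse a full titration
#'
#' Orchestrates stage 1: subtracts the blank when one is attached, runs
#' the Stern-Volmer and double-log fits, and classifies the mechanism.
#' A bare 3-point series triggers a low-point-count warning.
#'
#' @param series a [TitrationSeries-class].
#' @param tau0,threshold,constrainedIntercept,window passed to the fits.
#' @return list with elements `quenching` ([QuenchingFit-class]) and
#'   `binding` ([BindingFit-class]).
#' @export
analyzeTitration <- function(series, tau0 = 1e-8, threshold = 2.0e10,
                             constrainedIntercept = FALSE, window = 2) {
  stopifnot(is(series, "TitrationSeries"))
  if (!is.null(series@blank)) series <- subtractBlank(series)
  if (length(series@spectra) <= 4)
    warning("only ", length(series@spectra),
            " concentrations: fits will have few degrees of freedom")
  list(
    quenching = fitSternVolmer(series, tau0 = tau0, threshold = threshold,
                               constrainedIntercept = constrainedIntercept,
                               window = window),
    binding = fitDoubleLog(series, window = window)
  )
}
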