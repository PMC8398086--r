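## Stage 2: van't Hoff thermodynamics, Gibbs energies, driving-force
## classification, and docking-energy <-> dissociation-constant conversion.
## All internal arithmetic is in J; dH is reported in kJ/mol and dS in
## J/(mol K), the units this literature prints.

.R_GAS <- 8.314            # J/(mol K)
.R_KCAL <- 1.987207e-3     # kcal/(mol K), docking-score convention

#' Van't Hoff fit of binding constants across temperature
#'
#' Ordinary least squares of ln Kb on 1/T: ln Kb = -dH/(R T) + dS/R. The
#' slope gives the enthalpy change dH = -R * slope (reported in kJ/mol),
#' the intercept the entropy change dS = R * intercept (J/(mol K));
#' R = 8.314 J/(mol K). Gibbs energies dG = dH - T dS/1000 (kJ/mol) are
#' evaluated at every input temperature, and the (dH, dS) sign pattern is
#' mapped to a dominant driving force via [classifyDrivingForce()].
#'
#' @param temperature numeric, K, >= 2 distinct values.
#' @param kb numeric, binding constants, L/mol, > 0.
#' @param weights optional regression weights (e.g. from Kb standard
#'   errors); default unweighted.
#' @return a [VantHoffFit-class].
#' @examples
#' fitVantHoff(c(298, 305, 312), c(3.98, 3.90, 3.41) * 1e4)
#' @export
fitVantHoff <- function(temperature, kb, weights = NULL) {
  if (length(temperature) != length(kb))
    stop("temperature and kb must have equal length")
  if (length(unique(temperature)) < 2)
    stop("need at least 2 distinct temperatures")
  if (any(kb <= 0)) stop("binding constants must be positive")
  x <- 1 / temperature
  y <- log(kb)
  fit <- if (is.null(weights)) stats::lm(y ~ x)
         else stats::lm(y ~ x, weights = weights)
  sfit <- suppressWarnings(summary(fit))     # 2-point fits are exact
  cf <- sfit$coefficients
  dH <- -.R_GAS * cf[2, 1] / 1000           # kJ/mol
  dS <- .R_GAS * cf[1, 1]                   # J/(mol K)
  dHSE <- .R_GAS * cf[2, 2] / 1000
  dSSE <- .R_GAS * cf[1, 2]
  if (is.nan(dHSE)) dHSE <- 0
  if (is.nan(dSSE)) dSSE <- 0
  tK <- sort(unique(temperature))
  dG <- stats::setNames(gibbsEnergy(dH, dS, tK), format(tK))
  r2 <- sfit$r.squared
  .VantHoffFit(dH = dH, dS = dS, dHSE = dHSE, dSSE = dSSE, dG = dG,
               r2 = min(max(r2, 0), 1),
               drivingForce = classifyDrivingForce(dH, dS))
}

#' Gibbs free energy of binding
#'
#' dG = dH - T dS / 1000, with dH in kJ/mol and dS in J/(mol K); the
#' division by 1000 harmonises the units so dG comes out in kJ/mol.
#'
#' @param dH enthalpy change, kJ/mol.
#' @param dS entropy change, J/(mol K).
#' @param temperature K, > 0.
#' @return dG in kJ/mol (vectorised over `temperature`).
#' @examples
#' gibbsEnergy(-8.43, 59.93, 298)   # -26.29 kJ/mol
#' @export
gibbsEnergy <- function(dH, dS, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive (K)")
  dH - temperature * dS / 1000
}

#' Classify the dominant binding driving force
#'
#' Ross-Subramanian sign heuristic: dH < 0 with dS > 0 points to
#' electrostatic interaction; dH > 0 with dS > 0 to hydrophobic
#' interaction; dH < 0 with dS < 0 to hydrogen bonding / van der Waals.
#' A zero on either axis makes the sign indeterminate: "unclassified".
#'
#' @param dH enthalpy change, kJ/mol.
#' @param dS entropy change, J/(mol K).
#' @return one of `"electrostatic"`, `"hydrophobic"`, `"hbond_vdw"`,
#'   `"unclassified"`.
#' @examples
#' classifyDrivingForce(-8.43, 59.93)   # electrostatic
#' @export
classifyDrivingForce <- function(dH, dS) {
  if (dH < 0 && dS > 0) "electrostatic"
  else if (dH > 0 && dS > 0) "hydrophobic"
  else if (dH < 0 && dS < 0) "hbond_vdw"
  else "unclassified"
}

#' Convert a docking binding energy to a dissociation constant
#'
#' Kd = exp(Eb / (R' T)) with R' = 1.987207e-3 kcal/(mol K), the
#' convention docking tools use to relate a score in kcal/mol to a
#' dissociation constant in mol/L. Strictly increasing in Eb and
#' multiplicative: Kd(a + b) = Kd(a) * Kd(b) at fixed T.
#'
#' @param eb binding energy, kcal/mol (negative = favourable).
#' @param temperature K (default 298.15).
#' @return Kd in mol/L (vectorised over `eb`).
#' @examples
#' ebToKd(-7.53)   # about 3.0e-6 mol/L
#' @export
ebToKd <- function(eb, temperature = 298.15) {
  if (any(temperature <= 0)) stop("temperature must be positive (K)")
  exp(eb / (.R_KCAL * temperature))
}

#' Run the thermodynamics stage over a binding table
#'
#' One van't Hoff fit per pH. Input is a long table with columns `pH`,
#' `temperature_K` and `Kb`; a pH represented at fewer than 2 temperatures
#' is skipped with a warning.
#'
#' @param bindingTable data.frame with columns `pH`, `temperature_K`, `Kb`.
#' @return named list (by pH) of [VantHoffFit-class] objects.
#' @examples
#' tab <- data.frame(pH = rep(c(7.4, 2.0), each = 3),
#'                   temperature_K = rep(c(298, 305, 312), 2),
#'                   Kb = c(3.98, 3.90, 3.41, 6.48, 6.17, 5.73) * 1e4)
#' runThermoStage(tab)
#' @export
runThermoStage <- function(bindingTable) {
  need <- c("pH", "temperature_K", "Kb")
  miss <- setdiff(need, names(bindingTable))
  if (length(miss))
    stop("binding table lacks column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (p in unique(bindingTable$pH)) {
    sub <- bindingTable[bindingTable$pH == p, ]
    if (length(unique(sub$temperature_K)) < 2) {
      warning("pH ", p, ": fewer than 2 temperatures, skipped")
      next
    }
    out[[format(p)]] <- fitVantHoff(sub$temperature_K, sub$Kb)
  }
  out
}
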