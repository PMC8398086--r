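# Shared fixtures. The reference constants are the study's printed binding
# table for the casein-curcumin system: per (pH, T) Stern-Volmer and
# binding parameters, and the per-pH thermodynamic parameters.

ref_table1 <- data.frame(
  pH  = c(7.4, 7.4, 7.4, 2.0, 2.0, 2.0),
  temperature_K = c(298, 305, 312, 298, 305, 312),
  Ksv = c(3.67, 3.49, 3.42, 6.28, 5.98, 5.74) * 1e4,   # L/mol
  Kq  = c(3.67, 3.49, 3.42, 6.28, 5.98, 5.74) * 1e12,  # L/(mol s)
  n   = c(1.59, 1.35, 1.01, 1.13, 1.17, 1.07),
  Kb  = c(3.98, 3.90, 3.41, 6.48, 6.17, 5.73) * 1e4    # L/mol
)

ref_thermo <- data.frame(
  pH = c(7.4, 2.0),
  dH = c(-8.43, -6.84),    # kJ/mol
  dS = c(59.93, 69.21)     # J/(mol K)
)

# scale every intensity in a series by a constant
scale_series <- function(series, fac) {
  sp <- lapply(spectra(series), function(s)
    EmissionSpectrum(wavelengths(s), fac * intensities(s),
                     temperatureK(s), pHValue(s), quencherConc(s)))
  TitrationSeries(sp)
}

# two ideal antiparallel strands registered so the central residues form
# Kabsch-Sander bridges (inter-strand spacing ~4.8 Angstrom)
make_sheet_fixture <- function() {
  s1 <- buildIdealChain(6, -139, 135, 180, chain = "A")
  s2 <- applyRigidMotion(buildIdealChain(6, -139, 135, 180, chain = "B"),
                         rotation = c(180, 0, 0),
                         translation = c(-2, 4.8, -1))
  ProteinStructure(rbind(atoms(s1), atoms(s2)))
}

# brute-force superposition oracle: minimise RMSD over rotations by a
# coarse Euler-angle grid followed by local refinement (independent of the
# closed-form Kabsch path)
grid_rmsd_oracle <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(a) {
    a <- a * pi / 180
    cx <- cos(a[1]); sx <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  }
  f <- function(a) sqrt(sum((Q0 %*% t(rot(a)) - P0)^2) / nrow(P0))
  grid <- as.matrix(expand.grid(seq(0, 345, 15), seq(0, 345, 15),
                                seq(0, 345, 15)))
  vals <- apply(grid, 1, f)
  starts <- grid[order(vals)[1:5], , drop = FALSE]
  best <- Inf
  for (k in seq_len(nrow(starts))) {
    o <- stats::optim(starts[k, ], f, control = list(reltol = 1e-14,
                                                     maxit = 5000))
    best <- min(best, o$value)
  }
  best
}

# tiny asymmetric point sets for the superposition oracle
toy_point_sets <- function(seed) {
  set.seed(seed)
  P <- matrix(stats::rnorm(12, sd = 2), ncol = 3)
  Q <- P + matrix(stats::rnorm(12, sd = 0.4), ncol = 3)
  list(P = P, Q = Q)
}

structure_from_points <- function(M, elety = "CA") {
  ProteinStructure(data.frame(
    elety = elety, elesy = "C", resid = "ALA", chain = "A",
    resno = seq_len(nrow(M)), x = M[, 1], y = M[, 2], z = M[, 3],
    het = FALSE, stringsAsFactors = FALSE))
}
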