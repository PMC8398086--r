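## Toy-structure generators: ideal poly-alanine backbones, seeded rigid
## motions with optional jitter, and minimal hydrogen-bond fixtures. These
## give the structural metrics a ground truth that needs no downloads.

## standard backbone geometry (Engh-Huber-style averages)
.BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.01,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

#' Build an ideal poly-alanine backbone
#'
#' Sequential internal-to-Cartesian construction of an N, H, CA, C, O
#' backbone in which every residue takes the same (phi, psi, omega). The
#' canonical alpha-helix is (-57, -47, 180); an extended strand is around
#' (-120, 120, 180). The amide H is placed in the peptide plane opposite
#' the bisector of the two N bonds at 1.01 Angstrom (residue 1 gets none).
#'
#' @param nRes number of residues, >= 2.
#' @param phi,psi,omega backbone dihedrals, degrees.
#' @param chain chain identifier.
#' @return a [ProteinStructure-class].
#' @examples
#' helix <- buildIdealChain(20, -57, -47)
#' @export
buildIdealChain <- function(nRes, phi = -57, psi = -47, omega = 180,
                            chain = "A") {
  if (nRes < 2) stop("need at least 2 residues")
  g <- .BB_GEOM
  ## seed residue 1 in the xy-plane
  N <- list(); CA <- list(); C <- list(); O <- list(); H <- list()
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq(2, nRes)) {
    N[[i]] <- .place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                          g$c_n, g$ang_ca_c_n, psi)
    CA[[i]] <- .place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                           g$n_ca, g$ang_c_n_ca, omega)
    C[[i]] <- .place_atom(C[[i - 1]], N[[i]], CA[[i]],
                          g$ca_c, g$ang_n_ca_c, phi)
  }
  for (i in seq_len(nRes)) {
    ## carbonyl O trans to the next amide N (psi + 180 about N-CA-C)
    O[[i]] <- .place_atom(N[[i]], CA[[i]], C[[i]],
                          g$c_o, g$ang_ca_c_o, psi + 180)
    if (i >= 2) {
      u1 <- .unit(N[[i]] - C[[i - 1]])
      u2 <- .unit(N[[i]] - CA[[i]])
      H[[i]] <- N[[i]] + g$n_h * .unit(u1 + u2)
    }
  }
  rows <- list()
  for (i in seq_len(nRes)) {
    add <- function(name, p) {
      rows[[length(rows) + 1]] <<- data.frame(
        elety = name, elesy = substr(name, 1, 1), resid = "ALA",
        chain = chain, resno = i, x = p[1], y = p[2], z = p[3],
        het = FALSE, stringsAsFactors = FALSE)
    }
    add("N", N[[i]])
    if (i >= 2) add("H", H[[i]])
    add("CA", CA[[i]])
    add("C", C[[i]])
    add("O", O[[i]])
  }
  ProteinStructure(do.call(rbind, rows))
}

#' Apply a rigid motion (plus optional jitter) to a structure
#'
#' Coordinates are rotated (successive rotations about the x, y, z axes, in
#' degrees), then translated, then optionally perturbed by per-coordinate
#' Gaussian jitter under the given seed. With `jitterSD = 0` the motion is
#' exactly rigid, so superposition RMSD against the original is 0.
#'
#' @param structure a [ProteinStructure-class].
#' @param rotation numeric(3), Euler angles in degrees.
#' @param translation numeric(3), Angstrom.
#' @param jitterSD per-coordinate Gaussian SD, Angstrom.
#' @param seed integer seed for the jitter stream.
#' @return a transformed [ProteinStructure-class].
#' @export
applyRigidMotion <- function(structure, rotation = c(0, 0, 0),
                             translation = c(0, 0, 0), jitterSD = 0,
                             seed = NULL) {
  stopifnot(is(structure, "ProteinStructure"))
  xyz <- .coords(structure)
  R <- .euler_matrix(rotation)
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, translation, `+`)
  if (jitterSD > 0) {
    if (is.null(seed)) stop("a seed is required when jitterSD > 0")
    xyz <- .with_seed(seed,
      xyz + matrix(stats::rnorm(length(xyz), sd = jitterSD), ncol = 3))
  }
  .set_coords(structure, xyz)
}

#' Build a minimal hydrogen-bond fixture
#'
#' Two residues: a donor amide (N with its H) and an acceptor carbonyl
#' (C=O), arranged so the donor-acceptor distance is exactly `dDA` and the
#' D-H...A angle (vertex at H) exactly `angleDHA`. Used to probe
#' [detectHbonds()] criteria.
#'
#' @param dDA donor-acceptor (N...O) distance, Angstrom, > 0.
#' @param angleDHA angle at the hydrogen, degrees, in (0, 180].
#' @return a [ProteinStructure-class] with 2 residues.
#' @examples
#' nrow(detectHbonds(makeHbondFixture(2.9, 180)))  # 1
#' @export
makeHbondFixture <- function(dDA, angleDHA) {
  if (dDA <= 0) stop("dDA must be positive")
  if (angleDHA <= 0 || angleDHA > 180) stop("angleDHA must be in (0, 180]")
  rNH <- .BB_GEOM$n_h
  N <- c(0, 0, 0)
  Hp <- c(rNH, 0, 0)
  alpha <- (180 - angleDHA) * pi / 180
  ## solve |N - A| = dDA with A = H + r (cos alpha, sin alpha, 0), r > 0
  bq <- 2 * rNH * cos(alpha)
  cq <- rNH^2 - dDA^2
  disc <- bq^2 - 4 * cq
  if (disc < 0) stop("geometrically infeasible distance/angle combination")
  r <- (-bq + sqrt(disc)) / 2
  if (r <= 0) stop("geometrically infeasible distance/angle combination")
  A <- Hp + r * c(cos(alpha), sin(alpha), 0)
  ## acceptor antecedent carbon: extend away from the hydrogen
  Cc <- A + .BB_GEOM$c_o * .unit(A - Hp)
  ## a CA on the donor so the residue looks residue-like
  CAd <- c(-0.77, -1.24, 0)
  df <- data.frame(
    elety = c("N", "H", "CA", "C", "O"),
    elesy = c("N", "H", "C", "C", "O"),
    resid = "ALA", chain = "A",
    resno = c(1L, 1L, 1L, 4L, 4L),
    x = c(N[1], Hp[1], CAd[1], Cc[1], A[1]),
    y = c(N[2], Hp[2], CAd[2], Cc[2], A[2]),
    z = c(N[3], Hp[3], CAd[3], Cc[3], A[3]),
    het = FALSE, stringsAsFactors = FALSE)
  ProteinStructure(df)
}
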