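## Ramachandran region classification. The shipped region map is an owned,
## deliberately coarse rectangle grid over the (phi, psi) torus with four
## levels (core > additional > generous > disallowed); glycine gets a
## widened map because its missing side chain opens the right half-plane.

#' The package's Ramachandran region map
#'
#' A rectangle list, one row per region, columns `level` (`core`,
#' `additional`, `generous`), `phiMin`/`phiMax`, `psiMin`/`psiMax` and
#' `gly` (`TRUE` = applies to glycine only). Classification takes the
#' highest level whose rectangle contains the residue's (phi, psi);
#' anything uncovered is disallowed. The core rows hold the canonical
#' alpha-helical and beta-strand basins; the left-handed helix basin is
#' `additional` for general residues and widened for glycine.
#'
#' @return data.frame of region rectangles (degrees).
#' @export
ramachandranMap <- function() {
  rect <- function(level, phiMin, phiMax, psiMin, psiMax, gly = FALSE)
    data.frame(level = level, phiMin = phiMin, phiMax = phiMax,
               psiMin = psiMin, psiMax = psiMax, gly = gly,
               stringsAsFactors = FALSE)
  rbind(
    ## core: alpha basin, beta basin (with its psi ~ 180 wrap)
    rect("core", -100, -30, -80, -5),
    rect("core", -180, -45, 90, 180),
    rect("core", -180, -45, -180, -150),
    ## additional: widened alpha/beta, plus the left-handed alpha basin
    rect("additional", -160, -20, -120, 30),
    rect("additional", -180, -20, 60, 180),
    rect("additional", -180, -20, -180, -140),
    rect("additional", 40, 80, -30, 45),
    ## generous: the whole left half-plane and a band around alpha-L
    rect("generous", -180, 0, -180, 180),
    rect("generous", 20, 100, -50, 55),
    ## glycine widenings: alpha-L neighbourhood and mirrored beta
    rect("additional", 20, 140, -60, 120, gly = TRUE),
    rect("generous", 0, 180, -180, 180, gly = TRUE)
  )
}

.rama_class <- function(phi, psi, isGly, map) {
  for (lvl in c("core", "additional", "generous")) {
    sub <- map[map$level == lvl & (!map$gly | isGly), , drop = FALSE]
    hit <- phi >= sub$phiMin & phi <= sub$phiMax &
           psi >= sub$psiMin & psi <= sub$psiMax
    if (any(hit)) return(lvl)
  }
  "disallowed"
}

#' Ramachandran region summary of a structure
#'
#' Computes (phi, psi) for every residue via [backboneDihedrals()],
#' classifies each against the region map, and reports the percentage of
#' classified residues per level. Termini (phi or psi undefined) and
#' residues with incomplete backbones are skipped and tallied separately.
#'
#' @param structure a [ProteinStructure-class] with >= 3 residues.
#' @param map region map, default [ramachandranMap()].
#' @return list with `perResidue` (data.frame: chain, resno, resid, phi,
#'   psi, class), `fractions` (named numeric percentages `core`,
#'   `additional`, `generous`, `disallowed`, summing to 100) and
#'   `skipped` (count of unclassifiable residues).
#' @examples
#' ramachandranSummary(buildIdealChain(20, -57, -47))$fractions
#' @export
ramachandranSummary <- function(structure, map = ramachandranMap()) {
  stopifnot(is(structure, "ProteinStructure"))
  di <- backboneDihedrals(structure)
  if (nrow(di) < 3) stop("need at least 3 residues")
  usable <- !is.na(di$phi) & !is.na(di$psi)
  per <- di[usable, c("chain", "resno", "resid", "phi", "psi")]
  per$class <- mapply(.rama_class, per$phi, per$psi,
                      per$resid == "GLY", MoreArgs = list(map = map))
  counts <- vapply(c("core", "additional", "generous", "disallowed"),
                   function(l) sum(per$class == l), numeric(1))
  if (!sum(counts)) stop("no classifiable residues")
  list(perResidue = per, fractions = 100 * counts / sum(counts),
       skipped = sum(!usable))
}
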