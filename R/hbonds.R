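## Geometric hydrogen-bond detection. Criteria: donor-acceptor distance
## d(D,A) <= dCut and, when the donor hydrogen is present, a D-H...A angle
## (vertex at H) >= angleCut. Without any hydrogens in the structure the
## distance criterion alone is applied and the result is flagged.

.DONOR_NAMES <- c("N", "ND1", "ND2", "NE", "NE1", "NE2", "NZ",
                  "NH1", "NH2", "OG", "OG1", "OH")
.ACCEPTOR_NAMES <- c("O", "OXT", "OD1", "OD2", "OE1", "OE2",
                     "OG", "OG1", "OH", "ND1", "NE2")

#' Detect hydrogen bonds in a structure
#'
#' Donors are N/O atoms with hydrogen-bearing names (backbone N, side-chain
#' N/O hydroxyls); acceptors are carbonyl/carboxyl/hydroxyl oxygens and
#' imidazole-type nitrogens, both identified by a PDB atom-name table.
#' Pairs within the same residue and the covalent backbone pair
#' (amide N of residue i with carbonyl O of residue i-1 on the same chain)
#' are excluded. A hydrogen is considered attached to a donor when it lies
#' within 1.2 Angstrom of it.
#'
#' @param structure a [ProteinStructure-class].
#' @param dCut donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angleCut minimum D-H...A angle, degrees (default 120).
#' @param chainPair optional length-2 character vector: keep only bonds
#'   whose donor and acceptor lie in different members of the pair (either
#'   direction), e.g. ligand-protein contacts.
#' @return data.frame with one row per bond: donor/hydrogen/acceptor atom
#'   row indices and descriptions, `dDA` (Angstrom), `angleDHA` (degrees,
#'   NA in heavy-atom-only mode). The attribute `heavyOnly` records whether
#'   the angle criterion could be applied.
#' @examples
#' detectHbonds(makeHbondFixture(2.9, 180))
#' @export
detectHbonds <- function(structure, dCut = 3.5, angleCut = 120,
                         chainPair = NULL) {
  stopifnot(is(structure, "ProteinStructure"))
  at <- structure@atoms
  xyz <- .coords(structure)
  isH <- at$elesy == "H" | grepl("^[0-9]?H", trimws(at$elety))
  donors <- which(!at$het & at$elety %in% .DONOR_NAMES & !isH)
  acceptors <- which(!at$het & at$elety %in% .ACCEPTOR_NAMES & !isH)
  hIdx <- which(isH)
  heavyOnly <- length(hIdx) == 0
  desc <- function(i) paste0(at$chain[i], ":", at$resno[i], ":",
                             at$elety[i])
  rows <- list()
  for (d in donors) {
    ## hydrogens covalently attached to this donor
    hs <- if (heavyOnly) integer() else
      hIdx[sqrt(colSums((t(xyz[hIdx, , drop = FALSE]) - xyz[d, ])^2)) <= 1.2]
    for (a in acceptors) {
      if (at$chain[a] == at$chain[d] && at$resno[a] == at$resno[d]) next
      ## covalent peptide-bond neighbour: N(i) vs O(i-1)
      if (at$chain[a] == at$chain[d] && at$elety[d] == "N" &&
          at$elety[a] == "O" && at$resno[a] == at$resno[d] - 1) next
      dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dda > dCut) next
      ang <- NA_real_
      bestH <- NA_integer_
      if (!heavyOnly) {
        if (!length(hs)) next   # donor without hydrogen cannot donate
        angs <- vapply(hs, function(h) {
          v1 <- xyz[d, ] - xyz[h, ]
          v2 <- xyz[a, ] - xyz[h, ]
          acos(max(-1, min(1, sum(v1 * v2) /
                  (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
        }, numeric(1))
        if (max(angs) < angleCut) next
        ang <- max(angs)
        bestH <- hs[which.max(angs)]
      }
      if (!is.null(chainPair)) {
        ok <- (at$chain[d] == chainPair[1] && at$chain[a] == chainPair[2]) ||
              (at$chain[d] == chainPair[2] && at$chain[a] == chainPair[1])
        if (!ok) next
      }
      rows[[length(rows) + 1]] <- data.frame(
        donor = d, hydrogen = bestH, acceptor = a,
        donorDesc = desc(d), acceptorDesc = desc(a),
        dDA = dda, angleDHA = ang, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = integer(), hydrogen = integer(),
               acceptor = integer(), donorDesc = character(),
               acceptorDesc = character(), dDA = numeric(),
               angleDHA = numeric(), stringsAsFactors = FALSE)
  attr(out, "heavyOnly") <- heavyOnly
  out
}

#' Hydrogen-bond count time series over an ensemble
#'
#' Applies [detectHbonds()] to every frame; optionally restricted to
#' bonds between two chains (e.g. ligand vs protein).
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param dCut,angleCut,chainPair passed to [detectHbonds()].
#' @return data.frame with columns `time` (ps) and `count`.
#' @export
hbondSeries <- function(ensemble, dCut = 3.5, angleCut = 120,
                        chainPair = NULL) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  data.frame(
    time = ensemble@times,
    count = vapply(ensemble@frames, function(f)
      nrow(detectHbonds(f, dCut = dCut, angleCut = angleCut,
                        chainPair = chainPair)), numeric(1)))
}
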