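## Secondary-structure assignment from backbone hydrogen-bond patterns
## (a four-class simplification of the Kabsch-Sander scheme) and backbone
## dihedral extraction.

## per-chain list of residue backbone atom coordinates
.backbone_by_residue <- function(structure) {
  at <- structure@atoms[!structure@atoms$het, , drop = FALSE]
  out <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    resnos <- sort(unique(sub$resno))
    res <- lapply(resnos, function(r) {
      rows <- sub[sub$resno == r, , drop = FALSE]
      grab <- function(nm) {
        i <- which(rows$elety == nm)[1]
        if (is.na(i)) NULL else as.numeric(rows[i, c("x", "y", "z")])
      }
      list(resno = r, resid = rows$resid[1],
           N = grab("N"), CA = grab("CA"), C = grab("C"),
           O = grab("O"), H = grab("H"))
    })
    names(res) <- as.character(resnos)
    out[[ch]] <- res
  }
  out
}

## reconstruct missing amide hydrogens in-plane, opposite the bisector of
## the two N bonds, at 1.01 A; residue 1 (no preceding C) gets none
.ensure_amide_h <- function(res) {
  placed <- FALSE
  for (i in seq_along(res)) {
    if (!is.null(res[[i]]$H) || i == 1) next
    prevC <- res[[i - 1]]$C
    if (is.null(prevC) || is.null(res[[i]]$N) || is.null(res[[i]]$CA)) next
    u1 <- .unit(res[[i]]$N - prevC)
    u2 <- .unit(res[[i]]$N - res[[i]]$CA)
    res[[i]]$H <- res[[i]]$N + 1.01 * .unit(u1 + u2)
    placed <- TRUE
  }
  attr(res, "placedH") <- placed
  res
}

## Kabsch-Sander electrostatic H-bond energy, kcal/mol: donor NH of
## residue i, acceptor C=O of residue j; bond iff E < -0.5
.ks_energy <- function(ri, rj) {
  if (is.null(ri$N) || is.null(ri$H) || is.null(rj$O) || is.null(rj$C))
    return(Inf)
  d <- function(p, q) sqrt(sum((p - q)^2))
  0.084 * (1 / d(rj$O, ri$N) + 1 / d(rj$C, ri$H) -
           1 / d(rj$O, ri$H) - 1 / d(rj$C, ri$N)) * 332
}

## n x n matrix over the flattened residue list: hb[i, j] TRUE when NH(i)
## donates to CO(j); covalently adjacent residues of one chain are skipped
.ks_hbond_matrix <- function(res, chainOf, eCut = -0.5) {
  n <- length(res)
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (chainOf[i] == chainOf[j] && abs(i - j) <= 1) next
    hb[i, j] <- .ks_energy(res[[i]], res[[j]]) < eCut
  }
  hb
}

#' Backbone dihedrals of every residue
#'
#' Phi (C(i-1)-N-CA-C), psi (N-CA-C-N(i+1)) and omega (CA-C-N(i+1)-CA(i+1))
#' per residue; NA where the flanking residue or an atom is missing
#' (chain termini).
#'
#' @param structure a [ProteinStructure-class].
#' @return data.frame with columns `chain`, `resno`, `resid`, `phi`,
#'   `psi`, `omega` (degrees).
#' @export
backboneDihedrals <- function(structure) {
  stopifnot(is(structure, "ProteinStructure"))
  chains <- .backbone_by_residue(structure)
  rows <- list()
  for (ch in names(chains)) {
    res <- chains[[ch]]
    n <- length(res)
    for (i in seq_len(n)) {
      r <- res[[i]]
      phi <- psi <- omega <- NA_real_
      ok <- !is.null(r$N) && !is.null(r$CA) && !is.null(r$C)
      if (ok && i > 1 && !is.null(res[[i - 1]]$C))
        phi <- dihedralAngle(res[[i - 1]]$C, r$N, r$CA, r$C)
      if (ok && i < n && !is.null(res[[i + 1]]$N)) {
        psi <- dihedralAngle(r$N, r$CA, r$C, res[[i + 1]]$N)
        if (!is.null(res[[i + 1]]$CA))
          omega <- dihedralAngle(r$CA, r$C, res[[i + 1]]$N, res[[i + 1]]$CA)
      }
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, resno = r$resno, resid = r$resid,
        phi = phi, psi = psi, omega = omega, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Assign four-class secondary structure
#'
#' A simplified Kabsch-Sander assignment: backbone H-bonds are scored by
#' the electrostatic energy E = 0.084 (1/rON + 1/rCH - 1/rOH - 1/rCN) x 332
#' kcal/mol (bond iff E < -0.5), missing amide hydrogens are placed
#' geometrically first. Classes: H (alpha-type helix, two consecutive
#' i -> i+4 bonds), E (bridge-paired strand residues, parallel or
#' antiparallel), T (i -> i+3 turn not already helix), C (the rest).
#' Chains shorter than 5 residues are all-coil with a warning.
#'
#' @param structure a [ProteinStructure-class] with carbonyl O atoms.
#' @param eCut H-bond energy cutoff, kcal/mol (default -0.5).
#' @return list with `labels` (data.frame: chain, resno, ss) and
#'   `fractions` (named numeric, percentages `helix`, `sheet`, `turn`,
#'   `coil`, summing to 100).
#' @examples
#' assignSecondaryStructure(buildIdealChain(20, -57, -47))$fractions
#' @export
assignSecondaryStructure <- function(structure, eCut = -0.5) {
  stopifnot(is(structure, "ProteinStructure"))
  chains <- .backbone_by_residue(structure)
  ## flatten across chains so inter-chain bridges are visible
  res <- list(); chainOf <- character()
  for (ch in names(chains)) {
    r <- .ensure_amide_h(chains[[ch]])
    if (length(r) < 5)
      warning("chain ", ch, " has fewer than 5 residues: all coil")
    res <- c(res, r)
    chainOf <- c(chainOf, rep(ch, length(r)))
  }
  n <- length(res)
  ss <- rep("C", n)
  chainLen <- table(chainOf)
  eligible <- chainOf %in% names(chainLen)[chainLen >= 5]
  if (any(eligible)) {
    hb <- .ks_hbond_matrix(res, chainOf, eCut)
    sameChain <- function(i, j) chainOf[i] == chainOf[j]
    turn4 <- function(i) i + 4 <= n && sameChain(i, i + 4) && hb[i + 4, i]
    turn3 <- function(i) i + 3 <= n && sameChain(i, i + 3) && hb[i + 3, i]
    ## helix: two consecutive 4-turns at i-1, i mark residues i..i+3
    isH <- rep(FALSE, n)
    for (i in seq_len(n - 4)) {
      if (i >= 2 && turn4(i - 1) && turn4(i)) isH[i:(i + 3)] <- TRUE
    }
    ## bridges (Kabsch-Sander parallel/antiparallel patterns); the partner
    ## sits on another chain or at sequence separation > 2
    isE <- rep(FALSE, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sameChain(i, j) && abs(i - j) <= 2) next
      par <- (i - 1 >= 1 && hb[j, i - 1] && i + 1 <= n && hb[i + 1, j]) ||
             (j - 1 >= 1 && hb[i, j - 1] && j + 1 <= n && hb[j + 1, i])
      anti <- (hb[i, j] && hb[j, i]) ||
              (i - 1 >= 1 && j + 1 <= n && hb[j + 1, i - 1] &&
               i + 1 <= n && j - 1 >= 1 && hb[i + 1, j - 1])
      if (par || anti) { isE[i] <- TRUE; isE[j] <- TRUE }
    }
    isT <- rep(FALSE, n)
    for (i in seq_len(n - 3)) if (turn3(i)) isT[i:(i + 3)] <- TRUE
    ss[isT & eligible] <- "T"
    ss[isE & eligible] <- "E"
    ss[isH & eligible] <- "H"
  }
  labels <- data.frame(
    chain = chainOf,
    resno = vapply(res, function(r) r$resno, numeric(1)),
    ss = ss, stringsAsFactors = FALSE)
  counts <- c(helix = sum(labels$ss == "H"), sheet = sum(labels$ss == "E"),
              turn = sum(labels$ss == "T"), coil = sum(labels$ss == "C"))
  list(labels = labels, fractions = 100 * counts / sum(counts))
}
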