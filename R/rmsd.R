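## Optimal-superposition backbone RMSD (Kabsch algorithm) and per-frame
## RMSD series over an ensemble.

## closed-form least-squares rigid alignment; P is the reference (n x 3)
.kabsch_rmsd <- function(P, Q) {
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc)
  Q0 <- sweep(Q, 2, qc)
  H <- t(Q0) %*% P0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))      # reflection guard
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(sum((Q0 %*% t(R) - P0)^2) / nrow(P))
}

.select_matched <- function(ref, mobile, selection) {
  pick <- function(st) {
    at <- st@atoms
    at <- at[!at$het & at$elety %in% selection, , drop = FALSE]
    at$key <- paste(at$chain, at$resno, at$elety)
    at
  }
  a <- pick(ref); b <- pick(mobile)
  onlyA <- setdiff(a$key, b$key)
  onlyB <- setdiff(b$key, a$key)
  if (length(onlyA) || length(onlyB))
    stop("atom selections do not match; unmatched: ",
         paste(utils::head(c(onlyA, onlyB), 10), collapse = "; "))
  b <- b[match(a$key, b$key), , drop = FALSE]
  list(P = as.matrix(a[, c("x", "y", "z")]),
       Q = as.matrix(b[, c("x", "y", "z")]))
}

#' Backbone RMSD after optimal superposition
#'
#' Atoms named in `selection` (default the N, CA, C backbone) are matched
#' between the two structures by (chain, residue number, atom name), the
#' mobile set is rigidly aligned onto the reference by the closed-form
#' Kabsch algorithm (SVD of the covariance with a reflection guard), and
#' the root-mean-square deviation of the aligned coordinates is returned.
#' Symmetric in its arguments and invariant to rigid motion of either.
#'
#' @param ref,mobile [ProteinStructure-class] objects.
#' @param selection atom names to superpose (default `c("N","CA","C")`).
#' @return RMSD in Angstrom.
#' @examples
#' ch <- buildIdealChain(10)
#' moved <- applyRigidMotion(ch, rotation = c(10, 40, -30),
#'                           translation = c(5, -2, 1))
#' backboneRmsd(ch, moved)   # 0
#' @export
backboneRmsd <- function(ref, mobile, selection = c("N", "CA", "C")) {
  stopifnot(is(ref, "ProteinStructure"), is(mobile, "ProteinStructure"))
  m <- .select_matched(ref, mobile, selection)
  if (nrow(m$P) < 3) stop("need at least 3 matched atoms")
  .kabsch_rmsd(m$P, m$Q)
}

#' RMSD time series over an ensemble
#'
#' Superposition RMSD of every frame against a reference frame (the first
#' by default); the reference's own entry is 0.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param refFrame index of the reference frame.
#' @param selection atom names to superpose.
#' @return data.frame with columns `time` (ps) and `rmsd` (Angstrom).
#' @export
rmsdSeries <- function(ensemble, refFrame = 1,
                       selection = c("N", "CA", "C")) {
  stopifnot(is(ensemble, "StructureEnsemble"))
  ref <- ensemble@frames[[refFrame]]
  data.frame(
    time = ensemble@times,
    rmsd = vapply(ensemble@frames,
                  function(f) backboneRmsd(ref, f, selection = selection),
                  numeric(1)))
}
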