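test_that("PDB write/read round-trips structures and ensembles", {
  ch <- buildIdealChain(8)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  writePDB(ch, p1)
  back <- readPDB(p1)
  expect_s4_class(back, "ProteinStructure")
  expect_equal(atoms(back)$elety, atoms(ch)$elety)
  expect_equal(QuenchBind:::.coords(back), QuenchBind:::.coords(ch),
               tolerance = 1e-3)

  ens <- StructureEnsemble(
    list(ch,
         applyRigidMotion(ch, c(5, 5, 5), c(1, 1, 1)),
         applyRigidMotion(ch, c(0, 0, 0), c(0, 0, 2), jitterSD = 0.3,
                          seed = 5)),
    times = c(0, 20, 40))
  p2 <- withr::local_tempfile(fileext = ".pdb")
  writePDB(ens, p2)
  back2 <- readPDB(p2)
  expect_s4_class(back2, "StructureEnsemble")
  expect_equal(nFrames(back2), 3)
  expect_equal(frameTimes(back2), c(0, 20, 40))
})

test_that("malformed ATOM records fail with a line number", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      0.000   0.000"), p)
  expect_error(readPDB(p), "line 1")
})

test_that("superposition RMSD is zero for rigid copies and symmetric", {
  ch <- buildIdealChain(10)
  mv <- applyRigidMotion(ch, c(33, -21, 150), c(10, -4, 2))
  expect_equal(backboneRmsd(ch, mv), 0, tolerance = 1e-9)
  jt <- applyRigidMotion(ch, c(10, 20, 30), c(1, 2, 3), jitterSD = 0.4,
                         seed = 2)
  r1 <- backboneRmsd(ch, jt)
  expect_gt(r1, 0)
  expect_equal(backboneRmsd(jt, ch), r1, tolerance = 1e-9)
  # invariant to rigid motion of either argument
  expect_equal(backboneRmsd(applyRigidMotion(ch, c(5, 6, 7), c(1, 1, 1)),
                            jt), r1, tolerance = 1e-9)
  expect_error(backboneRmsd(ch, buildIdealChain(9)), "unmatched")
})

test_that("Kabsch RMSD matches a rotation-grid search oracle", {
  for (seed in c(1, 2, 3)) {
    pts <- toy_point_sets(seed)
    ours <- backboneRmsd(structure_from_points(pts$P),
                         structure_from_points(pts$Q))
    oracle <- grid_rmsd_oracle(pts$P, pts$Q)
    expect_equal(ours, oracle, tolerance = 1e-3)
  }
})

test_that("Kabsch RMSD agrees with an established reference aligner", {
  pts <- toy_point_sets(4)
  ours <- backboneRmsd(structure_from_points(pts$P),
                       structure_from_points(pts$Q))
  ref <- bio3d::rmsd(as.numeric(t(pts$P)), as.numeric(t(pts$Q)),
                     fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("RMSD series over an ensemble behaves as expected", {
  ch <- buildIdealChain(12)
  rigid <- StructureEnsemble(lapply(1:4, function(k)
    applyRigidMotion(ch, c(10 * k, -5 * k, 3 * k), c(k, 0, -k))),
    times = (0:3) * 20)
  out <- rmsdSeries(rigid)
  expect_equal(out$time, (0:3) * 20)
  expect_equal(out$rmsd, rep(0, 4), tolerance = 1e-9)

  single <- StructureEnsemble(list(ch), times = 0)
  expect_equal(rmsdSeries(single)$rmsd, 0)

  # jittered frames: mean RMSD within 10% of a Monte-Carlo estimate made
  # with the reference aligner on independently jittered replicates
  jit <- StructureEnsemble(c(list(ch), lapply(1:20, function(k)
    applyRigidMotion(ch, jitterSD = 0.5, seed = 100 + k))),
    times = 0:20)
  ours <- mean(rmsdSeries(jit)$rmsd[-1])
  sel <- atoms(ch)$elety %in% c("N", "CA", "C")
  P <- QuenchBind:::.coords(ch)[sel, ]
  set.seed(77)
  mc <- replicate(60, {
    Q <- P + matrix(rnorm(length(P), sd = 0.5), ncol = 3)
    bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
  })
  expect_equal(ours, mean(mc), tolerance = 0.1)
})

test_that("hydrogen-bond detection honours its geometric criteria", {
  expect_equal(nrow(detectHbonds(makeHbondFixture(2.9, 180))), 1)
  expect_equal(nrow(detectHbonds(makeHbondFixture(5.0, 180))), 0)
  expect_equal(nrow(detectHbonds(makeHbondFixture(2.9, 90))), 0)
  # just inside the distance cutoff; angle cutoff configurable
  expect_equal(nrow(detectHbonds(makeHbondFixture(3.45, 180))), 1)
  expect_equal(nrow(detectHbonds(makeHbondFixture(2.9, 125),
                                 angleCut = 130)), 0)
  hb <- detectHbonds(makeHbondFixture(2.9, 170))
  expect_equal(hb$dDA, 2.9, tolerance = 1e-9)
  expect_equal(hb$angleDHA, 170, tolerance = 1e-9)
  expect_false(attr(hb, "heavyOnly"))
})

test_that("hydrogen-bond criteria are invariant under rigid motion", {
  st <- makeHbondFixture(3.1, 155)
  mv <- applyRigidMotion(st, c(40, 10, -70), c(3, -8, 12))
  a <- detectHbonds(st); b <- detectHbonds(mv)
  expect_equal(nrow(b), nrow(a))
  expect_equal(b$dDA, a$dDA, tolerance = 1e-9)
  expect_equal(b$angleDHA, a$angleDHA, tolerance = 1e-9)
})

test_that("heavy-atom-only mode applies the distance criterion alone", {
  st <- makeHbondFixture(2.9, 90)     # angle would fail with H present
  noH <- ProteinStructure(atoms(st)[atoms(st)$elety != "H", ])
  hb <- detectHbonds(noH)
  expect_equal(nrow(hb), 1)
  expect_true(is.na(hb$angleDHA))
  expect_true(attr(hb, "heavyOnly"))
})

test_that("hydrogen-bond series counts per frame", {
  bonded <- makeHbondFixture(2.9, 180)
  unbonded <- makeHbondFixture(4.5, 180)
  ens <- StructureEnsemble(list(bonded, unbonded, bonded, unbonded),
                           times = (0:3) * 20)
  expect_equal(hbondSeries(ens)$count, c(1, 0, 1, 0))
  # restricting to a chain pair with no contacts gives zeros
  expect_equal(hbondSeries(ens, chainPair = c("A", "Z"))$count, rep(0, 4))
})

test_that("dihedral angles follow the right-hand convention", {
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(2, 1, 0)), 0)           # planar cis
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(2, -1, 0)), 180)        # planar trans
  # hand-computed chiral case
  expect_equal(dihedralAngle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                             c(1, 0, 1)), 90)
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                             c(3, 1, 0)), "collinear")
})

test_that("chain dihedrals agree with an established torsion reference", {
  ch <- buildIdealChain(8, -63, -42, 180)
  p <- withr::local_tempfile(fileext = ".pdb")
  writePDB(ch, p)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(p))
  ours <- backboneDihedrals(ch)
  expect_equal(ours$phi[-1], unname(tor$phi[-1]), tolerance = 1e-2)
  expect_equal(ours$psi[-8], unname(tor$psi[-8]), tolerance = 1e-2)
})

test_that("an ideal helix is assigned mostly H and fractions sum to 100", {
  ss <- assignSecondaryStructure(buildIdealChain(20, -57, -47, 180))
  expect_gte(ss$fractions[["helix"]], 80)
  expect_equal(sum(ss$fractions), 100, tolerance = 1e-6)
  # interior residues are all helix
  expect_true(all(ss$labels$ss[3:18] == "H"))
})

test_that("antiparallel strand pairs are assigned sheet", {
  ss <- assignSecondaryStructure(make_sheet_fixture())
  expect_gte(sum(ss$labels$ss == "E"), 2)
  expect_equal(sum(ss$fractions), 100, tolerance = 1e-6)
  expect_equal(ss$fractions[["helix"]], 0)
})

test_that("secondary structure is invariant under rigid motion and
           atom-order permutation", {
  ch <- buildIdealChain(15, -57, -47, 180)
  base <- assignSecondaryStructure(ch)
  mv <- applyRigidMotion(ch, c(17, 123, -45), c(-30, 2, 9))
  expect_identical(assignSecondaryStructure(mv)$labels$ss, base$labels$ss)
  set.seed(9)
  at <- atoms(ch)
  perm <- unlist(lapply(split(seq_len(nrow(at)), at$resno), sample))
  shuffled <- ProteinStructure(at[perm, ])
  expect_identical(assignSecondaryStructure(shuffled)$labels$ss,
                   base$labels$ss)
})

test_that("short chains fall back to all-coil with a warning", {
  expect_warning(ss <- assignSecondaryStructure(buildIdealChain(4)),
                 "fewer than 5")
  expect_true(all(ss$labels$ss == "C"))
  expect_equal(sum(ss$fractions), 100, tolerance = 1e-6)
})

test_that("Ramachandran summary classifies canonical conformations", {
  helix <- ramachandranSummary(buildIdealChain(20, -57, -47, 180))
  expect_equal(helix$fractions[["core"]], 100)
  expect_equal(sum(helix$fractions), 100, tolerance = 1e-6)

  strand <- ramachandranSummary(buildIdealChain(12, -120, 120, 180))
  expect_equal(strand$fractions[["core"]], 100)

  # (60, 60) is disallowed for a general residue but not for glycine
  lh <- ramachandranSummary(buildIdealChain(8, 60, 60, 180))
  expect_equal(lh$fractions[["disallowed"]], 100)
  map <- ramachandranMap()
  expect_identical(QuenchBind:::.rama_class(60, 60, FALSE, map),
                   "disallowed")
  expect_false(QuenchBind:::.rama_class(60, 60, TRUE, map) == "disallowed")
})

test_that("residues with broken backbones are skipped, not classified", {
  ch <- buildIdealChain(10)
  at <- atoms(ch)
  drop <- which(at$resno == 5 & at$elety == "CA")
  broken <- ProteinStructure(at[-drop, ])
  out <- ramachandranSummary(broken)
  expect_gt(out$skipped, 2)     # termini plus the residues around the gap
  expect_equal(sum(out$fractions), 100, tolerance = 1e-6)
})
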