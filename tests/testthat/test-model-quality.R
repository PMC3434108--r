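# Dihedrals, Ramachandran summaries, clashscore, bond geometry.

test_that("ideal fixtures return their constructed dihedrals", {
  h <- makeIdealSSE("helix", 12)
  dih <- backboneDihedrals(h)
  expect_true(all(abs(dih$phi[-1] + 57) < 1e-3))
  expect_true(all(abs(dih$psi[-12] + 47) < 1e-3))
  expect_true(all(abs(abs(dih$omega[-1]) - 180) < 1e-3))  # trans peptide
  expect_true(is.na(dih$phi[1]))
  expect_true(is.na(dih$psi[12]))
})

test_that("a cis arrangement of four coplanar atoms gives a zero omega", {
  ## CA(1)-C(1)-N(2)-CA(2) coplanar with both CAs on the same side -> cis, 0
  at <- rbind(
    make_atoms(x = c(0, 0, 0), y = c(2, 1, 0), z = 0,
               elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
               resno = 1L),
    make_atoms(x = c(1, 1, 2), y = c(0, 1, 1), z = 0,
               elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
               resno = 2L)
  )
  dih <- backboneDihedrals(StructureModel(at, "cis"))
  expect_equal(dih$omega[2], 0, tolerance = 1e-9)
})

test_that("chain breaks and missing atoms leave dihedrals undefined, not errors", {
  h <- makeIdealSSE("helix", 10)
  at <- atoms(h)
  ## displace residues 6..10 far away: break between 5 and 6
  sel <- at$resno >= 6
  at[sel, "x"] <- at[sel, "x"] + 100
  broken <- StructureModel(at, "broken")
  dih <- backboneDihedrals(broken)
  expect_true(is.na(dih$phi[6]))
  expect_true(is.na(dih$psi[5]))
  expect_false(is.na(dih$phi[5]))
  ## drop one CA entirely
  at2 <- atoms(h)
  at2 <- at2[!(at2$resno == 4 & at2$elety == "CA"), ]
  dih2 <- backboneDihedrals(StructureModel(at2, "gap"))
  expect_true(is.na(dih2$phi[4]))
  expect_true(is.na(dih2$psi[4]))
})

test_that("dihedrals are invariant under rigid transforms", {
  h <- makeIdealSSE("strand", 9)
  base <- backboneDihedrals(h)
  for (seed in 1:4) {
    moved <- applyRandomTransform(h, seed = seed)$model
    got <- backboneDihedrals(moved)
    expect_equal(got$phi, base$phi, tolerance = 1e-6)
    expect_equal(got$psi, base$psi, tolerance = 1e-6)
  }
})

test_that("ramachandran percentage arithmetic matches the published tables", {
  tab <- rama_counts_table()
  ok <- tab[tab$consistent, ]
  for (k in seq_len(nrow(ok))) {
    counts <- as.numeric(ok[k, c("most_favoured", "additional_allowed",
                                 "generously_allowed", "disallowed")])
    expect_equal(ramaPercentages(counts)[1], ok$printed_most_favoured_pct[k],
                 info = paste(ok$model[k], ok$stage[k]))
  }
  ## two full rows checked against the complete printed percentage sets
  expect_equal(ramaPercentages(c(89, 21, 4, 3)), c(76.1, 17.9, 3.4, 2.6))
  expect_equal(ramaPercentages(c(84, 33, 0, 0)), c(71.8, 28.2, 0.0, 0.0))
})

test_that("ramachandran summary classifies ideal fixtures as expected", {
  h <- makeIdealSSE("helix", 20)
  rs <- ramachandranSummary(backboneDihedrals(h))
  expect_equal(rs$n, 18L)
  expect_equal(unname(rs$counts["most_favoured"]), 18L)
  expect_equal(unname(rs$percentages["most_favoured"]), 100)
  s <- makeIdealSSE("strand", 20)
  rs2 <- ramachandranSummary(backboneDihedrals(s))
  expect_equal(unname(rs2$counts["most_favoured"]), 18L)
  ## percentages recompute from counts and sum to ~100
  expect_equal(unname(rs$percentages), unname(ramaPercentages(rs$counts)))
  expect_lt(abs(sum(rs$percentages) - 100), 0.2)
})

test_that("clashscore counts only non-bonded overlaps and scales per 1000 atoms", {
  ## 100 isolated carbons on a wide grid, two moved to 2.9 A apart:
  ## overlap 2*1.70 - 2.9 = 0.5 > 0.4 -> exactly one clash -> score 10
  g <- expand.grid(x = seq(0, 90, by = 10), y = seq(0, 90, by = 10))
  at <- make_atoms(x = g$x[1:100], y = g$y[1:100], z = 0,
                   elety = "C", elesy = "C", resno = 1:100)
  at$z[2] <- 0; at$x[2] <- at$x[1] + 2.9; at$y[2] <- at$y[1]
  m <- StructureModel(at, "grid")
  cs <- clashscore(m)
  expect_equal(cs$n_atoms, 100L)
  expect_equal(cs$n_clashes, 1L)
  expect_equal(cs$score, 10.0)

  ## no clash at exactly the threshold overlap
  at2 <- make_atoms(x = c(0, 2 * 1.70 - 0.4), y = 0, z = 0, elety = "C",
                    elesy = "C", resno = 1:2)
  expect_equal(clashscore(StructureModel(at2, "edge"))$n_clashes, 0L)

  ## covalently bonded neighbours are never clashes
  h <- makeIdealSSE("helix", 12)
  expect_equal(clashscore(h)$score, 0)
})

test_that("clashscore is invariant to ordering, rigid motion and duplication", {
  tp <- makeToyProtease(noiseSigma = 0.4, seed = 3)
  base <- clashscore(tp$model)$score
  at <- atoms(tp$model)
  expect_equal(clashscore(StructureModel(at[rev(seq_len(nrow(at))), ],
                                         "rev"))$score, base)
  moved <- applyRandomTransform(tp$model, seed = 21)$model
  expect_equal(clashscore(moved)$score, base)
  ## two far-apart copies leave the per-1000-atom rate unchanged
  at2 <- atoms(moved)
  at2$x <- at2$x + 500
  at2$chain <- "B"
  doubled <- StructureModel(rbind(atoms(tp$model), at2), "double")
  expect_equal(clashscore(doubled)$score, base)
})

test_that("bond geometry rmsd is zero on ideal fixtures and follows the closed form", {
  h <- makeIdealSSE("helix", 12)
  bg <- bondGeometryRMSD(h)
  expect_lt(bg$length_rmsd, 1e-9)
  expect_lt(bg$angle_rmsd, 1e-9)
  expect_gt(bg$n_bonds, 0)

  ## N residues with only an N-CA bond each; stretch one by +0.1
  n <- 16L
  at <- do.call(rbind, lapply(seq_len(n), function(i) {
    make_atoms(x = c(10 * i, 10 * i + 1.458), y = 0, z = 0,
               elety = c("N", "CA"), elesy = c("N", "C"),
               resno = c(i, i))
  }))
  at$x[2] <- at$x[1] + 1.458 + 0.1
  m <- StructureModel(at, "bonds")
  bg2 <- bondGeometryRMSD(m)
  expect_equal(bg2$n_bonds, n)
  expect_equal(bg2$length_rmsd, 0.1 / sqrt(n), tolerance = 1e-12)

  ## random +-0.02 A perturbations recompute to ~0.02 rmsd (direct oracle)
  set.seed(14)
  pert <- at
  bumps <- sample(c(-0.02, 0.02), n, replace = TRUE)
  pert$x[pert$elety == "CA"] <- pert$x[pert$elety == "N"] + 1.458 + bumps
  pert$x[2] <- at$x[1] + 1.458 + bumps[1]
  bg3 <- bondGeometryRMSD(StructureModel(pert, "pert"))
  expect_equal(bg3$length_rmsd, sqrt(mean(bumps^2)), tolerance = 1e-9)
})

test_that("qualityReport composes the three metrics coherently", {
  h <- makeIdealSSE("helix", 12)
  q <- qualityReport(h)
  expect_equal(q$clashscore, 0)
  expect_lt(q$bond_length_rmsd, 1e-9)
  expect_equal(sum(q$rama$counts), q$rama$n)
})
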