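# Triad geometry, aggregation, proximity, stabilizing contacts.

toy_triad_model <- function(his, asp, ser) {
  StructureModel(make_atoms(x = c(his[1], asp[1], ser[1]),
                            y = c(his[2], asp[2], ser[2]),
                            z = c(his[3], asp[3], ser[3]),
                            resid = c("HIS", "ASP", "SER"),
                            resno = c(57L, 102L, 195L)), "triad")
}

triad_locators <- catalyticTriad(his = "A:57", asp = "A:102", ser = "A:195")

test_that("triad geometry returns the hand-computed Calpha distances", {
  ## Asp (0,0,0), His (3,4,0), Ser (0,0,5): Asp-His 5, Asp-Ser 5,
  ## His-Ser sqrt(3^2+4^2+5^2) = sqrt(50)
  m <- toy_triad_model(his = c(3, 4, 0), asp = c(0, 0, 0), ser = c(0, 0, 5))
  g <- triadGeometry(m, triad_locators)
  d <- triadDistances(g)
  expect_equal(unname(d), c(5, sqrt(50), 5), tolerance = 1e-12)
})

test_that("toy protease construction hits its target distances exactly", {
  tp <- makeToyProtease(distances = c(6.4, 8.4, 9.8), noiseSigma = 0)
  d <- triadDistances(triadGeometry(tp$model, tp$triad))
  expect_equal(unname(d), c(6.4, 8.4, 9.8), tolerance = 1e-6)
})

test_that("degenerate triads are rejected and mistyped residues warn", {
  expect_error(catalyticTriad(his = "A:57", asp = "A:57", ser = "A:195"),
               "distinct")
  m <- toy_triad_model(his = c(3, 4, 0), asp = c(0, 0, 0), ser = c(0, 0, 5))
  expect_error(triadGeometry(m, catalyticTriad("A:57", "A:102", "B:999")),
               "not found")
  sw <- catalyticTriad(his = "A:102", asp = "A:57", ser = "A:195")
  ## both the His and the Asp locator are mistyped -> two warnings
  expect_warning(expect_warning(triadGeometry(m, sw), "expected"), "expected")
})

test_that("triad geometry is invariant under rigid transforms", {
  tp <- makeToyProtease(noiseSigma = 0.2, seed = 4)
  base <- triadDistances(triadGeometry(tp$model, tp$triad))
  for (seed in 1:5) {
    moved <- applyRandomTransform(tp$model, seed = seed)$model
    expect_equal(triadDistances(triadGeometry(moved, tp$triad)), base,
                 tolerance = 1e-9)
  }
})

test_that("aggregated statistics use the sample SD and behave at the edges", {
  g <- triadGeometry(toy_triad_model(c(3, 4, 0), c(0, 0, 0), c(0, 0, 5)),
                     triad_locators)
  one <- aggregateTriadStats(list(g))
  expect_equal(unname(one$sd), c(0, 0, 0))
  expect_equal(one$n, 1L)

  five <- aggregateTriadStats(rep(list(g), 5))
  expect_equal(unname(five$mean), unname(triadDistances(g)))
  expect_equal(unname(five$sd), c(0, 0, 0))
  expect_error(aggregateTriadStats(list()), "no geometries")
})

test_that("survey aggregation reproduces the published experimental means", {
  sv <- triad_survey()
  ex <- sv[sv$source == "experimental", ]
  st <- aggregateTriadStats(ex[, c("d_asp_his", "d_his_ser", "d_asp_ser")])
  expect_equal(st$n, 16L)
  ## direct-formula oracle for the sample SD
  x <- ex$d_asp_his
  sd_direct <- sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  expect_equal(unname(st$sd["d_asp_his"]), sd_direct, tolerance = 1e-12)
  rounded <- vapply(st$mean, function(m) {
    sign(m) * floor(abs(m) * 10 + 0.5) / 10
  }, 0)
  expect_equal(unname(rounded[c("d_asp_his", "d_his_ser")]), c(6.4, 8.4))
})

test_that("proximal residues respect the strict radius and exclude the triad", {
  at <- rbind(
    make_atoms(x = c(3, 4, 0), y = c(0, 0, 0), z = c(0, 0, 0),
               resid = c("HIS", "ASP", "SER"), resno = c(57L, 102L, 195L)),
    make_atoms(x = 3 + 5.9, y = 0, z = 0, resid = "GLY", resno = 300L),
    make_atoms(x = 3, y = 6.1, z = 0, resid = "VAL", resno = 301L)
  )
  m <- StructureModel(at, "prox")
  hits <- proximalResidues(m, triad_locators, radius = 6)
  expect_equal(hits$resno, 300L)
  ## empty model apart from the triad
  m2 <- toy_triad_model(c(3, 4, 0), c(0, 0, 0), c(0, 0, 5))
  expect_equal(nrow(proximalResidues(m2, triad_locators, radius = 6)), 0L)
})

test_that("proximal residues grow monotonically with the radius", {
  tp <- makeToyProtease(noiseSigma = 0.1, seed = 6)
  radii <- c(4, 6, 9, 14)
  sets <- lapply(radii, function(r) {
    h <- proximalResidues(tp$model, tp$triad, radius = r)
    paste(h$chain, h$resno)
  })
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }
})

test_that("disulfides are detected at bonding distance only", {
  cys_pair <- function(d) {
    StructureModel(make_atoms(x = c(0, d), y = 0, z = 0, elety = "SG",
                              elesy = "S", resid = "CYS", resno = c(10L, 80L)),
                   "ss")
  }
  hit <- detectStabilizingContacts(cys_pair(2.04))
  expect_equal(hit$kind, "disulfide")
  expect_equal(hit$distance, 2.04, tolerance = 1e-9)
  expect_equal(nrow(detectStabilizingContacts(cys_pair(3.0), ssDmax = 2.3)), 0L)
})

test_that("an ideal helix shows the O(i)..N(i+4) hydrogen-bond ladder", {
  h <- makeIdealSSE("helix", 12)
  ct <- detectStabilizingContacts(h)
  hb <- ct[ct$kind == "hbond", ]
  expect_true(all(hb$resno1 - hb$resno2 == 4))
  expect_equal(hb$resno1, 5:12)
  ## the criteria the pairs must satisfy, re-measured from the fixture
  expect_true(all(hb$distance <= 3.5))
  expect_true(all(hb$angle >= 120))
})

test_that("contact detection is invariant to atom order and rigid motion", {
  h <- makeIdealSSE("helix", 10)
  base <- detectStabilizingContacts(h)
  at <- atoms(h)
  shuffled <- StructureModel(at[rev(seq_len(nrow(at))), ], "rev")
  expect_equal(detectStabilizingContacts(shuffled), base)
  moved <- applyRandomTransform(h, seed = 12)$model
  got <- detectStabilizingContacts(moved)
  expect_equal(got[, c("kind", "resno1", "atom1", "resno2", "atom2")],
               base[, c("kind", "resno1", "atom1", "resno2", "atom2")])
  expect_equal(got$distance, base$distance, tolerance = 1e-9)
  expect_equal(got$angle, base$angle, tolerance = 1e-6)
})
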