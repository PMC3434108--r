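# Kabsch fitting and iterative common-core detection.

test_that("kabschFit is exact on identical and rigidly transformed clouds", {
  set.seed(1)
  p <- matrix(rnorm(24), ncol = 3)
  fit <- kabschFit(p, p)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(rotation(fit$transform), diag(3), tolerance = 1e-9)
  expect_equal(translation(fit$transform), c(0, 0, 0), tolerance = 1e-9)

  ## 90 degrees about z plus a translation is recovered exactly
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- tcrossprod(p, R90) + rep(c(1, 2, 3), each = nrow(p))
  fit2 <- kabschFit(p, moved)
  expect_lt(fit2$rmsd, 1e-9)
  expect_equal(rotation(fit2$transform), t(R90), tolerance = 1e-9)
  back <- applyTransform(moved, fit2$transform)
  expect_lt(max(abs(back - p)), 1e-9)
})

test_that("kabschFit matches a brute-force rotation-space optimizer on noisy clouds", {
  set.seed(42)
  for (rep in 1:12) {
    p <- matrix(rnorm(15), ncol = 3)
    q <- p + matrix(rnorm(15, sd = 0.1), ncol = 3)
    expect_equal(kabschFit(p, q)$rmsd, brute_force_rmsd(p, q),
                 tolerance = 1e-6)
  }
})

test_that("kabschFit rejects degenerate input and never returns a reflection", {
  p <- matrix(rnorm(6), ncol = 3)
  expect_error(kabschFit(p, p), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschFit(line, line + 1), "collinear|degenerate")

  ## mirrored cloud: the optimal orthogonal map is a reflection, which must
  ## be rejected in favour of the best proper rotation
  set.seed(7)
  p <- matrix(rnorm(21), ncol = 3)
  mirrored <- p %*% diag(c(-1, 1, 1))
  fit <- kabschFit(p, mirrored)
  expect_equal(det(rotation(fit$transform)), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("kabsch rmsd is invariant under a joint rigid pre-transformation", {
  set.seed(3)
  p <- matrix(rnorm(30), ncol = 3)
  q <- p + matrix(rnorm(30, sd = 0.2), ncol = 3)
  base <- kabschFit(p, q)$rmsd
  for (seed in 1:5) {
    helper <- applyRandomTransform(make_model(x = p[, 1], y = p[, 2], z = p[, 3]),
                                   seed = seed)
    tr <- helper$transform
    expect_equal(kabschFit(applyTransform(p, tr), applyTransform(q, tr))$rmsd,
                 base, tolerance = 1e-9)
  }
})

test_that("identical chains superpose with a full core and zero rmsd", {
  h <- makeIdealSSE("helix", 20)
  sup <- iterativeCoreSuperpose(h, h, pruneCutoff = 2)
  expect_equal(fractionMatched(sup), 100)
  expect_lt(rmsd(sup), 1e-9)
})

test_that("pruning isolates the coherent half of a half-perturbed chain", {
  fx <- make_half_perturbed_pair(n = 40, sigma = 8, seed = 11)
  sup <- iterativeCoreSuperpose(fx$ref, fx$target, pairs = fx$pairs,
                                pruneCutoff = 2)
  expect_true(all(corePairs(sup)$ref_resno <= 20))
  expect_gt(fractionMatched(sup), 40)
  expect_lt(fractionMatched(sup), 55)
  expect_lt(rmsd(sup), 0.5)
})

test_that("the iteration is a fixed point at convergence and rmsd is monotone", {
  fx <- make_half_perturbed_pair(n = 40, sigma = 8, seed = 11)
  sup <- iterativeCoreSuperpose(fx$ref, fx$target, pairs = fx$pairs,
                                pruneCutoff = 2)
  again <- iterativeCoreSuperpose(fx$ref, fx$target, pairs = corePairs(sup),
                                  pruneCutoff = 2)
  expect_equal(corePairs(again), corePairs(sup))
  expect_equal(rmsd(again), rmsd(sup), tolerance = 1e-12)
  expect_equal(rotation(transform(again)), rotation(transform(sup)),
               tolerance = 1e-9)

  ## monotone non-increasing rmsd across manual iterations
  pairs <- fx$pairs
  ca_ref <- namedAtomCoords(fx$ref)
  ca_tgt <- namedAtomCoords(fx$target)
  rmsds <- numeric(0)
  repeat {
    f <- ca_ref[as.character(pairs$ref_resno), ]
    m <- ca_tgt[as.character(pairs$target_resno), ]
    fit <- kabschFit(f, m)
    rmsds <- c(rmsds, fit$rmsd)
    d <- sqrt(rowSums((applyTransform(m, fit$transform) - f)^2))
    if (all(d <= 2)) break
    pairs <- pairs[d <= 2, ]
  }
  expect_true(all(diff(rmsds) <= 1e-12))
})

test_that("a core shrinking below three pairs is an error with a diagnostic", {
  ref <- makeIdealSSE("helix", 10)
  at <- atoms(ref)
  set.seed(2)
  at[, c("x", "y", "z")] <- as.matrix(at[, c("x", "y", "z")]) +
    matrix(rnorm(nrow(at) * 3, sd = 20), ncol = 3)
  scr <- StructureModel(at, "scrambled")
  expect_error(
    iterativeCoreSuperpose(ref, scr,
                           pairs = data.frame(ref_resno = 1:10,
                                              target_resno = 1:10),
                           pruneCutoff = 0.5),
    "3 pairs|below 3")
})

test_that("alignment-seeded correspondence drives superposition of sequence-identical chains", {
  tp1 <- makeToyProtease(noiseSigma = 0.05, seed = 1)
  tp2 <- makeToyProtease(noiseSigma = 0.05, seed = 2)
  moved <- applyRandomTransform(tp2$model, seed = 33)
  sup <- iterativeCoreSuperpose(tp1$model, moved$model, pruneCutoff = 2)
  expect_equal(fractionMatched(sup), 100)
  expect_lt(rmsd(sup), 0.3)
})
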