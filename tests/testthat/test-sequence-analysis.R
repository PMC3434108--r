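# Global alignment, conservation, reference numbering, composition.

test_that("globalAlign handles the elementary cases", {
  same <- globalAlign("ACDE", "ACDE")
  expect_equal(same$score, 4)
  expect_equal(same$identity_pct, 100)
  expect_equal(same$aligned_a, "ACDE")

  one <- globalAlign("A", "G")
  expect_equal(one$score, -1)
  expect_equal(one$aligned_a, "A")
  expect_equal(one$aligned_b, "G")

  mid <- globalAlign("ACD", "AD")
  expect_equal(mid$score, enum_align_score("ACD", "AD"))
  expect_equal(mid$aligned_b, "A-D")
  expect_error(globalAlign("", "A"), "non-empty")
})

test_that("globalAlign equals exhaustive enumeration for short sequences", {
  set.seed(20)
  for (rep in 1:60) {
    a <- random_aa_string(sample(1:6, 1))
    b <- random_aa_string(sample(1:6, 1))
    got <- globalAlign(a, b)
    expect_equal(got$score, enum_align_score(a, b),
                 info = paste(a, b))
    ## the reported alignment actually scores what it claims
    ca <- strsplit(got$aligned_a, "")[[1]]
    cb <- strsplit(got$aligned_b, "")[[1]]
    expect_false(any(ca == "-" & cb == "-"))
    rescored <- sum(ifelse(ca == "-" | cb == "-", -1,
                           ifelse(ca == cb, 1, -1)))
    expect_equal(rescored, got$score)
    expect_equal(gsub("-", "", got$aligned_a), a)
    expect_equal(gsub("-", "", got$aligned_b), b)
  }
})

test_that("column conservation counts occupancy over all rows", {
  aln <- makeSyntheticAlignment(21, 40,
                                conserved = data.frame(col = c(10, 20),
                                                       residue = c("T", "G"),
                                                       occupancy = c(16 / 21, 1)),
                                seed = 7)
  cc <- columnConservation(aln)
  expect_equal(cc$occupancy_pct[10], 100 * 16 / 21, tolerance = 1e-9)
  expect_equal(sprintf("%.0f", cc$occupancy_pct[10]), "76")
  expect_equal(cc$occupancy_pct[20], 100)
  expect_equal(cc$symbol[20], "*")
  expect_equal(cc$modal_residue[10], "T")
})

test_that("conservation symbols follow the strong/weak group rules", {
  aln <- ProteinAlignment(c(a = "GIVC", b = "GLAC", c = "GVTC"))
  cc <- columnConservation(aln)
  expect_equal(cc$symbol, c("*", ":", ".", "*"))  # {I,L,V} in MILV; {V,A,T} in ATV
  ## a gap disqualifies "*" but not the group symbols ({G} is only in the
  ## weak group SAG; {I,L,V} is in the strong group MILV despite the gap row)
  aln2 <- ProteinAlignment(c(a = "G-I", b = "GGL", c = "GGV"))
  cc2 <- columnConservation(aln2)
  expect_equal(cc2$symbol, c("*", ".", ":"))
  expect_equal(cc2$occupancy_pct[2], 100 * 2 / 3)
})

test_that("a * column implies full occupancy", {
  aln <- makeSyntheticAlignment(10, 50, seed = 9,
                                conserved = data.frame(col = 5, residue = "H",
                                                       occupancy = 1))
  cc <- columnConservation(aln)
  expect_true(all(cc$occupancy_pct[cc$symbol == "*"] == 100))
})

test_that("reference numbering maps identity, insertions and anchored columns", {
  aln <- ProteinAlignment(c(ref = "ACDEF", tgt = "ACDEF"))
  mp <- mapReferenceNumbering(aln, "ref")
  tgt <- mp[mp$seq_id == "tgt", ]
  expect_equal(tgt$ref_number, 1:5)

  ## 3-residue insertion in the target relative to the reference
  aln2 <- ProteinAlignment(c(ref = "ACD---EF", tgt = "ACDGGGEF"))
  mp2 <- mapReferenceNumbering(aln2, "ref")
  tgt2 <- mp2[mp2$seq_id == "tgt", ]
  expect_equal(tgt2$ref_number, c(1, 2, 3, NA, NA, NA, 4, 5))
  expect_equal(tgt2$insertion, c(F, F, F, T, T, T, F, F))

  ## the reference maps onto itself as consecutive integers
  ref2 <- mp2[mp2$seq_id == "ref", ]
  expect_equal(ref2$ref_number, seq_len(sum(ref2$residue != "-")))

  ## a His engineered into the reference's column 57 receives number 57
  ref_row <- paste(rep("A", 80), collapse = "")
  tgt_row <- paste(c(rep("A", 56), "H", rep("A", 23)), collapse = "")
  aln3 <- ProteinAlignment(c(CTRB = ref_row, target = tgt_row))
  mp3 <- mapReferenceNumbering(aln3, "CTRB")
  his <- mp3[mp3$seq_id == "target" & mp3$residue == "H", ]
  expect_equal(his$ref_number, 57L)

  expect_error(mapReferenceNumbering(aln, "nope"), "not present")
})

test_that("composition profiles follow the class definitions", {
  g <- compositionProfile("GGGG")
  expect_equal(unname(g[c("tiny", "aromatic", "nonpolar")]), c(100, 0, 100))
  expect_equal(unname(compositionProfile("FHWY")["aromatic"]), 100)
  all20 <- "ACDEFGHIKLMNPQRSTVWY"
  p20 <- compositionProfile(all20)
  expect_equal(unname(p20["aromatic"]), 20)
  expect_equal(unname(p20["nonpolar"] + p20["polar"]), 100)
  expect_equal(unname(p20["acidic"]), 10)
})

test_that("composition is permutation-invariant, X-insensitive in the denominator", {
  set.seed(5)
  s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30,
                    replace = TRUE), collapse = "")
  shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(compositionProfile(s), compositionProfile(shuf))
  expect_equal(compositionProfile(paste0(s, "XXX")), compositionProfile(s))
  expect_error(compositionProfile("XXX"), "no standard residues")
})

test_that("composition outliers are flagged beyond one strict SD", {
  mk <- function(v) c(tiny = v)
  profs <- list(p1 = mk(10), p2 = mk(10), p3 = mk(10), p4 = mk(16))
  fl <- flagCompositionOutliers(profs)
  ## mean 11.5, sd 3: only 16 > 14.5
  expect_equal(fl$label, "p4")
  expect_equal(fl$direction, "high")

  same <- list(a = mk(10), b = mk(10), c = mk(10))
  expect_equal(nrow(flagCompositionOutliers(same)), 0L)
  expect_error(flagCompositionOutliers(same[1:2]), "at least 3")

  set.seed(8)
  base <- lapply(1:5, function(i) compositionProfile(random_aa_string(40)))
  names(base) <- paste0("s", 1:5)
  aro <- vapply(base, function(p) p[["aromatic"]], 0)
  boosted <- base
  boosted$s5["aromatic"] <- mean(aro[1:4]) + 2 * stats::sd(aro[1:4]) + 20
  fl2 <- flagCompositionOutliers(boosted)
  expect_true(any(fl2$label == "s5" & fl2$class == "aromatic" &
                    fl2$direction == "high"))
})
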