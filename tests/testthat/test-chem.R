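# Expected masses frozen from an independent elemental-composition x
# NIST-atomic-mass computation (pyteomics 5.0.1).

test_that("monoisotopic masses match the independent oracle", {
  expect_equal(monoisotopicMass(elementalComposition(c(H = 2, O = 1))),
               18.0105646, tolerance = 1e-6)
  expect_equal(monoisotopicMass(elementalComposition("C9H11N2O8P")),
               306.025302, tolerance = 1e-4)
  expect_identical(monoisotopicMass(elementalComposition()), 0)
  expect_error(elementalComposition(c(Zz = 1)), "unknown element")
})

test_that("amino-acid and nucleotide residue masses agree with the oracle", {
  oracleAA <- c(A = 71.037114, C = 103.009185, D = 115.026943,
                E = 129.042593, F = 147.068414, G = 57.021464,
                H = 137.058912, I = 113.084064, K = 128.094963,
                L = 113.084064, M = 131.040485, N = 114.042927,
                P = 97.052764, Q = 128.058578, R = 156.101111,
                S = 87.032028, T = 101.047678, V = 99.068414,
                W = 186.079313, Y = 163.063329)
  tabs <- chemTables()
  expect_equal(tabs$aminoAcids[names(oracleAA)], oracleAA,
               tolerance = 1e-4)
  oracleNT <- c(A = 329.052520, C = 305.041286, G = 345.047434,
                U = 306.025302)
  expect_equal(tabs$nucleotides[names(oracleNT)], oracleNT,
               tolerance = 1e-4)
  expect_true(all(tabs$aminoAcids > 0) && all(tabs$nucleotides > 0))
})

test_that("peptide neutral mass is residue sum plus water", {
  expect_equal(peptideNeutralMass("G"), 75.03203, tolerance = 1e-5)
  expect_equal(peptideNeutralMass("GG"), 132.05349, tolerance = 1e-5)
  expect_error(peptideNeutralMass(""), "nonempty")
  expect_error(peptideNeutralMass("GXZ"), "unknown amino acid")
})

test_that("oligo neutral mass follows NMP convention and terminal states", {
  # mononucleotide with 5'-OH/3'-phosphate equals the free NMP
  expect_equal(oligoNeutralMass(oligoComposition(c(U = 1))), 324.035867,
               tolerance = 1e-4)
  # additivity by construction
  expect_equal(oligoNeutralMass(oligoComposition(c(U = 1, C = 1))),
               oligoNeutralMass(oligoComposition(c(U = 1))) + 305.041286,
               tolerance = 1e-4)
  # 5'-phosphate adds one HPO3
  expect_equal(oligoNeutralMass(oligoComposition(c(A = 1)), "5p_3p") -
                 oligoNeutralMass(oligoComposition(c(A = 1))),
               79.96633, tolerance = 1e-5)
  # cyclic phosphate loses one water
  expect_equal(oligoNeutralMass("U1", "cyclic"),
               oligoNeutralMass("U1") - 18.0105646, tolerance = 1e-6)
  expect_error(oligoNeutralMass(oligoComposition(c(A = 0))),
               "at least one nucleotide")
})

test_that("label shifts are correct per scheme", {
  full <- labelScheme("full_13C15N")
  expect_equal(labelShift("U1", full), 11.0243, tolerance = 1e-4)
  expect_equal(labelShift("C1U1", full), 23.0456, tolerance = 1e-4)
  expect_equal(labelShift("C1", full), 12.0213, tolerance = 1e-4)
  expect_equal(labelShift("A2G1U1", full), labelShift("A1", full) * 2 +
                 labelShift("G1", full) + labelShift("U1", full))
  expect_identical(labelShift("A1C1G1U1", labelScheme("none")), 0)
  # post-digestion 18O: constant shift, independent of composition length
  p18 <- labelScheme("post_digest_18O")
  expect_equal(labelShift("U1", p18), 6.0127, tolerance = 1e-3)
  expect_equal(labelShift("A2C1U1", p18), labelShift("G1", p18))
  # empty composition shifts by 0 under every scheme
  empty <- oligoComposition(c(A = 0))
  for (s in list(full, p18, labelScheme("none")))
    expect_identical(labelShift(empty, s), 0)
})

test_that("composition arithmetic is element-wise and guards negatives", {
  a <- elementalComposition(c(C = 2, H = 6))
  b <- elementalComposition(c(H = 2, O = 1))
  expect_equal(monoisotopicMass(a + b),
               monoisotopicMass(a) + monoisotopicMass(b),
               tolerance = 1e-12)
  expect_error(b - a, "negative count")
  # mass additivity over random compositions
  set.seed(42)
  for (i in 1:25) {
    x <- randomComposition(); y <- randomComposition()
    expect_equal(monoisotopicMass(x + y),
                 monoisotopicMass(x) + monoisotopicMass(y),
                 tolerance = 1e-9)
  }
})

test_that("label shift is additive over nucleotides up to length 4", {
  full <- labelScheme("full_13C15N")
  per <- vapply(c("A", "C", "G", "U"),
                function(n) labelShift(paste0(n, 1), full), 0)
  comps <- enumerateCompositions(4L)
  for (i in seq_len(nrow(comps))) {
    cnt <- unlist(comps[i, c("A", "C", "G", "U")])
    expect_equal(labelShift(comps$composition[i], full), sum(cnt * per),
                 tolerance = 1e-9)
  }
})

test_that("composition strings are canonical and round-trip", {
  expect_identical(compositionString(c(U = 1, C = 1)), "C1U1")
  expect_identical(compositionString("UCU"), "C1U2")
  expect_identical(compositionString(oligoComposition("A2G1U1")), "A2G1U1")
  expect_identical(length(oligoComposition("C1U2")), 3L)
  expect_error(oligoComposition(c(X = 1)), "unknown nucleotide")
})

test_that("chemistry tables can be overridden from a YAML config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("elements:\n  H: 2.0", f)
  tabs <- chemTables(f)
  expect_equal(tabs$water, 2 * 2.0 + 15.99491461956, tolerance = 1e-8)
  expect_error(chemTables({
    g <- withr::local_tempfile(fileext = ".yaml")
    writeLines("elements:\n  Xx: 5", g); g
  }), "unknown element")
})
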