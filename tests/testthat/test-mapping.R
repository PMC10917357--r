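test_that("residue maps count identifications per localized residue", {
  ids <- data.frame(protein = "P1",
                    site = c(10L, 10L, 10L, 12L),
                    composition = c("U1", "U1", "C1U1", "U1"))
  m <- residueMap(ids)
  expect_identical(residueCounts(m),
                   data.frame(site = c(10L, 12L), count = c(3L, 1L)))
  # composition breakdown accounts for every identification
  expect_identical(sum(residueCompositions(m)$count), 4L)
  # empty input: all-zero map
  m0 <- residueMap(ids[0, ], protein = "P1")
  expect_identical(nrow(residueCounts(m0)), 0L)
  expect_error(residueMap(ids, protein = "OTHER"), "unknown protein")
  expect_error(residueMap(ids, protein = "P1", proteinLength = 5),
               "outside protein")
})

test_that("residue map totals are conserved and argmax matches truth", {
  rt <- toyRoundTrip(nSites = 8L, nIds = 24L, seed = 303L)
  csms <- rt$filt$csms
  m <- residueMap(csms, protein = toyProtein()$id)
  expect_identical(sum(residueCounts(m)$count), nrow(csms))
  top <- residueCounts(m)$site[which.max(residueCounts(m)$count)]
  truthTop <- as.integer(names(which.max(table(rt$truth$site))))
  expect_identical(top, truthTop)
})

test_that("composition-to-RNA mapping finds exactly the matching windows", {
  rna3x <- toyRNA()
  expect_identical(nrow(mapCompositionToRNA("U5", rna3x)), 0L)
  a3 <- mapCompositionToRNA("A1", "AAA")
  expect_identical(a3$start, 1:3)
  # every returned window re-validates against the queried multiset
  set.seed(55)
  for (i in 1:20) {
    comp <- enumerateCompositions(3L)
    cs <- sample(comp$composition, 1)
    win <- mapCompositionToRNA(cs, rna3x)
    if (nrow(win))
      for (s in win$sequence)
        expect_identical(compositionString(s), cs)
    # exhaustive scan oracle: count windows directly
    k <- length(oligoComposition(cs))
    n <- nchar(rna3x$sequence)
    cnt <- sum(vapply(seq_len(n - k + 1), function(p)
      compositionString(substr(rna3x$sequence, p, p + k - 1)) == cs,
      TRUE))
    expect_identical(nrow(win), as.integer(cnt))
  }
})

test_that("offset maps local windows into external RNA numbering", {
  # stem-loop RNA with local coordinates 1..45; an offset of 725 reports
  # sites in the 750s-760s numbering of the parent 3'-UTR
  s2m <- "GGUUCACCGAGGCCACGCGGAGUACGAUCGAGUGUACAGUGAACC"
  gu <- mapCompositionToRNA("G1U1", s2m, offset = 725L)
  expect_true(all(c(757L, 764L) %in% gu$start))
  # offset is a pure shift of both interval ends
  gu0 <- mapCompositionToRNA("G1U1", s2m, offset = 0L)
  expect_identical(gu$start, gu0$start + 725L)
  expect_identical(gu$end, gu0$end + 725L)
})

test_that("IUPAC motif matching counts repeats and registers", {
  expect_length(findMotifMatches("UCUCU", toyRNA()), 3L)
  expect_length(findMotifMatches("YCUNN", "UCUCUAAAAA"), 2L)
  expect_length(findMotifMatches("ACGUACGU", "ACG"), 0L)
  expect_error(findMotifMatches("YCJ", "ACGU"), "invalid IUPAC")
})

test_that("phase comparison partitions keys with paired counts", {
  a <- data.frame(protein = "P", site = c(1L, 1L, 2L, 3L),
                  composition = "U1")
  b <- data.frame(protein = "P", site = c(1L, 3L, 4L),
                  composition = "U1")
  pc <- comparePhases(a, b)
  expect_identical(nrow(sharedSites(pc)), 2L)
  expect_identical(sharedSites(pc)$countA[sharedSites(pc)$key ==
                                          "P|1|U1"], 2L)
  expect_identical(uniqueSites(pc, "A"), "P|2|U1")
  expect_identical(uniqueSites(pc, "B"), "P|4|U1")
  # identical inputs: everything shared
  pcId <- comparePhases(a, a)
  expect_identical(length(uniqueSites(pcId, "A")), 0L)
  expect_identical(length(uniqueSites(pcId, "B")), 0L)
  # disjoint inputs: nothing shared
  d <- data.frame(protein = "Q", site = 9L, composition = "G1")
  expect_identical(nrow(sharedSites(comparePhases(a, d))), 0L)
  # symmetric up to swapping labels
  pcSwap <- comparePhases(b, a)
  expect_identical(uniqueSites(pcSwap, "A"), uniqueSites(pc, "B"))
  expect_identical(sharedSites(pcSwap)$countA, sharedSites(pc)$countB)
  expect_error(comparePhases(a, data.frame(x = 1)), "key columns")
})

test_that("two-phase round trip recovers the constructed partition", {
  truth <- makeTruthTable(toyProtein(), toyRNA(), nSites = 10L,
                          nIds = 20L, seed = 404L)
  u <- truth[!duplicated(paste(truth$site, truth$composition)), ]
  tp <- simulateTwoPhase(u[1:5, ], u[6:7, ], u[8:10, ], seed = 405L)
  cand <- toyCandidates()
  fA <- filterFdr(searchSpectra(tp$A$spectra, cand))
  fB <- filterFdr(searchSpectra(tp$B$spectra, cand))
  pc <- comparePhases(fA$csms, fB$csms)
  expect_identical(nrow(sharedSites(pc)), 5L)
  expect_identical(length(uniqueSites(pc, "A")), 2L)
  expect_identical(length(uniqueSites(pc, "B")), 3L)
})

test_that("windowed aggregation sums neighbouring residues without losing counts", {
  ids <- data.frame(protein = "P1", site = c(10L, 11L, 14L),
                    composition = "U1")
  m <- residueMap(ids, window = 1L)
  rc <- residueCounts(m)
  expect_identical(rc$window_count[rc$site == 10L], 2L)
  expect_identical(rc$window_count[rc$site == 14L], 1L)
  # raw counts still conserve the identification total
  expect_identical(sum(rc$count), nrow(ids))
})
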