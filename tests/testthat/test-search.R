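test_that("doublet detection pairs precursors by neutral-mass spacing", {
  dmU <- labelShift("U1", labelScheme("full_13C15N"))
  mkSpec <- function(id, M, z)
    Spectrum(id, (M + z * 1.00727646677) / z, z, mz = 200, intensity = 1)
  shifts <- data.frame(dm = dmU, compositions = "U1")
  # worked pair at z = 1
  sp <- list(mkSpec("a", 1000, 1), mkSpec("b", 1000 + dmU, 1))
  d <- findDoublets(sp, shifts, ppmTol = 10)
  expect_identical(nrow(d), 1L)
  expect_identical(d$light_id, "a")
  expect_equal(d$dm_obs, dmU, tolerance = 1e-9)
  # same neutral pair at z = 2: m/z spacing is dm / 2
  sp2 <- list(mkSpec("a", 1000, 2), mkSpec("b", 1000 + dmU, 2))
  expect_equal(sp2[[2]]@precursorMz - sp2[[1]]@precursorMz, dmU / 2,
               tolerance = 1e-9)
  expect_identical(nrow(findDoublets(sp2, shifts)), 1L)
  # charge mismatch or lone spectrum yields nothing
  spMix <- list(mkSpec("a", 1000, 1), mkSpec("b", 1000 + dmU, 2))
  expect_identical(nrow(findDoublets(spMix, shifts)), 0L)
  expect_identical(nrow(findDoublets(sp[1], shifts)), 0L)
})

test_that("precursor matching respects mass and shift tolerances", {
  cand <- toyCandidates(maxAdductLen = 2L)
  tgt <- cand[!cand$is_decoy, ][5, ]
  db <- data.frame(light_id = "L", heavy_id = "H", charge = 2L,
                   light_mass = tgt$light, dm_obs = tgt$dm)
  hit <- matchPrecursor(db, cand, ppmTol = 10)
  expect_true(any(hit$sequence == tgt$sequence &
                  hit$composition == tgt$composition &
                  hit$loss == tgt$loss & !hit$is_decoy))
  # zero tolerance keeps only exact masses
  hit0 <- matchPrecursor(db, cand, ppmTol = 0)
  expect_true(all(hit0$light == tgt$light & hit0$dm == tgt$dm))
  # an off-by-1-Da precursor matches nothing at 10 ppm
  db1 <- db; db1$light_mass <- db1$light_mass + 1
  expect_identical(nrow(matchPrecursor(db1, cand, ppmTol = 10)), 0L)
})

test_that("site localization recovers the true residue on clean spectra", {
  pep <- "AGHTLK"; site <- 3L; comp <- "C1U1"
  frag <- theoreticalFragments(pep, site, comp)
  spec <- Spectrum("s", 500, 2, mz = frag$mz,
                   intensity = rep(100, nrow(frag)))
  loc <- localizeAndScore(spec, pep, comp)
  expect_identical(loc$site, site)
  expect_identical(loc$ambiguity, site)
  expect_gt(loc$score, 0)
  # length-1 peptide is forced to site 1
  f1 <- theoreticalFragments("K", 1, "U1")
  s1 <- Spectrum("s1", 300, 1, mz = f1$mz, intensity = rep(10, nrow(f1)))
  l1 <- localizeAndScore(s1, "K", "U1")
  expect_identical(l1$site, 1L)
  expect_identical(l1$ambiguity, 1L)
  # a spectrum whose only informative peaks are short adduct-free y-ions
  # is consistent with every site upstream of them: ambiguous
  fAll <- theoreticalFragments(pep, site, comp)
  fFree <- fAll[fAll$series == "y" & !fAll$hasAdduct & fAll$index <= 2, ]
  sFree <- Spectrum("s2", 500, 2, mz = fFree$mz,
                    intensity = rep(100, nrow(fFree)))
  lFree <- localizeAndScore(sFree, pep, comp)
  expect_gt(length(lFree$ambiguity), 1L)
  expect_identical(lFree$site, min(lFree$ambiguity))
  expect_error(localizeAndScore(Spectrum("e", 500, 2), pep, comp),
               "empty peak list")
})

test_that("decoys reverse sequences, keep termini and preserve mass", {
  peps <- data.frame(protein = "P", start = c(1L, 5L), end = c(4L, 10L),
                     sequence = c("GASK", "LMNPQR"), missed = 0L)
  dec <- buildDecoys(peps)
  expect_identical(dec$sequence, c("SAGK", "QPNMLR"))
  expect_true(all(dec$is_decoy))
  expect_identical(dec$protein, rep("DECOY_P", 2))
  expect_equal(vapply(dec$sequence, peptideNeutralMass, 0,
                      USE.NAMES = FALSE),
               vapply(peps$sequence, peptideNeutralMass, 0,
                      USE.NAMES = FALSE), tolerance = 1e-12)
  # palindromic-after-rule peptides are excluded with a warning
  pal <- data.frame(protein = "P", start = 1L, end = 3L,
                    sequence = "AAK", missed = 0L)
  expect_warning(d2 <- buildDecoys(rbind(peps, pal)), "themselves")
  expect_identical(nrow(d2), 2L)
})

test_that("FDR filtering counts decoys and monotonizes q-values", {
  mkCsm <- function(n, score, decoy, offset = 0)
    data.frame(peptide = paste0("PEP", offset + seq_len(n)),
               adduct_mass = 324.0359, site = offset + seq_len(n),
               score = score, is_decoy = decoy)
  # clean separation: every target outscores every decoy
  sep <- rbind(mkCsm(100, 100 + 1:100, FALSE),
               mkCsm(20, 1:20, TRUE, offset = 1000))
  f <- filterFdr(sep)
  expect_identical(nrow(f$identifications), 100L)
  expect_identical(f$estimatedFdr, 0)
  # exactly one decoy above the 100th target: boundary at 1%
  bnd <- rbind(mkCsm(100, 100 + 1:100, FALSE),
               mkCsm(1, 101.5, TRUE, offset = 1000))
  fb <- filterFdr(bnd, qThreshold = 0.01)
  expect_identical(nrow(fb$identifications), 100L)
  expect_equal(fb$estimatedFdr, 0.01, tolerance = 1e-12)
  # all targets below all decoys: nothing passes
  low <- rbind(mkCsm(10, 1:10, FALSE), mkCsm(10, 100 + 1:10, TRUE,
                                             offset = 1000))
  fl <- filterFdr(low)
  expect_identical(nrow(fl$identifications), 0L)
  # q-values are monotone nonincreasing in score
  set.seed(77)
  rnd <- rbind(mkCsm(200, rnorm(200, 10), FALSE),
               mkCsm(200, rnorm(200, 8), TRUE, offset = 1000))
  fr <- filterFdr(rnd, qThreshold = 0.5)
  u <- fr$unique[order(-fr$unique$score), ]
  expect_true(all(diff(u$qvalue) >= -1e-12))
  expect_error(filterFdr(mkCsm(5, 1:5, FALSE)), "no decoy")
})

test_that("unique collapse keeps the best score per peptide/mass/site key", {
  csms <- data.frame(peptide = c("AAK", "AAK", "AAK", "CCK"),
                     adduct_mass = c(324.0359, 324.0359, 650.1, 324.0359),
                     site = c(2L, 2L, 2L, 5L),
                     score = c(5, 9, 7, 4),
                     is_decoy = FALSE)
  csms <- rbind(csms, data.frame(peptide = "DDK", adduct_mass = 1,
                                 site = 1L, score = 0.5, is_decoy = TRUE))
  f <- filterFdr(csms, qThreshold = 1)
  u <- f$unique[!f$unique$is_decoy, ]
  expect_identical(nrow(u), 3L)
  expect_identical(u$score[u$peptide == "AAK" &
                           abs(u$adduct_mass - 324.0359) < 1e-6], 9)
  # spectral-count level retains all CSMs of passing keys
  expect_identical(nrow(f$csms), 4L)
})

test_that("noiseless round trip recovers nearly all ground truth at 1% FDR", {
  rt <- toyRoundTrip(nSites = 12L, nIds = 30L, seed = 101L)
  truthKeys <- unique(truthKey(rt$truth))
  idKeys <- truthKey(rt$filt$identifications)
  recovery <- mean(truthKeys %in% idKeys)
  expect_gte(recovery, 0.99)
  # recovered rows carry the right composition and site by construction of
  # the key; check FDR estimate is controlled
  expect_lte(rt$filt$estimatedFdr, 0.01)
})

test_that("realized error against ground truth stays near the estimate", {
  rt <- toyRoundTrip(nSites = 12L, nIds = 40L, seed = 202L,
                     noise = noiseParams(nNoisePeaks = 60L,
                                         intensitySd = 0.3))
  ids <- rt$filt$identifications
  expect_gt(nrow(ids), 0L)
  fdp <- mean(!truthKey(ids) %in% truthKey(rt$truth))
  # realized false-discovery proportion <= 2x the estimated FDR, with an
  # absolute floor of one count for small-sample stability
  bound <- max(2 * rt$filt$estimatedFdr, 2 * rt$filt$qThreshold)
  expect_lte(fdp, bound + 1 / nrow(ids))
})
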