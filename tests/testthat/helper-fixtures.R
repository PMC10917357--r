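# Shared fixtures, built in code at test time.

# toy RNA-binding protein with a realistic mix of tryptic sites
toyProtein <- function(id = "TOY1") {
  data.frame(id = id, kind = "protein",
    sequence = paste0("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQ",
                      "DNLSGAEKAVQVKVKALPDAQFEVVHSLAKWKRPFLNVSYAHELK"),
    stringsAsFactors = FALSE)
}

# pyrimidine-tract RNA: three UCUCU repeats separated by adenosines
toyRNA <- function(id = "RNA1") {
  data.frame(id = id, kind = "rna",
    sequence = "GGGAGAUCUCUAAAAAUCUCUAAAAAUCUCUAAAAA",
    stringsAsFactors = FALSE)
}

# target + decoy precursor candidate table for the toy protein
toyCandidates <- function(maxAdductLen = 3L, scheme = labelScheme("full_13C15N"),
                          maxMissed = 0L) {
  peps <- digestProtein(toyProtein(), maxMissed = maxMissed,
                        lengthRange = c(5L, 40L))
  comps <- enumerateCompositions(maxAdductLen)
  rbind(generateCandidates(peps, comps, scheme = scheme),
        generateCandidates(suppressWarnings(buildDecoys(peps)), comps,
                           scheme = scheme))
}

# simulate + search + FDR in one go; returns everything for inspection
toyRoundTrip <- function(nSites = 6L, nIds = 12L, seed = 11L,
                         noise = noiseParams(),
                         scheme = labelScheme("full_13C15N"),
                         qThreshold = 0.01) {
  truth <- makeTruthTable(toyProtein(), toyRNA(), nSites = nSites,
                          nIds = nIds, seed = seed)
  sim <- simulateDataset(truth, scheme = scheme, noise = noise,
                         seed = seed + 1L)
  cand <- toyCandidates(scheme = scheme)
  csms <- searchSpectra(sim$spectra, cand, scheme = scheme)
  filt <- filterFdr(csms, qThreshold = qThreshold)
  list(truth = truth, sim = sim, candidates = cand, csms = csms,
       filt = filt)
}

truthKey <- function(df) paste(df$peptide, df$site, df$composition)

# random elemental composition over light elements
randomComposition <- function() {
  syms <- c("C", "H", "N", "O", "P", "S")
  n <- sample(2:5, 1)
  pick <- sample(syms, n)
  elementalComposition(stats::setNames(sample(0:20, n, replace = TRUE), pick))
}
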