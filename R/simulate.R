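#' Noise model parameters for the spectrum simulator
#'
#' @param nNoisePeaks Number of uniform random decoy peaks added per MS2
#'   spectrum (0 disables noise).
#' @param intensitySd Standard deviation (log scale) of the multiplicative
#'   log-normal jitter applied to fragment intensities (0 disables
#'   jitter).
#' @param mzRange m/z window for noise peaks.
#' @param noiseIntensity Mean intensity of noise peaks.
#' @return A list of noise parameters.
#' @export
noiseParams <- function(nNoisePeaks = 0L, intensitySd = 0,
                        mzRange = c(100, 2000), noiseIntensity = 30) {
  stopifnot(nNoisePeaks >= 0L, intensitySd >= 0, length(mzRange) == 2L)
  list(nNoisePeaks = as.integer(nNoisePeaks), intensitySd = intensitySd,
       mzRange = mzRange, noiseIntensity = noiseIntensity)
}

#' Sample a ground-truth cross-link table
#'
#' Draws plausible cross-link identifications for a protein/RNA system:
#' tryptic peptides within a length range, a uniformly chosen residue per
#' peptide, and adduct compositions taken from the actual nuclease digest
#' of the RNA (capped at \code{maxAdductLen}). \code{nSites} unique
#' (peptide, site, composition) combinations are drawn, then \code{nIds}
#' identifications are sampled from them with replacement, emulating
#' spectral counts.
#'
#' @param proteins data.frame of protein records (id, sequence).
#' @param rna One-row RNA record or sequence string.
#' @param nSites Number of unique cross-link sites.
#' @param nIds Total identifications (>= nSites); each becomes one
#'   light/heavy doublet pair.
#' @param phase Phase label stamped on every record.
#' @param nucleases,maxAdductLen RNA digestion settings.
#' @param lengthRange Tryptic peptide length range.
#' @param seed Integer seed.
#' @return data.frame with columns \code{protein}, \code{pep_start},
#'   \code{pep_end}, \code{peptide}, \code{site} (protein coordinates),
#'   \code{composition}, \code{loss}, \code{phase}.
#' @export
makeTruthTable <- function(proteins, rna, nSites = 10L, nIds = nSites,
                           phase = "dispersed",
                           nucleases = c("RNaseT1", "RNaseA", "benzonase"),
                           maxAdductLen = 3L, lengthRange = c(6L, 25L),
                           seed = 1L) {
  stopifnot(nIds >= nSites, nSites >= 1L)
  set.seed(seed)
  peps <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
    digestProtein(proteins[i, , drop = FALSE], maxMissed = 0L,
                  lengthRange = lengthRange)))
  if (!nrow(peps)) stop("no tryptic peptides in the requested length range")
  oligos <- digestRNA(rna, nucleases = nucleases, maxLength = maxAdductLen)
  oligos <- oligos[nchar(oligos$sequence) <= maxAdductLen, , drop = FALSE]
  comps <- unique(vapply(oligos$sequence, compositionString, "",
                         USE.NAMES = FALSE))
  sites <- data.frame()
  tries <- 0L
  while (nrow(sites) < nSites && tries < 50L * nSites) {
    tries <- tries + 1L
    p <- peps[sample.int(nrow(peps), 1L), ]
    off <- sample.int(nchar(p$sequence), 1L)
    cand <- data.frame(protein = p$protein, pep_start = p$start,
                       pep_end = p$end, peptide = p$sequence,
                       site = p$start + off - 1L,
                       composition = sample(comps, 1L),
                       stringsAsFactors = FALSE)
    sites <- unique(rbind(sites, cand))
  }
  if (nrow(sites) < nSites)
    stop("could not draw ", nSites, " unique cross-link sites")
  idx <- c(seq_len(nSites), sample.int(nSites, nIds - nSites, replace = TRUE))
  out <- sites[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$loss <- "none"
  out$phase <- phase
  out
}

#' Simulate a doublet-bearing cross-link MS2 dataset
#'
#' For every ground-truth record the simulator emits a light and a heavy
#' precursor as two separate MS2 spectra whose neutral masses differ by
#' the label shift of the adduct composition, with precursor intensity
#' split so that heavy/(light+heavy) equals \code{heavyFraction} exactly.
#' Fragment peaks are the full theoretical b/y ladder (the heavy member
#' carries the shifted adduct on adduct-bearing ions), optionally jittered
#' in intensity and topped with uniform random noise peaks. Output is
#' byte-identical for a fixed seed.
#'
#' @param truth data.frame as produced by \code{\link{makeTruthTable}}.
#' @param scheme A \linkS4class{LabelScheme}.
#' @param heavyFraction Heavy intensity share, strictly between 0 and 1
#'   (0.5 models equimolar heavy/light RNA mixing).
#' @param noise List from \code{\link{noiseParams}}.
#' @param chargeStates Precursor charges to draw from.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param outDir If non-NULL, writes \code{spectra.mgf} and
#'   \code{truth.tsv} there.
#' @param baseIntensity Mean total precursor intensity per doublet.
#' @return List with \code{spectra} (list of \linkS4class{Spectrum}) and
#'   \code{truth} (input table augmented with spectrum ids, charge and
#'   m/z columns), plus file paths when \code{outDir} is given.
#' @export
simulateDataset <- function(truth, scheme = labelScheme("full_13C15N"),
                            heavyFraction = 0.5, noise = noiseParams(),
                            chargeStates = c(2L, 3L), seed = 1L,
                            outDir = NULL, baseIntensity = 1000) {
  if (length(heavyFraction) != 1L || is.na(heavyFraction) ||
      heavyFraction <= 0 || heavyFraction >= 1)
    stop("heavyFraction must lie strictly between 0 and 1")
  stopifnot(nrow(truth) >= 1L)
  bad <- which(truth$site < truth$pep_start | truth$site > truth$pep_end)
  if (length(bad))
    stop("truth row ", bad[1], ": site outside its peptide span")
  set.seed(seed)
  spectra <- vector("list", 2L * nrow(truth))
  truth$light_id <- truth$heavy_id <- NA_character_
  truth$charge <- NA_integer_
  truth$light_mz <- truth$heavy_mz <- NA_real_
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    siteInPep <- tr$site - tr$pep_start + 1L
    comp <- oligoComposition(tr$composition)
    pepM <- peptideNeutralMass(tr$peptide)
    adduct <- oligoNeutralMass(comp) - neutralLosses(tr$loss)$mass
    lightM <- pepM + adduct
    dm <- labelShift(comp, scheme)
    z <- if (length(chargeStates) > 1L)
      sample(as.integer(chargeStates), 1L) else as.integer(chargeStates)
    total <- baseIntensity *
      if (noise$intensitySd > 0) exp(rnorm(1L, 0, noise$intensitySd)) else 1
    ids <- sprintf("sim_%05d_%s", i, c("L", "H"))
    for (h in 1:2) {
      heavy <- h == 2L
      frag <- theoreticalFragments(tr$peptide, siteInPep, comp,
                                   loss = tr$loss, scheme = scheme,
                                   heavy = heavy)
      fint <- rep(100, nrow(frag))
      if (noise$intensitySd > 0)
        fint <- fint * exp(rnorm(nrow(frag), 0, noise$intensitySd))
      mzv <- frag$mz
      if (noise$nNoisePeaks > 0L) {
        nm <- runif(noise$nNoisePeaks, noise$mzRange[1], noise$mzRange[2])
        ni <- noise$noiseIntensity * exp(rnorm(noise$nNoisePeaks, 0,
                                               max(noise$intensitySd, 0.5)))
        mzv <- c(mzv, nm)
        fint <- c(fint, ni)
      }
      precM <- if (heavy) lightM + dm else lightM
      precInt <- total * if (heavy) heavyFraction else 1 - heavyFraction
      spectra[[2L * (i - 1L) + h]] <- Spectrum(
        ids[h], (precM + z * .MASS_PROTON) / z, z,
        mz = mzv, intensity = fint, precursorIntensity = precInt)
    }
    truth$light_id[i] <- ids[1]
    truth$heavy_id[i] <- ids[2]
    truth$charge[i] <- z
    truth$light_mz[i] <- (lightM + z * .MASS_PROTON) / z
    truth$heavy_mz[i] <- (lightM + dm + z * .MASS_PROTON) / z
  }
  res <- list(spectra = spectra, truth = truth)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    res$mgf <- file.path(outDir, "spectra.mgf")
    res$truthFile <- file.path(outDir, "truth.tsv")
    writeMGF(spectra, res$mgf)
    utils::write.table(truth, res$truthFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

#' Simulate a two-phase (dispersed/condensed) cross-link experiment
#'
#' Builds two datasets whose ground-truth site sets intersect exactly in
#' \code{shared}: phase A receives \code{shared} plus \code{aOnly}, phase
#' B receives \code{shared} plus \code{bOnly}. The phase-specific tables
#' must be disjoint from each other and from the shared set (keyed on
#' protein, site, composition).
#'
#' @param shared,aOnly,bOnly Truth tables (possibly 0-row) with the
#'   columns of \code{\link{makeTruthTable}}.
#' @param labels Phase labels, default dispersed/condensed.
#' @param seed Integer seed; phase B uses \code{seed + 1}.
#' @param ... Passed on to \code{\link{simulateDataset}}.
#' @return List with elements \code{A}, \code{B} (each a
#'   \code{simulateDataset} result) and \code{truth} (merged table with
#'   phase labels).
#' @export
simulateTwoPhase <- function(shared, aOnly = NULL, bOnly = NULL,
                             labels = c("dispersed", "condensed"),
                             seed = 1L, ...) {
  key <- function(df) if (is.null(df) || !nrow(df)) character() else
    paste(df$protein, df$site, df$composition, sep = "|")
  if (length(intersect(key(aOnly), key(bOnly))))
    stop("phase-specific site sets overlap")
  if (length(intersect(key(shared), c(key(aOnly), key(bOnly)))))
    stop("shared sites reappear in a phase-specific set")
  bindT <- function(...) {
    parts <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
    do.call(rbind, parts)
  }
  tA <- bindT(shared, aOnly); tA$phase <- labels[1]
  tB <- bindT(shared, bOnly); tB$phase <- labels[2]
  A <- simulateDataset(tA, seed = seed, ...)
  B <- simulateDataset(tB, seed = seed + 1L, ...)
  list(A = A, B = B, truth = rbind(A$truth, B$truth), labels = labels)
}
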