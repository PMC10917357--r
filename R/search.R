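#' Label-shift hypotheses for doublet detection
#'
#' Unique heavy-minus-light shifts implied by a composition search space
#' under a labeling scheme, with the compositions producing each shift.
#'
#' @param compositions data.frame from \code{\link{enumerateCompositions}}.
#' @param scheme A \linkS4class{LabelScheme}.
#' @return data.frame with columns \code{dm} and \code{compositions}
#'   (comma-joined canonical strings).
#' @export
shiftHypotheses <- function(compositions, scheme) {
  dm <- vapply(compositions$composition, function(cs)
    labelShift(oligoComposition(cs), scheme), 0, USE.NAMES = FALSE)
  key <- round(dm, 6)
  agg <- tapply(compositions$composition, key, paste, collapse = ",")
  data.frame(dm = as.numeric(names(agg)),
             compositions = unname(as.character(agg)),
             stringsAsFactors = FALSE)
}

#' Detect light/heavy precursor doublets
#'
#' Pairs of same-charge precursors whose neutral-mass difference matches
#' one of the label-shift hypotheses within a ppm tolerance (relative to
#' the light neutral mass). A spectrum may take part in several candidate
#' pairs; downstream precursor matching disambiguates.
#'
#' @param spectra List of \linkS4class{Spectrum}.
#' @param shifts data.frame from \code{\link{shiftHypotheses}} (column
#'   \code{dm}; optional \code{compositions}).
#' @param ppmTol Tolerance in ppm.
#' @return data.frame with columns \code{light_id}, \code{heavy_id},
#'   \code{charge}, \code{light_mass}, \code{dm_obs},
#'   \code{hypotheses} (comma-joined compositions consistent with the
#'   observed shift).
#' @export
findDoublets <- function(spectra, shifts, ppmTol = 10) {
  empty <- data.frame(light_id = character(), heavy_id = character(),
                      charge = integer(), light_mass = numeric(),
                      dm_obs = numeric(), hypotheses = character(),
                      stringsAsFactors = FALSE)
  if (length(spectra) < 2L) return(empty)
  z <- vapply(spectra, slot, 0L, "charge")
  M <- vapply(spectra, neutralPrecursorMass, 0)
  id <- vapply(spectra, slot, "", "id")
  hyComp <- if (!is.null(shifts$compositions)) shifts$compositions else
    rep("", nrow(shifts))
  rows <- list()
  for (zz in unique(z)) {
    sel <- which(z == zz)
    o <- sel[order(M[sel])]
    m <- M[o]
    for (h in seq_len(nrow(shifts))) {
      dm <- shifts$dm[h]
      tol <- ppmTol * 1e-6 * m + abs(dm) * ppmTol * 1e-6
      lo <- findInterval(m + dm - tol, m)
      hi <- findInterval(m + dm + tol, m)
      for (i in which(hi > lo)) {
        for (j in (lo[i] + 1L):hi[i]) {
          if (j == i && dm == 0) next
          rows[[length(rows) + 1L]] <- data.frame(
            light_id = id[o[i]], heavy_id = id[o[j]], charge = zz,
            light_mass = m[i], dm_obs = m[j] - m[i],
            hypotheses = hyComp[h], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- unique(out[, c("light_id", "heavy_id", "charge", "light_mass",
                        "dm_obs", "hypotheses")])
  # merge hypothesis lists for pairs matched by several shift values
  keyp <- paste(out$light_id, out$heavy_id, out$charge)
  if (anyDuplicated(keyp)) {
    hyp <- tapply(out$hypotheses, keyp, function(x)
      paste(unique(unlist(strsplit(x, ","))), collapse = ","))
    out <- out[!duplicated(keyp), , drop = FALSE]
    out$hypotheses <- unname(hyp[paste(out$light_id, out$heavy_id,
                                       out$charge)])
  }
  rownames(out) <- NULL
  out
}

#' Match precursor candidates to a doublet
#'
#' Candidates whose light neutral mass matches the doublet's light member
#' and whose label shift matches the observed spacing, both within the
#' ppm tolerance.
#'
#' @param doublet One row of the \code{\link{findDoublets}} output.
#' @param candidates data.frame from \code{\link{generateCandidates}}.
#' @param ppmTol Tolerance in ppm.
#' @return Subset of \code{candidates} (possibly empty).
#' @export
matchPrecursor <- function(doublet, candidates, ppmTol = 10) {
  stopifnot(nrow(doublet) == 1L)
  tolM <- ppmTol * 1e-6 * doublet$light_mass
  ok <- abs(candidates$light - doublet$light_mass) <= tolM &
    abs(candidates$dm - doublet$dm_obs) <= tolM
  candidates[ok, , drop = FALSE]
}

#' Localize the cross-linked residue and score the assignment
#'
#' Evaluates every residue of the peptide as the putative cross-link site.
#' For each site the theoretical b/y ladder (adduct on that site) is
#' matched against the peak list at \code{fragTolPpm}; the surrogate score
#' is the sum of log2(1 + intensity) over matched theoretical ions,
#' multiplied by the fraction of theoretical ions matched — a log-intensity
#' weighted matched-ion count penalized for incomplete ladders, so that a
#' long candidate cannot outscore a short one on scattered coincidental
#' matches. The reported site is the lowest-position argmax; all sites
#' scoring within \code{tieTol} of the maximum form the ambiguity set.
#'
#' @param spec A \linkS4class{Spectrum} with a nonempty peak list.
#' @param peptide Peptide sequence.
#' @param comp Adduct composition.
#' @param loss Neutral-loss id.
#' @param fragTolPpm Fragment tolerance in ppm.
#' @param scheme,heavy Labeling context for the ladder (heavy member
#'   spectra carry shifted adduct ions).
#' @param tieTol Score difference under which two sites count as tied.
#' @return List with \code{site} (1-based within peptide), \code{score},
#'   \code{ambiguity} (integer site set), \code{siteScores}.
#' @export
localizeAndScore <- function(spec, peptide, comp, loss = "none",
                             fragTolPpm = 20, scheme = labelScheme("none"),
                             heavy = FALSE, tieTol = 1e-9) {
  stopifnot(is(spec, "Spectrum"))
  if (!length(spec@mz)) stop("empty peak list: spectrum ", spec@id)
  n <- nchar(peptide)
  scores <- numeric(n)
  for (s in seq_len(n)) {
    frag <- theoreticalFragments(peptide, s, comp, loss = loss,
                                 scheme = scheme, heavy = heavy)
    scores[s] <- .matchScore(frag$mz, spec@mz, spec@intensity, fragTolPpm)
  }
  best <- max(scores)
  amb <- which(scores >= best - tieTol)
  list(site = amb[1], score = best, ambiguity = amb, siteScores = scores)
}

# sum of log2(1+intensity) over theoretical m/z values with a peak within
# tol ppm (nearest peak per theoretical ion), scaled by the matched
# fraction of the theoretical ladder
.matchScore <- function(theo, mz, intensity, ppm) {
  if (!length(theo) || !length(mz)) return(0)
  idx <- findInterval(theo, mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(mz))
  dLo <- abs(theo - mz[lo])
  dHi <- abs(theo - mz[hi])
  nearest <- ifelse(dLo <= dHi, lo, hi)
  dist <- pmin(dLo, dHi)
  ok <- dist <= ppm * 1e-6 * theo
  sum(log2(1 + intensity[nearest[ok]])) * sum(ok) / length(theo)
}

#' Build decoy peptides
#'
#' Reverses each target sequence keeping the C-terminal residue fixed (so
#' tryptic termini and the exact precursor mass are preserved). Peptides
#' that map to themselves under the rule are excluded with a warning.
#'
#' @param peptides data.frame from \code{\link{digestProtein}}.
#' @return data.frame of the same shape with reversed sequences,
#'   \code{protein} prefixed \code{"DECOY_"} and \code{is_decoy = TRUE}.
#' @examples
#' buildDecoys(data.frame(protein = "P", start = 1, end = 4,
#'                        sequence = "GASK", missed = 0))
#' @export
buildDecoys <- function(peptides) {
  revKeep <- function(s) {
    n <- nchar(s)
    if (n <= 2L) return(s)
    paste0(paste(rev(strsplit(substr(s, 1L, n - 1L), "")[[1]]),
                 collapse = ""), substr(s, n, n))
  }
  dec <- peptides
  dec$sequence <- vapply(peptides$sequence, revKeep, "", USE.NAMES = FALSE)
  self <- dec$sequence == peptides$sequence
  if (any(self)) {
    warning(sum(self), " peptide(s) map to themselves under reversal ",
            "and were excluded from the decoy set: ",
            paste(utils::head(peptides$sequence[self], 5), collapse = ", "))
    dec <- dec[!self, , drop = FALSE]
  }
  dec$protein <- paste0("DECOY_", dec$protein)
  dec$is_decoy <- TRUE
  rownames(dec) <- NULL
  dec
}

#' Search a spectrum set against precursor candidates
#'
#' The identification engine: detects doublets, matches candidates by
#' light mass and shift, localizes and scores each assignment on the
#' light member of the doublet, and returns one cross-link spectrum match
#' (CSM) row per (doublet, candidate).
#'
#' @param spectra List of \linkS4class{Spectrum}.
#' @param candidates Target (and decoy) candidates from
#'   \code{\link{generateCandidates}}.
#' @param scheme \linkS4class{LabelScheme} used for the search.
#' @param ppmPrecursor,ppmFragment Tolerances in ppm.
#' @param phase Optional phase label stamped on all rows.
#' @param verbose Print per-stage counts.
#' @return data.frame of CSMs: spectrum ids, charge, peptide and protein
#'   coordinates, \code{site} (protein coordinates), \code{site_in_pep},
#'   \code{n_ambiguous}, \code{composition}, \code{loss},
#'   \code{adduct_mass}, \code{dm}, \code{score}, \code{is_decoy},
#'   \code{phase}.
#' @export
searchSpectra <- function(spectra, candidates,
                          scheme = labelScheme("full_13C15N"),
                          ppmPrecursor = 10, ppmFragment = 20,
                          phase = NA_character_, verbose = FALSE) {
  shifts <- data.frame(dm = sort(unique(round(candidates$dm, 6))))
  doublets <- findDoublets(spectra, shifts, ppmTol = ppmPrecursor)
  if (verbose)
    message(length(spectra), " spectra; ", nrow(doublets),
            " doublet candidates")
  specIdx <- structure(seq_along(spectra),
                       names = vapply(spectra, slot, "", "id"))
  rows <- list()
  for (d in seq_len(nrow(doublets))) {
    db <- doublets[d, ]
    cand <- matchPrecursor(db, candidates, ppmTol = ppmPrecursor)
    if (!nrow(cand)) next
    lightSpec <- spectra[[specIdx[[db$light_id]]]]
    for (ci in seq_len(nrow(cand))) {
      cc <- cand[ci, ]
      loc <- localizeAndScore(lightSpec, cc$sequence, cc$composition,
                              loss = cc$loss, fragTolPpm = ppmFragment,
                              scheme = scheme, heavy = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        light_id = db$light_id, heavy_id = db$heavy_id,
        charge = db$charge, protein = cc$protein,
        peptide = cc$sequence, pep_start = cc$start, pep_end = cc$end,
        site = cc$start + loc$site - 1L, site_in_pep = loc$site,
        n_ambiguous = length(loc$ambiguity),
        composition = cc$composition, loss = cc$loss,
        adduct_mass = cc$adduct_mass, dm = cc$dm, score = loc$score,
        is_decoy = isTRUE(cc$is_decoy), phase = phase,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(light_id = character(), heavy_id = character(),
                      charge = integer(), protein = character(),
                      peptide = character(), pep_start = integer(),
                      pep_end = integer(), site = integer(),
                      site_in_pep = integer(), n_ambiguous = integer(),
                      composition = character(), loss = character(),
                      adduct_mass = numeric(), dm = numeric(),
                      score = numeric(), is_decoy = logical(),
                      phase = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  if (verbose)
    message(nrow(out), " CSMs (", sum(out$is_decoy), " decoy)")
  out
}

#' Filter identifications to a target-decoy FDR threshold
#'
#' Collapses CSMs to the best score per unique key — by default the
#' combination of peptide sequence, RNA adduct mass and modification site
#' — separately for targets and decoys, then estimates
#' FDR(s) = #decoys >= s / #targets >= s at every target score,
#' monotonizes into q-values, and keeps targets with q <= threshold.
#'
#' @param csms data.frame from \code{\link{searchSpectra}} containing
#'   both target and decoy rows.
#' @param qThreshold FDR threshold (default 0.01, i.e. 1 percent).
#' @param keys Character vector of column names forming the uniqueness
#'   key; \code{adduct_mass} is rounded to 4 decimals for keying.
#' @return List with \code{identifications} (unique passing targets with
#'   \code{qvalue}), \code{unique} (all collapsed rows with q-values),
#'   \code{csms} (target CSMs whose key passed — the spectral-count
#'   level), \code{scoreThreshold} and \code{estimatedFdr} (decoy-based
#'   FDR of the emitted list).
#' @export
filterFdr <- function(csms, qThreshold = 0.01,
                      keys = c("peptide", "adduct_mass", "site")) {
  stopifnot(all(keys %in% names(csms)))
  if (!nrow(csms) || !any(csms$is_decoy))
    stop("no decoy identifications present; FDR is undefined")
  kv <- csms[keys]
  if ("adduct_mass" %in% keys)
    kv$adduct_mass <- sprintf("%.4f", kv$adduct_mass)
  key <- do.call(paste, c(kv, sep = "|"))
  ord <- order(csms$is_decoy, key, -csms$score)
  csms2 <- csms[ord, , drop = FALSE]
  key2 <- key[ord]
  first <- !duplicated(paste(csms2$is_decoy, key2))
  uniq <- csms2[first, , drop = FALSE]
  # decoys sort before targets at tied scores so a threshold placed at a
  # tie counts the tied decoys (conservative)
  uniq <- uniq[order(-uniq$score, !uniq$is_decoy), , drop = FALSE]
  nT <- cumsum(!uniq$is_decoy)
  nD <- cumsum(uniq$is_decoy)
  fdr <- ifelse(nT > 0, nD / nT, 0)
  # q-value: minimum FDR at this score or any lower score
  uniq$qvalue <- rev(cummin(rev(fdr)))
  pass <- uniq[!uniq$is_decoy & uniq$qvalue <= qThreshold, , drop = FALSE]
  rownames(pass) <- NULL
  if (nrow(pass)) {
    sThr <- min(pass$score)
    estFdr <- sum(uniq$is_decoy & uniq$score >= sThr) /
      sum(!uniq$is_decoy & uniq$score >= sThr)
    kvp <- pass[keys]
    if ("adduct_mass" %in% keys)
      kvp$adduct_mass <- sprintf("%.4f", kvp$adduct_mass)
    passKeys <- do.call(paste, c(kvp, sep = "|"))
    csmPass <- csms[!csms$is_decoy & key %in% passKeys, , drop = FALSE]
  } else {
    sThr <- Inf
    estFdr <- 0
    csmPass <- csms[0, , drop = FALSE]
  }
  rownames(csmPass) <- NULL
  list(identifications = pass, unique = uniq, csms = csmPass,
       scoreThreshold = sThr, estimatedFdr = estFdr,
       qThreshold = qThreshold)
}
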