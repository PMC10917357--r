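#' Residue-level cross-link map
#'
#' Aggregates FDR-passing identifications of one protein into per-residue
#' spectral counts with a per-residue composition breakdown. Spectral
#' count is the number of passing identifications supporting a residue —
#' the semiquantitative abundance proxy of the workflow.
#'
#' @param identifications data.frame with columns \code{protein},
#'   \code{site}, \code{composition} (e.g. the \code{csms} element of
#'   \code{\link{filterFdr}}).
#' @param protein Protein id to map; must be the only one present if
#'   omitted.
#' @param proteinLength Optional protein length used only for validation.
#' @param window Aggregation half-width in residues: counts at residue r
#'   are summed over sites within \code{r +/- window}. The default 0
#'   reports exact residues; a small window groups cross-links
#'   "surrounding" a hotspot residue.
#' @return A \linkS4class{ResidueXlMap}.
#' @export
residueMap <- function(identifications, protein = NULL,
                       proteinLength = NULL, window = 0L) {
  if (is.null(protein)) {
    prot <- unique(identifications$protein)
    if (length(prot) > 1L)
      stop("identifications cover several proteins; pass `protein`")
    protein <- if (length(prot)) prot else NA_character_
  } else {
    unknown <- setdiff(unique(identifications$protein), protein)
    if (length(unknown))
      stop("identifications reference unknown protein(s): ",
           paste(unknown, collapse = ", "))
  }
  ids <- identifications[identifications$protein %in% protein, ,
                         drop = FALSE]
  if (!is.null(proteinLength) && nrow(ids) &&
      any(ids$site < 1L | ids$site > proteinLength))
    stop("identification site outside protein 1..", proteinLength)
  if (!nrow(ids)) {
    return(new("ResidueXlMap", protein = as.character(protein),
               counts = data.frame(site = integer(), count = integer()),
               compositions = data.frame(site = integer(),
                                         composition = character(),
                                         count = integer())))
  }
  tab <- aggregate(list(count = rep(1L, nrow(ids))),
                   by = list(site = ids$site), FUN = sum)
  tab <- tab[order(tab$site), , drop = FALSE]
  if (window > 0L)   # windowed totals reported alongside the raw counts
    tab$window_count <- vapply(tab$site, function(r)
      sum(tab$count[abs(tab$site - r) <= window]), 0L)
  comp <- aggregate(list(count = rep(1L, nrow(ids))),
                    by = list(site = ids$site,
                              composition = ids$composition), FUN = sum)
  comp <- comp[order(comp$site, comp$composition), , drop = FALSE]
  rownames(tab) <- rownames(comp) <- NULL
  new("ResidueXlMap", protein = as.character(protein), counts = tab,
      compositions = comp)
}

setMethod("show", "ResidueXlMap", function(object) {
  cat("ResidueXlMap for", object@protein, "-",
      sum(object@counts$count), "identifications over",
      nrow(object@counts), "residues\n")
  if (nrow(object@counts)) {
    top <- object@counts[order(-object@counts$count), ][
      seq_len(min(5L, nrow(object@counts))), ]
    cat("top sites:",
        paste(sprintf("%d (n=%d)", top$site, top$count), collapse = ", "),
        "\n")
  }
})

#' @describeIn residueMap Per-residue counts as a data.frame.
#' @param x A \linkS4class{ResidueXlMap}.
#' @export
residueCounts <- function(x) {
  stopifnot(is(x, "ResidueXlMap"))
  x@counts
}

#' @describeIn residueMap Per-residue composition breakdown.
#' @export
residueCompositions <- function(x) {
  stopifnot(is(x, "ResidueXlMap"))
  x@compositions
}

#' Map an adduct composition onto an RNA sequence
#'
#' MS determines the adduct's nucleotide multiset, not its sequence, so a
#' composition maps to every window of the RNA whose content equals that
#' multiset — possibly several, overlapping, or none. Coordinates are
#' shifted by \code{offset} so local position 1 reports as
#' \code{offset + 1} (e.g. to express sites in genomic numbering).
#'
#' @param comp Adduct composition.
#' @param rna One-row RNA record or sequence string.
#' @param offset Numbering offset (external = local + offset).
#' @return data.frame with columns \code{start}, \code{end},
#'   \code{sequence} in external coordinates; zero rows when no window
#'   matches.
#' @export
mapCompositionToRNA <- function(comp, rna, offset = 0L) {
  comp <- oligoComposition(comp)
  record <- .asRecord(rna, "rna")
  s <- record$sequence
  k <- length(comp)
  if (k > nchar(s))
    stop("composition longer than the RNA sequence")
  nt <- strsplit(s, "")[[1]]
  onehot <- sapply(c("A", "C", "G", "U"), function(b) as.integer(nt == b))
  csum <- rbind(0, apply(onehot, 2, cumsum))
  target <- comp@counts
  starts <- integer()
  for (i in seq_len(nchar(s) - k + 1L)) {
    w <- csum[i + k, ] - csum[i, ]
    if (all(w == target)) starts <- c(starts, i)
  }
  if (!length(starts))
    return(data.frame(start = integer(), end = integer(),
                      sequence = character(), stringsAsFactors = FALSE))
  data.frame(start = starts + offset, end = starts + k - 1L + offset,
             sequence = substring(s, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

#' Find IUPAC motif matches in an RNA sequence
#'
#' All 1-based start positions where an IUPAC consensus (Y = pyrimidine,
#' R = purine, N = any, etc.) matches, via
#' \code{Biostrings::matchPattern} with ambiguity codes enabled.
#'
#' @param motif Motif string over IUPAC codes.
#' @param rna One-row RNA record or sequence string.
#' @return Integer vector of start positions (empty when none, including
#'   a motif longer than the sequence).
#' @examples
#' findMotifMatches("YCUNN", "UCUCUAAAAA")  # registers 1 and 3
#' @export
findMotifMatches <- function(motif, rna) {
  record <- .asRecord(rna, "rna")
  iupac <- c(names(Biostrings::IUPAC_CODE_MAP), "U")
  bad <- setdiff(strsplit(toupper(motif), "")[[1]], iupac)
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
  if (nchar(motif) > nchar(record$sequence)) return(integer())
  hits <- Biostrings::matchPattern(Biostrings::RNAString(toupper(motif)),
                                   Biostrings::RNAString(record$sequence),
                                   fixed = FALSE)
  Biostrings::start(hits)
}

#' Compare cross-link identifications between two phases
#'
#' Partitions site keys (by default protein, site, composition) into
#' those observed in both result sets and those unique to each, pairing
#' spectral counts only for shared keys. The comparison is
#' semiquantitative: differing cross-linking and ionization efficiencies
#' mean only identical sites can be compared between samples, so no
#' cross-phase ratio is computed for non-shared keys and no statistical
#' test is attempted.
#'
#' @param resultsA,resultsB data.frames of FDR-passing identifications
#'   (spectral-count level), each with the key columns.
#' @param keyCols Columns forming the site key.
#' @param labels Phase labels.
#' @return A \linkS4class{PhaseComparison}.
#' @export
comparePhases <- function(resultsA, resultsB,
                          keyCols = c("protein", "site", "composition"),
                          labels = c("dispersed", "condensed")) {
  if (!all(keyCols %in% names(resultsA)) ||
      !all(keyCols %in% names(resultsB)))
    stop("both result sets must contain the key columns: ",
         paste(keyCols, collapse = ", "))
  keyOf <- function(df) if (nrow(df))
    do.call(paste, c(df[keyCols], sep = "|")) else character()
  cntA <- table(keyOf(resultsA))
  cntB <- table(keyOf(resultsB))
  shared <- sort(intersect(names(cntA), names(cntB)))
  new("PhaseComparison",
      shared = data.frame(key = shared,
                          countA = as.integer(cntA[shared]),
                          countB = as.integer(cntB[shared]),
                          stringsAsFactors = FALSE),
      uniqueA = sort(setdiff(names(cntA), names(cntB))),
      uniqueB = sort(setdiff(names(cntB), names(cntA))),
      labels = labels)
}

setMethod("show", "PhaseComparison", function(object) {
  cat(sprintf("PhaseComparison (%s vs %s): %d shared, %d %s-only, %d %s-only\n",
              object@labels[1], object@labels[2], nrow(object@shared),
              length(object@uniqueA), object@labels[1],
              length(object@uniqueB), object@labels[2]))
})

#' @describeIn comparePhases Shared-key table with paired counts.
#' @param x A \linkS4class{PhaseComparison}.
#' @export
sharedSites <- function(x) {
  stopifnot(is(x, "PhaseComparison"))
  x@shared
}

#' @describeIn comparePhases Phase-specific keys.
#' @param which \code{"A"} or \code{"B"}.
#' @export
uniqueSites <- function(x, which = c("A", "B")) {
  stopifnot(is(x, "PhaseComparison"))
  if (match.arg(which) == "A") x@uniqueA else x@uniqueB
}

#' Plot a residue-level cross-link map
#'
#' Bar chart of spectral counts along the protein sequence. Requires
#' ggplot2.
#'
#' @param map A \linkS4class{ResidueXlMap}.
#' @return A ggplot object.
#' @export
plotResidueMap <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- residueCounts(map)
  ggplot2::ggplot(df, ggplot2::aes(x = site, y = count)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "protein residue", y = "spectral count",
                  title = map@protein) +
    ggplot2::theme_minimal()
}
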