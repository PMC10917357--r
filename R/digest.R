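#' Read protein or RNA sequences from FASTA
#'
#' Thin wrapper over \code{Biostrings::readBStringSet}. Sequences are
#' uppercased; for RNA, T is normalized to U and the alphabet is checked
#' against A/C/G/U; for proteins against the 20 standard letters.
#'
#' @param path FASTA file.
#' @param kind \code{"protein"} or \code{"rna"}.
#' @return data.frame with columns \code{id}, \code{kind}, \code{sequence}.
#' @export
readSequences <- function(path, kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (kind == "rna") seqs <- chartr("T", "U", seqs)
  pat <- if (kind == "rna") "^[ACGU]+$" else
    "^[ACDEFGHIKLMNPQRSTVWY]+$"
  bad <- which(!grepl(pat, seqs))
  if (length(bad))
    stop("record '", ids[bad[1]], "' is empty or contains letters outside ",
         "the ", kind, " alphabet")
  data.frame(id = ids, kind = kind, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

.asRecord <- function(record, kind) {
  if (is.data.frame(record)) {
    stopifnot(all(c("id", "sequence") %in% names(record)),
              nrow(record) == 1L)
    return(record)
  }
  data.frame(id = if (!is.null(names(record))) names(record)[1] else "seq1",
             kind = kind, sequence = as.character(record)[1],
             stringsAsFactors = FALSE)
}

#' In-silico tryptic digestion of a protein
#'
#' Cleaves C-terminal to K or R, suppressed when the next residue is P.
#' Peptides with up to \code{maxMissed} missed cleavages within
#' \code{lengthRange} are returned with 1-based inclusive coordinates on
#' the protein.
#'
#' @param record One-row data.frame from \code{\link{readSequences}}, or a
#'   (named) sequence string.
#' @param enzyme Only \code{"trypsin"} is supported.
#' @param maxMissed Maximum missed cleavages (>= 0).
#' @param lengthRange Length-2 integer vector, inclusive.
#' @return data.frame with columns \code{protein}, \code{start},
#'   \code{end}, \code{sequence}, \code{missed}.
#' @examples
#' digestProtein("AKRG", maxMissed = 1)
#' @export
digestProtein <- function(record, enzyme = "trypsin", maxMissed = 0L,
                          lengthRange = c(1L, 60L)) {
  if (!identical(enzyme, "trypsin"))
    stop("unsupported enzyme: ", enzyme)
  record <- .asRecord(record, "protein")
  s <- record$sequence
  if (is.na(s) || !nzchar(s)) stop("protein sequence is empty")
  stopifnot(maxMissed >= 0L, length(lengthRange) == 2L)
  aa <- strsplit(s, "")[[1]]
  n <- length(aa)
  # cut after position i when aa[i] in {K,R} and aa[i+1] != P
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts == n | aa[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts[cuts < n], n)        # segment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  nseg <- length(starts)
  out <- vector("list", 0L)
  for (i in seq_len(nseg)) {
    for (m in 0:min(maxMissed, nseg - i)) {
      st <- starts[i]; en <- ends[i + m]
      len <- en - st + 1L
      if (len >= lengthRange[1] && len <= lengthRange[2])
        out[[length(out) + 1L]] <- data.frame(
          protein = record$id, start = st, end = en,
          sequence = substr(s, st, en), missed = m,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein = character(), start = integer(),
                      end = integer(), sequence = character(),
                      missed = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' In-silico nuclease digestion of an RNA
#'
#' RNase T1 cleaves 3' of G; RNase A cleaves 3' of pyrimidines (C, U);
#' both leave 5'-OH / 3'-phosphate products. Benzonase is nonspecific and
#' is modeled as every substring up to \code{maxLength} (the search
#' operates on adduct compositions, so completeness of products matters,
#' not their kinetic distribution). When benzonase is among the nucleases
#' the substring model supersedes the site-specific ones.
#'
#' @param record One-row data.frame or (named) RNA sequence string.
#' @param nucleases Character subset of \code{"RNaseT1"}, \code{"RNaseA"},
#'   \code{"benzonase"}.
#' @param maxLength Benzonase product length cap.
#' @return data.frame with columns \code{rna}, \code{start}, \code{end},
#'   \code{sequence} (1-based inclusive coordinates).
#' @examples
#' digestRNA("GGAUG", nucleases = "RNaseT1")
#' @export
digestRNA <- function(record, nucleases = c("RNaseT1", "RNaseA"),
                      maxLength = 4L) {
  known <- c("RNaseT1", "RNaseA", "benzonase")
  bad <- setdiff(nucleases, known)
  if (length(bad))
    stop("unknown nuclease id(s): ", paste(bad, collapse = ", "))
  if (!length(nucleases)) stop("at least one nuclease required")
  record <- .asRecord(record, "rna")
  s <- record$sequence
  if (is.na(s) || !nzchar(s)) stop("RNA sequence is empty")
  nt <- strsplit(s, "")[[1]]
  n <- length(nt)
  if ("benzonase" %in% nucleases) {
    starts <- rep(seq_len(n), each = maxLength)
    ends <- starts + rep(seq_len(maxLength), times = n) - 1L
    keep <- ends <= n
    starts <- starts[keep]; ends <- ends[keep]
  } else {
    after <- character(0)
    if ("RNaseT1" %in% nucleases) after <- c(after, "G")
    if ("RNaseA" %in% nucleases) after <- c(after, "C", "U")
    cuts <- which(nt %in% after)
    bounds <- unique(c(0L, cuts[cuts < n], n))
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1]
  }
  data.frame(rna = record$id, start = starts, end = ends,
             sequence = substring(s, starts, ends),
             stringsAsFactors = FALSE)
}

#' Enumerate oligonucleotide adduct compositions
#'
#' All nucleotide multisets over A/C/G/U of length 1..\code{maxLen},
#' without duplicates: \code{choose(k + 3, 3)} compositions of length k
#' (4, 10, 20, 35 for k = 1..4).
#'
#' @param maxLen Maximum adduct length (>= 1). The default of 4 reflects
#'   mono- to tetranucleotide adducts typically observed after exhaustive
#'   nuclease digestion.
#' @return data.frame with integer columns \code{A}, \code{C}, \code{G},
#'   \code{U}, plus \code{length} and the canonical \code{composition}
#'   string.
#' @export
enumerateCompositions <- function(maxLen = 4L) {
  if (length(maxLen) != 1L || is.na(maxLen) || maxLen < 1L)
    stop("maxLen must be >= 1")
  maxLen <- as.integer(maxLen)
  g <- expand.grid(A = 0:maxLen, C = 0:maxLen, G = 0:maxLen, U = 0:maxLen)
  len <- rowSums(g)
  g <- g[len >= 1L & len <= maxLen, , drop = FALSE]
  g$length <- as.integer(rowSums(g[, c("A", "C", "G", "U")]))
  g <- g[order(g$length, -g$A, -g$C, -g$G, -g$U), , drop = FALSE]
  rownames(g) <- NULL
  g$composition <- apply(g[, c("A", "C", "G", "U")], 1L, function(r) {
    r <- r[r > 0]
    paste0(names(r), r, collapse = "")
  })
  g
}

#' Neutral-loss table
#'
#' Default precursor neutral losses considered during candidate
#' generation: none, loss of water, and loss of HPO3 (the 3'-phosphate).
#'
#' @param ids Subset of \code{"none"}, \code{"H2O"}, \code{"HPO3"}, or a
#'   data.frame with columns \code{id} and \code{mass} for custom losses.
#' @return data.frame with columns \code{id}, \code{mass} (Da, subtracted
#'   from the precursor).
#' @export
neutralLosses <- function(ids = c("none", "H2O", "HPO3")) {
  if (is.data.frame(ids)) {
    stopifnot(all(c("id", "mass") %in% names(ids)))
    return(ids)
  }
  tab <- c(none = 0, H2O = .MASS_H2O, HPO3 = .MASS_HPO3)
  bad <- setdiff(ids, names(tab))
  if (length(bad)) stop("unknown loss id(s): ", paste(bad, collapse = ", "))
  data.frame(id = ids, mass = unname(tab[ids]), stringsAsFactors = FALSE)
}

#' Generate peptide-oligonucleotide precursor candidates
#'
#' Cartesian product of peptides, adduct compositions and neutral losses.
#' For each candidate the light neutral mass is peptide mass + adduct mass
#' - loss mass (+ an optional fixed cross-link mass offset), the heavy
#' mass adds the scheme's label shift, and delta-m is their difference.
#'
#' @param peptides data.frame from \code{\link{digestProtein}} (optionally
#'   with an \code{is_decoy} column).
#' @param compositions data.frame from \code{\link{enumerateCompositions}}.
#' @param losses data.frame from \code{\link{neutralLosses}}.
#' @param scheme A \linkS4class{LabelScheme}.
#' @param crosslinkOffset Fixed mass offset of the covalent bond itself
#'   (Da; 0 assumes pure mass additivity).
#' @param terminalState Adduct terminal state, see
#'   \code{\link{oligoNeutralMass}}.
#' @return data.frame with one row per candidate: peptide fields,
#'   \code{composition}, \code{loss}, \code{adduct_mass}, \code{light},
#'   \code{heavy}, \code{dm}.
#' @export
generateCandidates <- function(peptides, compositions,
                               losses = neutralLosses(),
                               scheme = labelScheme("full_13C15N"),
                               crosslinkOffset = 0,
                               terminalState = "5OH_3p") {
  stopifnot(nrow(peptides) > 0L, nrow(compositions) > 0L,
            nrow(losses) > 0L, is(scheme, "LabelScheme"))
  pepMass <- vapply(peptides$sequence, peptideNeutralMass, 0,
                    USE.NAMES = FALSE)
  ntm <- .NT_MASSES[c("A", "C", "G", "U")]
  cm <- as.matrix(compositions[, c("A", "C", "G", "U")])
  oligoMass <- drop(cm %*% ntm) + .MASS_H2O +
    if (terminalState == "5p_3p") .MASS_HPO3 else
      if (terminalState == "cyclic") -.MASS_H2O else 0
  shift <- switch(scheme@id,
    none = rep(0, nrow(cm)),
    full_13C15N = drop(cm %*% (.NT_NCARBON * .SHIFT_13C +
                               .NT_NNITROGEN * .SHIFT_15N)),
    post_digest_18O = rep(scheme@heavyOxygens * .SHIFT_18O, nrow(cm)))
  idx <- expand.grid(pep = seq_len(nrow(peptides)),
                     comp = seq_len(nrow(compositions)),
                     loss = seq_len(nrow(losses)))
  out <- peptides[idx$pep, , drop = FALSE]
  rownames(out) <- NULL
  out$composition <- compositions$composition[idx$comp]
  out$loss <- losses$id[idx$loss]
  out$adduct_mass <- oligoMass[idx$comp] - losses$mass[idx$loss] +
    crosslinkOffset
  out$light <- pepMass[idx$pep] + out$adduct_mass
  out$dm <- shift[idx$comp]
  out$heavy <- out$light + out$dm
  if (is.null(out$is_decoy)) out$is_decoy <- FALSE
  out
}
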