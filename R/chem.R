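# Monoisotopic atomic masses (NIST). Heavy isotopes carry their own symbol
# so labeled and unlabeled atoms coexist in one composition.
.ELEMENT_MASSES <- c(
  H     = 1.00782503207,
  C     = 12.0,
  N     = 14.0030740048,
  O     = 15.99491461956,
  P     = 30.97376163,
  S     = 31.972071,
  `13C` = 13.0033548378,
  `15N` = 15.0001088982,
  `18O` = 17.999161
)

# Amino-acid residue compositions (peptide-bond internal residues), as
# count matrix over C, H, N, O, S.
.AA_ELEMENTS <- c("C", "H", "N", "O", "S")
.AA_COMP <- matrix(c(
  # C   H   N   O   S
    3,  5,  1,  1,  0,  # A
    3,  5,  1,  1,  1,  # C
    4,  5,  1,  3,  0,  # D
    5,  7,  1,  3,  0,  # E
    9,  9,  1,  1,  0,  # F
    2,  3,  1,  1,  0,  # G
    6,  7,  3,  1,  0,  # H
    6, 11,  1,  1,  0,  # I
    6, 12,  2,  1,  0,  # K
    6, 11,  1,  1,  0,  # L
    5,  9,  1,  1,  1,  # M
    4,  6,  2,  2,  0,  # N
    5,  7,  1,  1,  0,  # P
    5,  8,  2,  2,  0,  # Q
    6, 12,  4,  1,  0,  # R
    3,  5,  1,  2,  0,  # S
    4,  7,  1,  2,  0,  # T
    5,  9,  1,  1,  0,  # V
   11, 10,  2,  1,  0,  # W
    9,  9,  1,  2,  0   # Y
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  .AA_ELEMENTS))

# Ribonucleotide residue = nucleoside-3'-monophosphate minus water, so an
# oligo with the default 5'-OH/3'-phosphate termini weighs sum(residues) +
# H2O, and a mononucleotide equals the free NMP. Matches RNase T1/A
# product chemistry (5'-OH, 3'-phosphate).
.NT_ELEMENTS <- c("C", "H", "N", "O", "P")
.NT_COMP <- matrix(c(
  # C   H   N   O   P
   10, 12,  5,  6,  1,  # A
    9, 12,  3,  7,  1,  # C
   10, 12,  5,  7,  1,  # G
    9, 11,  2,  8,  1   # U
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "U"), .NT_ELEMENTS))

.MASS_H2O    <- 2 * .ELEMENT_MASSES[["H"]] + .ELEMENT_MASSES[["O"]]
.MASS_PROTON <- 1.00727646677
.MASS_HPO3   <- .ELEMENT_MASSES[["H"]] + .ELEMENT_MASSES[["P"]] +
  3 * .ELEMENT_MASSES[["O"]]
.SHIFT_13C <- .ELEMENT_MASSES[["13C"]] - .ELEMENT_MASSES[["C"]]
.SHIFT_15N <- .ELEMENT_MASSES[["15N"]] - .ELEMENT_MASSES[["N"]]
.SHIFT_18O <- .ELEMENT_MASSES[["18O"]] - .ELEMENT_MASSES[["O"]]

.AA_MASSES <- drop(.AA_COMP %*% .ELEMENT_MASSES[.AA_ELEMENTS])
.NT_MASSES <- drop(.NT_COMP %*% .ELEMENT_MASSES[.NT_ELEMENTS])

#' Construct an elemental composition
#'
#' @param counts Named numeric vector of element counts (e.g.
#'   \code{c(C = 9, H = 11, N = 2, O = 8, P = 1)}), or a molecular formula
#'   string such as \code{"C9H11N2O8P"}. Heavy isotopes are written with a
#'   leading mass number (\code{"13C"}).
#' @return An \linkS4class{ElementalComposition}.
#' @examples
#' elementalComposition("C9H11N2O8P")
#' elementalComposition(c(H = 2, O = 1))
#' @export
elementalComposition <- function(counts = integer()) {
  if (is.character(counts)) counts <- .parseFormula(counts)
  cnt <- as.integer(round(counts))
  names(cnt) <- names(counts)
  if (length(cnt)) cnt <- cnt[cnt != 0L]
  new("ElementalComposition", counts = cnt)
}

.parseFormula <- function(x) {
  stopifnot(length(x) == 1L, nzchar(x))
  m <- gregexpr("(\\d*)([A-Z][a-z]?)(\\d*)", x)
  toks <- regmatches(x, m)[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(gsub("\\s", "", x)))
    stop("cannot parse formula: ", x)
  parts <- regmatches(toks, regexec("^(\\d*)([A-Z][a-z]?)(\\d*)$", toks))
  syms <- vapply(parts, function(p) paste0(p[2], p[3]), "")
  n <- vapply(parts, function(p) if (nzchar(p[4])) as.integer(p[4]) else 1L, 0L)
  tapply(n, factor(syms, levels = unique(syms)), sum)[unique(syms)]
}

setMethod("show", "ElementalComposition", function(object) {
  cnt <- object@counts
  if (!length(cnt)) {
    cat("ElementalComposition: (empty)\n")
  } else {
    cat("ElementalComposition:",
        paste0(names(cnt), cnt, collapse = " "),
        sprintf("(%.6f Da)\n", monoisotopicMass(object)))
  }
})

#' @describeIn elementalComposition Element-wise sum of two compositions.
#' @param e1,e2 \linkS4class{ElementalComposition} objects.
#' @export
setMethod("+", signature("ElementalComposition", "ElementalComposition"),
  function(e1, e2) {
    syms <- union(names(e1@counts), names(e2@counts))
    a <- structure(integer(length(syms)), names = syms)
    a[names(e1@counts)] <- e1@counts
    a[names(e2@counts)] <- a[names(e2@counts)] + e2@counts
    new("ElementalComposition", counts = a)
  })

#' @describeIn elementalComposition Element-wise difference; an error if
#'   any resulting count would be negative.
#' @export
setMethod("-", signature("ElementalComposition", "ElementalComposition"),
  function(e1, e2) {
    syms <- union(names(e1@counts), names(e2@counts))
    a <- structure(integer(length(syms)), names = syms)
    a[names(e1@counts)] <- e1@counts
    a[names(e2@counts)] <- a[names(e2@counts)] - e2@counts
    if (any(a < 0L))
      stop("composition subtraction would produce a negative count for: ",
           paste(names(a)[a < 0L], collapse = ", "))
    new("ElementalComposition", counts = a)
  })

#' Monoisotopic mass of an elemental composition
#'
#' Sum of count times monoisotopic atomic mass over all elements;
#' additive over composition sums.
#'
#' @param object An \linkS4class{ElementalComposition}, or a named numeric
#'   vector / formula string coerced through
#'   \code{\link{elementalComposition}}.
#' @return Mass in Da.
#' @examples
#' monoisotopicMass(elementalComposition(c(H = 2, O = 1)))  # 18.010565
#' @export
setGeneric("monoisotopicMass",
           function(object) standardGeneric("monoisotopicMass"))

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "ElementalComposition", function(object) {
  cnt <- object@counts
  if (!length(cnt)) return(0)
  sum(cnt * .ELEMENT_MASSES[names(cnt)])
})

#' @rdname monoisotopicMass
#' @export
setMethod("monoisotopicMass", "ANY", function(object) {
  monoisotopicMass(elementalComposition(object))
})

#' Neutral monoisotopic mass of a peptide
#'
#' @param sequence Nonempty string over the 20 standard amino-acid letters.
#' @return Sum of residue masses plus water, in Da.
#' @examples
#' peptideNeutralMass("G")   # 75.03203
#' peptideNeutralMass("GG")  # 132.05349
#' @export
peptideNeutralMass <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("peptide sequence must be a nonempty string")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, rownames(.AA_COMP))
  if (length(bad))
    stop("unknown amino acid letter(s): ", paste(unique(bad), collapse = ", "))
  sum(.AA_MASSES[aa]) + .MASS_H2O
}

#' Construct an oligonucleotide composition
#'
#' @param x Named counts (e.g. \code{c(U = 1, C = 1)}), a canonical
#'   composition string such as \code{"C1U1"}, or an RNA sequence whose
#'   multiset is taken (\code{"UCU"} gives \code{C1U2}).
#' @return An \linkS4class{OligoComposition}.
#' @export
oligoComposition <- function(x) {
  if (is(x, "OligoComposition")) return(x)
  cnt <- c(A = 0L, C = 0L, G = 0L, U = 0L)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (grepl("^[ACGU]+$", x) && !grepl("[0-9]", x)) {
      tab <- table(strsplit(x, "")[[1]])
      cnt[names(tab)] <- as.integer(tab)
    } else {
      m <- gregexpr("([ACGU])([0-9]+)", x)
      toks <- regmatches(x, m)[[1]]
      if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(x))
        stop("cannot parse composition string: ", x)
      for (t in toks) {
        nt <- substr(t, 1, 1)
        cnt[nt] <- cnt[nt] + as.integer(substr(t, 2, nchar(t)))
      }
    }
  } else {
    x <- x[!is.na(x)]
    bad <- setdiff(names(x), names(cnt))
    if (length(bad))
      stop("unknown nucleotide(s): ", paste(bad, collapse = ", "))
    cnt[names(x)] <- as.integer(x)
  }
  new("OligoComposition", counts = cnt)
}

#' @describeIn oligoComposition Total number of nucleotides.
#' @param x An \linkS4class{OligoComposition}.
#' @export
setMethod("length", "OligoComposition", function(x) sum(x@counts))

setMethod("show", "OligoComposition", function(object) {
  cat("OligoComposition:", compositionString(object), "\n")
})

#' Canonical composition string
#'
#' Serializes a nucleotide multiset alphabetically (\code{"C1U1"}), making
#' uniqueness collapsing and comparison keys deterministic.
#'
#' @param comp An \linkS4class{OligoComposition} or anything
#'   \code{\link{oligoComposition}} accepts.
#' @return A string such as \code{"A1G2U1"}.
#' @export
compositionString <- function(comp) {
  comp <- oligoComposition(comp)
  cnt <- comp@counts[comp@counts > 0L]
  if (!length(cnt)) return("")
  paste0(names(cnt), cnt, collapse = "")
}

#' Neutral monoisotopic mass of an oligonucleotide adduct
#'
#' The default terminal state is 5'-OH / 3'-phosphate, the product
#' chemistry of RNase T1 and RNase A, so a mononucleotide equals the free
#' NMP mass. A 5'-phosphate terminal state adds one HPO3; a 2',3'-cyclic
#' phosphate subtracts one water.
#'
#' @param comp Oligonucleotide composition (length >= 1).
#' @param terminalState \code{"5OH_3p"} (default), \code{"5p_3p"}, or
#'   \code{"cyclic"}.
#' @return Mass in Da.
#' @examples
#' oligoNeutralMass(oligoComposition(c(U = 1)))  # 324.0359, free UMP
#' @export
oligoNeutralMass <- function(comp, terminalState = c("5OH_3p", "5p_3p",
                                                     "cyclic")) {
  terminalState <- match.arg(terminalState)
  comp <- oligoComposition(comp)
  if (length(comp) < 1L)
    stop("adduct composition must contain at least one nucleotide")
  m <- sum(comp@counts * .NT_MASSES) + .MASS_H2O
  switch(terminalState,
         `5OH_3p` = m,
         `5p_3p`  = m + .MASS_HPO3,
         cyclic   = m - .MASS_H2O)
}

#' Construct an isotope labeling scheme
#'
#' @param id \code{"none"}, \code{"full_13C15N"} (all C and N of every
#'   nucleotide heavy), or \code{"post_digest_18O"} (heavy-oxygen
#'   phosphate transferred to the 5'-OH after digestion).
#' @param heavyOxygens Heavy oxygens retained on the transferred phosphate
#'   (post-digestion labeling only); default 3.
#' @return A \linkS4class{LabelScheme}.
#' @export
labelScheme <- function(id = c("none", "full_13C15N", "post_digest_18O"),
                        heavyOxygens = 3L) {
  id <- match.arg(id)
  new("LabelScheme", id = id, heavyOxygens = as.integer(heavyOxygens))
}

setMethod("show", "LabelScheme", function(object) {
  cat("LabelScheme:", object@id)
  if (object@id == "post_digest_18O")
    cat(sprintf(" (%d heavy O, dm = %.4f Da)", object@heavyOxygens,
                labelShift(oligoComposition(c(U = 1)), object)))
  cat("\n")
})

# heavy-atom counts per nucleotide residue under full 13C/15N labeling
.NT_NCARBON   <- .NT_COMP[, "C"]
.NT_NNITROGEN <- .NT_COMP[, "N"]

#' Isotope-label mass shift of an RNA adduct
#'
#' The heavy-minus-light mass difference (delta-m) that a labeling scheme
#' imparts to an oligonucleotide adduct. For full 13C/15N labeling the
#' shift is additive over nucleotides (carbons times the 13C-12C increment
#' plus nitrogens times the 15N-14N increment); for post-digestion 18O
#' labeling it is a constant \code{heavyOxygens} times the 18O-16O
#' increment regardless of composition; for \code{"none"} it is 0.
#'
#' @param comp Oligonucleotide composition (may be empty, giving 0).
#' @param scheme A \linkS4class{LabelScheme}.
#' @return Shift in Da.
#' @examples
#' labelShift(oligoComposition(c(U = 1)), labelScheme("full_13C15N"))
#' # 11.0243
#' @export
labelShift <- function(comp, scheme) {
  stopifnot(is(scheme, "LabelScheme"))
  comp <- oligoComposition(comp)
  switch(scheme@id,
    none = 0,
    full_13C15N = sum(comp@counts * (.NT_NCARBON * .SHIFT_13C +
                                     .NT_NNITROGEN * .SHIFT_15N)),
    post_digest_18O = if (length(comp) == 0L) 0 else
      scheme@heavyOxygens * .SHIFT_18O)
}

#' Chemistry constants
#'
#' Returns the built-in chemistry tables: monoisotopic element masses,
#' amino-acid and ribonucleotide residue masses, and the water, proton and
#' HPO3 constants. \code{chemOverride} merges a plain-text YAML config on
#' top of the element table (advanced use; residue compositions are then
#' re-derived from the overridden element masses).
#'
#' @param config Optional path to a YAML file with an \code{elements}
#'   mapping of symbol to mass.
#' @return A list with components \code{elements}, \code{aminoAcids},
#'   \code{nucleotides}, \code{water}, \code{proton}, \code{hpo3}.
#' @export
chemTables <- function(config = NULL) {
  elements <- .ELEMENT_MASSES
  if (!is.null(config)) {
    ov <- yaml::read_yaml(config)
    if (!is.null(ov$elements)) {
      ovv <- unlist(ov$elements)
      bad <- setdiff(names(ovv), names(elements))
      if (length(bad))
        stop("unknown element symbol(s) in config: ",
             paste(bad, collapse = ", "))
      elements[names(ovv)] <- ovv
    }
  }
  list(elements = elements,
       aminoAcids = drop(.AA_COMP %*% elements[.AA_ELEMENTS]),
       nucleotides = drop(.NT_COMP %*% elements[.NT_ELEMENTS]),
       water = 2 * elements[["H"]] + elements[["O"]],
       proton = .MASS_PROTON,
       hpo3 = elements[["H"]] + elements[["P"]] + 3 * elements[["O"]])
}
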