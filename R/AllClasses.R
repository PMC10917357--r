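#' @import methods
NULL

#' Elemental composition
#'
#' An element-symbol to count map underlying all mass computations. Heavy
#' isotopes are tracked as separate symbols (\code{"13C"}, \code{"15N"},
#' \code{"18O"}). Compositions add and subtract element-wise; subtraction
#' that would produce a negative count is an error.
#'
#' @slot counts Named integer vector of nonnegative element counts.
#'
#' @examples
#' w <- elementalComposition(c(H = 2, O = 1))
#' monoisotopicMass(w)
#' @export
setClass("ElementalComposition",
  representation(counts = "integer"))

setValidity("ElementalComposition", function(object) {
  cnt <- object@counts
  if (length(cnt) && is.null(names(cnt)))
    return("counts must be named by element symbol")
  bad <- setdiff(names(cnt), names(.ELEMENT_MASSES))
  if (length(bad))
    return(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  if (any(is.na(cnt)) || any(cnt < 0L))
    return("all element counts must be nonnegative")
  if (anyDuplicated(names(cnt)))
    return("duplicated element symbol")
  TRUE
})

#' Isotope labeling scheme
#'
#' Describes how heavy RNA differs from light RNA. \code{full_13C15N}
#' replaces every carbon and nitrogen of each nucleotide with its heavy
#' isotope (metabolic/in-vitro transcription labeling), so the mass shift
#' grows additively with adduct composition. \code{post_digest_18O} models
#' enzymatic transfer of a heavy-oxygen phosphate onto the 5'-hydroxyl of
#' the cross-linked oligonucleotide after digestion: the shift is
#' \code{heavyOxygens} times the 18O-16O increment, independent of adduct
#' length. \code{none} yields a zero shift.
#'
#' @slot id One of \code{"none"}, \code{"full_13C15N"},
#'   \code{"post_digest_18O"}.
#' @slot heavyOxygens Integer; number of heavy oxygens retained on the
#'   transferred phosphate (default 3: the three nonbridging positions;
#'   the bridging oxygen comes from the 5'-OH).
#' @export
setClass("LabelScheme",
  representation(id = "character", heavyOxygens = "integer"))

setValidity("LabelScheme", function(object) {
  if (length(object@id) != 1L ||
      !object@id %in% c("none", "full_13C15N", "post_digest_18O"))
    return("id must be one of 'none', 'full_13C15N', 'post_digest_18O'")
  if (length(object@heavyOxygens) != 1L || is.na(object@heavyOxygens) ||
      object@heavyOxygens < 0L)
    return("heavyOxygens must be a single nonnegative integer")
  TRUE
})

#' Oligonucleotide composition
#'
#' The nucleotide multiset of an RNA adduct. MS2 fragmentation of a
#' peptide-RNA conjugate determines the composition of the covalently
#' linked oligonucleotide, not its sequence, so the search space is over
#' multisets of A/C/G/U.
#'
#' @slot counts Integer vector of length 4, named A, C, G, U.
#' @export
setClass("OligoComposition",
  representation(counts = "integer"))

setValidity("OligoComposition", function(object) {
  cnt <- object@counts
  if (length(cnt) != 4L || !identical(names(cnt), c("A", "C", "G", "U")))
    return("counts must be an integer vector named A, C, G, U")
  if (any(is.na(cnt)) || any(cnt < 0L))
    return("nucleotide counts must be nonnegative")
  TRUE
})

#' Centroided MS2 spectrum
#'
#' A peak list with precursor information. Peaks are stored sorted by m/z.
#'
#' @slot id Spectrum identifier (MGF TITLE).
#' @slot precursorMz Precursor m/z in Th.
#' @slot charge Positive integer precursor charge.
#' @slot precursorIntensity Precursor intensity (arbitrary units; NA when
#'   unknown).
#' @slot mz Numeric vector of fragment m/z values, strictly positive,
#'   ascending.
#' @slot intensity Numeric vector of fragment intensities, same length as
#'   \code{mz}, nonnegative.
#' @export
setClass("Spectrum",
  representation(id = "character", precursorMz = "numeric",
                 charge = "integer", precursorIntensity = "numeric",
                 mz = "numeric", intensity = "numeric"))

setValidity("Spectrum", function(object) {
  if (length(object@id) != 1L) return("id must be a single string")
  if (length(object@precursorMz) != 1L || object@precursorMz <= 0)
    return("precursorMz must be a single positive number")
  if (length(object@charge) != 1L || is.na(object@charge) ||
      object@charge < 1L)
    return("charge must be a positive integer")
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must have equal length")
  if (length(object@mz)) {
    if (any(object@mz <= 0)) return("all m/z values must be positive")
    if (is.unsorted(object@mz)) return("peaks must be sorted by m/z")
    if (any(object@intensity < 0)) return("intensities must be nonnegative")
  }
  TRUE
})

#' Residue-level cross-link map
#'
#' Per-residue spectral counts for one protein, with a per-residue
#' breakdown by adduct composition. The total count equals the number of
#' contributing identifications.
#'
#' @slot protein Protein identifier.
#' @slot counts data.frame with columns \code{site} and \code{count},
#'   ordered by site.
#' @slot compositions data.frame with columns \code{site},
#'   \code{composition}, \code{count}.
#' @export
setClass("ResidueXlMap",
  representation(protein = "character", counts = "data.frame",
                 compositions = "data.frame"))

setValidity("ResidueXlMap", function(object) {
  if (!all(c("site", "count") %in% names(object@counts)))
    return("counts needs columns site, count")
  if (nrow(object@counts) && any(object@counts$count < 0))
    return("counts must be nonnegative")
  if (sum(object@counts$count) != sum(object@compositions$count))
    return("composition breakdown must account for every identification")
  TRUE
})

#' Condensed-versus-dispersed phase comparison
#'
#' Partition of cross-link site keys into those shared by both phases and
#' those unique to each, with paired spectral counts for shared keys.
#' Only identical cross-linking sites are compared between samples; no
#' cross-phase ratio is formed for non-shared keys.
#'
#' @slot shared data.frame with columns \code{key}, \code{countA},
#'   \code{countB}.
#' @slot uniqueA,uniqueB Character vectors of phase-specific keys.
#' @slot labels Length-2 character vector naming the two phases.
#' @export
setClass("PhaseComparison",
  representation(shared = "data.frame", uniqueA = "character",
                 uniqueB = "character", labels = "character"))

setValidity("PhaseComparison", function(object) {
  keys <- c(object@shared$key, object@uniqueA, object@uniqueB)
  if (anyDuplicated(keys))
    return("shared and unique key sets must be disjoint")
  if (length(object@labels) != 2L)
    return("labels must name exactly two phases")
  TRUE
})
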