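#' Construct a centroided spectrum
#'
#' Peaks are sorted by m/z on construction.
#'
#' @param id Spectrum identifier.
#' @param precursorMz Precursor m/z (Th).
#' @param charge Precursor charge (positive integer).
#' @param mz,intensity Fragment peak vectors of equal length.
#' @param precursorIntensity Precursor intensity; NA when unknown.
#' @return A \linkS4class{Spectrum}.
#' @export
Spectrum <- function(id, precursorMz, charge, mz = numeric(),
                     intensity = numeric(), precursorIntensity = NA_real_) {
  o <- order(mz)
  new("Spectrum", id = as.character(id),
      precursorMz = as.numeric(precursorMz),
      charge = as.integer(charge),
      precursorIntensity = as.numeric(precursorIntensity),
      mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
}

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum %s: precursor %.4f Th (z=%d), %d peaks\n",
              object@id, object@precursorMz, object@charge,
              length(object@mz)))
})

#' @describeIn Spectrum Number of peaks.
#' @param x A \linkS4class{Spectrum}.
#' @export
setMethod("length", "Spectrum", function(x) length(x@mz))

#' Neutral (uncharged) precursor mass of a spectrum
#'
#' @param x A \linkS4class{Spectrum}.
#' @return Mass in Da: \code{mz * z - z * proton}.
#' @export
neutralPrecursorMass <- function(x) {
  stopifnot(is(x, "Spectrum"))
  x@precursorMz * x@charge - x@charge * .MASS_PROTON
}

#' Read and write Mascot Generic Format peak lists
#'
#' \code{readMGF} parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS
#' (m/z and optional intensity) and CHARGE headers; \code{writeMGF} emits
#' them so that a write/read round trip reproduces every value to within
#' 1e-4 Th. Malformed blocks raise an error naming the offending block.
#'
#' @param path File path.
#' @return \code{readMGF}: a list of \linkS4class{Spectrum} (empty list
#'   for an empty file).
#' @export
readMGF <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends))
    stop("malformed MGF: ", length(begins), " BEGIN IONS but ",
         length(ends), " END IONS (block starting near line ",
         if (length(begins)) begins[length(ends) + 1L] else ends[1], ")")
  if (length(begins) && any(ends < begins))
    stop("malformed MGF: END IONS before BEGIN IONS")
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    blk <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", blk, fixed = TRUE)
    kv <- strsplit(blk[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(kv, `[`, "", 1L))
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    title <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      paste0("spectrum_", k)
    if (!"PEPMASS" %in% keys)
      stop("malformed MGF: block '", title, "' lacks PEPMASS")
    pm <- strsplit(trimws(vals[match("PEPMASS", keys)]), "\\s+")[[1]]
    precMz <- as.numeric(pm[1])
    precInt <- if (length(pm) > 1L) as.numeric(pm[2]) else NA_real_
    ch <- if ("CHARGE" %in% keys)
      as.integer(sub("\\+$", "", vals[match("CHARGE", keys)])) else 1L
    if (is.na(precMz) || is.na(ch))
      stop("malformed MGF: block '", title, "' has unparsable PEPMASS/CHARGE")
    pk <- blk[!hdr]
    if (length(pk)) {
      mat <- do.call(rbind, lapply(strsplit(pk, "\\s+"), function(x)
        as.numeric(x[1:2])))
      if (anyNA(mat))
        stop("malformed MGF: block '", title, "' has an unparsable peak line")
    } else mat <- matrix(numeric(), ncol = 2)
    out[[k]] <- Spectrum(title, precMz, ch, mz = mat[, 1],
                         intensity = mat[, 2],
                         precursorIntensity = precInt)
  }
  out
}

#' @param spectra List of \linkS4class{Spectrum} objects.
#' @rdname readMGF
#' @export
writeMGF <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(is(s, "Spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s@id), con)
    pm <- if (is.na(s@precursorIntensity))
      sprintf("PEPMASS=%.6f", s@precursorMz) else
      sprintf("PEPMASS=%.6f %.4f", s@precursorMz, s@precursorIntensity)
    writeLines(pm, con)
    writeLines(sprintf("CHARGE=%d+", s@charge), con)
    if (length(s@mz))
      writeLines(sprintf("%.6f %.4f", s@mz, s@intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Theoretical b/y fragment ladder of a cross-linked peptide
#'
#' Generates singly-charged (by default) b- and y-ion m/z values for a
#' peptide carrying an RNA adduct on one residue. A prefix ion b_i carries
#' the full adduct mass iff the cross-linked site is at position <= i; a
#' suffix ion y_j carries it iff the site is at position >= length - j +
#' 1. Adduct-bearing ions are labeled with the composition appended (e.g.
#' \code{"b3+U1"}); localization information comes entirely from which
#' side of the ladder shifts.
#'
#' @param sequence Peptide sequence.
#' @param site Cross-linked residue position, 1-based within the peptide.
#' @param comp Adduct composition (anything \code{\link{oligoComposition}}
#'   accepts).
#' @param loss Neutral-loss id applied to the adduct (\code{"none"},
#'   \code{"H2O"}, \code{"HPO3"}).
#' @param scheme \linkS4class{LabelScheme}; with \code{heavy = TRUE} the
#'   adduct mass includes the label shift (fragments of the heavy doublet
#'   member).
#' @param heavy Logical; generate the heavy-labeled ladder.
#' @param fragmentCharges Integer vector of fragment charges (default 1).
#' @param terminalState Adduct terminal state.
#' @return data.frame with columns \code{ion}, \code{series}, \code{index},
#'   \code{charge}, \code{hasAdduct}, \code{mz}.
#' @export
theoreticalFragments <- function(sequence, site, comp, loss = "none",
                                 scheme = labelScheme("none"),
                                 heavy = FALSE, fragmentCharges = 1L,
                                 terminalState = "5OH_3p") {
  n <- nchar(sequence)
  if (length(site) != 1L || is.na(site) || site < 1L || site > n)
    stop("cross-link site ", site, " outside peptide 1..", n)
  comp <- oligoComposition(comp)
  aa <- strsplit(sequence, "")[[1]]
  res <- .AA_MASSES[aa]
  adduct <- oligoNeutralMass(comp, terminalState) -
    neutralLosses(loss)$mass +
    if (heavy) labelShift(comp, scheme) else 0
  cs <- compositionString(comp)
  pre <- cumsum(res)                      # b fragments: residues 1..i
  suf <- rev(cumsum(rev(res)))            # y fragments: residues j..n
  rows <- list()
  for (z in as.integer(fragmentCharges)) {
    if (n > 1L) {
      i <- seq_len(n - 1L)
      bAdd <- site <= i
      bneutral <- pre[i] + ifelse(bAdd, adduct, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        ion = paste0("b", i, ifelse(bAdd, paste0("+", cs), ""),
                     if (z > 1L) paste0("^", z) else ""),
        series = "b", index = i, charge = z, hasAdduct = bAdd,
        mz = (bneutral + z * .MASS_PROTON) / z,
        stringsAsFactors = FALSE)
      j <- seq_len(n - 1L)
      yAdd <- site >= n - j + 1L
      yneutral <- suf[n - j + 1L] + .MASS_H2O + ifelse(yAdd, adduct, 0)
      rows[[length(rows) + 1L]] <- data.frame(
        ion = paste0("y", j, ifelse(yAdd, paste0("+", cs), ""),
                     if (z > 1L) paste0("^", z) else ""),
        series = "y", index = j, charge = z, hasAdduct = yAdd,
        mz = (yneutral + z * .MASS_PROTON) / z,
        stringsAsFactors = FALSE)
    }
    # full-length (precursor-type) ion always carries the adduct; for a
    # length-1 peptide it is the only species and there is no ambiguity
    rows[[length(rows) + 1L]] <- data.frame(
      ion = paste0("M+", cs, if (z > 1L) paste0("^", z) else ""),
      series = "M", index = n, charge = z, hasAdduct = TRUE,
      mz = (sum(res) + .MASS_H2O + adduct + z * .MASS_PROTON) / z,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
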