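utils::globalVariables(c("site", "count"))

#' Default pipeline configuration
#'
#' Every tunable of the end-to-end run with its default. Unknown keys in
#' a user config are rejected.
#'
#' @return Named list of defaults.
#' @export
defaultConfig <- function() {
  list(
    proteins = NULL,            # protein FASTA path
    rna = NULL,                 # RNA FASTA path
    spectra = NULL,             # MGF path (phase A / single sample)
    spectra_b = NULL,           # optional second-phase MGF
    phase_labels = c("dispersed", "condensed"),
    scheme = "full_13C15N",
    heavy_oxygens = 3L,
    enzyme = "trypsin",
    max_missed = 2L,
    peptide_length = c(5L, 40L),
    max_adduct_len = 4L,
    losses = c("none", "H2O", "HPO3"),
    crosslink_offset = 0,
    terminal_state = "5OH_3p",
    ppm_precursor = 10,
    ppm_fragment = 20,
    fdr = 0.01,
    rna_offset = 0L,
    seed = 1L,
    out_dir = "clirpipe_out")
}

#' Read and validate a pipeline configuration
#'
#' YAML key/value file; keys must be a subset of
#' \code{\link{defaultConfig}}, unknown keys are an error.
#'
#' @param path YAML file.
#' @return Validated config list (defaults filled in).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  def <- defaultConfig()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  def[names(cfg)] <- cfg
  validateConfig(def)
}

#' @rdname readPipelineConfig
#' @param config Config list to validate.
#' @export
validateConfig <- function(config) {
  stopifnot(is.list(config))
  if (!config$scheme %in% c("none", "full_13C15N", "post_digest_18O"))
    stop("config: unknown labeling scheme '", config$scheme, "'")
  if (config$fdr <= 0 || config$fdr >= 1)
    stop("config: fdr must lie in (0, 1)")
  if (config$max_adduct_len < 1L)
    stop("config: max_adduct_len must be >= 1")
  for (f in c("proteins", "rna", "spectra", "spectra_b")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop("config: input file for '", f, "' not found: ", p)
  }
  config
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end cross-link identification pipeline
#'
#' digestion -> candidate generation (targets plus decoys) -> doublet
#' search -> site localization and scoring -> FDR filtering -> residue
#' mapping, and a phase comparison when a second spectra file is given.
#' Writes TSV outputs and a JSON manifest (config, seed, versions,
#' per-file MD5 checksums) into \code{out_dir}; identical config and
#' inputs give identical outputs. A failing stage aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config List as returned by \code{\link{readPipelineConfig}}
#'   (\code{proteins}, \code{rna} and \code{spectra} are required).
#' @param verbose Print per-stage counts.
#' @return Invisible list with \code{identifications}, \code{csms},
#'   \code{maps}, \code{comparison} (or NULL), \code{manifest}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  config <- validateConfig(config)
  for (f in c("proteins", "rna", "spectra"))
    if (is.null(config[[f]]))
      stop("config: '", f, "' input is required")
  outDir <- config$out_dir
  newOut <- !dir.exists(outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit({
    if (!ok) {
      unlink(written)
      if (newOut) unlink(outDir, recursive = TRUE)
    }
  })
  set.seed(config$seed)
  scheme <- labelScheme(config$scheme, heavyOxygens = config$heavy_oxygens)

  proteins <- .stage("read_inputs", readSequences(config$proteins, "protein"))
  rna <- .stage("read_inputs", readSequences(config$rna, "rna"))

  peptides <- .stage("digestion", {
    p <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i)
      digestProtein(proteins[i, , drop = FALSE],
                    enzyme = config$enzyme,
                    maxMissed = config$max_missed,
                    lengthRange = config$peptide_length)))
    if (is.null(p) || !nrow(p)) stop("no peptides produced")
    p
  })
  if (verbose) message("digestion: ", nrow(peptides), " target peptides")

  candidates <- .stage("candidates", {
    decoys <- suppressWarnings(buildDecoys(peptides))
    comps <- enumerateCompositions(config$max_adduct_len)
    losses <- neutralLosses(config$losses)
    tgt <- generateCandidates(peptides, comps, losses, scheme,
                              crosslinkOffset = config$crosslink_offset,
                              terminalState = config$terminal_state)
    dec <- generateCandidates(decoys, comps, losses, scheme,
                              crosslinkOffset = config$crosslink_offset,
                              terminalState = config$terminal_state)
    rbind(tgt, dec)
  })
  if (verbose) message("candidates: ", nrow(candidates),
                       " (incl. ", sum(candidates$is_decoy), " decoy)")

  phases <- list(A = config$spectra)
  if (!is.null(config$spectra_b)) phases$B <- config$spectra_b
  results <- list()
  for (ph in names(phases)) {
    label <- config$phase_labels[match(ph, c("A", "B"))]
    spectra <- .stage("read_spectra", readMGF(phases[[ph]]))
    if (verbose) message("phase ", label, ": ", length(spectra), " spectra")
    csms <- .stage("search",
      searchSpectra(spectra, candidates, scheme = scheme,
                    ppmPrecursor = config$ppm_precursor,
                    ppmFragment = config$ppm_fragment,
                    phase = label, verbose = verbose))
    filt <- .stage("fdr", filterFdr(csms, qThreshold = config$fdr))
    if (verbose)
      message("phase ", label, ": ", nrow(filt$identifications),
              " unique identifications at q <= ", config$fdr,
              " (estimated FDR ", sprintf("%.3f", filt$estimatedFdr), ")")
    results[[ph]] <- filt
    f1 <- file.path(outDir, paste0("identifications_", label, ".tsv"))
    f2 <- file.path(outDir, paste0("csms_", label, ".tsv"))
    utils::write.table(filt$identifications, f1, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(filt$csms, f2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, f1, f2)
  }

  maps <- .stage("mapping", {
    lapply(stats::setNames(nm = proteins$id), function(pid) {
      byProt <- lapply(results, function(r)
        r$csms[r$csms$protein == pid, , drop = FALSE])
      lapply(byProt, residueMap, protein = pid)
    })
  })
  for (pid in names(maps)) {
    for (ph in names(maps[[pid]])) {
      label <- config$phase_labels[match(ph, c("A", "B"))]
      f <- file.path(outDir, paste0("residue_map_", pid, "_", label,
                                    ".tsv"))
      utils::write.table(residueCounts(maps[[pid]][[ph]]), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written <- c(written, f)
    }
  }

  comparison <- NULL
  if (length(results) == 2L) {
    comparison <- .stage("comparison",
      comparePhases(results$A$csms, results$B$csms,
                    labels = config$phase_labels))
    f <- file.path(outDir, "phase_comparison.tsv")
    utils::write.table(sharedSites(comparison), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fu <- file.path(outDir, "phase_unique.tsv")
    utils::write.table(
      data.frame(phase = rep(config$phase_labels,
                             c(length(uniqueSites(comparison, "A")),
                               length(uniqueSites(comparison, "B")))),
                 key = c(uniqueSites(comparison, "A"),
                         uniqueSites(comparison, "B"))),
      fu, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f, fu)
  }

  manifest <- list(
    package = "CLIRpipe",
    version = as.character(utils::packageVersion("CLIRpipe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = config[!vapply(config, is.null, TRUE)],
    outputs = lapply(stats::setNames(nm = basename(written)), function(b)
      list(md5 = unname(tools::md5sum(file.path(outDir, b))))))
  mf <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  written <- c(written, mf)
  ok <- TRUE
  invisible(list(identifications = lapply(results, `[[`,
                                          "identifications"),
                 csms = lapply(results, `[[`, "csms"),
                 filters = results, maps = maps,
                 comparison = comparison, manifest = manifest,
                 files = written))
}
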