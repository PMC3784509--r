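# End-to-end orchestration with reconciliation counts and a JSON-able
# run summary.

#' Pipeline parameter defaults
#'
#' The stage parameters of the consensus pipeline, with defaults reproducing
#' the published protocol: 12-base tags, exact spacer match, 4-base trim,
#' minimum family size 3, 70% agreement, 5-base end clip, near-tag Hamming
#' distance 3, clonality cutoff 1%, homoplasmy cutoff 90%, 95% confidence.
#'
#' @param tagLength,spacer,trimBases Tag extraction parameters.
#' @param minFamily,agreement SSCS thresholds.
#' @param clip End-clip width.
#' @param dedupDistance,dedupKeepLargest Near-tag deduplication.
#' @param clonalityCutoff,homoplasmyCutoff Variant clonality thresholds.
#' @param confidence Confidence level for intervals.
#' @param countMolecules Use molecule counts rather than unique sites in the
#'   frequency numerator.
#' @return Named list of parameters.
#' @export
pipelineParams <- function(tagLength = 12L, spacer = "TGACT", trimBases = 4L,
                           minFamily = 3L, agreement = 0.7, clip = 5L,
                           dedupDistance = 3L, dedupKeepLargest = FALSE,
                           clonalityCutoff = 0.01, homoplasmyCutoff = 0.90,
                           confidence = 0.95, countMolecules = FALSE) {
  list(tagLength = as.integer(tagLength), spacer = spacer,
       trimBases = as.integer(trimBases), minFamily = as.integer(minFamily),
       agreement = agreement, clip = as.integer(clip),
       dedupDistance = as.integer(dedupDistance),
       dedupKeepLargest = dedupKeepLargest,
       clonalityCutoff = clonalityCutoff,
       homoplasmyCutoff = homoplasmyCutoff, confidence = confidence,
       countMolecules = countMolecules)
}

#' Process a duplex library through the consensus and calling cascade
#'
#' Runs tag extraction, family grouping, SSCS/DCS consensus, clipping,
#' deduplication, optional NUMT filtering, pileup and variant calling on
#' in-memory reads and alignments (as produced by
#' \code{\link{simulateLibrary}} or read from FASTQ/SAM files).
#'
#' @param reads data.frame(qname, read1, read2).
#' @param alignments data.frame(qname, mate, flag, rname, pos, strand, seq).
#' @param genome A \code{MitoGenome}.
#' @param annotation Optional \code{MitoAnnotation} for region labels.
#' @param params Parameter list from \code{\link{pipelineParams}}.
#' @param decoys Nuclear decoy sequences for the NUMT filter.
#' @return List: prep counts, familySet, sscs, dcs, pileup, calls, frequency,
#'   and a reconciliation \code{counts} vector.
#' @export
processLibrary <- function(reads, alignments, genome, annotation = NULL,
                           params = pipelineParams(), decoys = character()) {
  prep <- prepareReadPairs(reads$read1, reads$read2, spacer = params$spacer,
                           tagLength = params$tagLength,
                           trimBases = params$trimBases, qname = reads$qname)
  aligned <- attachAlignments(prep, alignments, genome)
  fams <- groupFamilies(aligned,
                        extraCounts = c(prep$counts["too_short"],
                                        prep$counts["bad_spacer"],
                                        prep$counts["ambiguous_tag"],
                                        offTarget = unname(aligned$counts["offTarget"])))
  cons <- duplexConsensus(fams, genome, minFamily = params$minFamily,
                          agreement = params$agreement, clip = params$clip,
                          dedupDistance = params$dedupDistance,
                          dedupKeepLargest = params$dedupKeepLargest,
                          decoys = decoys)
  pileup <- buildPileup(cons$dcs, genome)
  calls <- callVariants(pileup, clonalityCutoff = params$clonalityCutoff,
                        homoplasmyCutoff = params$homoplasmyCutoff,
                        annotation = annotation)
  freq <- if (totalBases(pileup) > 0)
    mutationFrequency(calls, pileup, confidence = params$confidence,
                      numerator = if (params$countMolecules) "molecules"
                      else "sites")
  else list(frequency = NA_real_, lower = NA_real_, upper = NA_real_,
            k = 0L, n = 0L)
  list(prep = prep$counts, families = fams, sscs = cons$sscs, dcs = cons$dcs,
       pileup = pileup, calls = calls, frequency = freq,
       counts = cons$dcs@counts)
}

#' Run the full pipeline on a simulated library
#'
#' Simulates a library from \code{config}, processes it end to end, computes
#' the headline statistics (frequency with Wilson interval, spectrum, strand
#' asymmetry), and returns a machine-readable run summary whose stage counts
#' reconcile (inputs = outputs + discards at every stage). Identical config
#' and seed give identical summaries.
#'
#' @param config A \code{\link{DuplexSimConfig}}.
#' @param annotation Optional \code{MitoAnnotation}.
#' @param params Pipeline parameters from \code{\link{pipelineParams}}.
#' @param decoys Nuclear decoy sequences.
#' @param outDir Optional directory: writes variants TSV, spectrum TSV,
#'   asymmetry TSV, and summary JSON beside the resolved parameters.
#' @return List: \code{library} (the \code{SimLibrary}), \code{result}
#'   (from \code{\link{processLibrary}}), \code{spectrum},
#'   \code{asymmetry}, \code{summary}.
#' @export
runFull <- function(config, annotation = NULL, params = pipelineParams(),
                    decoys = character(), outDir = NULL) {
  # the extraction parameters must describe the simulated reads
  params$spacer <- config@spacer
  params$tagLength <- config@tagLength
  lib <- simulateLibrary(config)
  res <- processLibrary(lib@reads, lib@alignments, config@genome,
                        annotation = annotation, params = params,
                        decoys = decoys)
  spec <- mutationSpectrum(res$calls, res$pileup)
  asym <- strandAsymmetry(res$calls, res$pileup)
  summary <- runSummary(lib, res, spec, params)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeVariantsTsv(res$calls, file.path(outDir, "variants.tsv"),
                     genome = config@genome)
    utils::write.table(spec$collapsed, file.path(outDir, "spectrum.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(asym, file.path(outDir, "asymmetry.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(library = lib, result = res, spectrum = spec, asymmetry = asym,
       summary = summary)
}

#' Build the machine-readable run summary
#'
#' @param lib The \code{SimLibrary} processed.
#' @param res Result list from \code{\link{processLibrary}}.
#' @param spectrum Result of \code{\link{mutationSpectrum}}.
#' @param params The parameter list used.
#' @return Nested list serialisable to JSON: per-stage counts, headline
#'   statistics, parameter echo, seed and package version.
#' @export
runSummary <- function(lib, res, spectrum, params) {
  dn <- res$calls[res$calls$deNovo, , drop = FALSE]
  list(
    seed = lib@config@seed,
    version = as.character(utils::packageVersion("mitoDuplex")),
    parameters = params,
    stages = list(
      inputPairs = unname(res$prep["input"]),
      prepared = unname(res$prep["prepared"]),
      rejected = unname(res$prep["input"] - res$prep["prepared"]),
      families = unname(res$counts["families"]),
      sscs = unname(res$counts["sscs"]),
      sscsDropped = unname(res$counts["sscs_dropped"]),
      sscsUnpaired = unname(res$counts["sscs_unpaired"]),
      dcs = unname(res$counts["dcs"]),
      dedupRemoved = unname(res$counts["dedup_removed"]),
      numtRemoved = unname(res$counts["numt_removed"])),
    statistics = list(
      dcsBases = totalBases(res$pileup),
      deNovoSites = nrow(dn),
      clonalSites = sum(res$calls$isClonal),
      homoplasmicSites = sum(res$calls$isHomoplasmic),
      frequency = res$frequency$frequency,
      frequencyLower = res$frequency$lower,
      frequencyUpper = res$frequency$upper,
      spectrumProportions = stats::setNames(
        as.list(spectrum$collapsed$proportion), spectrum$collapsed$class)))
}

#' Write variant calls as a VCF-like TSV
#'
#' Plain columns CHROM, POS, REF, ALT, COUNT, DEPTH, CLONALITY, REGION,
#' FLAGS -- heteroplasmy counting has no ploidy semantics, so the native
#' output is a TSV; see \code{\link{exportVcf}} for strict VCF.
#'
#' @param calls Variant table.
#' @param path Output path.
#' @param genome The reference genome (for the CHROM column).
#' @export
writeVariantsTsv <- function(calls, path, genome) {
  flags <- paste0(ifelse(calls$isHomoplasmic, "HOM;", ""),
                  ifelse(calls$isClonal, "CLONAL", "DENOVO"))
  tab <- data.frame(CHROM = genome@name, POS = calls$pos, REF = calls$ref,
                    ALT = calls$alt, COUNT = calls$count,
                    DEPTH = calls$depth, CLONALITY = calls$clonality,
                    REGION = calls$region, FLAGS = flags,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export variant calls as minimal strict VCF
#'
#' VCFv4.2 with site-only records; molecule counts, depth and clonality are
#' carried in INFO (AC, DP, AF).
#'
#' @param calls Variant table.
#' @param path Output path.
#' @param genome The reference genome.
#' @export
exportVcf <- function(calls, path, genome) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", genome@name,
                       genomeLength(genome)),
               "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Mutant molecule count\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Molecule depth\">",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Clonality (mutant fraction)\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAC=%d;DP=%d;AF=%.6g",
                       genome@name, calls$pos, calls$ref, calls$alt,
                       calls$count, as.integer(calls$depth),
                       calls$clonality), con)
  }
  invisible(path)
}

#' Load a pipeline run configuration from YAML
#'
#' Reads simulator and pipeline parameters (any subset; the rest take their
#' defaults) for the command-line entry point. Recognised top-level keys:
#' \code{sim} (fields of \code{\link{DuplexSimConfig}} except genome),
#' \code{params} (fields of \code{\link{pipelineParams}}), \code{reference}
#' (FASTA path), \code{annotation} (TSV path).
#'
#' @param path YAML file path.
#' @return Named list with elements \code{sim}, \code{params},
#'   \code{reference}, \code{annotation}.
#' @export
loadRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  list(sim = y$sim, params = do.call(pipelineParams,
                                     if (is.null(y$params)) list() else
                                       y$params),
       reference = y$reference, annotation = y$annotation)
}
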