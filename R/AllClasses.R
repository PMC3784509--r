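#' @import methods
NULL

#' Circular mitochondrial reference genome
#'
#' Holds the light-strand (L-strand) sequence of a circular mitochondrial
#' genome. All coordinates in the package are 1-based and inclusive, and
#' position arithmetic wraps modulo the genome length, so \code{baseAt(g, L+1)}
#' equals \code{baseAt(g, 1)}.
#'
#' @slot name Sequence name (e.g. \code{"chrM"}).
#' @slot bases Uppercase base string over \{A,C,G,T\}; the L-strand.
#' @slot circular Always \code{TRUE} for mitochondrial genomes.
#'
#' @export
setClass("MitoGenome",
  representation(name = "character", bases = "character", circular = "logical"),
  prototype(circular = TRUE))

setValidity("MitoGenome", function(object) {
  if (length(object@name) != 1L || length(object@bases) != 1L)
    return("'name' and 'bases' must be length-1 character")
  bad <- gregexpr("[^ACGT]", object@bases)[[1L]]
  if (bad[1L] != -1L) {
    sym <- substring(object@bases, bad, bad)
    return(sprintf("non-ACGT characters %s at positions %s",
                   paste(unique(sym), collapse = ","),
                   paste(utils::head(bad, 10L), collapse = ",")))
  }
  if (nchar(object@bases) < 1L) return("empty sequence")
  if (!isTRUE(object@circular)) return("only circular genomes are supported")
  TRUE
})

#' Region annotation of a mitochondrial genome
#'
#' A table of genome regions (protein-coding genes, rRNAs, tRNAs and the
#' control region). \code{end < start} denotes a region wrapping the origin,
#' as the human D-loop (16024--576) does. \code{coding_strand} follows the
#' mitochondrial convention: \code{"H"} for heavy-strand-encoded genes (their
#' mRNA sense equals the deposited L-strand orientation) and \code{"L"} for
#' light-strand-encoded genes (mRNA sense is the reverse complement).
#'
#' @slot regions A data.frame with columns \code{label}, \code{start},
#'   \code{end}, \code{region_class}, \code{coding_strand}, \code{frame}.
#'
#' @export
setClass("MitoAnnotation", representation(regions = "data.frame"))

setValidity("MitoAnnotation", function(object) {
  r <- object@regions
  need <- c("label", "start", "end", "region_class", "coding_strand", "frame")
  if (!all(need %in% names(r)))
    return(paste("annotation must have columns:", paste(need, collapse = ", ")))
  okClass <- c("protein_coding", "rRNA", "tRNA", "control")
  if (!all(r$region_class %in% okClass))
    return(paste("unknown region_class:",
                 paste(setdiff(r$region_class, okClass), collapse = ",")))
  if (!all(r$coding_strand %in% c("H", "L")))
    return("coding_strand must be 'H' or 'L'")
  if (any(r$start < 1L) || any(r$end < 1L)) return("coordinates are 1-based")
  TRUE
})

#' Configuration for the duplex library simulator
#'
#' Defines one simulated duplex-sequencing experiment: the reference genome,
#' library geometry (fragments, 101-bp reads carrying a 12-bp duplex tag and a
#' fixed spacer on each end), per-strand family-size distribution, and the four
#' error classes with their rates: true mutations (both parental strands),
#' single-strand damage (one parental strand, first-round PCR class), late PCR
#' errors (a subset of one family), and per-read sequencing errors. The seed
#' fully determines the output.
#'
#' @slot genome A \code{MitoGenome}.
#' @slot nFragments Number of double-stranded fragments.
#' @slot fragmentMean,fragmentSd Fragment length distribution (bases).
#' @slot readLength Read length in bases (default 101).
#' @slot tagLength Duplex tag length per end (default 12).
#' @slot spacer Fixed spacer sequence between tag and insert.
#' @slot familyMean,familyMin Per-strand family size: shifted Poisson with the
#'   given minimum and mean.
#' @slot trueMutationRate Per-base per-fragment probability of a true mutation.
#' @slot damageRate Per-base per-parental-strand probability of a damage event.
#' @slot damageSpectrum Named probabilities over the 12 directional
#'   substitution classes, applied on the lesion strand (default concentrated
#'   on G>T, the 8-oxo-dG signature).
#' @slot latePcrRate Per-base per-duplication probability of a late PCR error.
#' @slot seqErrorRate Per-base per-read probability of a sequencing error.
#' @slot clonalVariants data.frame(pos, alt, fraction) of clonal heteroplasmies.
#' @slot injectTrueMutations Number of true mutations placed deterministically
#'   on distinct fragments (in addition to \code{trueMutationRate} draws);
#'   used for exactly-one-event sensitivity experiments.
#' @slot seed Integer seed.
#'
#' @export
setClass("DuplexSimConfig",
  representation(genome = "MitoGenome", nFragments = "integer",
    fragmentMean = "numeric", fragmentSd = "numeric",
    readLength = "integer", tagLength = "integer", spacer = "character",
    familyMean = "numeric", familyMin = "integer",
    trueMutationRate = "numeric", damageRate = "numeric",
    damageSpectrum = "numeric", latePcrRate = "numeric",
    seqErrorRate = "numeric", clonalVariants = "data.frame",
    injectTrueMutations = "integer", seed = "integer"))

setValidity("DuplexSimConfig", function(object) {
  rates <- c(object@trueMutationRate, object@damageRate, object@latePcrRate,
             object@seqErrorRate)
  if (any(rates < 0 | rates > 1)) return("all rates must lie in [0,1]")
  if (object@readLength < object@tagLength + nchar(object@spacer) + 5L)
    return("readLength must be >= tagLength + spacer length + 5")
  if (object@nFragments < 0L) return("nFragments must be >= 0")
  if (object@familyMin < 1L) return("familyMin must be >= 1")
  if (object@familyMean < object@familyMin)
    return("familyMean must be >= familyMin")
  if (nrow(object@clonalVariants)) {
    f <- object@clonalVariants$fraction
    if (any(f <= 0 | f > 1)) return("clonal variant fractions must be in (0,1]")
  }
  if (abs(sum(object@damageSpectrum) - 1) > 1e-8)
    return("damageSpectrum must sum to 1")
  TRUE
})

#' A simulated duplex library
#'
#' Container returned by \code{\link{simulateLibrary}}: paired read sequences
#' (tag + spacer + insert, as they would appear in FASTQ), ground-truth
#' alignments of the prepared (tag-stripped, trimmed) reads, and the event
#' ledger attributing every non-reference base to exactly one injected event.
#'
#' @slot reads data.frame(qname, read1, read2).
#' @slot alignments data.frame(qname, mate, flag, rname, pos, strand, seq);
#'   one row per read, coordinates of the prepared 1-based leftmost position.
#' @slot truth Event ledger data.frame(class, pos, ref, alt, fragment,
#'   strand, orientation, members).
#' @slot config The \code{DuplexSimConfig} used.
#'
#' @export
setClass("SimLibrary",
  representation(reads = "data.frame", alignments = "data.frame",
                 truth = "data.frame", config = "DuplexSimConfig"))

#' A set of duplex tag families
#'
#' Read pairs sharing one 24-nt concatenated duplex tag and identical mapping
#' coordinates, the unit over which single-strand consensus is computed.
#' Stored compactly: one metadata row per family plus an index into the
#' prepared read table.
#'
#' @slot info data.frame(tagKey, tag1, tag2, pos1, strand1, pos2, strand2,
#'   size); one row per family.
#' @slot members list of integer vectors indexing rows of \code{reads}.
#' @slot reads data.frame of prepared read pairs (aligned orientation).
#' @slot counts Named integer vector of bookkeeping counts (input pairs,
#'   rejected, off-target).
#'
#' @export
setClass("FamilySet",
  representation(info = "data.frame", members = "list", reads = "data.frame",
                 counts = "integer"))

#' A set of consensus reads (SSCS or DCS)
#'
#' Each consensus covers the two read-end segments of its source fragment;
#' undefined positions are \code{N}. For DCS, a position is defined only where
#' the two strand-mate SSCS agree on a non-N base.
#'
#' @slot calls data.frame with one row per consensus: level, tagKey (and
#'   mateKey for DCS), segment positions/strands, sequences with N, and
#'   per-strand family sizes.
#' @slot level "SSCS" or "DCS".
#' @slot counts Named integer bookkeeping vector.
#'
#' @export
setClass("ConsensusSet",
  representation(calls = "data.frame", level = "character",
                 counts = "integer"))

#' Per-position base counts from duplex consensus reads
#'
#' Wrap-aware pileup over the circular genome: a 4 x L matrix of A/C/G/T
#' counts observed in DCS reads (L-strand orientation), plus an optional indel
#' event table. Depth at a position is the column sum.
#'
#' @slot counts Integer matrix (4 x genome length), rownames A,C,G,T.
#' @slot genome The \code{MitoGenome} piled against.
#' @slot indels data.frame(pos, descriptor, count) of indel events.
#' @slot nReads Number of consensus reads contributing.
#'
#' @export
setClass("Pileup",
  representation(counts = "matrix", genome = "MitoGenome",
                 indels = "data.frame", nReads = "integer"))
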