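#' Vertebrate mitochondrial genetic code
#'
#' The translation table used for all codon classification (NCBI table 2),
#' with the vertebrate mitochondrial deviations from the standard code:
#' ATA = Met, TGA = Trp, AGA = Stop, AGG = Stop.
#'
#' @return Named character vector mapping the 64 codons to amino-acid symbols,
#'   with \code{"*"} for stop.
#' @examples mitoGeneticCode()[c("ATA", "TGA", "AGA", "AGG")]
#' @export
mitoGeneticCode <- function() {
  Biostrings::getGeneticCode("2")
}

# Codon context of every protein-coding position.
#
# Returns a data.frame with one row per (gene, genomic position) inside a
# complete codon: pos, gene, strand ("H": mRNA sense = deposited L-strand
# orientation; "L": reverse complement), codon (mRNA sense), cpos (0..2
# within codon). Trailing incomplete codons (stops completed by
# polyadenylation) are excluded. Wrap-aware for toy genomes whose genes span
# the origin.
.codonContexts <- function(genome, annotation) {
  L <- genomeLength(genome)
  r <- annotation@regions
  genes <- r[r$region_class == "protein_coding", , drop = FALSE]
  if (!nrow(genes)) stop("annotation contains no protein_coding regions")
  ref <- strsplit(genome@bases, "", fixed = TRUE)[[1L]]
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gpos <- .expandPositions(genes$start[i], genes$end[i], L)
    if (genes$frame[i] > 0L) gpos <- gpos[-seq_len(genes$frame[i])]
    if (genes$coding_strand[i] == "L") {
      mpos <- rev(gpos)
      mbase <- complementBases(ref[mpos])
    } else {
      mpos <- gpos
      mbase <- ref[mpos]
    }
    ncod <- length(mpos) %/% 3L
    if (ncod == 0L) next
    keep <- seq_len(ncod * 3L)
    mpos <- mpos[keep]; mbase <- mbase[keep]
    ci <- rep(seq_len(ncod), each = 3L)
    codons <- vapply(split(mbase, ci), paste0, character(1L), collapse = "")
    out[[i]] <- data.frame(
      pos = mpos, gene = genes$label[i], strand = genes$coding_strand[i],
      codon = codons[ci], cpos = rep(0:2, ncod),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# amino acid of codon(s) under the vertebrate mitochondrial code
.translateCodons <- function(codons, code) unname(code[codons])

#' Classify a single-base substitution as synonymous, nonsynonymous or noncoding
#'
#' For positions inside a protein-coding gene, the affected codon is
#' translated on the gene's mRNA sense strand before and after the
#' substitution under the vertebrate mitochondrial code; nonsense changes
#' count as nonsynonymous. Positions in rRNA, tRNA, control or intergenic
#' regions return \code{"noncoding"}. Where protein-coding genes overlap
#' (ATP8/ATP6, ND4L/ND4), a substitution is nonsynonymous if it is
#' nonsynonymous in any overlapping gene context.
#'
#' @param genome A \code{MitoGenome}.
#' @param annotation A \code{MitoAnnotation}.
#' @param pos 1-based genomic position.
#' @param alt Alternate base, given on the L-strand (deposited orientation).
#' @param code Genetic code, default \code{\link{mitoGeneticCode}}.
#' @return One of \code{"synonymous"}, \code{"nonsynonymous"},
#'   \code{"noncoding"}.
#' @export
classifySubstitution <- function(genome, annotation, pos, alt,
                                 code = mitoGeneticCode()) {
  L <- genomeLength(genome)
  pos <- as.integer(pos)
  if (pos < 1L || pos > L) stop("position out of range")
  if (!alt %in% .BASES) stop("alt base must be one of A,C,G,T")
  ref <- baseAt(genome, pos)
  if (alt == ref) stop("alt equals the reference base at position ", pos)
  ctx <- .codonContextsCached(genome, annotation)
  hit <- ctx[ctx$pos == pos, , drop = FALSE]
  if (!nrow(hit)) return("noncoding")
  anyNs <- FALSE
  for (j in seq_len(nrow(hit))) {
    aAlt <- if (hit$strand[j] == "L") complementBases(alt) else alt
    mut <- hit$codon[j]
    substr(mut, hit$cpos[j] + 1L, hit$cpos[j] + 1L) <- aAlt
    if (.translateCodons(mut, code) != .translateCodons(hit$codon[j], code))
      anyNs <- TRUE
  }
  if (anyNs) "nonsynonymous" else "synonymous"
}

# memoised codon contexts keyed by genome+annotation content
.codonContextsCached <- function(genome, annotation) {
  key <- paste0(genome@name, "|", nchar(genome@bases), "|",
                nrow(annotation@regions), "|",
                sum(utf8ToInt(substr(genome@bases, 1L,
                                     min(200L, nchar(genome@bases))))),
                "|", sum(annotation@regions$start), ":",
                sum(annotation@regions$end))
  hit <- .pkgCache$codonCtx
  if (!is.null(hit) && identical(hit$key, key)) return(hit$ctx)
  ctx <- .codonContexts(genome, annotation)
  .pkgCache$codonCtx <- list(key = key, ctx = ctx)
  ctx
}

#' Expected nonsynonymous fraction under uniform substitution
#'
#' Enumerates every possible single-base substitution (three per position) at
#' every protein-coding position, classifies each under the vertebrate
#' mitochondrial code, and returns the nonsynonymous fraction
#' nonsynonymous / (nonsynonymous + synonymous). Each genomic position is
#' counted once; in gene overlaps a substitution counts as nonsynonymous if
#' nonsynonymous in any overlapping gene context. Trailing incomplete stop
#' codons are excluded from the enumeration. On the human genome with the
#' standard 13-gene annotation this is the null expectation (about 75.7%)
#' against which observed nonsynonymous fractions are compared.
#'
#' @inheritParams classifySubstitution
#' @return Fraction in [0, 1].
#' @export
expectedNonsynFraction <- function(genome, annotation, code = mitoGeneticCode()) {
  ctx <- .codonContexts(genome, annotation)
  # per (gene-context, alt): synonymous or not; then any-gene rule per (pos, alt)
  refBase <- substring(ctx$codon, ctx$cpos + 1L, ctx$cpos + 1L)
  aaRef <- .translateCodons(ctx$codon, code)
  nsTally <- 0L; synTally <- 0L
  # iterate over the three substitution slots: for each context, the three
  # mRNA-sense alternates of its reference base
  altSets <- lapply(.BASES, function(b) setdiff(.BASES, b))
  names(altSets) <- .BASES
  # build per (pos, altL) any-nonsyn aggregation
  n <- nrow(ctx)
  posKey <- character(0L); nsFlag <- logical(0L)
  allKeys <- vector("list", 3L)
  allNs <- vector("list", 3L)
  for (k in 1:3) {
    aAlt <- vapply(seq_len(n), function(i) altSets[[refBase[i]]][k], character(1L))
    mut <- ctx$codon
    substr(mut, ctx$cpos + 1L, ctx$cpos + 1L) <- aAlt
    aaMut <- .translateCodons(mut, code)
    # represent the alternate on the L-strand for position-level dedup
    altL <- ifelse(ctx$strand == "L", complementBases(aAlt), aAlt)
    allKeys[[k]] <- paste0(ctx$pos, "_", altL)
    allNs[[k]] <- aaMut != aaRef
  }
  keys <- unlist(allKeys); nsv <- unlist(allNs)
  anyNs <- tapply(nsv, keys, any)
  ns <- sum(anyNs); syn <- length(anyNs) - ns
  ns / (ns + syn)
}
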