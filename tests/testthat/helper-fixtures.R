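# Shared fixtures, built in code.

# A toy circular genome containing one H-strand gene made of the given
# codons, flanked by fixed non-coding pads, plus an annotation table.
toyGeneGenome <- function(codons, pad5 = "TTTTTTTTTT", pad3 = "AAAAAAAAAA",
                          strand = "H", name = "toy") {
  geneSeq <- paste0(codons, collapse = "")
  if (strand == "L") geneSeq <- reverseComplement(geneSeq)
  bases <- paste0(pad5, geneSeq, pad3)
  genome <- MitoGenome(bases, name = name)
  start <- nchar(pad5) + 1L
  end <- nchar(pad5) + nchar(geneSeq)
  annot <- MitoAnnotation(data.frame(
    label = c("GENE1", "PAD"),
    start = c(start, end + 1L),
    end = c(end, nchar(bases)),
    region_class = c("protein_coding", "tRNA"),
    coding_strand = c(strand, "H"),
    frame = c(0L, 0L), stringsAsFactors = FALSE))
  list(genome = genome, annot = annot, start = start, end = end)
}

# Hand-built aligned read pairs sharing coordinates, for family/consensus
# tests. seqs1/seqs2: character vectors (one read pair per element).
makeAlignedPairs <- function(tag1, tag2, seqs1, seqs2, pos1 = 10L,
                             pos2 = 40L, strand1 = "+", strand2 = "-") {
  n <- length(seqs1)
  data.frame(
    qname = sprintf("p%03d", seq_len(n)),
    tagKey = paste0(tag1, tag2), tag1 = tag1, tag2 = tag2,
    pos1 = pos1, strand1 = strand1, seq1 = seqs1,
    pos2 = pos2, strand2 = strand2, seq2 = seqs2,
    stringsAsFactors = FALSE)
}

# A Pileup built directly from a count matrix (4 x L, rows A,C,G,T).
makePileup <- function(genome, counts,
                       indels = NULL) {
  new("Pileup", counts = counts, genome = genome,
      indels = if (is.null(indels))
        data.frame(pos = integer(), descriptor = character(),
                   count = integer(), stringsAsFactors = FALSE) else indels,
      nReads = 0L)
}

emptyCountMatrix <- function(genome) {
  matrix(0L, 4L, genomeLength(genome), dimnames = list(c("A","C","G","T"), NULL))
}

randomTag <- function(n = 12L) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
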