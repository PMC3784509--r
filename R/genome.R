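#' Construct a MitoGenome
#'
#' @param bases Base string (L-strand); lowercase is normalised to uppercase.
#' @param name Sequence name.
#' @return A \code{\link{MitoGenome}}.
#' @examples
#' g <- MitoGenome("ACGTACGTACGT", name = "toy")
#' genomeLength(g)
#' @export
MitoGenome <- function(bases, name = "chrM") {
  bases <- toupper(bases)
  bad <- gregexpr("[^ACGT]", bases)[[1L]]
  if (bad[1L] != -1L) {
    sym <- unique(substring(bases, bad, bad))
    stop(sprintf("sequence contains non-ACGT characters (%s) at positions %s",
                 paste(sym, collapse = ","),
                 paste(utils::head(bad, 10L), collapse = ",")))
  }
  new("MitoGenome", name = name, bases = bases, circular = TRUE)
}

#' Load a single-record circular reference from FASTA
#'
#' Reads a FASTA file that must contain exactly one record (the mitochondrial
#' target). Lowercase bases are normalised to uppercase; any non-ACGT symbol
#' is an error naming the offending characters and positions.
#'
#' @param path Path to a FASTA file.
#' @param name Optional override for the sequence name (default: FASTA header).
#' @return A \code{\link{MitoGenome}} with wrap-aware indexing.
#' @export
loadReference <- function(path, name = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L)
    stop(sprintf("expected exactly one FASTA record, found %d", length(set)))
  nm <- if (is.null(name)) sub("\\s.*$", "", names(set)[1L]) else name
  MitoGenome(as.character(set[[1L]]), name = nm)
}

#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' Genome length in bases
#' @param x A \code{MitoGenome}.
#' @return Integer length.
#' @rdname genomeLength
#' @export
setMethod("genomeLength", "MitoGenome", function(x) nchar(x@bases))

#' @export
setGeneric("genomeName", function(x) standardGeneric("genomeName"))

#' Genome name
#' @param x A \code{MitoGenome}.
#' @rdname genomeName
#' @export
setMethod("genomeName", "MitoGenome", function(x) x@name)

#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))

#' Genome sequence as a single string
#' @param x A \code{MitoGenome}.
#' @rdname genomeSequence
#' @export
setMethod("genomeSequence", "MitoGenome", function(x) x@bases)

#' @export
setGeneric("baseAt", function(x, pos) standardGeneric("baseAt"))

#' Base at a position, wrapping modulo the genome length
#'
#' @param x A \code{MitoGenome}.
#' @param pos Integer vector of 1-based positions; values outside
#'   \code{[1, length]} wrap around the circle.
#' @return Character vector of single bases.
#' @rdname baseAt
#' @export
setMethod("baseAt", "MitoGenome", function(x, pos) {
  L <- genomeLength(x)
  p <- .wrapPos(as.integer(pos), L)
  rawToChar(charToRaw(x@bases)[p], multiple = TRUE)
})

setMethod("show", "MitoGenome", function(object) {
  cat(sprintf("MitoGenome '%s': %d bp circular L-strand reference\n",
              object@name, genomeLength(object)))
  cnt <- strandBaseCounts(object)
  cat("  base counts:", paste(sprintf("%s=%d", names(cnt), cnt), collapse = " "),
      "\n")
})

#' Count A, C, G, T on the L-strand
#'
#' The human L-strand carries roughly three-fold more cytosine than guanine;
#' this compositional skew underlies the reciprocal-mutation normalisation
#' used by \code{\link{strandAsymmetry}}.
#'
#' @param genome A \code{MitoGenome}.
#' @return Named integer vector (A, C, G, T) summing to the genome length.
#' @export
strandBaseCounts <- function(genome) {
  r <- charToRaw(genome@bases)
  cnt <- vapply(seq_along(.BASE_RAW),
                function(k) sum(r == .BASE_RAW[k]), integer(1L))
  names(cnt) <- .BASES
  cnt
}

# -- rCRS-coordinate human mitochondrial genome -------------------------------

.pkgCache <- new.env(parent = emptyenv())

#' Human mitochondrial genome on rCRS coordinates
#'
#' Returns a 16,569-bp human mitochondrial genome whose coordinate system
#' matches the revised Cambridge Reference Sequence (rCRS) numbering, so the
#' standard gene annotation of \code{\link{rcrsAnnotation}} applies directly.
#'
#' The sequence is derived at run time from the human mitochondrial genome
#' bundled with the \pkg{seqinr} package (GenBank NC_001807.4, 16,571 bp).
#' That older deposit carries one extra cytosine in each of two D-loop poly-C
#' tracts relative to rCRS numbering; removing one base from each tract
#' (positions 310 and 16190 of NC_001807) aligns every gene to its exact rCRS
#' coordinates, which the test suite verifies by translating all 13
#' protein-coding genes. The result differs from the rCRS at a few dozen
#' polymorphic positions, which is immaterial for the site-enumeration and
#' region statistics computed here; it is real human mtDNA, not the rCRS
#' deposit itself.
#'
#' @return A \code{\link{MitoGenome}} of length 16,569 named \code{"chrM"}.
#' @export
humanMitoGenome <- function() {
  if (!is.null(.pkgCache$humanMito)) return(.pkgCache$humanMito)
  path <- system.file("sequences/humanMito.fasta", package = "seqinr")
  if (!nzchar(path) || !file.exists(path))
    stop("seqinr's bundled human mitochondrial genome was not found")
  fa <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
  s <- toupper(paste0(fa[[1L]], collapse = ""))
  if (nchar(s) != 16571L)
    stop("unexpected length for NC_001807: ", nchar(s))
  drop <- c(310L, 16190L)   # one C from each D-loop poly-C tract
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (!all(ch[drop] == "C"))
    stop("coordinate normalisation expected C at positions 310 and 16190")
  g <- MitoGenome(paste0(ch[-drop], collapse = ""), name = "chrM")
  stopifnot(genomeLength(g) == 16569L)
  .pkgCache$humanMito <- g
  g
}
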