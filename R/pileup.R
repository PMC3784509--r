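# Wrap-aware pileup of duplex consensus reads and variant calling.

#' Pile up duplex consensus reads
#'
#' Every defined (non-N) consensus base increments exactly one positional
#' counter, in L-strand orientation, wrapping positions modulo the genome
#' length for reads spanning the origin.
#'
#' @param consensus A \code{ConsensusSet} (DCS level for mutation analysis).
#' @param genome The reference \code{MitoGenome}.
#' @param indels Optional data.frame(pos, descriptor, count) of indel events
#'   (the simulator does not generate indels; this hook serves hand-built
#'   fixtures and real data).
#' @return A \code{\linkS4class{Pileup}}.
#' @export
buildPileup <- function(consensus, genome, indels = NULL) {
  G <- genomeLength(genome)
  c <- consensus@calls
  counts <- matrix(0L, 4L, G, dimnames = list(.BASES, NULL))
  if (is.null(indels))
    indels <- data.frame(pos = integer(), descriptor = character(),
                         count = integer(), stringsAsFactors = FALSE)
  if (nrow(c)) {
    if (any(c$pos1 < 1L | c$pos1 > G | c$pos2 < 1L | c$pos2 > G))
      stop("consensus read position outside the reference")
    for (seg in 1:2) {
      seqs <- c[[paste0("seq", seg)]]
      starts <- c[[paste0("pos", seg)]]
      w <- nchar(seqs)
      allRaw <- charToRaw(paste0(seqs, collapse = ""))
      posv <- .wrapPos(rep(starts, w) + (sequence(w) - 1L), G)
      for (k in 1:4) {
        sel <- allRaw == .BASE_RAW[k]
        if (any(sel)) counts[k, ] <- counts[k, ] + tabulate(posv[sel], G)
      }
    }
  }
  new("Pileup", counts = counts, genome = genome, indels = indels,
      nReads = nrow(c))
}

setMethod("show", "Pileup", function(object) {
  tot <- sum(object@counts)
  cov <- sum(colSums(object@counts) > 0L)
  cat(sprintf("Pileup on '%s': %d consensus reads, %d bases over %d/%d positions\n",
              object@genome@name, object@nReads, tot, cov,
              genomeLength(object@genome)))
})

#' @export
setGeneric("pileupCounts", function(x) standardGeneric("pileupCounts"))

#' Base-count matrix of a pileup
#' @param x A \code{Pileup}.
#' @rdname pileupCounts
#' @export
setMethod("pileupCounts", "Pileup", function(x) x@counts)

#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))

#' Total sequenced (defined) consensus bases
#' @param x A \code{Pileup}.
#' @rdname totalBases
#' @export
setMethod("totalBases", "Pileup", function(x) sum(x@counts))

#' Call variants from a duplex pileup
#'
#' Every (position, alternate base) with at least one supporting molecule
#' becomes one call, scored once per position regardless of its molecule
#' count. Clonality is the fraction of molecules at the position carrying the
#' variant; calls with clonality above \code{clonalityCutoff} are flagged
#' clonal (inherited or clonally expanded) and excluded from de novo
#' statistics, and those above \code{homoplasmyCutoff} are additionally
#' flagged homoplasmic.
#'
#' @param pileup A \code{\linkS4class{Pileup}} built from DCS reads.
#' @param clonalityCutoff Variants above this clonality are excluded from de
#'   novo counts (default 0.01, i.e. >1%).
#' @param homoplasmyCutoff Variants above this clonality are homoplasmic
#'   (default 0.90).
#' @param annotation Optional \code{MitoAnnotation} for region labels.
#' @return data.frame(pos, ref, alt, count, depth, clonality, region,
#'   isClonal, isHomoplasmic, deNovo), one row per (pos, alt).
#' @export
callVariants <- function(pileup, clonalityCutoff = 0.01,
                         homoplasmyCutoff = 0.90, annotation = NULL) {
  g <- pileup@genome
  G <- genomeLength(g)
  refIdx <- .RAW2IDX[as.integer(.genomeRaw(g)) + 1L]
  depth <- colSums(pileup@counts)
  rows <- vector("list", 4L)
  for (k in 1:4) {
    p <- which(pileup@counts[k, ] > 0L & refIdx != k)
    if (length(p))
      rows[[k]] <- data.frame(pos = p, ref = .BASES[refIdx[p]],
                              alt = .BASES[k],
                              count = pileup@counts[k, p],
                              depth = depth[p], stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  if (is.null(calls))
    calls <- data.frame(pos = integer(), ref = character(), alt = character(),
                        count = integer(), depth = numeric(),
                        stringsAsFactors = FALSE)
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  calls$clonality <- calls$count / calls$depth
  calls$region <- if (!is.null(annotation) && nrow(calls))
    regionOf(g, annotation, calls$pos) else rep(NA_character_, nrow(calls))
  calls$isClonal <- calls$clonality > clonalityCutoff
  calls$isHomoplasmic <- calls$clonality > homoplasmyCutoff
  calls$deNovo <- !calls$isClonal
  row.names(calls) <- NULL
  calls
}
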