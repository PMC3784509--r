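# Single-strand and duplex consensus construction, end clipping, near-tag
# deduplication, and NUMT decoy filtering.

# per-position consensus over an m x w raw base matrix: a position is the
# modal base when coverage >= minFamily and the modal fraction >= agreement
# with a unique mode; otherwise N.
.consensusRaw <- function(mat, minFamily, agreement) {
  m <- nrow(mat); w <- ncol(mat)
  if (m < minFamily) return(strrep("N", w))
  cnts <- matrix(0L, 4L, w)
  for (k in 1:4) cnts[k, ] <- colSums(mat == .BASE_RAW[k])
  mx <- cnts[1L, ]; wh <- rep(1L, w)
  for (k in 2:4) {
    b <- cnts[k, ] > mx
    mx[b] <- cnts[k, b]; wh[b] <- k
  }
  ties <- colSums(cnts == rep(mx, each = 4L)) > 1L
  out <- .BASE_RAW[wh]
  out[mx / m < agreement | ties] <- .N_RAW
  rawToChar(out)
}

.stringsToMatrix <- function(strings) {
  do.call(rbind, lapply(strings, charToRaw))
}

#' Build single-strand consensus sequences
#'
#' For every tag family, computes the per-position consensus of each of its
#' two read-end segments: a position is undefined (N) if represented by fewer
#' than \code{minFamily} reads, or if less than \code{agreement} of the reads
#' agree on one base (70% exactly passes). Families whose every position is
#' undefined are dropped and counted.
#'
#' @param families A \code{\linkS4class{FamilySet}}.
#' @param minFamily Minimum reads per position (default 3).
#' @param agreement Minimum modal-base fraction (default 0.7).
#' @return A \code{\linkS4class{ConsensusSet}} of level \code{"SSCS"}.
#' @export
buildSscs <- function(families, minFamily = 3L, agreement = 0.7) {
  info <- families@info
  nf <- nrow(info)
  seq1 <- character(nf); seq2 <- character(nf)
  reads <- families@reads
  for (i in seq_len(nf)) {
    mem <- families@members[[i]]
    seq1[i] <- .consensusRaw(.stringsToMatrix(reads$seq1[mem]), minFamily,
                             agreement)
    seq2[i] <- .consensusRaw(.stringsToMatrix(reads$seq2[mem]), minFamily,
                             agreement)
  }
  defined <- !(grepl("^N*$", seq1) & grepl("^N*$", seq2))
  calls <- cbind(info[defined, , drop = FALSE],
                 data.frame(seq1 = seq1[defined], seq2 = seq2[defined],
                            stringsAsFactors = FALSE))
  row.names(calls) <- NULL
  counts <- c(families@counts, sscs = sum(defined),
              sscs_dropped = nf - sum(defined))
  new("ConsensusSet", calls = calls, level = "SSCS", counts = counts)
}

setMethod("show", "ConsensusSet", function(object) {
  cat(sprintf("ConsensusSet: %d %s reads\n", nrow(object@calls), object@level))
})

#' @export
setGeneric("consensusCalls", function(x) standardGeneric("consensusCalls"))

#' Consensus call table
#' @param x A \code{ConsensusSet}.
#' @rdname consensusCalls
#' @export
setMethod("consensusCalls", "ConsensusSet", function(x) x@calls)

#' Pair single-strand consensus reads with their strand mates
#'
#' The strand mate of a family with key t1|t2 and coordinates (c1, c2) is the
#' family with the swapped key t2|t1 at the swapped coordinates (c2, c1) --
#' the descendants of the complementary parental strand. Each SSCS appears in
#' at most one pair; unpaired SSCS are counted and excluded from DCS
#' building.
#'
#' @param sscs A \code{ConsensusSet} of level SSCS.
#' @return List with \code{pairs} (two-column matrix of row indices into the
#'   call table) and \code{unpaired} (count).
#' @export
pairStrandMates <- function(sscs) {
  stopifnot(sscs@level == "SSCS")
  c <- sscs@calls
  tagLen <- nchar(c$tagKey[1L]) %/% 2L
  selfKey <- paste(c$tagKey, c$pos1, c$strand1, c$pos2, c$strand2, sep = "|")
  mate <- paste(mateTagKey(c$tagKey, tagLen), c$pos2, c$strand2, c$pos1,
                c$strand1, sep = "|")
  j <- match(mate, selfKey)
  i <- seq_len(nrow(c))
  ok <- !is.na(j) & i < j
  pairs <- cbind(i[ok], j[ok])
  unpaired <- nrow(c) - 2L * nrow(pairs)
  list(pairs = pairs, unpaired = unpaired)
}

# position-wise duplex agreement of two strings: identical non-N bases kept,
# anything else N
.duplexAgree <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  out <- ra
  out[ra != rb | ra == .N_RAW] <- .N_RAW
  rawToChar(out)
}

#' Build duplex consensus sequences
#'
#' For each strand-mate pair of SSCS, keeps a base only where the two
#' single-strand consensus reads carry identical non-N bases at that
#' position; any disagreement or undefined position yields N. The operation
#' is symmetric in the two mates.
#'
#' @param sscs A \code{ConsensusSet} of level SSCS.
#' @param pairs Optional pairing as returned by
#'   \code{\link{pairStrandMates}}; computed if missing.
#' @return A \code{ConsensusSet} of level \code{"DCS"}. Each row records the
#'   two source keys and per-strand family sizes.
#' @export
buildDcs <- function(sscs, pairs = NULL) {
  stopifnot(sscs@level == "SSCS")
  if (is.null(pairs)) pairs <- pairStrandMates(sscs)
  c <- sscs@calls
  pm <- pairs$pairs
  np <- nrow(pm)
  out <- vector("list", np)
  for (k in seq_len(np)) {
    i <- pm[k, 1L]; j <- pm[k, 2L]
    # orient on the lexicographically smaller key so the result is symmetric
    if (c$tagKey[j] < c$tagKey[i]) { t <- i; i <- j; j <- t }
    if (c$pos1[i] != c$pos2[j] || c$pos2[i] != c$pos1[j] ||
        c$strand1[i] != c$strand2[j] || c$strand2[i] != c$strand1[j])
      stop("strand mates must map to matching coordinates")
    out[[k]] <- data.frame(
      tagKey = c$tagKey[i], mateKey = c$tagKey[j],
      tag1 = c$tag1[i], tag2 = c$tag2[i],
      pos1 = c$pos1[i], strand1 = c$strand1[i],
      pos2 = c$pos2[i], strand2 = c$strand2[i],
      sizeFwd = c$size[i], sizeRev = c$size[j],
      seq1 = .duplexAgree(c$seq1[i], c$seq2[j]),
      seq2 = .duplexAgree(c$seq2[i], c$seq1[j]),
      stringsAsFactors = FALSE)
  }
  calls <- if (np) do.call(rbind, out) else
    data.frame(tagKey = character(), mateKey = character(),
               tag1 = character(), tag2 = character(),
               pos1 = integer(), strand1 = character(), pos2 = integer(),
               strand2 = character(), sizeFwd = integer(),
               sizeRev = integer(), seq1 = character(), seq2 = character(),
               stringsAsFactors = FALSE)
  row.names(calls) <- NULL
  counts <- c(sscs@counts, dcs = np, sscs_unpaired = pairs$unpaired)
  new("ConsensusSet", calls = calls, level = "DCS", counts = counts)
}

#' Soft-clip consensus read ends
#'
#' Sets the first and last \code{n} positions of every consensus segment to
#' N, removing alignment artifacts common at read ends. Coordinates are
#' unchanged. If \code{2n} reaches the segment length the whole segment
#' becomes undefined (not an error).
#'
#' @param consensus A \code{ConsensusSet}.
#' @param n Bases to clip from each end (default 5).
#' @return The clipped \code{ConsensusSet}.
#' @export
clipEnds <- function(consensus, n = 5L) {
  stopifnot(n >= 0L)
  if (n == 0L) return(consensus)
  clip1 <- function(s) {
    w <- nchar(s)
    if (2L * n >= w) return(strrep("N", w))
    r <- charToRaw(s)
    r[c(seq_len(n), (w - n + 1L):w)] <- .N_RAW
    rawToChar(r)
  }
  c <- consensus@calls
  c$seq1 <- vapply(c$seq1, clip1, character(1L), USE.NAMES = FALSE)
  c$seq2 <- vapply(c$seq2, clip1, character(1L), USE.NAMES = FALSE)
  new("ConsensusSet", calls = c, level = consensus@level,
      counts = consensus@counts)
}

# connected components under Hamming distance < maxDistance (equal-length keys)
.nearTagComponents <- function(keys, maxDistance) {
  n <- length(keys)
  comp <- seq_len(n)
  if (n > 1L) {
    rawKeys <- lapply(keys, charToRaw)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (sum(rawKeys[[i]] != rawKeys[[j]]) < maxDistance) {
        old <- comp[j]; new <- comp[i]
        comp[comp == old] <- new
      }
    }
  }
  match(comp, unique(comp))
}

#' Remove near-duplicate tag families at shared coordinates
#'
#' Among consensus reads mapped to the same genomic coordinates, links those
#' whose 24-base tag keys differ by fewer than \code{maxDistance} bases
#' (Hamming); such near-tags are PCR or sequencing derivatives of one
#' molecule. By default every member of a linked component of size > 1 is
#' removed; \code{keepLargest} instead retains the component's
#' largest-family representative.
#'
#' @param consensus A \code{ConsensusSet} (typically DCS level).
#' @param maxDistance Families closer than this Hamming distance are linked
#'   (default 3, i.e. distance < 3 links; distance 3 does not).
#' @param keepLargest Keep the largest family of each linked component
#'   instead of removing the whole component.
#' @return The filtered \code{ConsensusSet} with a \code{dedup_removed} count.
#' @export
dedupNearTags <- function(consensus, maxDistance = 3L, keepLargest = FALSE) {
  c <- consensus@calls
  n <- nrow(c)
  if (n == 0L) return(consensus)
  cA <- paste(c$pos1, c$strand1); cB <- paste(c$pos2, c$strand2)
  coordKey <- ifelse(cA <= cB, paste(cA, cB, sep = "~"),
                     paste(cB, cA, sep = "~"))
  keep <- rep(TRUE, n)
  size <- if ("sizeFwd" %in% names(c)) c$sizeFwd + c$sizeRev else c$size
  for (grp in split(seq_len(n), coordKey)) {
    if (length(grp) < 2L) next
    comp <- .nearTagComponents(c$tagKey[grp], maxDistance)
    for (cc in split(seq_along(grp), comp)) {
      if (length(cc) < 2L) next
      if (keepLargest) {
        drop <- cc[-which.max(size[grp[cc]])]
        keep[grp[drop]] <- FALSE
      } else {
        keep[grp[cc]] <- FALSE
      }
    }
  }
  counts <- c(consensus@counts, dedup_removed = sum(!keep))
  new("ConsensusSet", calls = c[keep, , drop = FALSE],
      level = consensus@level, counts = counts)
}

# longest run of non-N characters in a string (for decoy alignment queries)
.longestDefinedRun <- function(s) {
  parts <- strsplit(s, "N+")[[1L]]
  if (!length(parts)) return("")
  parts[which.max(nchar(parts))]
}

#' Filter mutant consensus reads that align better to nuclear decoys
#'
#' Reimplements the nuclear-pseudogene (NUMT) screen as a local-alignment
#' score comparison: each consensus read carrying at least one non-reference
#' call is aligned (Smith-Waterman) against the mitochondrial reference and
#' against every decoy sequence; the read is removed when any decoy score
#' strictly exceeds the mitochondrial score. With no decoys every read is
#' kept.
#'
#' @param consensus A \code{ConsensusSet} (DCS level).
#' @param genome The mitochondrial \code{MitoGenome}.
#' @param decoys Character vector (or \code{DNAStringSet}) of nuclear decoy
#'   sequences; may be empty.
#' @param match,mismatch,gapOpening,gapExtension Alignment scoring.
#' @return List with \code{set} (filtered \code{ConsensusSet}) and
#'   \code{removed} (count).
#' @export
numtFilter <- function(consensus, genome, decoys = character(),
                       match = 1, mismatch = -1, gapOpening = 5,
                       gapExtension = 2) {
  c <- consensus@calls
  n <- nrow(c)
  decoys <- as.character(decoys)
  if (n == 0L || length(decoys) == 0L) {
    counts <- c(consensus@counts, numt_removed = 0L)
    return(list(set = new("ConsensusSet", calls = c, level = consensus@level,
                          counts = counts), removed = 0L))
  }
  refRaw <- .genomeRaw(genome)
  G <- genomeLength(genome)
  # circular subject: append a prefix so origin-spanning reads align contiguously
  mitoSubject <- paste0(genome@bases,
                        substr(genome@bases, 1L, min(G, 500L)))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  score1 <- function(query, subject) {
    Biostrings::pairwiseAlignment(query, subject, type = "local",
                                  substitutionMatrix = sm,
                                  gapOpening = gapOpening,
                                  gapExtension = gapExtension,
                                  scoreOnly = TRUE)
  }
  hasMismatch <- vapply(seq_len(n), function(i) {
    for (seg in c("seq1", "seq2")) {
      s <- charToRaw(c[[seg]][i])
      p <- .wrapPos(c[[if (seg == "seq1") "pos1" else "pos2"]][i] +
                      0:(length(s) - 1L), G)
      def <- s != .N_RAW
      if (any(s[def] != refRaw[p[def]])) return(TRUE)
    }
    FALSE
  }, logical(1L))
  keep <- rep(TRUE, n)
  for (i in which(hasMismatch)) {
    q1 <- .longestDefinedRun(c$seq1[i]); q2 <- .longestDefinedRun(c$seq2[i])
    qs <- c(q1, q2); qs <- qs[nchar(qs) > 0L]
    if (!length(qs)) next
    mitoScore <- sum(vapply(qs, score1, numeric(1L), subject = mitoSubject))
    for (d in decoys) {
      if (sum(vapply(qs, score1, numeric(1L), subject = d)) > mitoScore) {
        keep[i] <- FALSE
        break
      }
    }
  }
  counts <- c(consensus@counts, numt_removed = sum(!keep))
  list(set = new("ConsensusSet", calls = c[keep, , drop = FALSE],
                 level = consensus@level, counts = counts),
       removed = sum(!keep))
}

#' Run the full consensus cascade on a family set
#'
#' Convenience composition: SSCS construction, strand-mate pairing, DCS
#' construction, end clipping, near-tag deduplication, and (optionally) the
#' NUMT decoy filter, with bookkeeping counts carried through.
#'
#' @param families A \code{\linkS4class{FamilySet}}.
#' @param genome The reference \code{MitoGenome} (needed for the decoy
#'   filter).
#' @param minFamily,agreement SSCS thresholds.
#' @param clip Bases clipped from each consensus end.
#' @param dedupDistance Near-tag Hamming threshold.
#' @param dedupKeepLargest See \code{\link{dedupNearTags}}.
#' @param decoys Decoy sequences for \code{\link{numtFilter}}.
#' @return List with \code{sscs} and \code{dcs} \code{ConsensusSet}s.
#' @export
duplexConsensus <- function(families, genome, minFamily = 3L, agreement = 0.7,
                            clip = 5L, dedupDistance = 3L,
                            dedupKeepLargest = FALSE, decoys = character()) {
  sscs <- buildSscs(families, minFamily = minFamily, agreement = agreement)
  dcs <- buildDcs(sscs)
  dcs <- clipEnds(dcs, n = clip)
  dcs <- dedupNearTags(dcs, maxDistance = dedupDistance,
                       keepLargest = dedupKeepLargest)
  dcs <- numtFilter(dcs, genome, decoys = decoys)$set
  list(sscs = sscs, dcs = dcs)
}
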