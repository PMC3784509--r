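# Tag extraction, technical-base trimming, and tag-family grouping.

#' Validate read pairs and extract duplex tag keys
#'
#' Vectorised over read pairs. Each read must carry its 12-base duplex tag
#' followed by the fixed spacer; the two tag halves are excised and
#' concatenated in read order into the 24-base key, the spacer is verified
#' exactly at its expected offset, and four further bases are trimmed from
#' each read start to remove end-repair/ligation artifacts. Pairs failing a
#' check are rejected (a normal, counted outcome) with a machine-readable
#' reason: \code{too_short}, \code{bad_spacer} (spacer mismatch in either
#' read), or \code{ambiguous_tag} (non-ACGT base in a tag half).
#'
#' @param read1,read2 Character vectors of raw read sequences.
#' @param spacer Expected fixed spacer sequence.
#' @param tagLength Tag length per read (default 12).
#' @param trimBases Additional bases trimmed from each read start after
#'   spacer removal (default 4).
#' @param qname Optional read names carried through.
#' @return List with \code{prepared} (data.frame qname, tagKey, tag1, tag2,
#'   insert1, insert2), \code{rejected} (data.frame index, reason), and
#'   \code{counts}.
#' @export
prepareReadPairs <- function(read1, read2, spacer = "TGACT", tagLength = 12L,
                             trimBases = 4L, qname = NULL) {
  n <- length(read1)
  stopifnot(length(read2) == n)
  if (is.null(qname)) qname <- sprintf("pair%07d", seq_len(n))
  sLen <- nchar(spacer)
  minLen <- tagLength + sLen + trimBases + 1L
  reason <- rep(NA_character_, n)
  tooShort <- nchar(read1) < minLen | nchar(read2) < minLen
  reason[tooShort] <- "too_short"
  ok <- !tooShort
  tag1 <- substr(read1, 1L, tagLength)
  tag2 <- substr(read2, 1L, tagLength)
  sp1 <- substr(read1, tagLength + 1L, tagLength + sLen)
  sp2 <- substr(read2, tagLength + 1L, tagLength + sLen)
  badSpacer <- ok & (sp1 != spacer | sp2 != spacer)
  reason[badSpacer] <- "bad_spacer"
  ok <- ok & !badSpacer
  goodTag <- grepl("^[ACGT]+$", tag1) & grepl("^[ACGT]+$", tag2)
  ambiguous <- ok & !goodTag
  reason[ambiguous] <- "ambiguous_tag"
  ok <- ok & goodTag
  prepared <- data.frame(
    qname = qname[ok],
    tagKey = paste0(tag1[ok], tag2[ok]),
    tag1 = tag1[ok], tag2 = tag2[ok],
    insert1 = substring(read1[ok], tagLength + sLen + trimBases + 1L),
    insert2 = substring(read2[ok], tagLength + sLen + trimBases + 1L),
    stringsAsFactors = FALSE)
  rejected <- data.frame(index = which(!is.na(reason)),
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  counts <- c(input = n, prepared = nrow(prepared),
              too_short = sum(reason == "too_short", na.rm = TRUE),
              bad_spacer = sum(reason == "bad_spacer", na.rm = TRUE),
              ambiguous_tag = sum(reason == "ambiguous_tag", na.rm = TRUE))
  list(prepared = prepared, rejected = rejected, counts = counts)
}

#' Mate tag key
#'
#' The key of the strand-mate family: the two tag halves swapped. An
#' involution: \code{mateTagKey(mateTagKey(k)) == k}.
#'
#' @param tagKey Character vector of concatenated 2x\code{tagLength} keys.
#' @param tagLength Length of one half.
#' @return Character vector of mate keys.
#' @export
mateTagKey <- function(tagKey, tagLength = 12L) {
  paste0(substr(tagKey, tagLength + 1L, 2L * tagLength),
         substr(tagKey, 1L, tagLength))
}

#' Attach alignment coordinates to prepared read pairs
#'
#' Joins mapping coordinates (from the simulator's ground-truth SAM or any
#' aligner's output on the prepared reads) onto prepared pairs by read name.
#' Insert sequences of reverse-strand reads are reverse-complemented into
#' reference (L-strand) orientation. Pairs that are unmapped or mapped to a
#' different reference are dropped and counted as off-target.
#'
#' @param prep Result of \code{\link{prepareReadPairs}} (or its
#'   \code{$prepared} data.frame).
#' @param alignments data.frame(qname, mate, flag, rname, pos, strand, seq)
#'   as from \code{\link{readSam}} or a \code{SimLibrary}.
#' @param genome The mitochondrial \code{MitoGenome}; reads mapped elsewhere
#'   are off-target.
#' @return List with \code{pairs} (aligned, reference-orientation inserts)
#'   and \code{counts}.
#' @export
attachAlignments <- function(prep, alignments, genome) {
  prepared <- if (is.data.frame(prep)) prep else prep$prepared
  a1 <- alignments[alignments$mate == 1L, ]
  a2 <- alignments[alignments$mate == 2L, ]
  i1 <- match(prepared$qname, a1$qname)
  i2 <- match(prepared$qname, a2$qname)
  mapped <- !is.na(i1) & !is.na(i2)
  onTarget <- mapped & a1$rname[i1] == genome@name &
    a2$rname[i2] == genome@name & bitwAnd(a1$flag[i1], 4L) == 0L &
    bitwAnd(a2$flag[i2], 4L) == 0L
  onTarget[is.na(onTarget)] <- FALSE
  k1 <- i1[onTarget]; k2 <- i2[onTarget]
  p <- prepared[onTarget, , drop = FALSE]
  s1 <- a1$strand[k1]; s2 <- a2$strand[k2]
  ins1 <- p$insert1; ins2 <- p$insert2
  rev1 <- s1 == "-"; rev2 <- s2 == "-"
  ins1[rev1] <- reverseComplement(ins1[rev1])
  ins2[rev2] <- reverseComplement(ins2[rev2])
  pairs <- data.frame(
    qname = p$qname, tagKey = p$tagKey, tag1 = p$tag1, tag2 = p$tag2,
    pos1 = a1$pos[k1], strand1 = s1, seq1 = ins1,
    pos2 = a2$pos[k2], strand2 = s2, seq2 = ins2,
    stringsAsFactors = FALSE)
  counts <- c(input = nrow(prepared), onTarget = nrow(pairs),
              offTarget = nrow(prepared) - nrow(pairs))
  list(pairs = pairs, counts = counts)
}

#' Group aligned read pairs into duplex tag families
#'
#' Family identity is the 24-base tag key together with the pair's mapped
#' coordinates (leftmost positions and orientations of both reads), merging
#' the two grouping criteria -- identical tag sequences, identical mapping --
#' into one key. Families partition the input.
#'
#' @param aligned Result of \code{\link{attachAlignments}} (or its
#'   \code{$pairs} data.frame).
#' @param extraCounts Named integer counts carried into the result's
#'   bookkeeping (e.g. rejected counts from tag extraction).
#' @return A \code{\linkS4class{FamilySet}}.
#' @export
groupFamilies <- function(aligned, extraCounts = integer()) {
  pairs <- if (is.data.frame(aligned)) aligned else aligned$pairs
  key <- paste(pairs$tagKey, pairs$pos1, pairs$strand1, pairs$pos2,
               pairs$strand2, sep = "|")
  members <- split(seq_len(nrow(pairs)), key)
  first <- vapply(members, `[`, integer(1L), 1L)
  info <- data.frame(
    tagKey = pairs$tagKey[first], tag1 = pairs$tag1[first],
    tag2 = pairs$tag2[first],
    pos1 = pairs$pos1[first], strand1 = pairs$strand1[first],
    pos2 = pairs$pos2[first], strand2 = pairs$strand2[first],
    size = lengths(members), stringsAsFactors = FALSE, row.names = NULL)
  counts <- c(pairs = nrow(pairs), families = nrow(info), extraCounts)
  new("FamilySet", info = info, members = unname(members), reads = pairs,
      counts = counts)
}

setMethod("show", "FamilySet", function(object) {
  cat(sprintf("FamilySet: %d families over %d read pairs; size range %s\n",
              nrow(object@info), nrow(object@reads),
              if (nrow(object@info))
                paste(range(object@info$size), collapse = "-") else "NA"))
})

#' @export
setGeneric("familyInfo", function(x) standardGeneric("familyInfo"))

#' Family metadata table
#' @param x A \code{FamilySet}.
#' @rdname familyInfo
#' @export
setMethod("familyInfo", "FamilySet", function(x) x@info)
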