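# Internal low-level helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.BASE_RAW <- charToRaw("ACGT")
.N_RAW <- charToRaw("N")

# complement lookup indexed by raw byte value (A<->T, C<->G); identity elsewhere
.COMP_TABLE <- local({
  tab <- as.raw(0:255)
  from <- charToRaw("ACGTacgt")
  to   <- charToRaw("TGCAtgca")
  tab[as.integer(from) + 1L] <- to
  tab
})

.compRaw <- function(r) .COMP_TABLE[as.integer(r) + 1L]

#' Complement bases
#'
#' Vectorised Watson-Crick complement of base strings (not reversed).
#' \code{complementBases(complementBases(x))} is the identity.
#'
#' @param x Character vector of base strings.
#' @return Character vector of the same shape.
#' @examples complementBases(c("A", "GATC"))
#' @export
complementBases <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

#' Reverse complement
#'
#' @param x Character vector of base strings.
#' @return Reverse-complemented strings.
#' @export
reverseComplement <- function(x) {
  vapply(x, function(s) rawToChar(rev(.compRaw(charToRaw(s)))), character(1L),
         USE.NAMES = FALSE)
}

# 1-based wrap onto a circle of length L
.wrapPos <- function(pos, L) ((pos - 1L) %% L) + 1L

# positions covered by [start, end] inclusive, wrapping when end < start
.expandPositions <- function(start, end, L) {
  if (end >= start) seq.int(start, end) else c(seq.int(start, L), seq.int(1L, end))
}

# Hamming distance between two equal-length strings
.hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}

# raw genome vector with wrap-aware extraction
.genomeRaw <- function(genome) charToRaw(genome@bases)

.substrAll <- function(x, start, stop) substr(x, start, stop)
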