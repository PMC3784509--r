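# Duplex library simulator: seeded generation of tag-families with the four
# error classes (true mutations on both parental strands; single-strand damage
# confined to one family; late PCR errors in a subset of one family; per-read
# sequencing errors), plus ground-truth alignments and an event ledger.

.RAW2IDX <- local({
  t <- integer(256)
  t[as.integer(.BASE_RAW) + 1L] <- 1:4
  t
})

# alternatives (base indices) for each current base index
.ALT_TAB <- local({
  m <- matrix(0L, 4, 3)
  for (i in 1:4) m[i, ] <- setdiff(1:4, i)
  m
})

.SUB_CLASSES <- as.vector(outer(.BASES, .BASES, function(a, b)
  paste0(a, ">", b)))[as.vector(outer(1:4, 1:4, "!="))]

#' Default damage spectrum (8-oxo-dG-like)
#'
#' Probabilities over the 12 directional substitution classes applied on the
#' lesion strand. The default concentrates 80% of the mass on G>T, mimicking
#' 8-oxo-dG, with the remainder uniform over the other 11 classes.
#'
#' @param gt Mass on G>T.
#' @return Named numeric vector over the 12 classes summing to 1.
#' @export
defaultDamageSpectrum <- function(gt = 0.8) {
  p <- rep((1 - gt) / 11, 12)
  names(p) <- .SUB_CLASSES
  p["G>T"] <- gt
  p
}

#' Construct a simulator configuration
#'
#' See \code{\linkS4class{DuplexSimConfig}} for the meaning of each
#' parameter. Defaults reflect the study conditions: 101-bp paired-end reads
#' with 12-bp duplex tags, sequencing error 1e-3/base, strand-specific damage
#' 1e-4/base concentrated on G>T, late PCR errors 1e-4/base/duplication, true
#' mutation frequency 1e-5/base, and per-strand family sizes drawn from a
#' shifted Poisson (minimum 1, mean 6).
#'
#' @param genome A \code{MitoGenome}.
#' @param nFragments Number of fragments.
#' @param trueMutationRate,damageRate,latePcrRate,seqErrorRate Error rates.
#' @param clonalVariants data.frame(pos, alt, fraction) or NULL.
#' @param injectTrueMutations Number of true mutations placed
#'   deterministically, one per distinct fragment at a uniform position in
#'   the sequenced core of the fragment's first read segment, in addition to
#'   the \code{trueMutationRate} draws; for exactly-one-event sensitivity
#'   experiments.
#' @param fragmentMean,fragmentSd Fragment length distribution.
#' @param readLength,tagLength,spacer Read geometry.
#' @param familyMean,familyMin Per-strand family size distribution.
#' @param damageSpectrum Named probabilities over the 12 substitution classes.
#' @param seed Integer seed; fully determines the output.
#' @return A validated \code{DuplexSimConfig}.
#' @export
DuplexSimConfig <- function(genome, nFragments,
                            trueMutationRate = 1e-5, damageRate = 1e-4,
                            latePcrRate = 1e-4, seqErrorRate = 1e-3,
                            clonalVariants = NULL, injectTrueMutations = 0L,
                            fragmentMean = 160, fragmentSd = 10,
                            readLength = 101L, tagLength = 12L,
                            spacer = "TGACT",
                            familyMean = 6, familyMin = 1L,
                            damageSpectrum = defaultDamageSpectrum(),
                            seed = 1L) {
  if (is.null(clonalVariants))
    clonalVariants <- data.frame(pos = integer(), alt = character(),
                                 fraction = numeric(), stringsAsFactors = FALSE)
  new("DuplexSimConfig", genome = genome, nFragments = as.integer(nFragments),
      fragmentMean = fragmentMean, fragmentSd = fragmentSd,
      readLength = as.integer(readLength), tagLength = as.integer(tagLength),
      spacer = spacer, familyMean = familyMean,
      familyMin = as.integer(familyMin),
      trueMutationRate = trueMutationRate, damageRate = damageRate,
      damageSpectrum = damageSpectrum, latePcrRate = latePcrRate,
      seqErrorRate = seqErrorRate, clonalVariants = clonalVariants,
      injectTrueMutations = as.integer(injectTrueMutations),
      seed = as.integer(seed))
}

setMethod("show", "DuplexSimConfig", function(object) {
  cat(sprintf(paste0("DuplexSimConfig: %d fragments on '%s' (%d bp), ",
                     "read %d bp, tag %d bp, spacer '%s'\n"),
              object@nFragments, object@genome@name,
              genomeLength(object@genome), object@readLength,
              object@tagLength, object@spacer))
  cat(sprintf("  rates: true=%g damage=%g latePCR=%g seq=%g; family min %d mean %g; seed %d\n",
              object@trueMutationRate, object@damageRate, object@latePcrRate,
              object@seqErrorRate, object@familyMin, object@familyMean,
              object@seed))
})

# ledger accumulator helpers ---------------------------------------------

.accNew <- function() {
  e <- new.env(parent = emptyenv())
  e$rows <- list(); e$i <- 0L
  e
}

.accAdd <- function(acc, class, pos, ref, alt, fragment, strand, orientation,
                    members) {
  n <- length(pos)
  if (!n) return(invisible())
  acc$i <- acc$i + 1L
  acc$rows[[acc$i]] <- list(class = rep(class, n), pos = pos, ref = ref,
                            alt = alt, fragment = rep(fragment, n),
                            strand = rep(strand, length.out = n),
                            orientation = rep(orientation, length.out = n),
                            members = rep(members, length.out = n))
  invisible()
}

.accFinalize <- function(acc) {
  if (!acc$i)
    return(data.frame(class = character(), pos = integer(), ref = character(),
                      alt = character(), fragment = integer(),
                      strand = character(), orientation = character(),
                      members = character(), stringsAsFactors = FALSE))
  data.frame(
    class = unlist(lapply(acc$rows, `[[`, "class")),
    pos = unlist(lapply(acc$rows, `[[`, "pos")),
    ref = unlist(lapply(acc$rows, `[[`, "ref")),
    alt = unlist(lapply(acc$rows, `[[`, "alt")),
    fragment = unlist(lapply(acc$rows, `[[`, "fragment")),
    strand = unlist(lapply(acc$rows, `[[`, "strand")),
    orientation = unlist(lapply(acc$rows, `[[`, "orientation")),
    members = unlist(lapply(acc$rows, `[[`, "members")),
    stringsAsFactors = FALSE)
}

# draw alternates != current (vectorised); returns list(curIdx, altIdx)
.drawAlts <- function(curRaw) {
  n <- length(curRaw)
  curIdx <- .RAW2IDX[as.integer(curRaw) + 1L]
  pick <- sample.int(3L, n, replace = TRUE)
  altIdx <- .ALT_TAB[cbind(curIdx, pick)]
  list(cur = curIdx, alt = altIdx)
}

.rowsToStrings <- function(mat) {
  vapply(seq_len(nrow(mat)), function(i) rawToChar(mat[i, ]), character(1L))
}

#' Simulate a duplex-tagged paired-end library
#'
#' Generates \code{nFragments} double-stranded fragments at uniform positions
#' on the circular genome (fragments may wrap the origin). Each fragment
#' yields two tag families -- alpha-beta and beta-alpha orientation -- whose
#' per-strand sizes are drawn independently. True mutations and clonal
#' variants are present in every read of both families; damage events in
#' every read of exactly one family; late PCR errors in a strict subset of
#' one family; sequencing errors independently per read and base. Reads embed
#' tag + spacer + insert; the ground-truth alignments describe the prepared
#' (tag-stripped, 4-base-trimmed) reads. Identical seeds give identical
#' output.
#'
#' @param config A \code{\link{DuplexSimConfig}}.
#' @return A \code{\linkS4class{SimLibrary}}.
#' @export
simulateLibrary <- function(config) {
  validObject(config)
  set.seed(config@seed)
  g <- config@genome
  G <- genomeLength(g)
  refRaw <- .genomeRaw(g)
  n <- config@nFragments
  insertLen <- config@readLength - config@tagLength - nchar(config@spacer)
  trimB <- 4L
  alnLen <- insertLen - trimB
  if (alnLen < 1L) stop("insert shorter than read after tag/spacer removal")
  acc <- .accNew()
  emptyReads <- data.frame(qname = character(), read1 = character(),
                           read2 = character(), stringsAsFactors = FALSE)
  emptyAln <- data.frame(qname = character(), mate = integer(),
                         flag = integer(), rname = character(),
                         pos = integer(), strand = character(),
                         seq = character(), stringsAsFactors = FALSE)
  if (n == 0L)
    return(new("SimLibrary", reads = emptyReads, alignments = emptyAln,
               truth = .accFinalize(acc), config = config))
  if (config@fragmentMean < insertLen)
    stop(sprintf("fragment mean %g shorter than the %d-base genomic portion of a read",
                 config@fragmentMean, insertLen))

  fragLen <- pmax(insertLen,
                  as.integer(round(stats::rnorm(n, config@fragmentMean,
                                                config@fragmentSd))))
  fragStart <- sample.int(G, n, replace = TRUE)
  # deterministic injections: one per distinct fragment, placed uniformly in
  # the sequenced core of the first read segment (clear of the trimmed start
  # and of end positions that downstream clipping renders undefined), so a
  # sensitivity experiment measures the pipeline, not fragment coverage
  injected <- integer(n)   # 0 = none, else the fragment offset to mutate
  if (config@injectTrueMutations > 0L) {
    ff <- sample.int(n, min(config@injectTrueMutations, n))
    lo <- trimB + 6L
    hi <- insertLen - 5L
    injected[ff] <- lo + vapply(ff, function(i) sample.int(hi - lo + 1L, 1L),
                                integer(1L)) - 1L
  }
  shift <- config@familyMean - config@familyMin
  mAB <- config@familyMin + stats::rpois(n, shift)
  mBA <- config@familyMin + stats::rpois(n, shift)
  totalPairs <- sum(mAB) + sum(mBA)

  qname <- character(totalPairs)
  read1 <- character(totalPairs)
  read2 <- character(totalPairs)
  a_qname <- character(2L * totalPairs); a_mate <- integer(2L * totalPairs)
  a_flag <- integer(2L * totalPairs); a_pos <- integer(2L * totalPairs)
  a_strand <- character(2L * totalPairs); a_seq <- character(2L * totalPairs)

  cv <- config@clonalVariants
  if (nrow(cv)) {
    if (any(cv$fraction <= 0 | cv$fraction > 1))
      stop("clonal variant fractions must be in (0,1]")
    cv$altRaw <- charToRaw(paste0(cv$alt, collapse = ""))
  }
  spec <- config@damageSpectrum
  specSrc <- substring(names(spec), 1L, 1L)
  specAlt <- substring(names(spec), 3L, 3L)
  # per source base: alternates and renormalised probabilities
  dmg <- lapply(.BASES, function(b) {
    i <- which(specSrc == b & spec > 0)
    list(alt = specAlt[i], p = spec[i] / sum(spec[i]))
  })
  names(dmg) <- .BASES

  off <- 0L  # filled pairs
  for (f in seq_len(n)) {
    l <- fragLen[f]
    idx <- .wrapPos(fragStart[f] + 0:(l - 1L), G)
    frag <- refRaw[idx]

    # clonal variants: per fragment Bernoulli(fraction)
    if (nrow(cv)) {
      for (v in seq_len(nrow(cv))) {
        j <- match(cv$pos[v], idx)
        if (!is.na(j) && stats::runif(1L) < cv$fraction[v]) {
          refb <- rawToChar(frag[j])
          if (refb != cv$alt[v]) {
            .accAdd(acc, "clonal_variant", idx[j], refb, cv$alt[v], f,
                    "both", "both", "")
            frag[j] <- cv$altRaw[v]
          }
        }
      }
    }
    # true mutations: both parental strands
    nT <- stats::rbinom(1L, l, config@trueMutationRate)
    jjInj <- if (injected[f] > 0L) injected[f] else integer(0L)
    if (nT > 0L || length(jjInj)) {
      jj <- unique(c(jjInj, if (nT > 0L) sample.int(l, nT) else integer(0L)))
      d <- .drawAlts(frag[jj])
      .accAdd(acc, "true_mutation", idx[jj], .BASES[d$cur], .BASES[d$alt], f,
              "both", "both", "")
      frag[jj] <- .BASE_RAW[d$alt]
    }
    # damage: one parental strand each; alpha strand reported in L-sense,
    # beta strand lesions complemented into L-sense representation
    tmplA <- frag; tmplB <- frag
    for (st in c("alpha", "beta")) {
      nD <- stats::rbinom(1L, l, config@damageRate)
      if (nD == 0L) next
      jj <- sample.int(l, nD)
      keepPos <- integer(0L); keepRef <- character(0L); keepAlt <- character(0L)
      for (j in jj) {
        lrefb <- rawToChar(frag[j])
        srcb <- if (st == "alpha") lrefb else complementBases(lrefb)
        hit <- dmg[[srcb]]
        if (!length(hit$alt)) next
        a <- sample(hit$alt, 1L, prob = hit$p)
        altL <- if (st == "alpha") a else complementBases(a)
        if (altL == lrefb) next
        keepPos <- c(keepPos, idx[j]); keepRef <- c(keepRef, lrefb)
        keepAlt <- c(keepAlt, altL)
        if (st == "alpha") tmplA[j] <- charToRaw(altL)
        else tmplB[j] <- charToRaw(altL)
      }
      .accAdd(acc, "damage", keepPos, keepRef, keepAlt, f, st,
              if (st == "alpha") "ab" else "ba", "")
    }

    tagA <- rawToChar(.BASE_RAW[sample.int(4L, config@tagLength, replace = TRUE)])
    tagB <- rawToChar(.BASE_RAW[sample.int(4L, config@tagLength, replace = TRUE)])
    leftIdx <- seq_len(insertLen)
    rightIdx <- (l - insertLen + 1L):l
    posLeftAln <- idx[trimB + 1L]            # leftmost genomic pos, forward read
    posRightAln <- idx[l - insertLen + 1L]   # leftmost genomic pos, reverse read

    for (ori in c("ab", "ba")) {
      m <- if (ori == "ab") mAB[f] else mBA[f]
      tmpl <- if (ori == "ab") tmplA else tmplB
      matL <- matrix(tmpl[leftIdx], m, insertLen, byrow = TRUE)
      matR <- matrix(tmpl[rightIdx], m, insertLen, byrow = TRUE)
      # late PCR errors: single lineage split affecting a strict subset
      if (m >= 2L && config@latePcrRate > 0) {
        for (side in 1:2) {
          nE <- stats::rpois(1L, config@latePcrRate * insertLen * (m - 1L))
          for (e in seq_len(nE)) {
            u <- sample.int(insertLen, 1L)
            dstep <- sample.int(max(1L, ceiling(log2(m))), 1L)
            kk <- max(1L, floor(m / 2^dstep))
            if (kk >= m) kk <- m - 1L
            rows <- sample.int(m, kk)
            curRaw <- if (side == 1L) matL[rows[1L], u] else matR[rows[1L], u]
            d <- .drawAlts(curRaw)
            gp <- if (side == 1L) idx[leftIdx[u]] else idx[rightIdx[u]]
            .accAdd(acc, "late_pcr", gp, .BASES[d$cur], .BASES[d$alt], f, "",
                    ori, paste(sort(rows), collapse = ","))
            if (side == 1L) matL[rows, u] <- .BASE_RAW[d$alt]
            else matR[rows, u] <- .BASE_RAW[d$alt]
          }
        }
      }
      # sequencing errors: iid per read per base
      if (config@seqErrorRate > 0) {
        for (side in 1:2) {
          nS <- stats::rbinom(1L, m * insertLen, config@seqErrorRate)
          if (nS == 0L) next
          cells <- sample.int(m * insertLen, nS)
          mat <- if (side == 1L) matL else matR
          d <- .drawAlts(mat[cells])
          rows <- ((cells - 1L) %% m) + 1L
          cols <- ((cells - 1L) %/% m) + 1L
          gp <- if (side == 1L) idx[leftIdx[cols]] else idx[rightIdx[cols]]
          .accAdd(acc, "sequencing", gp, .BASES[d$cur], .BASES[d$alt], f, "",
                  ori, as.character(rows))
          mat[cells] <- .BASE_RAW[d$alt]
          if (side == 1L) matL <- mat else matR <- mat
        }
      }

      fwdStr <- .rowsToStrings(matL)                 # genomic, fragment left end
      revSegStr <- .rowsToStrings(matR)              # genomic, fragment right end
      revReadStr <- reverseComplement(revSegStr)     # as sequenced
      qn <- sprintf("frag%07d:%s:%02d", f, ori, seq_len(m))
      sl <- off + seq_len(m)
      qname[sl] <- qn
      if (ori == "ab") {
        read1[sl] <- paste0(tagA, config@spacer, fwdStr)
        read2[sl] <- paste0(tagB, config@spacer, revReadStr)
        r1pos <- posLeftAln; r1strand <- "+"; r2pos <- posRightAln; r2strand <- "-"
        r1flag <- 99L; r2flag <- 147L
        r1seq <- substring(fwdStr, trimB + 1L, insertLen)
        r2seq <- substring(revSegStr, 1L, alnLen)
      } else {
        read1[sl] <- paste0(tagB, config@spacer, revReadStr)
        read2[sl] <- paste0(tagA, config@spacer, fwdStr)
        r1pos <- posRightAln; r1strand <- "-"; r2pos <- posLeftAln; r2strand <- "+"
        r1flag <- 83L; r2flag <- 163L
        r1seq <- substring(revSegStr, 1L, alnLen)
        r2seq <- substring(fwdStr, trimB + 1L, insertLen)
      }
      asl <- 2L * off + seq_len(2L * m)
      a_qname[asl] <- rep(qn, 2L)
      a_mate[asl] <- rep(1:2, each = m)
      a_flag[asl] <- rep(c(r1flag, r2flag), each = m)
      a_pos[asl] <- rep(c(r1pos, r2pos), each = m)
      a_strand[asl] <- rep(c(r1strand, r2strand), each = m)
      a_seq[asl] <- c(r1seq, r2seq)
      off <- off + m
    }
  }
  reads <- data.frame(qname = qname, read1 = read1, read2 = read2,
                      stringsAsFactors = FALSE)
  aln <- data.frame(qname = a_qname, mate = a_mate, flag = a_flag,
                    rname = g@name, pos = a_pos, strand = a_strand,
                    seq = a_seq, stringsAsFactors = FALSE)
  new("SimLibrary", reads = reads, alignments = aln,
      truth = .accFinalize(acc), config = config)
}

setMethod("show", "SimLibrary", function(object) {
  cat(sprintf("SimLibrary: %d read pairs, %d truth events on '%s'\n",
              nrow(object@reads), nrow(object@truth),
              object@config@genome@name))
  if (nrow(object@truth)) {
    tab <- table(object@truth$class)
    cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
})

#' Random circular genome for tests and examples
#'
#' Draws a base string with the given GC content and an L-strand C:G skew
#' (more C than G, as in mitochondrial genomes).
#'
#' @param length Genome length in bases.
#' @param gc GC fraction.
#' @param cSkew Fraction of the GC mass assigned to C.
#' @param seed Integer seed.
#' @param name Sequence name.
#' @return A \code{MitoGenome}.
#' @export
syntheticCircleGenome <- function(length, gc = 0.44, cSkew = 0.7, seed = 1L,
                                  name = "toyM") {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc * cSkew, G = gc * (1 - cSkew),
         T = (1 - gc) / 2)
  MitoGenome(paste0(sample(.BASES, length, replace = TRUE, prob = p),
                    collapse = ""), name = name)
}

#' Write a simulated library to FASTQ, SAM and truth TSV
#'
#' Emits standard 4-line paired FASTQ (constant high-quality placeholders --
#' the pipeline's filters are identity-based), a minimal SAM with an @SQ
#' header for the prepared reads' ground-truth alignments, and the event
#' ledger as TSV.
#'
#' @param lib A \code{SimLibrary}.
#' @param prefix Output path prefix; files
#'   \code{<prefix>_R1.fastq}, \code{<prefix>_R2.fastq},
#'   \code{<prefix>.sam}, \code{<prefix>_truth.tsv} are written.
#' @return Invisibly, the vector of paths written.
#' @export
writeSimLibrary <- function(lib, prefix) {
  r <- lib@reads
  paths <- c(R1 = paste0(prefix, "_R1.fastq"), R2 = paste0(prefix, "_R2.fastq"),
             sam = paste0(prefix, ".sam"), truth = paste0(prefix, "_truth.tsv"))
  writeFastq(r$qname, r$read1, paths[["R1"]])
  writeFastq(r$qname, r$read2, paths[["R2"]])
  writeSam(lib@alignments, lib@config@genome, paths[["sam"]])
  utils::write.table(lib@truth, paths[["truth"]], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}

#' Write reads as 4-line FASTQ
#'
#' @param qname Read names.
#' @param seqs Base strings.
#' @param path Output path.
#' @param quality Quality character used for every base (default "I", Q40).
#' @export
writeFastq <- function(qname, seqs, path, quality = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- qname
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(w)
    strrep(quality, w), character(1L)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write minimal SAM records
#'
#' One record per read with QNAME/FLAG/RNAME/POS/MAPQ/CIGAR and the aligned
#' (reference-orientation) sequence; header carries the @SQ line for the
#' circular reference. Reads spanning the origin keep a simple \code{<n>M}
#' CIGAR with positions interpreted modulo the genome length by this
#' package's pileup (a real aligner would split such records).
#'
#' @param alignments data.frame(qname, mate, flag, rname, pos, strand, seq).
#' @param genome The reference \code{MitoGenome}.
#' @param path Output path.
#' @export
writeSam <- function(alignments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", genome@name, genomeLength(genome))),
             con)
  if (nrow(alignments)) {
    lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                     alignments$qname, alignments$flag, alignments$rname,
                     alignments$pos, nchar(alignments$seq), alignments$seq)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read minimal SAM records
#'
#' Parses the subset of SAM emitted by \code{\link{writeSam}} (QNAME, FLAG,
#' RNAME, POS, SEQ; ungapped CIGAR). Mate and strand are recovered from the
#' flag bits.
#'
#' @param path Path to a SAM file.
#' @return data.frame(qname, mate, flag, rname, pos, strand, seq).
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(qname = character(), mate = integer(), flag = integer(),
                      rname = character(), pos = integer(),
                      strand = character(), seq = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(parts, function(p) as.integer(p[2L]), integer(1L))
  data.frame(
    qname = vapply(parts, `[[`, character(1L), 1L),
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    flag = flag,
    rname = vapply(parts, `[[`, character(1L), 3L),
    pos = vapply(parts, function(p) as.integer(p[4L]), integer(1L)),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq = vapply(parts, `[[`, character(1L), 10L),
    stringsAsFactors = FALSE)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 Paths to the R1 and R2 FASTQ files.
#' @return data.frame(qname, read1, read2).
#' @export
readFastqPairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  stopifnot(length(r1) == length(r2))
  data.frame(qname = sub("\\s.*$", "", names(r1)),
             read1 = as.character(r1), read2 = as.character(r2),
             stringsAsFactors = FALSE, row.names = NULL)
}
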