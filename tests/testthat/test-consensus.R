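# families built from hand-made aligned pairs; seq2 mirrors seq1 unless noted
famFromSeqs <- function(seqs1, seqs2 = seqs1, tag1 = "AAAACCCCGGGG",
                        tag2 = "TTTTAAAACCCC", ...) {
  groupFamilies(makeAlignedPairs(tag1, tag2, seqs1, seqs2, ...))
}

test_that("SSCS unanimity, minimum family size and 70% agreement", {
  # 3 identical reads: consensus equals the read everywhere
  f <- famFromSeqs(rep("ACGTACGTAC", 3))
  s <- consensusCalls(buildSscs(f))
  expect_equal(s$seq1, "ACGTACGTAC")
  # family of size 2: no defined positions, family dropped
  f2 <- famFromSeqs(rep("ACGTACGTAC", 2))
  s2 <- buildSscs(f2)
  expect_equal(nrow(consensusCalls(s2)), 0L)
  expect_equal(unname(s2@counts["sscs_dropped"]), 1L)
  # 10 reads, 7xA vs 3xG at one position: 0.70 >= 0.70 passes
  seqs <- c(rep("AAAA", 7), rep("AGAA", 3))
  s3 <- consensusCalls(buildSscs(famFromSeqs(seqs)))
  expect_equal(s3$seq1, "AAAA")
  # 6 vs 4: below 70%, undefined
  seqs4 <- c(rep("AAAA", 6), rep("AGAA", 4))
  s4 <- consensusCalls(buildSscs(famFromSeqs(seqs4)))
  expect_equal(s4$seq1, "ANAA")
})

test_that("SSCS agrees with an exhaustive per-position tally oracle", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:40) {
    m <- sample(1:5, 1)
    w <- sample(1:10, 1)
    mat <- matrix(sample(bases, m * w, replace = TRUE), m, w)
    seqs <- apply(mat, 1, paste0, collapse = "")
    minF <- sample(1:4, 1)
    agr <- stats::runif(1, 0.5, 1)
    got <- buildSscs(famFromSeqs(seqs, seqs), minFamily = minF,
                     agreement = agr)
    gotSeq <- if (nrow(consensusCalls(got))) consensusCalls(got)$seq1 else
      strrep("N", w)
    oracle <- vapply(seq_len(w), function(j) {
      if (m < minF) return("N")
      tab <- table(factor(mat[, j], levels = bases))
      mx <- max(tab)
      if (mx / m < agr || sum(tab == mx) > 1L) "N" else
        names(tab)[which.max(tab)]
    }, character(1L))
    expect_equal(gotSeq, paste0(oracle, collapse = ""),
                 label = sprintf("rep %d m=%d w=%d", rep, m, w))
  }
})

# build an SSCS set containing a mate pair by simulating the two families
mateSscs <- function(seqsF1, seqsF2, seqsM1 = NULL, seqsM2 = NULL) {
  t1 <- "AAAACCCCGGGG"; t2 <- "TTTTAAAACCCC"
  if (is.null(seqsM1)) seqsM1 <- seqsF2
  if (is.null(seqsM2)) seqsM2 <- seqsF1
  a <- makeAlignedPairs(t1, t2, seqsF1, seqsF2, pos1 = 10L, pos2 = 40L,
                        strand1 = "+", strand2 = "-")
  b <- makeAlignedPairs(t2, t1, seqsM1, seqsM2, pos1 = 40L, pos2 = 10L,
                        strand1 = "-", strand2 = "+")
  buildSscs(groupFamilies(rbind(a, b)))
}

test_that("strand mates pair by swapped key and coordinates", {
  s <- mateSscs(rep("ACGT", 3), rep("GGCC", 3))
  pr <- pairStrandMates(s)
  expect_equal(nrow(pr$pairs), 1L)
  expect_equal(pr$unpaired, 0L)
  # without the mate family: unpaired, no DCS
  a <- makeAlignedPairs("AAAACCCCGGGG", "TTTTAAAACCCC", rep("ACGT", 3),
                        rep("GGCC", 3))
  s2 <- buildSscs(groupFamilies(a))
  pr2 <- pairStrandMates(s2)
  expect_equal(nrow(pr2$pairs), 0L)
  expect_equal(pr2$unpaired, 1L)
  expect_equal(nrow(consensusCalls(buildDcs(s2, pr2))), 0L)
})

test_that("DCS keeps only identical non-N bases and is symmetric", {
  # identical SSCS pair: DCS equals both
  s <- mateSscs(rep("ACGTACGT", 3), rep("GGCCGGCC", 3))
  d <- consensusCalls(buildDcs(s))
  expect_equal(d$seq1, "ACGTACGT")
  expect_equal(d$seq2, "GGCCGGCC")
  # disagreement at one position: N there, all else retained
  s2 <- mateSscs(rep("ACGTACGT", 3), rep("GGCCGGCC", 3),
                 seqsM1 = rep("GGCCGGCC", 3), seqsM2 = rep("ACGAACGT", 3))
  d2 <- consensusCalls(buildDcs(s2))
  expect_equal(d2$seq1, "ACGNACGT")
  # undefined propagates: N in one strand's SSCS -> N in the DCS
  s3 <- mateSscs(c("ACGT", "ACGT", "ACTT"), rep("GGCC", 3))
  d3 <- consensusCalls(buildDcs(s3))
  expect_equal(d3$seq1, "ACNT")
  # symmetry: swapping which family is listed first changes nothing
  sA <- mateSscs(rep("ACGTACGT", 3), rep("GGCCGGCC", 3),
                 seqsM1 = rep("GGCCGGCC", 4), seqsM2 = rep("ACGAACGT", 4))
  cA <- consensusCalls(buildDcs(sA))
  sB <- mateSscs(rep("ACGAACGT", 4), rep("GGCCGGCC", 4),
                 seqsM1 = rep("GGCCGGCC", 3), seqsM2 = rep("ACGTACGT", 3))
  # sB constructs the same duplex with roles reversed; same DCS sequences
  cB <- consensusCalls(buildDcs(sB))
  expect_equal(sort(c(cA$seq1, cA$seq2)), sort(c(cB$seq1, cB$seq2)))
})

test_that("end clipping sets read ends to N and degenerates gracefully", {
  s <- mateSscs(rep(strrep("A", 20), 3), rep(strrep("C", 20), 3))
  d <- buildDcs(s)
  c5 <- consensusCalls(clipEnds(d, 5L))
  expect_equal(c5$seq1, paste0("NNNNN", strrep("A", 10), "NNNNN"))
  expect_equal(consensusCalls(clipEnds(d, 0L))$seq1, strrep("A", 20))
  # 8-base reads, clip 5: everything undefined
  s8 <- mateSscs(rep("ACGTACGT", 3), rep("GGCCGGCC", 3))
  expect_equal(consensusCalls(clipEnds(buildDcs(s8), 5L))$seq1,
               strrep("N", 8))
})

test_that("near-tag deduplication removes linked components", {
  t1 <- strrep("A", 24)
  t2 <- paste0(strrep("A", 22), "CC")    # Hamming 2 from t1
  t3 <- paste0(strrep("A", 21), "CCC")   # Hamming 3 from t1
  mk <- function(keys, sizes) {
    data.frame(tagKey = keys, pos1 = 10L, strand1 = "+", pos2 = 40L,
               strand2 = "-", size = sizes, seq1 = "ACGT", seq2 = "ACGT",
               stringsAsFactors = FALSE)
  }
  asSet <- function(df) new("ConsensusSet", calls = df, level = "DCS",
                            counts = c(dcs = nrow(df)))
  # distance 2 (< 3): both removed
  r <- dedupNearTags(asSet(mk(c(t1, t2), c(3L, 5L))))
  expect_equal(nrow(consensusCalls(r)), 0L)
  # distance exactly 3: both kept (strict inequality)
  r2 <- dedupNearTags(asSet(mk(c(t1, t3), c(3L, 5L))))
  expect_equal(nrow(consensusCalls(r2)), 2L)
  # singleton components always kept
  r3 <- dedupNearTags(asSet(mk(t1, 3L)))
  expect_equal(nrow(consensusCalls(r3)), 1L)
  # keepLargest retains one representative
  r4 <- dedupNearTags(asSet(mk(c(t1, t2), c(3L, 5L))), keepLargest = TRUE)
  expect_equal(consensusCalls(r4)$size, 5L)
  # different coordinates are never linked
  df <- mk(c(t1, t2), c(3L, 5L)); df$pos1[2L] <- 99L
  r5 <- dedupNearTags(asSet(df))
  expect_equal(nrow(consensusCalls(r5)), 2L)
})

test_that("the decoy filter removes reads scoring higher on a decoy", {
  g <- syntheticCircleGenome(300, seed = 14)
  ref <- genomeSequence(g)
  # a DCS read identical to the reference: cannot be beaten
  clean <- substr(ref, 50, 99)
  # a mutant read with 2 mismatches vs the reference
  mut <- clean
  substr(mut, 10, 10) <- setdiff(c("A","C","G","T"), substr(clean, 10, 10))[1]
  substr(mut, 20, 20) <- setdiff(c("A","C","G","T"), substr(clean, 20, 20))[1]
  mk <- function(s) new("ConsensusSet", calls = data.frame(
    tagKey = strrep("A", 24), pos1 = 50L, strand1 = "+", pos2 = 50L,
    strand2 = "-", size = 3L, seq1 = s, seq2 = strrep("N", nchar(s)),
    stringsAsFactors = FALSE), level = "DCS", counts = c(dcs = 1L))
  # decoy identical to the mutant read beats the mitochondrial score
  res <- numtFilter(mk(mut), g, decoys = mut)
  expect_equal(res$removed, 1L)
  expect_equal(nrow(consensusCalls(res$set)), 0L)
  # read identical to mtDNA is kept even with the decoy present
  res2 <- numtFilter(mk(clean), g, decoys = mut)
  expect_equal(res2$removed, 0L)
  # empty decoy set keeps everything
  res3 <- numtFilter(mk(mut), g, decoys = character())
  expect_equal(res3$removed, 0L)
})

test_that("error suppression is ordered raw >= SSCS >= DCS", {
  g <- syntheticCircleGenome(700, seed = 15)
  for (seed in c(3L, 17L)) {
    cfg <- DuplexSimConfig(g, nFragments = 150, trueMutationRate = 0,
                           damageRate = 0, latePcrRate = 5e-4,
                           seqErrorRate = 3e-3, familyMin = 3L,
                           familyMean = 5, seed = seed)
    lib <- simulateLibrary(cfg)
    prep <- prepareReadPairs(lib@reads$read1, lib@reads$read2,
                             qname = lib@reads$qname)
    aligned <- attachAlignments(prep, lib@alignments, g)
    fams <- groupFamilies(aligned)
    sscs <- buildSscs(fams)
    dcs <- buildDcs(sscs)
    rawR <- mismatchRate(aligned$pairs, g)$rate
    sscsR <- mismatchRate(sscs, g)$rate
    dcsR <- mismatchRate(dcs, g)$rate
    expect_gt(rawR, sscsR)     # sequencing errors removed by SSCS
    expect_gte(sscsR, dcsR)
    # SSCS reduces the sequencing-error mismatch rate by >= 10x
    expect_gt(rawR / max(sscsR, 1e-12), 10)
  }
})

test_that("strand-specific damage never survives duplex comparison", {
  g <- syntheticCircleGenome(700, seed = 16)
  for (seed in c(7L, 23L, 41L)) {
    cfg <- DuplexSimConfig(g, nFragments = 150, trueMutationRate = 0,
                           damageRate = 1e-3, latePcrRate = 0,
                           seqErrorRate = 0, familyMin = 3L, seed = seed)
    lib <- simulateLibrary(cfg)
    prep <- prepareReadPairs(lib@reads$read1, lib@reads$read2,
                             qname = lib@reads$qname)
    fams <- groupFamilies(attachAlignments(prep, lib@alignments, g))
    sscs <- buildSscs(fams)
    dcs <- buildDcs(sscs)
    expect_gt(mismatchRate(sscs, g)$mismatches, 0)  # damage reaches SSCS
    expect_equal(mismatchRate(dcs, g)$mismatches, 0) # but never the DCS
  }
})
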