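test_that("Wilson interval boundary cases and closed form", {
  expect_equal(wilsonInterval(0, 50)$lower, 0)
  expect_gt(wilsonInterval(0, 50)$upper, 0)
  expect_equal(wilsonInterval(50, 50)$upper, 1)
  ci <- wilsonInterval(50, 100)
  expect_equal(round(ci$lower, 3), 0.404)
  expect_equal(round(ci$upper, 3), 0.596)
  # independent route: prop.test without continuity correction is the Wilson
  # score interval
  pt <- stats::prop.test(37, 212, correct = FALSE)$conf.int
  ci2 <- wilsonInterval(37, 212)
  expect_equal(ci2$lower, pt[1], tolerance = 1e-10)
  expect_equal(ci2$upper, pt[2], tolerance = 1e-10)
  expect_error(wilsonInterval(1, 0), "n must")
  expect_error(wilsonInterval(5, 4), "k must")
})

test_that("pileup counts every defined base exactly once, wrap-aware", {
  g <- syntheticCircleGenome(100, seed = 21)
  calls <- data.frame(
    tagKey = c(strrep("A", 24), strrep("C", 24)),
    pos1 = c(95L, 10L), strand1 = "+",
    pos2 = c(30L, 30L), strand2 = "-",
    seq1 = c(paste0(substr(genomeSequence(g), 95, 100),
                    substr(genomeSequence(g), 1, 4)),   # wraps the origin
             paste0("N", substr(genomeSequence(g), 11, 19))),
    seq2 = c(substr(genomeSequence(g), 30, 39), substr(genomeSequence(g), 30, 39)),
    stringsAsFactors = FALSE)
  set <- new("ConsensusSet", calls = calls, level = "DCS", counts = c(dcs = 2L))
  p <- buildPileup(set, g)
  expect_equal(totalBases(p), 10L + 9L + 10L + 10L)   # N contributes nothing
  # the wrap positions 95..100 and 1..4 each saw one molecule
  depth <- colSums(pileupCounts(p))
  expect_equal(unname(depth[c(95:100, 1:4)]), rep(1, 10))
  expect_equal(unname(depth[30:39]), rep(2, 10))      # both reads counted
  expect_equal(unname(depth[10]), 0)                   # N position
})

test_that("disagreeing overlapping reads both count toward depth", {
  g <- MitoGenome(strrep("A", 50), name = "t")
  calls <- data.frame(
    tagKey = c(strrep("A", 24), strrep("C", 24)),
    pos1 = 10L, strand1 = "+", pos2 = 30L, strand2 = "-",
    seq1 = c("AAAA", "AGAA"), seq2 = c("AAAA", "AAAA"),
    stringsAsFactors = FALSE)
  set <- new("ConsensusSet", calls = calls, level = "DCS", counts = c(dcs = 2L))
  p <- buildPileup(set, g)
  v <- callVariants(p)
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 11L)
  expect_equal(v$count, 1L)
  expect_equal(v$depth, 2)
  expect_equal(v$clonality, 0.5)
})

test_that("clonality cutoffs flag and exclude as specified", {
  g <- MitoGenome(strrep("A", 10), name = "t")
  cnt <- emptyCountMatrix(g)
  cnt["A", ] <- 1000L
  cnt["G", 2L] <- 20L   # clonality 20/1020 ~ 2%: clonal, excluded
  cnt["C", 3L] <- 5L    # ~0.5%: retained de novo
  cnt["T", 4L] <- 990L; cnt["A", 4L] <- 10L  # 99%: homoplasmic
  p <- makePileup(g, cnt)
  v <- callVariants(p)
  v2 <- v[v$pos == 2L, ]; v3 <- v[v$pos == 3L, ]; v4 <- v[v$pos == 4L, ]
  expect_true(v2$isClonal); expect_false(v2$deNovo)
  expect_false(v3$isClonal); expect_true(v3$deNovo)
  expect_true(v4$isHomoplasmic); expect_true(v4$isClonal)
  # homoplasmic implies clonal for every call
  expect_true(all(!v$isHomoplasmic | v$isClonal))
  # scored once per position regardless of molecule count
  f <- mutationFrequency(v, p)
  expect_equal(f$k, 1L)
  expect_equal(f$frequency, 1 / sum(cnt))
  fm <- mutationFrequency(v, p, numerator = "molecules")
  expect_equal(fm$k, 5L)
})

test_that("lowering the clonality cutoff never raises the de novo frequency", {
  g <- MitoGenome(strrep("A", 40), name = "t")
  set.seed(7)
  cnt <- emptyCountMatrix(g)
  cnt["A", ] <- 500L
  for (p in sample(40, 20)) {
    b <- sample(c("C", "G", "T"), 1)
    cnt[b, p] <- cnt[b, p] + rpois(1, 4)
  }
  pl <- makePileup(g, cnt)
  cuts <- c(0.05, 0.02, 0.01, 0.005, 0.001)
  freqs <- vapply(cuts, function(cc)
    mutationFrequency(callVariants(pl, clonalityCutoff = cc), pl)$frequency,
    numeric(1L))
  expect_true(all(diff(freqs) <= 1e-15))
})

test_that("spectrum frequencies normalise by wild-type base exposure", {
  g <- MitoGenome(paste0(strrep("G", 5), strrep("T", 5)), name = "t")
  cnt <- emptyCountMatrix(g)
  cnt["G", 1:5] <- 200L
  cnt["T", 6:10] <- 300L
  cnt["A", 2L] <- 1L    # one G>A site
  pl <- makePileup(g, cnt)
  v <- callVariants(pl)
  sp <- mutationSpectrum(v, pl)
  dG <- sp$directional[sp$directional$class == "G>A", ]
  expect_equal(dG$sites, 1L)
  expect_equal(unname(dG$exposure), 1000)
  expect_equal(unname(dG$frequency), 1 / 1000)
  expect_equal(dG$proportion, 1)
  cG <- sp$collapsed[sp$collapsed$class == "G>A/C>T", ]
  expect_equal(cG$sites, 1L)
  expect_equal(cG$exposure, 1000)   # C exposure is zero here
  # proportions over collapsed classes + indels sum to 1
  expect_equal(sum(sp$collapsed$proportion) + sp$indels$proportion, 1)
  # collapsed counts equal the sum of their directional members
  for (i in seq_len(nrow(sp$collapsed))) {
    pairCls <- strsplit(sp$collapsed$class[i], "/", fixed = TRUE)[[1L]]
    expect_equal(sp$collapsed$sites[i],
                 sum(sp$directional$sites[sp$directional$class %in% pairCls]))
  }
  # exposure conservation: summed exposures equal total DCS bases
  expect_equal(sum(sp$directional$exposure[match(c("A>C","C>A","G>A","T>A"),
                                                 sp$directional$class)]),
               totalBases(pl))
})

test_that("collapsed spectrum is invariant under strand relabelling", {
  g <- syntheticCircleGenome(60, seed = 30)
  set.seed(8)
  cnt <- emptyCountMatrix(g)
  refIdx <- match(strsplit(genomeSequence(g), "")[[1L]], c("A","C","G","T"))
  for (p in 1:60) cnt[refIdx[p], p] <- 400L
  for (p in sample(60, 12)) {
    k <- sample(setdiff(1:4, refIdx[p]), 1)
    cnt[k, p] <- cnt[k, p] + 2L
  }
  pl <- makePileup(g, cnt)
  spec1 <- mutationSpectrum(callVariants(pl), pl)
  # complement every read and the reference
  gC <- MitoGenome(complementBases(genomeSequence(g)), name = "comp")
  cntC <- cnt[c(4L, 3L, 2L, 1L), ]   # A<->T, C<->G row swap
  rownames(cntC) <- c("A","C","G","T")
  plC <- makePileup(gC, cntC)
  spec2 <- mutationSpectrum(callVariants(plC), plC)
  expect_equal(spec1$collapsed$frequency, spec2$collapsed$frequency)
  expect_equal(spec1$collapsed$sites, spec2$collapsed$sites)
})

test_that("strand asymmetry compares reciprocal pairs with their own exposures", {
  # 20 G>A sites vs 5 C>T sites on equal exposures: ratio 4
  g <- MitoGenome(paste0(strrep("G", 40), strrep("C", 40)), name = "t")
  cnt <- emptyCountMatrix(g)
  cnt["G", 1:40] <- 2500L
  cnt["C", 41:80] <- 2500L
  cnt["A", 1:20] <- 1L
  cnt["T", 41:45] <- 1L
  pl <- makePileup(g, cnt)
  v <- callVariants(pl)
  asym <- strandAsymmetry(v, pl)
  r <- asym[asym$pair == "G>A/C>T", ]
  expect_equal(r$sites1, 20L)
  expect_equal(r$sites2, 5L)
  expect_equal(r$ratio, 4)
  # independent oracle for the 2x2 comparison
  fisherP <- stats::fisher.test(matrix(c(20L, 100000L - 20L, 5L,
                                         100000L - 5L), 2))$p.value
  expect_lt(r$p.value, 0.05)
  expect_lt(fisherP, 0.05)
  expect_lt(abs(log10(r$p.value) - log10(fisherP)), 1)
  # equal counts and exposures: ratio 1, p = 1
  cnt2 <- cnt
  cnt2["A", 1:20] <- 0L; cnt2["A", 1:5] <- 1L
  pl2 <- makePileup(g, cnt2)
  a2 <- strandAsymmetry(callVariants(pl2), pl2)
  r2 <- a2[a2$pair == "G>A/C>T", ]
  expect_equal(r2$ratio, 1)
  expect_gt(r2$p.value, 0.99)
  # bases never sequenced report missing, not zero
  g3 <- MitoGenome(strrep("G", 30), name = "t3")
  cnt3 <- emptyCountMatrix(g3)
  cnt3["G", ] <- 100L
  pl3 <- makePileup(g3, cnt3)
  a3 <- strandAsymmetry(callVariants(pl3), pl3)
  r3 <- a3[a3$pair == "T>C/A>G", ]
  expect_true(is.na(r3$freq1) && is.na(r3$freq2))
})

test_that("asymmetry p-values are calibrated under a symmetric null", {
  # symmetric true mutations on a balanced genome: uniform p-values
  g <- MitoGenome(strrep("ACGT", 150), name = "bal")
  pvals <- c()
  for (seed in 1:12) {
    set.seed(seed + 100)
    cnt <- emptyCountMatrix(g)
    refIdx <- match(strsplit(genomeSequence(g), "")[[1L]], c("A","C","G","T"))
    for (p in seq_len(600)) cnt[refIdx[p], p] <- 3000L
    # symmetric mutation process: uniform positions, uniform alternates
    for (p in sample(600, 120)) {
      k <- sample(setdiff(1:4, refIdx[p]), 1)
      cnt[k, p] <- cnt[k, p] + 1L
    }
    pl <- makePileup(g, cnt)
    a <- strandAsymmetry(callVariants(pl), pl)
    pvals <- c(pvals, a$p.value[!is.na(a$p.value)])
  }
  # discrete counts can tie p-values; the KS statistic itself is unaffected
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("region comparison recovers fold structure and refuses tiny groups", {
  g <- syntheticCircleGenome(1000, seed = 33)
  annot <- MitoAnnotation(data.frame(
    label = c("CTRL", "GENE"), start = c(901L, 101L), end = c(100L, 900L),
    region_class = c("control", "protein_coding"),
    coding_strand = "H", frame = c(0L, 0L), stringsAsFactors = FALSE))
  mkSample <- function(seed, nCtrl, nRest) {
    set.seed(seed)
    cnt <- emptyCountMatrix(g)
    refIdx <- match(strsplit(genomeSequence(g), "")[[1L]], c("A","C","G","T"))
    for (p in 1:1000) cnt[refIdx[p], p] <- 400L
    ctrlPos <- c(901:1000, 1:100)
    for (p in sample(ctrlPos, nCtrl)) {
      k <- sample(setdiff(1:4, refIdx[p]), 1); cnt[k, p] <- cnt[k, p] + 1L
    }
    for (p in sample(101:900, nRest)) {
      k <- sample(setdiff(1:4, refIdx[p]), 1); cnt[k, p] <- cnt[k, p] + 1L
    }
    pl <- makePileup(g, cnt)
    list(calls = callVariants(pl), pileup = pl)
  }
  # control density ~5x the rest (per base: ~10/200 vs ~16/800)
  samples <- lapply(1:4, function(s) {
    set.seed(s * 7)
    mkSample(s, 8L + sample(0:4, 1), 13L + sample(0:6, 1))
  })
  rc <- regionCompare(lapply(samples, `[[`, "calls"),
                      lapply(samples, `[[`, "pileup"), annot)
  per <- rc$perSample
  fc <- mean(per$frequency[per$region == "control"]) /
    mean(per$frequency[per$region == "rest"])
  expect_gt(fc, 2)
  expect_s3_class(rc$regionTest, "htest")
  # near-identical region frequencies: fold ~1, p large
  samples2 <- lapply(5:8, function(s) {
    set.seed(s * 13)
    mkSample(s, 3L + sample(0:2, 1), 13L + sample(0:6, 1))
  })
  rc2 <- regionCompare(lapply(samples2, `[[`, "calls"),
                       lapply(samples2, `[[`, "pileup"), annot)
  per2 <- rc2$perSample
  fc2 <- mean(per2$frequency[per2$region == "control"]) /
    mean(per2$frequency[per2$region == "rest"])
  expect_lt(abs(fc2 - 1), 0.75)
  expect_gt(rc2$regionTest$p.value, 0.05)
  # groups of size < 2 are refused
  expect_error(regionCompare(lapply(samples[1], `[[`, "calls"),
                             lapply(samples[1], `[[`, "pileup"), annot,
                             groups = factor("a", levels = c("a", "b"))),
               "at least 2")
  # two groups with distinct frequencies: fold change and test
  hi <- lapply(9:12, function(s) {
    set.seed(s * 11)
    mkSample(s, 17L + sample(0:6, 1), 55L + sample(0:10, 1))
  })
  rc3 <- regionCompare(c(lapply(samples2, `[[`, "calls"),
                         lapply(hi, `[[`, "calls")),
                       c(lapply(samples2, `[[`, "pileup"),
                         lapply(hi, `[[`, "pileup")), annot,
                       groups = factor(rep(c("young", "aged"), each = 4),
                                       levels = c("young", "aged")))
  gt <- rc3$groupTests$rest
  expect_lt(gt$test$p.value, 0.05)
  expect_gt(gt$foldChange, 2)
  expect_gt(gt$foldChangeSE, 0)
})

test_that("t-test power against the analytic noncentral-t oracle", {
  # two groups of 5 samples from distinct known frequencies: simulated Welch
  # power matches the closed-form noncentral-t computation
  set.seed(99)
  mu1 <- 3.7e-6; mu2 <- 1.9e-5; sd0 <- 4e-6; n <- 5L
  reject <- replicate(400, {
    x <- rnorm(n, mu1, sd0); y <- rnorm(n, mu2, sd0)
    stats::t.test(x, y)$p.value < 0.05
  })
  delta <- (mu2 - mu1) / (sd0 * sqrt(2 / n))
  df <- 2L * n - 2L
  tc <- stats::qt(0.975, df)
  powerOracle <- 1 - stats::pt(tc, df, ncp = delta) +
    stats::pt(-tc, df, ncp = delta)
  expect_lt(abs(mean(reject) - powerOracle), 0.07)
})
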