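# Mutation frequency, spectrum, strand asymmetry and region statistics.

#' Wilson score interval for a binomial proportion
#'
#' The interval used for all frequency confidence bounds: well behaved at the
#' extreme counts typical of rare-mutation data (lower bound exactly 0 when
#' k = 0, upper bound exactly 1 when k = n).
#'
#' @param k Successes (vectorised).
#' @param n Trials; must be >= 1.
#' @param confidence Confidence level (default 0.95).
#' @return data.frame(lower, upper), clamped to [0, 1].
#' @examples wilsonInterval(50, 100)
#' @export
wilsonInterval <- function(k, n, confidence = 0.95) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must satisfy 0 <= k <= n")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' De novo mutation frequency with Wilson interval
#'
#' The frequency of de novo point mutations: the number of unique de novo
#' (position, alternate) pairs divided by the total number of DCS bases
#' sequenced, with the Wilson score interval on that count and denominator.
#' \code{numerator = "molecules"} instead counts mutant molecules
#' (sensitivity-analysis mode).
#'
#' @param calls Variant table from \code{\link{callVariants}}.
#' @param pileup The \code{Pileup} the calls came from.
#' @param confidence Confidence level for the interval.
#' @param numerator \code{"sites"} (default; unique position/alt pairs) or
#'   \code{"molecules"} (sum of mutant molecule counts).
#' @return List: frequency, lower, upper, k, n.
#' @export
mutationFrequency <- function(calls, pileup, confidence = 0.95,
                              numerator = c("sites", "molecules")) {
  numerator <- match.arg(numerator)
  n <- totalBases(pileup)
  if (n == 0) stop("pileup contains no sequenced bases")
  dn <- calls[calls$deNovo, , drop = FALSE]
  k <- if (numerator == "sites") nrow(dn) else sum(dn$count)
  ci <- wilsonInterval(k, n, confidence)
  list(frequency = k / n, lower = ci$lower, upper = ci$upper, k = k, n = n)
}

.COLLAPSED_PAIRS <- list(
  "G>A/C>T" = c("G>A", "C>T"),
  "T>C/A>G" = c("T>C", "A>G"),
  "G>T/C>A" = c("G>T", "C>A"),
  "G>C/C>G" = c("G>C", "C>G"),
  "T>A/A>T" = c("T>A", "A>T"),
  "T>G/A>C" = c("T>G", "A>C"))

# exposure of each source base: the number of times that base was sequenced,
# i.e. its total occurrence count in the pileup
.baseExposures <- function(pileup) {
  e <- rowSums(pileup@counts)
  names(e) <- .BASES
  e
}

#' Mutation spectrum normalised by wild-type base exposure
#'
#' Counts unique de novo sites for each of the 12 directional L-strand
#' substitution classes and divides by the number of times the wild-type
#' base of that class was sequenced (its exposure). The 6
#' complement-collapsed classes sum the counts and exposures of their two
#' directional members. Indels are scored independently as unique events per
#' total bases sequenced. Proportions over the 6 collapsed classes plus
#' indels sum to 1.
#'
#' @param calls Variant table from \code{\link{callVariants}}.
#' @param pileup The source \code{Pileup}.
#' @return An object of class \code{mitoSpectrum}: list with
#'   \code{directional} and \code{collapsed} data.frames, \code{indels},
#'   and \code{totalBases}.
#' @export
mutationSpectrum <- function(calls, pileup) {
  dn <- calls[calls$deNovo, , drop = FALSE]
  e <- .baseExposures(pileup)
  cls <- paste0(dn$ref, ">", dn$alt)
  directional <- data.frame(
    class = .SUB_CLASSES,
    ref = substring(.SUB_CLASSES, 1L, 1L),
    alt = substring(.SUB_CLASSES, 3L, 3L),
    sites = vapply(.SUB_CLASSES, function(x) sum(cls == x), integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  directional$exposure <- e[directional$ref]
  directional$frequency <- ifelse(directional$exposure > 0,
                                  directional$sites / directional$exposure,
                                  NA_real_)
  nIndel <- if (nrow(pileup@indels))
    nrow(unique(pileup@indels[c("pos", "descriptor")])) else 0L
  totalMut <- nrow(dn) + nIndel
  collapsed <- do.call(rbind, lapply(names(.COLLAPSED_PAIRS), function(lab) {
    members <- .COLLAPSED_PAIRS[[lab]]
    i <- match(members, directional$class)
    sites <- sum(directional$sites[i])
    exposure <- sum(directional$exposure[i])
    data.frame(class = lab, sites = sites, exposure = exposure,
               frequency = if (exposure > 0) sites / exposure else NA_real_,
               proportion = if (totalMut > 0) sites / totalMut else NA_real_,
               stringsAsFactors = FALSE)
  }))
  directional$proportion <- if (totalMut > 0)
    directional$sites / totalMut else NA_real_
  tb <- totalBases(pileup)
  out <- list(directional = directional, collapsed = collapsed,
              indels = list(events = nIndel,
                            frequency = if (tb > 0) nIndel / tb else NA_real_,
                            proportion = if (totalMut > 0)
                              nIndel / totalMut else NA_real_),
              totalBases = tb)
  class(out) <- "mitoSpectrum"
  out
}

#' @export
print.mitoSpectrum <- function(x, ...) {
  cat("Mutation spectrum (", sum(x$collapsed$sites), " point mutation sites, ",
      x$indels$events, " indel events over ", x$totalBases,
      " DCS bases)\n", sep = "")
  print(x$collapsed, row.names = FALSE)
  invisible(x)
}

#' Strand asymmetry of reciprocal mutations on the L-strand
#'
#' A mutation causes complementary changes on the two strands, so absent any
#' strand bias the L-strand frequency of a substitution class should equal
#' the L-strand frequency of its reciprocal (complement-source) class, each
#' normalised by its own source-base exposure. For each of the 6 reciprocal
#' pairs this compares e.g. G>A on the L-strand against C>T on the L-strand
#' with a two-proportion test.
#'
#' @param calls Variant table from \code{\link{callVariants}}.
#' @param pileup The source \code{Pileup}.
#' @param positions Optional subset of genomic positions over which to count
#'   sites and exposures (e.g. the D-loop only). Default: whole genome.
#' @return data.frame with one row per reciprocal pair: classes, site counts,
#'   exposures, the two frequencies, their ratio and the test p-value.
#'   Frequencies with zero exposure are NA (missing, not zero).
#' @export
strandAsymmetry <- function(calls, pileup, positions = NULL) {
  dn <- calls[calls$deNovo, , drop = FALSE]
  g <- pileup@genome
  if (!is.null(positions)) {
    dn <- dn[dn$pos %in% positions, , drop = FALSE]
    sel <- rep(FALSE, genomeLength(g)); sel[positions] <- TRUE
  } else sel <- rep(TRUE, genomeLength(g))
  expo <- vapply(1:4, function(k) sum(pileup@counts[k, sel]), numeric(1L))
  names(expo) <- .BASES
  cls <- paste0(dn$ref, ">", dn$alt)
  out <- lapply(names(.COLLAPSED_PAIRS), function(lab) {
    members <- .COLLAPSED_PAIRS[[lab]]
    k1 <- sum(cls == members[1L]); k2 <- sum(cls == members[2L])
    e1 <- expo[substring(members[1L], 1L, 1L)]
    e2 <- expo[substring(members[2L], 1L, 1L)]
    f1 <- if (e1 > 0) k1 / e1 else NA_real_
    f2 <- if (e2 > 0) k2 / e2 else NA_real_
    # score test without continuity correction: exposures are enormous
    # relative to site counts, where the Yates correction over-conserves
    pv <- if (e1 > 0 && e2 > 0 && k1 + k2 > 0)
      suppressWarnings(stats::prop.test(c(k1, k2), c(e1, e2),
                                        correct = FALSE)$p.value)
    else NA_real_
    data.frame(pair = lab, class1 = members[1L], class2 = members[2L],
               sites1 = k1, sites2 = k2, exposure1 = e1, exposure2 = e2,
               freq1 = f1, freq2 = f2,
               ratio = if (!is.na(f1) && !is.na(f2) && f2 > 0) f1 / f2
               else NA_real_,
               p.value = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  row.names(out) <- NULL
  out
}

# per-sample frequency in a region defined by a position mask
.maskedFrequency <- function(calls, pileup, mask) {
  depth <- colSums(pileup@counts)
  dn <- calls[calls$deNovo, , drop = FALSE]
  k <- sum(mask[dn$pos])
  n <- sum(depth[mask])
  c(k = k, n = n)
}

#' Compare mutation frequencies between the control region and the rest
#'
#' Computes, per sample, the de novo mutation frequency inside the annotated
#' control region (the D-loop, wrapping the origin) and in the remainder of
#' the genome, then compares regions and (optionally) sample groups: Welch
#' two-sample two-tailed t-tests on per-sample frequencies, and group fold
#' changes with first-order (delta-method) uncertainty propagation.
#'
#' @param callsList List of per-sample variant tables.
#' @param pileupList List of per-sample \code{Pileup}s (same order).
#' @param annotation A \code{MitoAnnotation} with a control-class region.
#' @param groups Optional factor of length \code{length(callsList)} with two
#'   levels (e.g. young/aged).
#' @param confidence Confidence level for per-sample Wilson intervals.
#' @return List with \code{perSample} (sample, group, region, k, n,
#'   frequency, lower, upper), \code{regionTest} (control vs rest across
#'   samples, per group when groups are given), and \code{groupTests}
#'   (between-group test and fold change per region; NULL without groups).
#' @export
regionCompare <- function(callsList, pileupList, annotation, groups = NULL,
                          confidence = 0.95) {
  stopifnot(length(callsList) == length(pileupList))
  ns <- length(callsList)
  if (ns == 0L) stop("no samples")
  g <- pileupList[[1L]]@genome
  L <- genomeLength(g)
  cls <- .regionClassVector(annotation, L)
  ctrlMask <- cls == "control"
  if (!any(ctrlMask)) stop("annotation has no control-class region")
  sampleNames <- if (!is.null(names(callsList))) names(callsList) else
    sprintf("sample%02d", seq_len(ns))
  per <- do.call(rbind, lapply(seq_len(ns), function(i) {
    rows <- lapply(c(control = TRUE, rest = FALSE), function(isCtrl) {
      mask <- if (isCtrl) ctrlMask else !ctrlMask
      kn <- .maskedFrequency(callsList[[i]], pileupList[[i]], mask)
      ci <- if (kn["n"] > 0) wilsonInterval(kn["k"], kn["n"], confidence) else
        data.frame(lower = NA_real_, upper = NA_real_)
      data.frame(sample = sampleNames[i],
                 group = if (is.null(groups)) NA_character_ else
                   as.character(groups[i]),
                 region = if (isCtrl) "control" else "rest",
                 k = kn[["k"]], n = kn[["n"]],
                 frequency = if (kn[["n"]] > 0) kn[["k"]] / kn[["n"]] else
                   NA_real_,
                 lower = ci$lower, upper = ci$upper, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  row.names(per) <- NULL
  regionTest <- NULL
  groupTests <- NULL
  tt <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L)
      stop("t-test requires at least 2 samples per group")
    stats::t.test(x, y, var.equal = FALSE)
  }
  ctrlF <- per$frequency[per$region == "control"]
  restF <- per$frequency[per$region == "rest"]
  if (is.null(groups)) {
    if (ns >= 2L) regionTest <- tt(ctrlF, restF)
  } else {
    groups <- as.factor(groups)
    lv <- levels(groups)
    stopifnot(length(lv) == 2L)
    regionTest <- lapply(stats::setNames(lv, lv), function(l) {
      sel <- groups == l
      if (sum(sel) >= 2L) tt(ctrlF[sel], restF[sel]) else NULL
    })
    groupTests <- lapply(stats::setNames(c("control", "rest"),
                                         c("control", "rest")), function(rg) {
      f <- per$frequency[per$region == rg]
      grp <- per$group[per$region == rg]
      f1 <- f[grp == lv[1L]]; f2 <- f[grp == lv[2L]]
      test <- tt(f1, f2)
      m1 <- mean(f1); m2 <- mean(f2)
      fold <- m2 / m1
      se <- fold * sqrt(stats::var(f1) / length(f1) / m1^2 +
                          stats::var(f2) / length(f2) / m2^2)
      list(test = test, foldChange = fold, foldChangeSE = se)
    })
  }
  list(perSample = per, regionTest = regionTest, groupTests = groupTests)
}

#' Mismatch rate of consensus or raw reads against the reference
#'
#' Fraction of defined bases differing from the reference; used to verify the
#' error-suppression ordering raw >= SSCS >= DCS.
#'
#' @param consensus A \code{ConsensusSet}, or a data.frame of aligned pairs
#'   (as from \code{\link{attachAlignments}}) for raw reads.
#' @param genome The reference \code{MitoGenome}.
#' @return List: mismatches, bases, rate.
#' @export
mismatchRate <- function(consensus, genome) {
  c <- if (is(consensus, "ConsensusSet")) consensus@calls else consensus
  G <- genomeLength(genome)
  refRaw <- .genomeRaw(genome)
  mm <- 0; nb <- 0
  for (seg in 1:2) {
    seqs <- c[[paste0("seq", seg)]]
    starts <- c[[paste0("pos", seg)]]
    if (is.null(seqs) || !length(seqs)) next
    w <- nchar(seqs)
    allRaw <- charToRaw(paste0(seqs, collapse = ""))
    posv <- .wrapPos(rep(starts, w) + (sequence(w) - 1L), G)
    def <- allRaw != .N_RAW
    mm <- mm + sum(allRaw[def] != refRaw[posv[def]])
    nb <- nb + sum(def)
  }
  list(mismatches = mm, bases = nb, rate = if (nb > 0) mm / nb else NA_real_)
}
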