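# Coding-consequence annotation and pathogenicity-score comparison.

#' Annotate variant calls with coding consequences
#'
#' Classifies each de novo substitution as synonymous, nonsynonymous or
#' noncoding via \code{\link{classifySubstitution}} (vertebrate mitochondrial
#' code, any-overlapping-gene rule), attaches the gene label(s), and joins
#' externally supplied pathogenicity scores when given. Scores are external
#' input (e.g. MutPred output); this package never computes them.
#'
#' @param calls Variant table from \code{\link{callVariants}} (de novo rows
#'   are annotated; clonal rows pass through with NA consequence).
#' @param genome A \code{MitoGenome}.
#' @param annotation A \code{MitoAnnotation}.
#' @param code Genetic code table.
#' @param scores Optional data.frame(variant, score) where variant keys are
#'   \code{"<pos><ref>><alt>"} (e.g. \code{"8993T>G"}) and scores lie in
#'   [0, 1]; scores attach to nonsynonymous calls only.
#' @return The call table with added columns \code{consequence}, \code{gene},
#'   \code{score}.
#' @export
annotateConsequences <- function(calls, genome, annotation,
                                 code = mitoGeneticCode(), scores = NULL) {
  n <- nrow(calls)
  consequence <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  if (n) {
    L <- genomeLength(genome)
    if (any(calls$pos < 1L | calls$pos > L))
      stop("variant position outside the genome")
    ctx <- .codonContextsCached(genome, annotation)
    for (i in which(calls$deNovo)) {
      consequence[i] <- classifySubstitution(genome, annotation, calls$pos[i],
                                             calls$alt[i], code)
      if (consequence[i] != "noncoding") {
        gs <- unique(ctx$gene[ctx$pos == calls$pos[i]])
        gene[i] <- paste(gs, collapse = ",")
      }
    }
  }
  calls$consequence <- consequence
  calls$gene <- gene
  calls$score <- NA_real_
  if (!is.null(scores) && n) {
    key <- paste0(calls$pos, calls$ref, ">", calls$alt)
    j <- match(key, scores$variant)
    hit <- !is.na(j) & consequence == "nonsynonymous"
    calls$score[hit] <- scores$score[j[hit]]
  }
  calls
}

#' Observed nonsynonymous fraction
#'
#' Nonsynonymous / (nonsynonymous + synonymous) among annotated de novo
#' calls; NA (missing) when no coding calls exist.
#'
#' @param annotated Output of \code{\link{annotateConsequences}}.
#' @return Fraction in [0, 1] or NA.
#' @export
observedNonsynFraction <- function(annotated) {
  ns <- sum(annotated$consequence == "nonsynonymous", na.rm = TRUE)
  syn <- sum(annotated$consequence == "synonymous", na.rm = TRUE)
  if (ns + syn == 0L) return(NA_real_)
  ns / (ns + syn)
}

#' Read a two-column pathogenicity score TSV
#'
#' @param path TSV with header columns \code{variant} and \code{score}.
#' @return data.frame(variant, score).
#' @export
readPathogenicityScores <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "score") %in% names(tab)))
  if (any(tab$score < 0 | tab$score > 1))
    stop("pathogenicity scores must lie in [0, 1]")
  tab
}

#' Compare pathogenicity score distributions between groups
#'
#' Wilcoxon rank-sum (Mann-Whitney) comparison of two score sets, two-sided:
#' exact enumeration for small untied samples (combined n < 20), otherwise
#' the normal approximation with continuity and tie correction.
#'
#' @param scores1,scores2 Nonempty numeric vectors of scores.
#' @return List: statistic (W), p.value, method.
#' @export
compareScoreDistributions <- function(scores1, scores2) {
  if (!length(scores1) || !length(scores2))
    stop("both score sets must be nonempty")
  nTot <- length(scores1) + length(scores2)
  hasTies <- anyDuplicated(c(scores1, scores2)) > 0L
  exact <- nTot < 20L && !hasTies
  res <- suppressWarnings(
    stats::wilcox.test(scores1, scores2, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       method = res$method)
}
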