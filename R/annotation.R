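#' Construct a MitoAnnotation
#'
#' @param regions data.frame with columns \code{label}, \code{start},
#'   \code{end}, \code{region_class} (one of protein_coding, rRNA, tRNA,
#'   control), \code{coding_strand} ("H" or "L") and \code{frame}.
#'   \code{end < start} marks a region wrapping the replication origin.
#' @return A \code{\link{MitoAnnotation}}.
#' @export
MitoAnnotation <- function(regions) {
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  regions$frame <- as.integer(regions$frame)
  new("MitoAnnotation", regions = regions)
}

#' Load a region annotation from BED-like TSV
#'
#' Tab-separated, header line, 1-based inclusive coordinates, columns
#' \code{label start end region_class coding_strand frame}.
#'
#' @param path Path to the TSV file.
#' @return A \code{\link{MitoAnnotation}}.
#' @export
loadAnnotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  MitoAnnotation(tab)
}

#' Standard rCRS gene annotation
#'
#' The standard human mitochondrial annotation on rCRS coordinates: 13
#' protein-coding genes, 2 rRNAs, 22 tRNAs and the control region (D-loop,
#' bp 16024--576, wrapping the origin). Shipped with the package as a
#' BED-like TSV under \code{inst/extdata}; users may supply their own table
#' via \code{\link{loadAnnotation}}.
#'
#' @return A \code{\link{MitoAnnotation}}.
#' @export
rcrsAnnotation <- function() {
  if (!is.null(.pkgCache$rcrsAnnot)) return(.pkgCache$rcrsAnnot)
  ann <- loadAnnotation(system.file("extdata", "rcrs_annotation.tsv",
                                    package = "mitoDuplex", mustWork = TRUE))
  .pkgCache$rcrsAnnot <- ann
  ann
}

#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' Region table of an annotation
#' @param x A \code{MitoAnnotation}.
#' @rdname regionTable
#' @export
setMethod("regionTable", "MitoAnnotation", function(x) x@regions)

setMethod("show", "MitoAnnotation", function(object) {
  tab <- table(object@regions$region_class)
  cat("MitoAnnotation:", nrow(object@regions), "regions (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
})

# per-position region class over a circle of length L, with precedence
# protein_coding > tRNA > rRNA > control; unannotated positions -> intergenic
.regionClassVector <- function(annotation, L) {
  cls <- rep("intergenic", L)
  r <- annotation@regions
  for (class in c("control", "rRNA", "tRNA", "protein_coding")) {
    rows <- which(r$region_class == class)
    for (i in rows) {
      pos <- .expandPositions(r$start[i], r$end[i], L)
      cls[pos] <- class
    }
  }
  cls
}

#' Region class at genomic positions
#'
#' Classifies positions by annotated region, wrap-aware: for the human D-loop
#' (16024--576), positions on both sides of the origin classify as
#' \code{"control"}. Where regions overlap (e.g. ATP8/ATP6), precedence is
#' protein_coding > tRNA > rRNA > control. Unannotated gaps return
#' \code{"intergenic"}.
#'
#' @param genome A \code{MitoGenome}.
#' @param annotation A \code{MitoAnnotation}.
#' @param pos Integer vector of 1-based positions in \code{[1, length]}.
#' @return Character vector of region classes.
#' @examples
#' g <- humanMitoGenome(); a <- rcrsAnnotation()
#' regionOf(g, a, c(16300, 300, 577))
#' @export
regionOf <- function(genome, annotation, pos) {
  L <- genomeLength(genome)
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > L))
    stop(sprintf("position out of range [1, %d]: %s", L,
                 paste(utils::head(pos[pos < 1L | pos > L], 5L), collapse = ",")))
  .regionClassVector(annotation, L)[pos]
}
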