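## CNV locus -> gene extraction: the step that turns each subject's affected
## chromosomal loci into the deduplicated gene list seeding the enrichment
## query.

#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors subjectHits
NULL

#' Genes spanned by a CNV locus
#'
#' Returns the gene symbols whose annotated interval overlaps the CNV by at
#' least \code{minOverlapBp} bases on the same chromosome. Duplications and
#' deletions are treated identically.
#'
#' @param cnv \code{GRanges} of one or more CNV loci.
#' @param annotation Gene annotation \code{GRanges} (see [geneAnnotation()]).
#' @param minOverlapBp Minimum overlap in base pairs (default 1: any overlap
#'   counts).
#' @return Character vector of gene symbols (sorted, deduplicated; possibly
#'   empty).
#' @examples
#' ann <- geneAnnotation("G1", "chr1", 101, 200)
#' mapCnvToGenes(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000)), ann)
#' @export
mapCnvToGenes <- function(cnv, annotation, minOverlapBp = 1L) {
  minOverlapBp <- as.integer(minOverlapBp)
  if (minOverlapBp < 1L) stop("minOverlapBp must be >= 1")
  if (!length(annotation) || !length(cnv)) return(character(0))
  ## differing chromosome sets between query and annotation are expected
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cnv, annotation, minoverlap = minOverlapBp))
  sort(unique(names(annotation)[S4Vectors::subjectHits(hits)]))
}

#' Union of CNV-spanned genes over a cohort
#'
#' Each gene is counted once regardless of how many subjects' CNVs hit it;
#' the result is independent of subject order.
#'
#' @param cohort A [SubjectCohort-class] object.
#' @param annotation Gene annotation \code{GRanges}.
#' @param minOverlapBp Minimum overlap in base pairs (default 1).
#' @return Sorted character vector of gene symbols.
#' @export
cohortGeneUnion <- function(cohort, annotation, minOverlapBp = 1L) {
  allCnv <- unlist(cnvIntervals(cohort), use.names = FALSE)
  mapCnvToGenes(allCnv, annotation, minOverlapBp)
}

#' Assemble the initial enrichment dataset
#'
#' Union of the CNV-spanned gene list and a curated neurodevelopmental gene
#' list, deduplicated case-insensitively. The component and union sizes are
#' reported as attributes and in a message.
#'
#' @param cnvGenes Character vector of CNV-derived gene symbols.
#' @param neurodevGenes Character vector of neurodevelopmental gene symbols.
#' @param quiet Suppress the size message.
#' @return Sorted character vector (the union), with attribute
#'   \code{"sizes"} = c(cnv, neurodev, union).
#' @examples
#' g <- assembleInitialDataset(c("A", "B"), c("B", "C"), quiet = TRUE)
#' attr(g, "sizes")
#' @export
assembleInitialDataset <- function(cnvGenes, neurodevGenes, quiet = FALSE) {
  cnvGenes <- dedupSymbols(as.character(cnvGenes))
  neurodevGenes <- dedupSymbols(as.character(neurodevGenes))
  out <- sort(dedupSymbols(c(cnvGenes, neurodevGenes)))
  sizes <- c(cnv = length(cnvGenes), neurodev = length(neurodevGenes),
             union = length(out))
  if (!quiet)
    message("initial dataset: ", sizes[["cnv"]], " CNV genes + ",
            sizes[["neurodev"]], " neurodevelopmental genes -> ",
            sizes[["union"]], " total")
  attr(out, "sizes") <- sizes
  out
}
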