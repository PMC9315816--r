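## The two successive evidence filters: keep genes with a high-confidence
## protein-protein interaction partner inside the current gene set, then keep
## genes with a strongly co-expressed partner inside the set. Both are
## induced-subgraph rules: evidence must connect two genes that are BOTH
## under consideration, which is what makes each stage a contraction.

#' @importFrom stats cor sd
NULL

#' Filter genes by high-confidence protein-protein interactions
#'
#' Retains exactly the genes having at least one edge with confidence
#' \code{>= minConf} to another gene of the input set. Edges to genes
#' outside the set do not count. Matching is case-insensitive; retained
#' genes keep the spelling of the input set.
#'
#' @param genes Character vector of gene symbols under consideration.
#' @param edges data.frame with columns gene_a, gene_b, confidence in
#'   \[0,1\] (see [readPpiEdges()]).
#' @param minConf Confidence threshold, inclusive (default 0.9, the highest-
#'   confidence tier of STRING-style scores).
#' @return A [FilterReport-class] with stage "ppi".
#' @export
filterByPPI <- function(genes, edges, minConf = 0.9) {
  genes <- dedupSymbols(as.character(genes))
  edges <- validatePpiEdges(edges)
  if (minConf < 0 || minConf > 1) stop("minConf must lie in [0, 1]")
  key <- toupper(genes)
  aIn <- toupper(edges$gene_a) %in% key
  bIn <- toupper(edges$gene_b) %in% key
  qual <- edges[aIn & bIn & edges$confidence >= minConf, , drop = FALSE]
  retained <- genes[key %in% toupper(c(qual$gene_a, qual$gene_b))]
  new("FilterReport", stage = "ppi", inputGenes = genes,
      retainedGenes = retained, threshold = minConf,
      supportingEdges = data.frame(gene_a = qual$gene_a,
                                   gene_b = qual$gene_b,
                                   score = qual$confidence,
                                   row.names = NULL))
}

#' Pearson product-moment correlation of two expression profiles
#'
#' A validated wrapper used by the co-expression filter: profiles must have
#' equal length of at least 3 and nonzero variance.
#'
#' @param x,y Numeric expression profiles.
#' @return Correlation in \[-1, 1\].
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (length(x) < 3) stop("profiles must have length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero-variance profile")
  stats::cor(x, y)
}

#' Filter genes by mRNA co-expression
#'
#' Retains exactly the genes having at least one partner in the input set
#' with \code{|r| > threshold} (strict), where r is the Pearson correlation
#' of the two genes' profiles across all samples of the bundle.
#' Self-correlations are excluded. Genes absent from the bundle, and genes
#' with zero expression variance, are dropped with a message before
#' testing.
#'
#' @param genes Character vector of gene symbols under consideration.
#' @param bundle A [BrainExpression-class] object.
#' @param threshold Absolute-correlation threshold, strict (default 0.7).
#' @return A [FilterReport-class] with stage "coexpression"; supporting
#'   edges carry the signed correlation as score.
#' @export
filterByCoexpression <- function(genes, bundle, threshold = 0.7) {
  genes <- dedupSymbols(as.character(genes))
  m <- expressionMatrix(bundle)
  idx <- match(toupper(genes), toupper(rownames(m)))
  absent <- is.na(idx)
  if (any(absent))
    message(sum(absent), " gene(s) absent from the expression bundle dropped")
  present <- genes[!absent]
  sub <- m[idx[!absent], , drop = FALSE]
  rownames(sub) <- present
  if (nrow(sub)) {
    novar <- apply(sub, 1, stats::sd) == 0
    if (any(novar)) {
      warning(sum(novar), " zero-variance gene(s) excluded from correlation")
      sub <- sub[!novar, , drop = FALSE]
      present <- present[!novar]
    }
  }
  edges <- data.frame(gene_a = character(0), gene_b = character(0),
                      score = numeric(0))
  retained <- character(0)
  if (nrow(sub) >= 2) {
    r <- stats::cor(t(sub))
    hit <- abs(r) > threshold
    hit[!upper.tri(hit)] <- FALSE
    ij <- which(hit, arr.ind = TRUE)
    if (nrow(ij)) {
      edges <- data.frame(gene_a = present[ij[, 1]],
                          gene_b = present[ij[, 2]],
                          score = r[ij], row.names = NULL)
      retained <- genes[toupper(genes) %in%
                        toupper(c(edges$gene_a, edges$gene_b))]
    }
  }
  new("FilterReport", stage = "coexpression", inputGenes = genes,
      retainedGenes = retained, threshold = threshold,
      supportingEdges = edges)
}

#' Write a FilterReport (retained genes TSV + provenance JSON)
#'
#' @param report A [FilterReport-class].
#' @param genesPath Path for the one-symbol-per-line retained gene list.
#' @param jsonPath Optional path for a JSON record of stage, threshold,
#'   counts and supporting edges.
#' @return \code{genesPath}, invisibly.
#' @export
writeFilterReport <- function(report, genesPath, jsonPath = NULL) {
  writeLines(retainedGenes(report), genesPath)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(list(
      stage = filterStage(report),
      threshold = filterThreshold(report),
      n_input = length(inputGenes(report)),
      n_retained = length(retainedGenes(report)),
      retained = retainedGenes(report),
      edges = supportingEdges(report)
    ), jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(genesPath)
}
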