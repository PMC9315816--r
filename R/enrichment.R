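## Hypergeometric gene-set over-representation. For a background of N genes
## containing a K-gene pathway and an n-gene query overlapping it in k genes,
## the enrichment p-value is the upper tail P(X >= k), X ~ hypergeometric.

#' @importFrom stats phyper p.adjust
NULL

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the chance
#' that a random n-gene draw from an N-gene universe containing K pathway
#' genes captures at least k of them. Vectorized; evaluated through the
#' distribution's log-space tail so large universes stay numerically stable.
#'
#' @param N Background (universe) size.
#' @param K Pathway size within the background.
#' @param n Query size within the background.
#' @param k Observed overlap.
#' @return Probability in (0, 1]; \code{k = 0} gives exactly 1.
#' @examples
#' hypergeomUpperTail(20, 5, 6, 3)  # 5090/38760
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  args <- cbind(N = N, K = K, n = n, k = k)  # recycles scalars
  N <- args[, "N"]; K <- args[, "K"]; n <- args[, "n"]; k <- args[, "k"]
  if (any(args != floor(args)) || any(N < 0))
    stop("parameters must be non-negative integers")
  if (any(K > N) || any(n > N)) stop("K and n must not exceed N")
  if (any(k > pmin(K, n)) || any(k < 0)) stop("k must lie in [0, min(K, n)]")
  unname(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Gene-set over-representation analysis
#'
#' Tests every pathway of a collection for over-representation in a query
#' gene list with the upper-tail hypergeometric probability. The query is
#' deduplicated and intersected with the background before testing (genes
#' absent from the background are dropped with a message, mirroring how
#' web-based enrichment tools behave). Gene symbols are compared
#' case-insensitively. Significance is \code{p <= alpha} (inclusive), on
#' the BH-adjusted p-value when \code{mtc = "bh"}.
#'
#' @param query Character vector of gene symbols.
#' @param collection A [GeneSetCollection-class]; if its background is unset
#'   the union of the sets is used.
#' @param alpha Significance level (default 0.001).
#' @param mtc "none" (default) or "bh" (Benjamini-Hochberg FDR).
#' @return data.frame sorted by p ascending with columns \code{pathway},
#'   \code{N}, \code{K}, \code{n}, \code{k}, \code{p_value},
#'   \code{adjusted_p} (NA when \code{mtc = "none"}), \code{significant},
#'   and list column \code{overlap_genes}.
#' @export
enrich <- function(query, collection, alpha = 0.001,
                   mtc = c("none", "bh")) {
  mtc <- match.arg(mtc)
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- geneSets(collection)
  bg <- background(collection)
  if (!length(bg)) bg <- dedupSymbols(unlist(sets, use.names = FALSE))
  if (!length(bg)) stop("empty background: supply sets or a background")
  bgKey <- toupper(bg)
  query <- dedupSymbols(as.character(query))
  inBg <- toupper(query) %in% bgKey
  if (any(!inBg))
    message(sum(!inBg), " query gene(s) absent from the background dropped")
  query <- query[inBg]
  N <- length(bg)
  n <- length(query)
  qKey <- toupper(query)
  rows <- lapply(names(sets), function(nm) {
    sKey <- toupper(sets[[nm]])
    K <- sum(sKey %in% bgKey)   # == length(set) under the validity contract
    ov <- query[qKey %in% sKey]
    k <- length(ov)
    p <- if (n == 0L) 1 else hypergeomUpperTail(N, K, n, k)
    list(pathway = nm, N = N, K = K, n = n, k = k, p_value = p,
         overlap_genes = ov)
  })
  res <- data.frame(
    pathway = vapply(rows, `[[`, character(1), "pathway"),
    N = vapply(rows, `[[`, numeric(1), "N"),
    K = vapply(rows, `[[`, numeric(1), "K"),
    n = vapply(rows, `[[`, numeric(1), "n"),
    k = vapply(rows, `[[`, numeric(1), "k"),
    p_value = vapply(rows, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  res$adjusted_p <- if (mtc == "bh") stats::p.adjust(res$p_value, "BH")
                    else NA_real_
  crit <- if (mtc == "bh") res$adjusted_p else res$p_value
  res$significant <- crit <= alpha
  res$overlap_genes <- I(lapply(rows, `[[`, "overlap_genes"))
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Union of genes in significant pathways
#'
#' The deduplicated union of overlap genes over pathways significant at
#' \code{alpha} (re-evaluated on the stored p-values, so the result can be
#' taken at a different level than the one used in [enrich()]).
#'
#' @param results data.frame from [enrich()].
#' @param alpha Significance level; significance is \code{p <= alpha} on the
#'   adjusted p-value when one was computed.
#' @return Sorted character vector of gene symbols.
#' @export
significantGeneUnion <- function(results, alpha = 0.001) {
  crit <- if (all(is.na(results$adjusted_p))) results$p_value
          else results$adjusted_p
  keep <- !is.na(crit) & crit <= alpha
  sort(dedupSymbols(as.character(unlist(results$overlap_genes[keep],
                                        use.names = FALSE))))
}

#' Flatten an enrichment table for TSV output
#'
#' Replaces the \code{overlap_genes} list column with a comma-separated
#' string so the table round-trips through \code{write.table}.
#'
#' @param results data.frame from [enrich()].
#' @return data.frame with character \code{overlap_genes}.
#' @export
flattenEnrichment <- function(results) {
  results$overlap_genes <- vapply(results$overlap_genes, paste,
                                  character(1), collapse = ",")
  results
}
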