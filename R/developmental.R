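## Developmental expression mapping: every gene gets the (brain region,
## developmental epoch) cell in which its mean expression is maximal,
## emulating a lookup against a developmental brain transcriptome atlas.

#' Classify an age into a developmental epoch
#'
#' Ages in post-conceptional weeks (pcw) fall into trimesters at the
#' standard obstetric boundaries (by default 13, 26 and 38 pcw, inclusive on
#' the left epoch); pcw beyond the last boundary, or any age in postnatal
#' days, is postnatal. Vectorized over \code{ageValue}/\code{ageUnit}.
#'
#' @param ageValue Positive numeric age(s).
#' @param ageUnit "pcw" or "postnatal_days" (recycled).
#' @param boundaries Three increasing pcw cut points (trimester ends).
#' @return Character vector of epoch labels (see [epochLevels()]).
#' @examples
#' classifyEpoch(8, "pcw")    # trimester1
#' classifyEpoch(20, "pcw")   # trimester2
#' classifyEpoch(365, "postnatal_days")
#' @export
classifyEpoch <- function(ageValue, ageUnit, boundaries = c(13, 26, 38)) {
  n <- max(length(ageValue), length(ageUnit))
  ageValue <- rep_len(ageValue, n)
  ageUnit <- rep_len(ageUnit, n)
  if (any(!ageUnit %in% ageUnits()))
    stop("age unit must be one of: ", paste(ageUnits(), collapse = ", "))
  if (any(!is.finite(ageValue)) || any(ageValue <= 0))
    stop("age values must be positive")
  out <- rep("postnatal", n)
  pcw <- ageUnit == "pcw"
  lev <- epochLevels()
  out[pcw] <- lev[findInterval(ageValue[pcw], boundaries,
                               left.open = TRUE) + 1L]
  out
}

## genes x cells mean matrix; cells ordered by (epoch rank, region code) so
## that max.col(ties.method = "first") realizes the documented tie-break
cellMeanMatrix <- function(bundle, boundaries = c(13, 26, 38)) {
  m <- expressionMatrix(bundle)
  meta <- sampleMeta(bundle)
  epoch <- classifyEpoch(meta$age_value, meta$age_unit, boundaries)
  cell <- paste(epoch, meta$region_code, sep = "|")
  erank <- match(epoch, epochLevels())
  ord <- order(erank, meta$region_code)
  cells <- unique(cell[ord])
  means <- vapply(cells, function(cl)
    rowMeans(m[, cell == cl, drop = FALSE]), numeric(nrow(m)))
  if (nrow(m) == 1L) means <- matrix(means, nrow = 1,
                                     dimnames = list(rownames(m), cells))
  means
}

#' Site of maximal expression for one gene
#'
#' Computes the mean expression in every populated (region, epoch) cell and
#' returns the argmax cell. Ties are broken deterministically toward the
#' earlier epoch, then the lexicographically smaller region code. Cells with
#' no samples are not candidates.
#'
#' @param gene Gene symbol (case-insensitive lookup).
#' @param bundle A [BrainExpression-class] object.
#' @param boundaries Trimester boundaries in pcw, passed to
#'   [classifyEpoch()].
#' @return One-row data.frame: gene, region, epoch, mean_expression,
#'   is_antenatal.
#' @export
maxExpressionSite <- function(gene, bundle, boundaries = c(13, 26, 38)) {
  res <- mapGeneSet(gene, bundle, boundaries)
  if (!nrow(res)) stop("gene not present in the expression bundle: ", gene)
  res
}

#' Sites of maximal expression for a gene set
#'
#' One row per gene present in the bundle; genes absent from the bundle are
#' listed in the \code{"skipped"} attribute. Rows are sorted by gene symbol,
#' so the output is independent of gene and sample ordering.
#'
#' @param genes Character vector of gene symbols.
#' @param bundle A [BrainExpression-class] object.
#' @param boundaries Trimester boundaries in pcw.
#' @return data.frame with columns gene, region, epoch, mean_expression,
#'   is_antenatal; attribute "skipped" lists absent genes.
#' @export
mapGeneSet <- function(genes, bundle, boundaries = c(13, 26, 38)) {
  genes <- dedupSymbols(as.character(genes))
  means <- cellMeanMatrix(bundle, boundaries)
  idx <- match(toupper(genes), toupper(rownames(means)))
  skipped <- genes[is.na(idx)]
  genes <- genes[!is.na(idx)]
  idx <- idx[!is.na(idx)]
  if (length(idx)) {
    sub <- means[idx, , drop = FALSE]
    best <- max.col(sub, ties.method = "first")
    cellParts <- strsplit(colnames(means)[best], "|", fixed = TRUE)
    epoch <- vapply(cellParts, `[`, character(1), 1)
    region <- vapply(cellParts, `[`, character(1), 2)
    out <- data.frame(gene = genes, region = region, epoch = epoch,
                      mean_expression = sub[cbind(seq_along(idx), best)],
                      is_antenatal = epoch != "postnatal",
                      stringsAsFactors = FALSE)
    out <- out[order(toupper(out$gene)), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(gene = character(0), region = character(0),
                      epoch = character(0), mean_expression = numeric(0),
                      is_antenatal = logical(0))
  }
  attr(out, "skipped") <- skipped
  out
}
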