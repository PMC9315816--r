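## Circuit mapping and behavioral association: genes are assigned to every
## neural circuit containing their expression-peak region; subjects carrying
## a CNV over a circuit gene (Group 2, following the cohort table convention)
## are contrasted against normal-microarray subjects (Group 1) on each
## behavioral item with a two-sample t-test.

#' @importFrom stats pt t.test wilcox.test p.adjust
#' @importFrom S4Vectors queryHits elementNROWS
NULL

#' Assign genes to neural circuits via their expression-peak region
#'
#' Each gene is assigned to every circuit whose region set contains the
#' gene's argmax region; multi-membership is expected (e.g. a striatal peak
#' lands in several systems). Region codes absent from every circuit yield
#' an empty assignment and are reported in the \code{"unknown_regions"}
#' attribute.
#'
#' @param sites data.frame from [mapGeneSet()].
#' @param circuitMap A [CircuitMap-class] object.
#' @return data.frame with columns gene, via_region, epoch and list column
#'   \code{circuits}.
#' @export
assignCircuits <- function(sites, circuitMap) {
  cc <- circuitRegions(circuitMap)
  vocab <- unique(unlist(cc, use.names = FALSE))
  hit <- lapply(sites$region, function(r)
    names(cc)[vapply(cc, function(set) r %in% set, logical(1))])
  unknown <- unique(sites$region[!sites$region %in% vocab])
  if (length(unknown))
    message("region code(s) outside the circuit map vocabulary: ",
            paste(unknown, collapse = ", "))
  out <- data.frame(gene = sites$gene, via_region = sites$region,
                    epoch = sites$epoch, stringsAsFactors = FALSE)
  out$circuits <- I(hit)
  attr(out, "unknown_regions") <- unknown
  out
}

#' Genes assigned to one circuit
#' @param assignments data.frame from [assignCircuits()].
#' @param circuit Circuit name.
#' @return Character vector of gene symbols.
#' @export
circuitGenes <- function(assignments, circuit) {
  keep <- vapply(assignments$circuits, function(cs) circuit %in% cs,
                 logical(1))
  sort(unique(assignments$gene[keep]))
}

#' Split a cohort into the two contrast groups for a circuit gene list
#'
#' Group 1 is every normal-microarray subject; Group 2 is every CNV subject
#' whose CNVs overlap at least one circuit gene by \code{minOverlapBp}
#' bases. CNV subjects carrying no circuit gene are excluded from the
#' contrast.
#'
#' @param cohort A [SubjectCohort-class].
#' @param circuitGenes Character vector of gene symbols defining the circuit.
#' @param annotation Gene annotation \code{GRanges}.
#' @param minOverlapBp Minimum CNV/gene overlap in bp (default 1).
#' @return List with character vectors \code{group1} and \code{group2} of
#'   subject ids.
#' @export
groupSubjects <- function(cohort, circuitGenes, annotation,
                          minOverlapBp = 1L) {
  sub <- subjectTable(cohort)
  group1 <- sub$subject_id[sub$microarray_status == "normal"]
  target <- annotation[toupper(names(annotation)) %in%
                       toupper(circuitGenes)]
  cnvList <- cnvIntervals(cohort)
  flat <- unlist(cnvList, use.names = FALSE)
  owner <- rep(names(cnvList), S4Vectors::elementNROWS(cnvList))
  carriers <- character(0)
  if (length(target) && length(flat)) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      flat, target, minoverlap = as.integer(minOverlapBp)))
    carriers <- unique(owner[S4Vectors::queryHits(hits)])
  }
  cnvIds <- sub$subject_id[sub$microarray_status == "cnv"]
  list(group1 = group1, group2 = cnvIds[cnvIds %in% carriers])
}

## guard for degenerate variance shared by the t machinery
degenerateT <- function(mean1, mean2, n1, n2) {
  if (isTRUE(all.equal(mean1, mean2)))
    list(t = 0, df = n1 + n2 - 2, p = 1)
  else
    list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2,
         p = .Machine$double.xmin)
}

#' Two-sample comparison of behavioral scores
#'
#' Two-sided two-sample t-test; Welch (Satterthwaite df, the default) or
#' pooled-variance. Missing values are dropped per group. When both groups
#' have zero variance the test degenerates: equal means give t = 0, p = 1;
#' unequal means give a p-value guarded at the smallest positive
#' representable number. A Mann-Whitney option is available for ordinal
#' items.
#'
#' @param scores1,scores2 Numeric score vectors (>= 2 finite values each).
#' @param method "welch" (default), "pooled", or "wilcoxon".
#' @return List: n1, mean1, se1, n2, mean2, se2, t, df, p.
#' @examples
#' compareGroups(c(1, 2, 3), c(2, 3, 4))  # t = -1.2247, df = 4
#' @export
compareGroups <- function(scores1, scores2,
                          method = c("welch", "pooled", "wilcoxon")) {
  method <- match.arg(method)
  scores1 <- scores1[is.finite(scores1)]
  scores2 <- scores2[is.finite(scores2)]
  n1 <- length(scores1); n2 <- length(scores2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 finite scores")
  m1 <- mean(scores1); m2 <- mean(scores2)
  se1 <- stats::sd(scores1) / sqrt(n1)
  se2 <- stats::sd(scores2) / sqrt(n2)
  base <- list(n1 = n1, mean1 = m1, se1 = se1, n2 = n2, mean2 = m2,
               se2 = se2)
  if (method == "wilcoxon") {
    wt <- suppressWarnings(stats::wilcox.test(scores1, scores2))
    return(c(base, list(t = unname(wt$statistic), df = NA_real_,
                        p = wt$p.value)))
  }
  if (se1 == 0 && se2 == 0) {
    d <- degenerateT(m1, m2, n1, n2)
    return(c(base, list(t = d$t, df = d$df, p = d$p)))
  }
  tt <- stats::t.test(scores1, scores2, var.equal = (method == "pooled"))
  c(base, list(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value))
}

#' Welch test from summary statistics
#'
#' For published tables reporting only group size, mean and standard error:
#' \eqn{t = (m_1 - m_2)/\sqrt{se_1^2 + se_2^2}} with Satterthwaite degrees
#' of freedom \eqn{(se_1^2+se_2^2)^2 / (se_1^4/(n_1-1) + se_2^4/(n_2-1))}
#' and a two-sided p-value.
#'
#' @param mean1,se1,n1 Group 1 mean, standard error, size (n >= 2, se >= 0).
#' @param mean2,se2,n2 Group 2 statistics.
#' @return List with t, df, p.
#' @examples
#' welchFromSummary(2.79, 0.158, 47, 2.39, 0.107, 90)  # |t| ~ 2.10
#' @export
welchFromSummary <- function(mean1, se1, n1, mean2, se2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (se1 < 0 || se2 < 0) stop("standard errors must be >= 0")
  v <- se1^2 + se2^2
  if (v == 0) return(degenerateT(mean1, mean2, n1, n2))
  t <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Behavioral association scan across circuits and items
#'
#' For every circuit with a non-empty gene list, contrasts the circuit's
#' carrier group (Group 2) against the normal-microarray group (Group 1) on
#' every behavioral item, plus one whole-cohort "inter-group" contrast per
#' item (all CNV subjects vs all normals). Items with fewer than 2 scored
#' subjects in either group are emitted with NA statistics and a skip
#' reason. Rows are ordered deterministically: inter-group first, then
#' circuits in map order, items in score-table order.
#'
#' @param cohort A [SubjectCohort-class].
#' @param assignments data.frame from [assignCircuits()].
#' @param circuitMap A [CircuitMap-class].
#' @param annotation Gene annotation \code{GRanges}.
#' @param items Behavioral item (score column) names; defaults to all.
#' @param config A [PipelineConfig-class]; supplies the test method,
#'   multiple-testing mode and overlap threshold.
#' @return data.frame with one row per (circuit, item): behavior_item,
#'   circuit, n1, mean1, se1, n2, mean2, se2, t, df, p_value, adjusted_p,
#'   genes (comma-separated), skip_reason.
#' @export
runAssociationScan <- function(cohort, assignments, circuitMap, annotation,
                               items = colnames(behaviorScores(cohort)),
                               config = PipelineConfig()) {
  scores <- behaviorScores(cohort)
  stopifnot(all(items %in% colnames(scores)))
  sub <- subjectTable(cohort)
  allCnv <- sub$subject_id[sub$microarray_status == "cnv"]
  normals <- sub$subject_id[sub$microarray_status == "normal"]
  ## one overlap pass: which annotated genes does each CNV subject carry
  cnvList <- cnvIntervals(cohort)
  flat <- unlist(cnvList, use.names = FALSE)
  owner <- rep(names(cnvList), S4Vectors::elementNROWS(cnvList))
  subjGenes <- list()
  if (length(flat) && length(annotation)) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(
      flat, annotation, minoverlap = config@minOverlapBp))
    subjGenes <- split(toupper(names(annotation))[S4Vectors::subjectHits(hits)],
                       owner[S4Vectors::queryHits(hits)])
  }
  contrasts <- list(list(circuit = "inter-group", group2 = allCnv,
                         genes = character(0)))
  for (nm in names(circuitRegions(circuitMap))) {
    cg <- circuitGenes(assignments, nm)
    if (!length(cg)) next
    cgKey <- toupper(cg)
    hasGene <- vapply(subjGenes, function(g) any(g %in% cgKey), logical(1))
    group2 <- allCnv[allCnv %in% names(subjGenes)[hasGene]]
    contrasts <- c(contrasts, list(list(circuit = nm, group2 = group2,
                                        genes = cg)))
  }
  total <- length(contrasts) * length(items)
  col <- list(behavior_item = character(total), circuit = character(total),
              n1 = integer(total), mean1 = rep(NA_real_, total),
              se1 = rep(NA_real_, total), n2 = integer(total),
              mean2 = rep(NA_real_, total), se2 = rep(NA_real_, total),
              t = rep(NA_real_, total), df = rep(NA_real_, total),
              p_value = rep(NA_real_, total), genes = character(total),
              skip_reason = character(total))
  s1mat <- as.matrix(scores[normals, items, drop = FALSE])
  r <- 0L
  for (ct in contrasts) {
    s2mat <- as.matrix(scores[ct$group2, items, drop = FALSE])
    geneStr <- paste(ct$genes, collapse = ",")
    for (j in seq_along(items)) {
      r <- r + 1L
      s1 <- s1mat[, j]; s2 <- s2mat[, j]
      n1 <- sum(is.finite(s1)); n2 <- sum(is.finite(s2))
      col$behavior_item[r] <- items[j]
      col$circuit[r] <- ct$circuit
      col$n1[r] <- n1; col$n2[r] <- n2
      col$genes[r] <- geneStr
      if (n1 < 2 || n2 < 2) {
        col$skip_reason[r] <- "fewer than 2 scored subjects in a group"
        next
      }
      cmp <- compareGroups(s1, s2, method = config@testMethod)
      col$mean1[r] <- cmp$mean1; col$se1[r] <- cmp$se1
      col$mean2[r] <- cmp$mean2; col$se2[r] <- cmp$se2
      col$t[r] <- cmp$t; col$df[r] <- cmp$df; col$p_value[r] <- cmp$p
    }
  }
  out <- as.data.frame(col, stringsAsFactors = FALSE)
  out$adjusted_p <- if (config@mtcMethod == "bh")
    stats::p.adjust(out$p_value, "BH") else NA_real_
  rownames(out) <- NULL
  out
}

#' Signed percent change between two means
#'
#' \code{100 * (comparison - reference) / reference}; the reference mean
#' must be nonzero.
#'
#' @param referenceMean Reference (control) mean.
#' @param comparisonMean Comparison mean.
#' @return Signed percent change.
#' @examples
#' percentChange(112, 73)   # -34.8
#' @export
percentChange <- function(referenceMean, comparisonMean) {
  if (any(referenceMean == 0)) stop("reference mean must be nonzero")
  100 * (comparisonMean - referenceMean) / referenceMean
}

#' Magnitude of a percent change, rounded for report parity
#' @inheritParams percentChange
#' @return Non-negative integer percent magnitude.
#' @examples
#' percentChangeMagnitude(0.41, 0.37)  # 10
#' @export
percentChangeMagnitude <- function(referenceMean, comparisonMean) {
  round(abs(percentChange(referenceMean, comparisonMean)))
}
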