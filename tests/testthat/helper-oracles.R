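# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately avoid the code paths they check.

# upper-tail hypergeometric by direct binomial-coefficient enumeration;
# returns P(X >= k) for all k = 0..min(K, n) at once
oracleHypergeomTail <- function(N, K, n) {
  kmax <- min(K, n)
  i <- 0:kmax
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  rev(cumsum(rev(pmf)))
}

# overlap width of two 1-based closed intervals
oracleOverlapBp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# quadratic CNV -> gene scan over plain vectors
oracleMapCnv <- function(cnvChrom, cnvStart, cnvEnd, ann, minBp = 1) {
  hit <- as.character(GenomicRanges::seqnames(ann)) == cnvChrom &
    oracleOverlapBp(cnvStart, cnvEnd,
                    GenomicRanges::start(ann),
                    GenomicRanges::end(ann)) >= minBp
  sort(names(ann)[hit])
}

# all-pairs PPI retention scan
oraclePpiRetain <- function(genes, edges, minConf) {
  key <- toupper(genes)
  kept <- logical(length(genes))
  for (i in seq_len(nrow(edges))) {
    a <- toupper(edges$gene_a[i]); b <- toupper(edges$gene_b[i])
    if (edges$confidence[i] >= minConf && a %in% key && b %in% key) {
      kept[key == a] <- TRUE
      kept[key == b] <- TRUE
    }
  }
  sort(genes[kept])
}

# all-pairs co-expression retention scan over a genes x samples matrix
oracleCoexprRetain <- function(mat, threshold) {
  g <- rownames(mat)
  kept <- logical(length(g))
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i == j) next
    if (abs(stats::cor(mat[i, ], mat[j, ])) > threshold) kept[i] <- TRUE
  }
  sort(g[kept])
}

# exhaustive (region, epoch) cell-mean argmax for one gene profile,
# replicating the documented tie-break (earlier epoch, then region code)
oracleArgmaxSite <- function(values, region, epoch) {
  cells <- unique(data.frame(region = region, epoch = epoch,
                             stringsAsFactors = FALSE))
  cells$mean <- mapply(function(r, e)
    mean(values[region == r & epoch == e]), cells$region, cells$epoch)
  cells$erank <- match(cells$epoch, epochLevels())
  cells <- cells[order(-cells$mean, cells$erank, cells$region), ]
  cells[1, c("region", "epoch", "mean")]
}

# membership scan: circuits whose region list contains the site region
oracleCircuits <- function(region, circuitList) {
  names(circuitList)[vapply(circuitList, function(set) region %in% set,
                            logical(1))]
}

# subject x gene overlap scan for group membership
oracleGroup2 <- function(cohort, circuitGenes, ann) {
  sub <- subjectTable(cohort)
  ids <- sub$subject_id[sub$microarray_status == "cnv"]
  target <- ann[names(ann) %in% circuitGenes]
  keep <- vapply(ids, function(id) {
    gr <- cnvIntervals(cohort)[[id]]
    any(vapply(seq_along(gr), function(i) {
      length(oracleMapCnv(as.character(GenomicRanges::seqnames(gr))[i],
                          GenomicRanges::start(gr)[i],
                          GenomicRanges::end(gr)[i], target)) > 0
    }, logical(1)))
  }, logical(1))
  ids[keep]
}

# two-sided permutation test on the difference of means
oraclePermutationP <- function(x, y, B = 10000, seed = 1) {
  set.seed(seed)
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  n <- length(x)
  hits <- 0L
  for (b in seq_len(B)) {
    idx <- sample(length(pooled), n)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# small expression bundle from explicit per-cell means
makeBundle <- function(mat, region, ageValue, ageUnit) {
  meta <- data.frame(sample_id = colnames(mat), region_code = region,
                     age_value = ageValue, age_unit = ageUnit,
                     stringsAsFactors = FALSE)
  BrainExpression(mat, meta)
}

# minimal handmade cohort
makeCohort <- function(status, cnvSpecs, scores) {
  ids <- sprintf("S%02d", seq_along(status))
  grl <- GenomicRanges::GRangesList(lapply(cnvSpecs, function(sp) {
    if (is.null(sp)) GenomicRanges::GRanges()
    else GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  }))
  names(grl) <- ids
  rownames(scores) <- ids
  SubjectCohort(data.frame(subject_id = ids, microarray_status = status,
                           stringsAsFactors = FALSE), grl, scores)
}
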