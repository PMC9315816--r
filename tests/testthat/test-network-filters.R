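test_that("PPI retention follows the induced-subgraph rule", {
  edges <- data.frame(gene_a = "A", gene_b = "B", confidence = 0.95)
  rep <- filterByPPI(c("A", "B", "C"), edges)
  expect_equal(sort(retainedGenes(rep)), c("A", "B"))
  expect_equal(nrow(supportingEdges(rep)), 1)

  # a high-confidence edge to a gene outside the set does not count
  out <- data.frame(gene_a = "A", gene_b = "X", confidence = 0.99)
  expect_length(retainedGenes(filterByPPI(c("A", "B", "C"), out)), 0)

  # threshold is inclusive at 0.9
  at <- data.frame(gene_a = "A", gene_b = "B", confidence = 0.9)
  expect_equal(sort(retainedGenes(filterByPPI(c("A", "B"), at))),
               c("A", "B"))
  below <- data.frame(gene_a = "A", gene_b = "B", confidence = 0.899)
  expect_length(retainedGenes(filterByPPI(c("A", "B"), below)), 0)
})

test_that("PPI retention matches a brute-force scan on random graphs", {
  set.seed(15)
  for (i in 1:30) {
    pool <- sprintf("G%03d", 1:200)
    genes <- sample(pool, 60)
    m <- 300
    edges <- data.frame(gene_a = sample(pool, m, replace = TRUE),
                        gene_b = sample(pool, m, replace = TRUE),
                        confidence = runif(m))
    edges <- edges[edges$gene_a != edges$gene_b, ]
    thr <- runif(1, 0.5, 0.95)
    got <- sort(retainedGenes(filterByPPI(genes, edges, thr)))
    expect_identical(got, oraclePpiRetain(genes, edges, thr))
  }
})

test_that("Pearson correlation matches hand-computed values and validates", {
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
  expect_error(pearsonCorrelation(1:2, 2:1), "length >= 3")
  expect_error(pearsonCorrelation(c(1, 1, 1), 1:3), "zero-variance")
})

test_that("Pearson correlation is symmetric and affine-invariant", {
  set.seed(16)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(pearsonCorrelation(x, y), pearsonCorrelation(y, x))
  expect_equal(pearsonCorrelation(3 * x + 7, y), pearsonCorrelation(x, y))
})

test_that("co-expression retention is sign-agnostic and needs a partner", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(4, 3, 2, 1), C = c(2, 2.5, 2, 2.5))
  colnames(m) <- sprintf("s%d", 1:4)
  b <- makeBundle(m, "ACC", c(10, 12, 20, 22), "pcw")
  rep <- filterByCoexpression(c("A", "B"), b)
  expect_equal(sort(retainedGenes(rep)), c("A", "B"))  # r = -1 passes |r| > 0.7
  expect_equal(supportingEdges(rep)$score, -1)

  solo <- filterByCoexpression("A", b)
  expect_length(retainedGenes(solo), 0)  # self-correlation excluded

  expect_message(filterByCoexpression(c("A", "ZZ"), b), "absent")
})

test_that("a planted co-expressed block is recovered and matches brute force", {
  recovered <- vapply(1:25, function(s) {
    set.seed(700 + s)
    nS <- 96
    f <- rnorm(nS)
    block <- t(vapply(1:12, function(i) 10 + 2 * f + rnorm(nS), numeric(nS)))
    decoys <- matrix(rnorm(30 * nS, 10), 30)
    m <- rbind(block, decoys)
    rownames(m) <- sprintf("G%02d", 1:42)
    colnames(m) <- sprintf("s%03d", 1:nS)
    bundle <- makeBundle(m, "STR", 20, "pcw")
    rep <- filterByCoexpression(rownames(m), bundle, 0.7)
    expect_identical(sort(retainedGenes(rep)),
                     oracleCoexprRetain(m, 0.7))   # exact oracle agreement
    setequal(retainedGenes(rep), sprintf("G%02d", 1:12))
  }, logical(1))
  expect_gte(mean(recovered), 0.95)
})

test_that("both filters are contractions and antitone in their thresholds", {
  set.seed(17)
  genes <- sprintf("G%02d", 1:20)
  edges <- data.frame(gene_a = sample(genes, 60, replace = TRUE),
                      gene_b = sample(genes, 60, replace = TRUE),
                      confidence = runif(60))
  edges <- edges[edges$gene_a != edges$gene_b, ]
  prev <- genes
  for (thr in c(0.2, 0.5, 0.8)) {
    cur <- retainedGenes(filterByPPI(genes, edges, thr))
    expect_true(all(cur %in% genes))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  m <- matrix(rnorm(20 * 30, 10), 20,
              dimnames = list(genes, sprintf("s%02d", 1:30)))
  bundle <- makeBundle(m, "ACC", 15, "pcw")
  prev <- genes
  for (thr in c(0.1, 0.3, 0.6)) {
    cur <- retainedGenes(filterByCoexpression(genes, bundle, thr))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("zero-variance genes are excluded with a warning", {
  m <- rbind(A = c(1, 1, 1, 1), B = c(1, 2, 3, 4), C = c(2, 4, 6, 8))
  colnames(m) <- sprintf("s%d", 1:4)
  b <- makeBundle(pmax(m, 0), "ACC", 10, "pcw")
  expect_warning(rep <- filterByCoexpression(c("A", "B", "C"), b),
                 "zero-variance")
  expect_equal(sort(retainedGenes(rep)), c("B", "C"))
})
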