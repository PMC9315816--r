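test_that("hypergeometric tail hits its exact boundary cases", {
  expect_identical(hypergeomUpperTail(100, 10, 20, 0), 1)
  expect_equal(hypergeomUpperTail(20, 5, 20, 5), 1)          # n = N forces k = K
  expect_equal(hypergeomUpperTail(20, 5, 6, 3), 5090 / 38760,
               tolerance = 1e-12)
  expect_error(hypergeomUpperTail(10, 12, 5, 2), "exceed N")
  expect_error(hypergeomUpperTail(10, 5, 5, 6), "min")
})

test_that("hypergeometric tail matches pmf enumeration on a dense grid", {
  for (N in c(1, 2, 5, 10, 17, 25)) {
    for (K in 0:N) for (n in 0:N) {
      want <- oracleHypergeomTail(N, K, n)
      got <- hypergeomUpperTail(N, K, n, 0:min(K, n))
      expect_lt(max(abs(got - want)), 1e-12)
    }
  }
})

test_that("tail probability is monotone in k and symmetric in K and n", {
  p <- hypergeomUpperTail(50, 12, 20, 0:12)
  expect_true(all(diff(p) <= 0))
  expect_equal(hypergeomUpperTail(50, 12, 20, 7),
               hypergeomUpperTail(50, 20, 12, 7), tolerance = 1e-14)
})

test_that("over-representation ranks the planted pathway first", {
  universe <- sprintf("G%03d", 1:100)
  sets <- list(HIT = universe[1:10], D1 = universe[21:30],
               D2 = universe[31:45])
  gsc <- GeneSetCollection(sets, background = universe)
  res <- enrich(universe[1:10], gsc, alpha = 0.001)
  expect_equal(res$pathway[1], "HIT")
  expect_equal(res$k[res$pathway == "HIT"], 10)
  expect_true(res$significant[res$pathway == "HIT"])
  expect_false(any(res$significant[res$pathway != "HIT"]))

  # query disjoint from every pathway: all k = 0, p = 1, nothing significant
  res2 <- enrich(universe[61:70], gsc, alpha = 0.5)
  expect_true(all(res2$k == 0))
  expect_true(all(res2$p_value == 1))
  expect_false(any(res2$significant))
})

test_that("enrichment is invariant to gene order, duplication and case", {
  universe <- sprintf("G%03d", 1:60)
  gsc <- GeneSetCollection(list(P = universe[1:12], Q = universe[30:40]),
                           background = universe)
  q <- universe[5:20]
  a <- enrich(q, gsc)
  b <- enrich(rev(c(q, tolower(q))), gsc)
  expect_equal(a[, c("pathway", "N", "K", "n", "k", "p_value")],
               b[, c("pathway", "N", "K", "n", "k", "p_value")])
})

test_that("query genes outside the background are dropped with a count", {
  gsc <- GeneSetCollection(list(P = c("A", "B")),
                           background = c("A", "B", "C"))
  expect_message(res <- enrich(c("A", "ZZZ"), gsc), "1 query gene")
  expect_equal(res$n, 1)
  expect_error(enrich("A", GeneSetCollection()), "empty background")
})

test_that("an empty query yields k = 0 and p = 1 everywhere", {
  gsc <- GeneSetCollection(list(P = c("A", "B"), Q = c("C")),
                           background = c("A", "B", "C", "D"))
  res <- suppressMessages(enrich(character(0), gsc))
  expect_true(all(res$k == 0))
  expect_true(all(res$p_value == 1))
})

test_that("BH adjustment is applied only when requested", {
  universe <- sprintf("G%03d", 1:100)
  gsc <- GeneSetCollection(list(P = universe[1:10], Q = universe[11:25]),
                           background = universe)
  res <- enrich(universe[1:10], gsc, mtc = "none")
  expect_true(all(is.na(res$adjusted_p)))
  res2 <- enrich(universe[1:10], gsc, alpha = 0.05, mtc = "bh")
  expect_equal(res2$adjusted_p, p.adjust(res2$p_value, "BH"))
})

test_that("the planted causal pathway is significant at 0.001 across seeds", {
  hits <- vapply(1:100, function(s) {
    uni <- simulateUniverse(SimulationDesign(rngSeed = 4000L + s))
    res <- enrich(uni$neurodevGenes, uni$geneSets, alpha = 0.001)
    res$significant[res$pathway == "PWY_CAUSAL"]
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the significant-gene union equals a brute-force row filter", {
  expect_equal(significantGeneUnion(data.frame(
    p_value = c(1e-5, 1e-4), adjusted_p = NA_real_,
    overlap_genes = I(list(c("A", "B"), c("B", "C"))))), c("A", "B", "C"))
  expect_equal(significantGeneUnion(data.frame(
    p_value = 0.5, adjusted_p = NA_real_,
    overlap_genes = I(list(c("A"))))), character(0))
  set.seed(14)
  for (i in 1:20) {
    m <- sample(3:12, 1)
    tab <- data.frame(p_value = runif(m, 0, 0.01), adjusted_p = NA_real_)
    tab$overlap_genes <- I(lapply(seq_len(m), function(j)
      sample(sprintf("G%02d", 1:40), sample(5, 1))))
    alpha <- 0.003
    want <- sort(unique(as.character(
      unlist(tab$overlap_genes[tab$p_value <= alpha]))))
    expect_equal(significantGeneUnion(tab, alpha), want)
  }
})
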