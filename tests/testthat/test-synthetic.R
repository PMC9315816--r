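# The generator is first-class code: these tests pin its contracts — seeded
# determinism, the planted structure at every stage, and the calibration of
# the planted behavioral effect.

test_that("identical design and seed reproduce the study byte for byte", {
  d <- SimulationDesign(rngSeed = 17L)
  a <- simulateStudy(d)
  b <- simulateStudy(d)
  dirA <- withr::local_tempdir(); dirB <- withr::local_tempdir()
  fa <- writeStudy(a, dirA); fb <- writeStudy(b, dirB)
  for (k in names(fa))
    expect_identical(readLines(fa[[k]]), readLines(fb[[k]]), label = k)
})

test_that("default cohort sizes are 47 normal and 90 CNV subjects", {
  co <- simulateStudy(SimulationDesign(rngSeed = 1L))$cohort
  st <- subjectTable(co)$microarray_status
  expect_equal(sum(st == "normal"), 47)
  expect_equal(sum(st == "cnv"), 90)
})

test_that("generators run untouched by the caller's RNG stream", {
  d <- SimulationDesign(rngSeed = 2L)
  set.seed(99); x <- runif(1)
  a <- simulateUniverse(d)
  set.seed(99); invisible(simulateUniverse(d)); y <- runif(1)
  expect_identical(x, y)
})

test_that("causal genes peak at the planted (region, epoch) cell", {
  study <- simulateStudy(SimulationDesign(rngSeed = 5L))
  sites <- mapGeneSet(study$causalGenes, study$expression)
  expect_setequal(sites$gene, study$causalGenes)
  expect_true(all(sites$region == study$design@targetRegion))
  expect_true(all(sites$epoch == study$design@targetEpoch))
  expect_true(all(sites$is_antenatal))
})

test_that("causal clique interactions carry high confidence", {
  study <- simulateStudy(SimulationDesign(rngSeed = 6L))
  e <- study$ppiEdges
  within <- e$gene_a %in% study$causalGenes & e$gene_b %in% study$causalGenes
  expect_equal(sum(within), choose(length(study$causalGenes), 2))
  expect_gt(mean(e$confidence[within]), 0.9)
  expect_lt(mean(e$confidence[!within]), 0.6)
})

test_that("planted co-expression matches the factor-model closed form", {
  # r = loading^2 / (loading^2 + noise^2) holds off the peak cell, whose
  # shared mean elevation adds a small extra covariance term by design
  d0 <- SimulationDesign(samplesPerCell = 4L)  # 192 samples
  lam <- d0@coexprLatentLoading; sig <- d0@noiseSd
  expected <- lam^2 / (lam^2 + sig^2)
  expect_equal(expected, 0.8)
  rs <- vapply(1:20, function(s) {
    uni <- simulateUniverse(SimulationDesign(samplesPerCell = 4L,
                                             rngSeed = 100L + s))
    m <- expressionMatrix(uni$expression)[uni$causalGenes, ]
    meta <- sampleMeta(uni$expression)
    peak <- meta$region_code == uni$design@targetRegion &
      classifyEpoch(meta$age_value, meta$age_unit) == uni$design@targetEpoch
    cm <- cor(t(m[, !peak]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  expect_lt(abs(mean(rs) - expected), 0.05)
})

test_that("carrier fraction controls causal-gene overlap exactly at its ends", {
  uni <- simulateUniverse(SimulationDesign(rngSeed = 8L))
  co0 <- simulateCohort(SimulationDesign(rngSeed = 8L, carrierFraction = 0),
                        uni$annotation, uni$causalGenes)
  hit0 <- cohortGeneUnion(co0, uni$annotation)
  expect_length(intersect(hit0, uni$causalGenes), 0)

  co1 <- simulateCohort(SimulationDesign(rngSeed = 8L, carrierFraction = 1),
                        uni$annotation, uni$causalGenes)
  hit1 <- cohortGeneUnion(co1, uni$annotation)
  expect_gt(length(intersect(hit1, uni$causalGenes)), 0)
  carriers <- attr(co1, "carriers")
  expect_length(carriers, 90)
})

test_that("detection of the planted effect is non-decreasing in effect size", {
  # common random numbers: the same seed set across effect sizes, so the
  # per-seed rejection indicator is monotone up to discretization
  uni <- simulateUniverse(SimulationDesign(rngSeed = 21L))
  asg <- analyzeStudy(c(uni, list(
    cohort = simulateCohort(uni$design, uni$annotation,
                            uni$causalGenes))))$assignments
  deltas <- c(0, 0.3, 0.6, 1.0)
  seeds <- 600L + seq_len(60)
  rate <- vapply(deltas, function(delta) {
    hits <- vapply(seeds, function(s) {
      d <- SimulationDesign(rngSeed = s, effectSizeSd = delta)
      co <- simulateCohort(d, uni$annotation, uni$causalGenes)
      scan <- runAssociationScan(co, asg, uni$circuitMap, uni$annotation)
      row <- scan[scan$circuit == d@targetCircuit &
                  scan$behavior_item == d@targetItem, ]
      is.finite(row$p_value) && row$p_value <= 0.05
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) >= 0))
  expect_lt(rate[1], 0.2)   # near-null at delta = 0
  expect_gt(rate[4], 0.7)   # clearly powered at delta = 1
})

test_that("infeasible designs are rejected up front", {
  expect_error(SimulationDesign(causalPathwaySize = 5000L), "nGenes")
  expect_error(SimulationDesign(carrierFraction = 1.5), "carrierFraction")
  expect_error(SimulationDesign(coexprLatentLoading = 0.5), "exceed 0.7")
  expect_error(SimulationDesign(targetRegion = "CEREBELLUM"), "vocabulary")
  expect_error(SimulationDesign(nNeurodev = 5L), "causal pathway")
})
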