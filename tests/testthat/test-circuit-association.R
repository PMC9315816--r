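test_that("a striatal expression peak joins several systems at once", {
  sites <- data.frame(gene = "G1", region = "STR", epoch = "trimester2",
                      mean_expression = 5, is_antenatal = TRUE)
  asg <- assignCircuits(sites, defaultCircuitMap())
  got <- asg$circuits[[1]]
  expect_true(all(c("Positive Valence", "Cognitive", "Social Processes")
                  %in% got))

  off <- sites; off$region <- "NOWHERE"
  asg2 <- suppressMessages(assignCircuits(off, defaultCircuitMap()))
  expect_length(asg2$circuits[[1]], 0)
  expect_equal(attr(asg2, "unknown_regions"), "NOWHERE")
})

test_that("circuit assignment equals a brute-force membership scan", {
  set.seed(20)
  for (i in 1:50) {
    regions <- rdocRegions()
    cmapList <- lapply(1:5, function(j) sample(regions, sample(2:6, 1)))
    names(cmapList) <- sprintf("CIRC%d", 1:5)
    cmap <- CircuitMap(cmapList)
    sites <- data.frame(gene = sprintf("G%02d", 1:20),
                        region = sample(regions, 20, replace = TRUE),
                        epoch = "trimester1",
                        mean_expression = 1, is_antenatal = TRUE)
    asg <- suppressMessages(assignCircuits(sites, cmap))
    for (r in seq_len(nrow(sites)))
      expect_setequal(asg$circuits[[r]],
                      oracleCircuits(sites$region[r], cmapList))
  }
})

test_that("group membership matches the subject-by-gene overlap oracle", {
  study <- simulateStudy(SimulationDesign(rngSeed = 23L))
  grp <- groupSubjects(study$cohort, study$causalGenes, study$annotation)
  expect_setequal(grp$group1,
                  subjectTable(study$cohort)$subject_id[
                    subjectTable(study$cohort)$microarray_status == "normal"])
  expect_setequal(grp$group2, attr(study$cohort, "carriers"))
  expect_setequal(grp$group2,
                  oracleGroup2(study$cohort, study$causalGenes,
                               study$annotation))
  none <- groupSubjects(study$cohort, "ABSENT", study$annotation)
  expect_length(none$group2, 0)
})

test_that("two-sample comparisons reproduce hand-derived statistics", {
  cmp <- compareGroups(c(1, 2, 3), c(2, 3, 4), method = "welch")
  expect_equal(cmp$t, -1.224745, tolerance = 1e-6)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$p, 0.2878641, tolerance = 1e-6)

  same <- compareGroups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  apart <- compareGroups(c(2, 2), c(5, 5))
  expect_equal(apart$p, .Machine$double.xmin)

  expect_error(compareGroups(1, c(1, 2)), "at least 2")
})

test_that("Welch and pooled coincide for balanced groups with equal variance", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  w <- compareGroups(x, y, "welch")
  p <- compareGroups(x, y, "pooled")
  expect_equal(w$t, p$t)
  expect_equal(w$df, p$df)
  expect_equal(w$p, p$p)
})

test_that("summary-statistic Welch matches raw-sample Welch and the published row", {
  # whole-cohort self-stimulatory item: group sizes 47 vs 90, means
  # 2.79 vs 2.39, SEs 0.158 vs 0.107 -> |t| ~ 2.10, p < 0.05
  w <- welchFromSummary(2.79, 0.158, 47, 2.39, 0.107, 90)
  expect_equal(abs(w$t), 2.10, tolerance = 0.01)
  expect_lt(w$p, 0.05)
  expect_gt(w$p, 0.01)

  expect_equal(welchFromSummary(3, 0.1, 10, 3, 0.1, 10)$p, 1)

  set.seed(21)
  x <- rnorm(25, 5); y <- rnorm(40, 5.6)
  cmp <- compareGroups(x, y, "welch")
  ws <- welchFromSummary(mean(x), sd(x) / sqrt(25), 25,
                         mean(y), sd(y) / sqrt(40), 40)
  expect_equal(ws$t, cmp$t, tolerance = 1e-12)
  expect_equal(ws$df, cmp$df, tolerance = 1e-12)
  expect_equal(ws$p, cmp$p, tolerance = 1e-12)
})

test_that("t-test p-values sit within Monte-Carlo error of a permutation test", {
  set.seed(22)
  for (i in 1:3) {
    x <- rnorm(15, 0); y <- rnorm(15, 0.6)
    pt <- compareGroups(x, y, "pooled")$p
    pp <- oraclePermutationP(x, y, B = 10000, seed = 30 + i)
    expect_lt(abs(pt - pp), 0.04)
  }
})

test_that("the association scan covers the full grid deterministically", {
  study <- simulateStudy(SimulationDesign(rngSeed = 24L))
  res <- analyzeStudy(study)
  scan <- res$associations
  items <- colnames(behaviorScores(study$cohort))
  nonempty <- sum(vapply(names(circuitRegions(study$circuitMap)),
                         function(nm) length(circuitGenes(res$assignments,
                                                          nm)) > 0,
                         logical(1)))
  expect_equal(nrow(scan), (nonempty + 1) * length(items))
  expect_equal(unique(scan$circuit)[1], "inter-group")
  # planted target cell is present and carries the designed carrier count
  row <- scan[scan$circuit == study$design@targetCircuit &
              scan$behavior_item == study$design@targetItem, ]
  expect_equal(row$n2, length(attr(study$cohort, "carriers")))
})

test_that("the scan is invariant to subject ordering", {
  study <- simulateStudy(SimulationDesign(rngSeed = 25L))
  res <- analyzeStudy(study)
  co <- study$cohort
  set.seed(1)
  perm <- sample(nrow(subjectTable(co)))
  shuffled <- SubjectCohort(subjectTable(co)[perm, ],
                            cnvIntervals(co)[perm],
                            behaviorScores(co)[perm, ])
  scan2 <- runAssociationScan(shuffled, res$assignments, study$circuitMap,
                              study$annotation)
  expect_equal(res$associations, scan2)
})

test_that("BH adjustment across the scan is opt-in", {
  study <- simulateStudy(SimulationDesign(rngSeed = 26L))
  res <- analyzeStudy(study, PipelineConfig(mtcMethod = "bh"))
  scan <- res$associations
  ok <- !is.na(scan$p_value)
  expect_equal(scan$adjusted_p[ok], p.adjust(scan$p_value, "BH")[ok])
})

test_that("percent change reproduces the published worked arithmetic", {
  expect_equal(percentChange(112, 73), -34.82143, tolerance = 1e-5)
  expect_equal(percentChangeMagnitude(112, 73), 35)
  expect_equal(percentChange(0.41, 0.37), -9.756098, tolerance = 1e-5)
  expect_equal(percentChangeMagnitude(0.41, 0.37), 10)
  expect_equal(percentChange(5, 5), 0)
  expect_error(percentChange(0, 1), "nonzero")
})

test_that("the ordinal Mann-Whitney option runs on Likert items", {
  cmp <- compareGroups(c(1, 2, 2, 3, 3), c(3, 4, 4, 5, 5),
                       method = "wilcoxon")
  expect_lt(cmp$p, 0.05)
  expect_true(is.na(cmp$df))
})
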