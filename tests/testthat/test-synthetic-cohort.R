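test_that("panel has the 35 expected labels, fixed order, no duplicates", {
  p <- panelAnalytes()
  expect_length(p, 35L)
  expect_true(all(c("HGF", "CCL5", "EGF", "VEGF") %in% p))
  expect_identical(anyDuplicated(p), 0L)
  expect_identical(p[1L], "EGF")
  expect_identical(p[35L], "VEGF")
})

test_that("identical config and seed reproduce the cohort; seeds differ", {
  a <- simulateCohort(nPatients = 8, seed = 7)
  b <- simulateCohort(nPatients = 8, seed = 7)
  expect_identical(SummarizedExperiment::assay(a, "pre"),
                   SummarizedExperiment::assay(b, "pre"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  expect_identical(psfsScores(a), psfsScores(b))
  c2 <- simulateCohort(nPatients = 8, seed = 8)
  expect_false(identical(SummarizedExperiment::assay(a, "pre"),
                         SummarizedExperiment::assay(c2, "pre")))
})

test_that("empty cohort keeps the full column schema", {
  coh <- simulateCohort(nPatients = 0, seed = 1)
  expect_identical(ncol(coh), 0L)
  expect_identical(rownames(coh), panelAnalytes())
  expect_length(groundTruth(coh)$trueLabels, 0L)
  tbl <- cohortTable(coh, "pre")
  expect_identical(nrow(tbl), 0L)
  expect_true(all(clinicalVariables() %in% names(tbl)))
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(nPatients = -1), "nonnegative")
  expect_error(cohortConfig(analyteNames = letters), "35 distinct")
  expect_error(cohortConfig(missingRates = c(NOPE = 0.2)), "unknown")
  expect_error(cohortConfig(missingRates = c(HGF = 1.2)), "\\[0, 1\\]")
  expect_error(cohortConfig(psfsDays = c(7, 14)), "start at 0")
  expect_error(cohortConfig(psfsDays = c(0, 7, 7)), "strictly increasing")
})

test_that("latent severity anti-correlates with generated AUPC", {
  gt <- groundTruth(simulateCohort(nPatients = 2000, seed = 1,
                                   severityEffect = 2))
  r <- cor(gt$latentSeverity, gt$aupc)
  expect_lt(r, -0.5)
  # monotone severity link: top severity quartile recovers worse
  qs <- quantile(gt$latentSeverity, c(0.25, 0.75))
  expect_lt(mean(gt$aupc[gt$latentSeverity >= qs[2L]]),
            mean(gt$aupc[gt$latentSeverity <= qs[1L]]))
})

test_that("generated AUPC distribution spans the expected clinical range", {
  gt <- groundTruth(simulateCohort(nPatients = 2000, seed = 3))
  s <- aupcSummary(gt$aupc)
  expect_gt(s$median, 0.6)
  expect_lt(s$median, 0.85)
  expect_lt(quantile(gt$aupc, 0.025), 0.55)
  expect_gt(quantile(gt$aupc, 0.975), 0.85)
})

test_that("missingness injection hits its rate and its edge cases", {
  coh <- simulateCohort(nPatients = 1000, seed = 5,
                        missingRates = c(HGF = 0))
  tbl <- cohortTable(coh, "pre")
  # rate 0: unchanged
  t0 <- injectMissingness(tbl, c(HGF = 0), seed = 1)
  expect_identical(t0$HGF, tbl$HGF)
  # rate 1: all missing
  t1 <- injectMissingness(tbl, c(HGF = 1), seed = 1)
  expect_true(all(is.na(t1$HGF)))
  # rate 0.3 at n = 1000: realized fraction concentrates
  t3 <- injectMissingness(tbl, c(HGF = 0.3), seed = 2)
  frac <- mean(is.na(t3$HGF))
  expect_gt(frac, 0.25); expect_lt(frac, 0.35)
  expect_equal(attr(t3, "realizedMissing")[["HGF"]], frac)
  expect_error(injectMissingness(tbl, c(NOPE = 0.1), seed = 1),
               "not in table")
})

test_that("with severityEffect 0 analytes are independent of the label", {
  coh <- simulateCohort(nPatients = 1500, seed = 9, severityEffect = 0,
                        missingRates = numeric())
  gt <- groundTruth(coh)
  tbl <- cohortTable(coh, "pre")
  lab <- gt$trueLabels[rownames(tbl)]
  pvals <- vapply(panelAnalytes(), function(a) {
    bins <- cut(tbl[[a]], quantile(tbl[[a]], c(0, 1 / 3, 2 / 3, 1)),
                include.lowest = TRUE)
    suppressWarnings(chisq.test(table(bins, lab))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.90)
  expect_identical(nrow(gt$plantedDag), 0L)
})

test_that("cohorts round-trip through the text writer/reader", {
  coh <- simulateCohort(nPatients = 9, seed = 13)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  back <- readCohort(dir)
  for (tp in c("pre", "post"))
    expect_identical(SummarizedExperiment::assay(coh, tp),
                     SummarizedExperiment::assay(back, tp))
  expect_identical(as.data.frame(SummarizedExperiment::colData(coh)),
                   as.data.frame(SummarizedExperiment::colData(back)))
  expect_equal(psfsScores(coh), psfsScores(back))
  expect_identical(groundTruth(coh)$trueLabels, groundTruth(back)$trueLabels)
  expect_identical(groundTruth(coh)$latentSeverity,
                   groundTruth(back)$latentSeverity)
  expect_identical(groundTruth(coh)$plantedDag[, "to"],
                   groundTruth(back)$plantedDag[, "to"])
})

test_that("unpaired cohorts assign each patient one timepoint", {
  coh <- simulateCohort(nPatients = 30, seed = 4, paired = FALSE)
  pre <- cohortTable(coh, "pre"); post <- cohortTable(coh, "post")
  expect_identical(nrow(pre) + nrow(post), 30L)
  expect_length(intersect(rownames(pre), rownames(post)), 0L)
})
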