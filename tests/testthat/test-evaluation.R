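test_that("AUC hand cases", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.3),
                      c("good", "good", "poor", "poor"))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 6), rep(c("good", "poor"), 3))$auc, 0.5)
  # 3 of 4 pairs concordant
  r <- rocAuc(c(0.9, 0.7, 0.8, 0.1), c("good", "good", "poor", "poor"))
  expect_equal(r$auc, 0.75)
  expect_equal(r$points[1L, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_error(rocAuc(c(0.3, 0.4), c("good", "good")), "both classes")
})

test_that("trapezoidal ROC area equals the rank-pair statistic", {
  set.seed(55)
  for (rep in 1:200) {
    n <- sample(4:40, 1)
    lab <- c("good", "poor", sample(c("good", "poor"), n - 2, TRUE))
    sc <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    r <- rocAuc(sc, lab)
    expect_equal(r$auc, trapezoid_area(r$points), tolerance = 1e-9)
    expect_equal(r$auc, pair_count_auc(sc, lab), tolerance = 1e-9)
  }
})

test_that("negating scores maps AUC to its complement", {
  set.seed(56)
  lab <- c("good", "poor", sample(c("good", "poor"), 18, TRUE))
  sc <- runif(20)
  expect_equal(rocAuc(-sc, lab)$auc, 1 - rocAuc(sc, lab)$auc,
               tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(57)
  lab <- c("good", "poor", sample(c("good", "poor"), 28, TRUE))
  sc <- round(runif(30), 2)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = lab, predictor = sc, levels = c("poor", "good"),
    direction = "<")))
  expect_equal(rocAuc(sc, lab)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("the 0.6 discriminator boundary is inclusive", {
  expect_identical(classifyDiscriminator(0.60), "good differentiator")
  expect_identical(classifyDiscriminator(0.59), "not a good differentiator")
  expect_identical(classifyDiscriminator(0.87), "good differentiator")
  expect_identical(classifyDiscriminator(0.90), "good differentiator")
  expect_error(classifyDiscriminator(1.2), "\\[0, 1\\]")
})

test_that("group contrasts flag separated analytes and count records", {
  tbl <- data.frame(a = c(6.44, 6.4, 6.5, 5.59, 5.6, 5.5),
                    b = rep(3, 6))
  lab <- c(rep("poor", 3), rep("good", 3))
  ct <- groupContrastAnalytes(tbl, lab, threshold = 0.25)
  expect_equal(ct$medianDiff[ct$analyte == "a"], 6.44 - 5.59)
  expect_true(ct$flagged[ct$analyte == "a"])
  expect_false(ct$flagged[ct$analyte == "b"])
  expect_identical(ct$nGood, c(3L, 3L))
  expect_identical(ct$nPoor, c(3L, 3L))
  # one group entirely missing: summaries emitted, flag suppressed
  tbl$a[lab == "good"] <- NA
  expect_warning(ct2 <- groupContrastAnalytes(tbl, lab), "unobserved")
  expect_false(ct2$flagged[ct2$analyte == "a"])
  expect_true(is.na(ct2$goodMedian[ct2$analyte == "a"]))
})

test_that("reports are byte-stable and internally consistent", {
  coh <- simulateCohort(nPatients = 14, seed = 21, severityEffect = 2)
  run <- runPipeline(coh, "pre", nested = FALSE)
  r1 <- renderReport(run)
  r2 <- renderReport(runPipeline(coh, "pre", nested = FALSE))
  expect_identical(r1, r2)
  # the printed AUC equals an independent recomputation from the scores
  auc <- pair_count_auc(run$looScores$score, run$looScores$true_label)
  expect_true(any(grepl(sprintf("AUC = %.4f", auc), r1, fixed = TRUE)))
  dir <- withr::local_tempdir()
  renderReport(run, file.path(dir, "report.md"))
  expect_identical(readLines(file.path(dir, "report.md")), r1)
})

test_that("discretizers and runs persist to disk faithfully", {
  coh <- simulateCohort(nPatients = 10, seed = 33, severityEffect = 2)
  tbl <- pipeline_table(coh, "pre")
  map <- fitDiscretizer(tbl, bins = 3)
  dir <- withr::local_tempdir()
  writeDiscretizer(map, file.path(dir, "map.json"))
  back <- readDiscretizer(file.path(dir, "map.json"))
  expect_equal(binCuts(back), binCuts(map))
  expect_identical(back@levelsMap, map@levelsMap)
  expect_identical(applyDiscretizer(back, tbl), applyDiscretizer(map, tbl))

  run <- runPipeline(coh, "pre", nested = FALSE)
  writeRun(run, file.path(dir, "run"))
  man <- jsonlite::read_json(file.path(dir, "run", "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$auc, run$roc$auc)
  expect_true(all(file.exists(file.path(dir, "run", man$files))))
  expect_identical(readLines(file.path(dir, "run", "report.md")),
                   renderReport(run))
  sc <- read.csv(file.path(dir, "run", "loo_scores.csv"))
  expect_equal(sc$score, run$looScores$score)
})

test_that("a run with an empty selection reports an explicit no-model section", {
  coh <- simulateCohort(nPatients = 14, seed = 21, severityEffect = 2)
  run <- runPipeline(coh, "pre", nested = FALSE)
  run$finalModel <- NULL
  run$selected <- character()
  run$connectivity <- NULL
  run$associateFrequency[] <- 0
  lines <- renderReport(run)
  expect_true(any(grepl("no model", lines)))
  expect_true(any(grepl("no variable was adjacent", lines)))
})
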