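make_table <- function(df, analytes = names(df)) {
  attr(df, "analytes") <- analytes
  df
}

test_that("log transform uses the floor and refuses reapplication", {
  tbl <- make_table(data.frame(A = c(1, 515, 0, NA), B = c(2, 2, 2, 2)))
  out <- logTransformAnalytes(tbl, floor = 0.5)
  expect_equal(out$A[1L], 0)
  expect_equal(out$A[2L], 6.244, tolerance = 1e-3)
  expect_equal(out$A[3L], log(0.5))
  expect_true(is.na(out$A[4L]))
  expect_error(logTransformAnalytes(out), "already log-transformed")
  neg <- make_table(data.frame(A = c(3, -1)))
  rownames(neg) <- c("r1", "r2")
  expect_error(logTransformAnalytes(neg), "negative analyte value: A, row r2")
})

test_that("missingness filter drops strictly above the threshold only", {
  tbl <- data.frame(a = c(rep(NA, 3), rep(1, 7)),   # 30% -> dropped
                    b = c(rep(NA, 2), rep(1, 8)),   # exactly 20% -> kept
                    c = rep(1, 10))                 # 0% -> kept
  res <- filterMissingVariables(tbl, 0.20)
  expect_identical(res$dropped, "a")
  expect_identical(names(res$table), c("b", "c"))
  expect_equal(unname(res$fraction), c(0.3, 0.2, 0))
  # exactness on randomized tables
  set.seed(7)
  for (rep in 1:10) {
    r <- as.data.frame(matrix(runif(200), nrow = 20))
    for (v in names(r)) r[[v]][runif(20) < runif(1, 0, 0.5)] <- NA
    out <- filterMissingVariables(r, 0.2)
    frac <- vapply(r, function(x) mean(is.na(x)), numeric(1))
    expect_setequal(out$dropped, names(r)[frac > 0.2])
    expect_true(all(frac[names(out$table)] <= 0.2))
  }
})

test_that("quantile discretizer reproduces the hand-computed tertiles", {
  tbl <- data.frame(x = as.numeric(1:9))
  rownames(tbl) <- paste0("r", 1:9)
  map <- fitDiscretizer(tbl, bins = 3)
  expect_equal(binCuts(map)$x, c(3 + 2 / 3, 6 + 1 / 3), tolerance = 1e-12)
  d <- applyDiscretizer(map, tbl)
  expect_identical(as.integer(table(d$x)), c(3L, 3L, 3L))
  expect_identical(as.character(d$x[5L]), "2")
  # clamping below/above the training range
  outside <- applyDiscretizer(map, data.frame(x = c(-100, 100)))
  expect_identical(as.character(outside$x), c("1", "3"))
})

test_that("degenerate variables are flagged; categoricals pass through", {
  tbl <- data.frame(const = rep(2.5, 6), flag = factor(rep(c("no", "yes"), 3)),
                    gone = rep(NA_real_, 6))
  map <- fitDiscretizer(tbl, bins = 3)
  expect_true("const" %in% map@flagged)
  expect_true("gone" %in% map@unusable)
  d <- applyDiscretizer(map, tbl)
  expect_false("gone" %in% names(d))
  expect_identical(nlevels(d$const), 1L)
  expect_identical(levels(d$flag), c("no", "yes"))
  # missing cells stay missing
  tbl2 <- data.frame(x = c(1, NA, 3, 4, 5, 6))
  d2 <- applyDiscretizer(fitDiscretizer(tbl2, bins = 3), tbl2)
  expect_true(is.na(d2$x[2L]))
  # empty table in, empty table out
  e <- applyDiscretizer(map, tbl[0, , drop = FALSE])
  expect_identical(nrow(e), 0L)
})

test_that("cut points never consult held-out rows", {
  set.seed(11)
  tbl <- data.frame(x = rnorm(20), y = rnorm(20))
  rownames(tbl) <- paste0("p", 1:20)
  train <- paste0("p", 1:15)
  m1 <- fitDiscretizer(tbl, trainingRows = train, bins = 3)
  mutated <- tbl
  mutated[16:20, ] <- mutated[16:20, ] + 1000
  m2 <- fitDiscretizer(mutated, trainingRows = train, bins = 3)
  expect_identical(binCuts(m1), binCuts(m2))
  expect_identical(m1@fittedOn, train)
})

test_that("unknown variables at apply time are refused", {
  map <- fitDiscretizer(data.frame(x = 1:9 / 2), bins = 3)
  expect_error(applyDiscretizer(map, data.frame(zz = 1:3)),
               "unknown variable")
})
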