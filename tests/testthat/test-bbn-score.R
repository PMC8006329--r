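test_that("hand-computed MDL for a single binary node over 4 records", {
  d <- data.frame(x = factor(c(0, 0, 1, 1)))
  s <- mdlScore(NULL, d)
  expect_equal(s$dataBits, 4)            # four records at -log2(1/2) each
  expect_equal(s$modelBits, 1)           # (log2 4)/2 * (2 - 1) parameters
  expect_equal(s$total, 5)
})

test_that("scoring rejects empty data, cycles and unknown variables", {
  d <- data.frame(x = factor(c(0, 1)), y = factor(c(0, 1)))
  expect_error(mdlScore(NULL, d[0, ]), "empty data")
  cyc <- rbind(c("x", "y"), c("y", "x"))
  expect_error(mdlScore(cyc, d), "cycle")
  expect_error(mdlScore(cbind("x", "zz"), d), "absent")
})

test_that("a deterministic dependence is cheaper to encode than independence", {
  set.seed(5)
  x <- factor(sample(0:1, 400, replace = TRUE))
  d <- data.frame(x = x, y = x)
  expect_lt(mdlScore(cbind("x", "y"), d)$total, mdlScore(NULL, d)$total)
})

test_that("the total decomposes over node families", {
  set.seed(8)
  d <- data.frame(a = factor(sample(1:3, 60, TRUE)),
                  b = factor(sample(1:2, 60, TRUE)),
                  c = factor(sample(1:3, 60, TRUE)))
  arcs <- rbind(c("a", "b"), c("b", "c"))
  s <- mdlScore(arcs, d)
  expect_equal(sum(s$perFamily$dataBits) + sum(s$perFamily$modelBits),
               s$total, tolerance = 1e-12)
  # family scores are independent of the rest of the graph
  s2 <- mdlScore(rbind(c("a", "b")), d)
  expect_equal(s$perFamily$dataBits[s$perFamily$node == "b"],
               s2$perFamily$dataBits[s2$perFamily$node == "b"])
})

test_that("families score on their own complete cases under missingness", {
  d <- data.frame(x = factor(c(0, 0, 1, 1, NA)), y = factor(c(0, 1, 0, 1, 1)))
  s <- mdlScore(NULL, d)
  fam <- s$perFamily
  expect_identical(fam$n[fam$node == "x"], 4L)
  expect_identical(fam$n[fam$node == "y"], 5L)
  # with x -> y, y's family drops the record where x is missing
  s2 <- mdlScore(cbind("x", "y"), d)
  expect_identical(s2$perFamily$n[s2$perFamily$node == "y"], 4L)
})

test_that("Laplace CPT fitting matches hand computation", {
  d <- data.frame(z = factor(c(1, 1, 1, 0)))
  m <- fitCPTs(NULL, d, alpha = 1)
  expect_equal(as.numeric(cpts(m)$z$prob),
               c((1 + 1) / (4 + 2), (3 + 1) / (4 + 2)))
  # alpha = 0 gives maximum-likelihood frequencies
  m0 <- fitCPTs(NULL, d, alpha = 0)
  expect_equal(as.numeric(cpts(m0)$z$prob), c(0.25, 0.75))
  # unobserved parent configuration -> uniform
  d2 <- data.frame(p = factor(c(0, 0, 0, 0), levels = c(0, 1)),
                   c = factor(c(1, 1, 0, 1)))
  m2 <- fitCPTs(cbind("p", "c"), d2, alpha = 1)
  expect_equal(as.numeric(cpts(m2)$c$prob[, 2L]), c(0.5, 0.5))
})

test_that("per-arc influence ranks arcs by description-length cost", {
  set.seed(2)
  x <- factor(sample(0:1, 300, TRUE))
  y <- factor(ifelse(runif(300) < 0.95, as.character(x),
                     as.character(1 - as.integer(as.character(x)))))
  z <- factor(sample(0:1, 300, TRUE))
  d <- data.frame(x = x, y = y, z = z)
  m <- fitCPTs(rbind(c("x", "y"), c("x", "z")), d)
  inf <- arcInfluence(m, d)
  expect_identical(inf$to[1L], "y")       # the real dependence costs most
  expect_gt(inf$deltaBits[1L], 0)
  expect_lt(inf$deltaBits[inf$to == "z"], inf$deltaBits[1L])
})
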