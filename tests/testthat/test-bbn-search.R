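test_that("independent noise yields the empty graph", {
  set.seed(31)
  d <- data.frame(a = factor(sample(0:1, 500, TRUE)),
                  b = factor(sample(0:1, 500, TRUE)),
                  c = factor(sample(0:2, 500, TRUE)))
  m <- learnStructure(d, lambda = 0.01)
  expect_identical(nrow(arcs(m)), 0L)
})

test_that("a planted strong edge is found and noise stays isolated", {
  set.seed(17)
  x <- sample(0:1, 500, TRUE)
  y <- ifelse(runif(500) < 0.95, x, 1 - x)
  z <- sample(0:1, 500, TRUE)
  d <- data.frame(X = factor(x), Y = factor(y), Z = factor(z))
  m <- learnStructure(d, lambda = 0.01)
  a <- arcs(m)
  und <- paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
  expect_true("X Y" %in% und)
  expect_false(any(grepl("Z", und)))
})

test_that("greedy search attains the exhaustive minimum on planted chains", {
  for (seed in c(3, 14, 15)) {
    set.seed(seed)
    a <- sample(0:1, 200, TRUE)
    b <- ifelse(runif(200) < 0.9, a, 1 - a)
    c_ <- ifelse(runif(200) < 0.9, b, 1 - b)
    d <- data.frame(A = factor(a), B = factor(b), C = factor(c_))
    m <- learnStructure(d, lambda = 0)
    best <- min(vapply(enumerate_dags3(), function(g) mdlScore(g, d)$total,
                       numeric(1)))
    expect_equal(mdlBits(m)[["total"]], best, tolerance = 1e-9)
  }
})

test_that("learned models are acyclic and reproducible under row shuffling", {
  set.seed(23)
  coh <- simulateCohort(nPatients = 30, seed = 23, severityEffect = 2)
  tbl <- pipeline_table(coh)
  map <- fitDiscretizer(tbl, bins = 3)
  d <- applyDiscretizer(map, tbl)
  m1 <- learnStructure(d, lambda = 0.01)
  expect_true(igraph::is_dag(asIgraph(m1)))   # independent acyclicity check
  perm <- sample(nrow(d))
  m2 <- learnStructure(d[perm, ], lambda = 0.01)
  expect_identical(arcs(m1), arcs(m2))
  expect_equal(mdlBits(m1), mdlBits(m2))
})

test_that("incremental search totals match a full rescoring", {
  set.seed(29)
  d <- as.data.frame(lapply(1:5, function(k)
    factor(sample(1:3, 150, TRUE))))
  names(d) <- paste0("V", 1:5)
  d$V2 <- d$V1
  m <- learnStructure(d, lambda = 0.01)
  expect_equal(mdlBits(m)[["total"]], mdlScore(arcs(m), d)$total,
               tolerance = 1e-9)
})

test_that("constraints are honored", {
  set.seed(37)
  x <- sample(0:1, 300, TRUE)
  y <- ifelse(runif(300) < 0.95, x, 1 - x)
  d <- data.frame(X = factor(x), Y = factor(y))
  mf <- learnStructure(d, lambda = 0, forbidden = rbind(c("X", "Y")))
  expect_false(any(mf@arcs[, 1] == "X" & mf@arcs[, 2] == "Y"))
  mr <- learnStructure(d, lambda = 0, required = rbind(c("X", "Y")))
  expect_true(any(mr@arcs[, 1] == "X" & mr@arcs[, 2] == "Y"))
  expect_error(learnStructure(d, required = rbind(c("X", "Y"), c("Y", "X"))),
               "cycle")
  expect_error(learnStructure(d[1, , drop = FALSE]), "at least 2 records")
  expect_error(learnStructure(d[, 1, drop = FALSE]), "at least 2 variables")
})

test_that("max parent count is enforced", {
  set.seed(41)
  d <- as.data.frame(lapply(1:5, function(k) factor(sample(0:1, 300, TRUE))))
  names(d) <- paste0("P", 1:4) |> c("child")
  # child = XOR-ish mixture of all four parents
  d$child <- factor((as.integer(d$P1) + as.integer(d$P2) +
                     as.integer(d$P3) + as.integer(d$P4)) %% 2)
  m <- learnStructure(d, lambda = 0, maxParents = 2)
  indeg <- table(factor(arcs(m)[, 2], levels = nodes(m)))
  expect_true(all(indeg <= 2))
})

test_that("first-degree associates and connectivity are exact", {
  d <- data.frame(X = factor(c(0, 1)), R = factor(c(0, 1)),
                  Y = factor(c(0, 1)), Z = factor(c(0, 1)))
  m <- fitCPTs(rbind(c("X", "R"), c("R", "Y"), c("Z", "X")), d)
  expect_identical(firstDegreeAssociates(m, "R"), c("X", "Y"))
  expect_error(firstDegreeAssociates(m, "nope"), "unknown target")
  cs <- connectivityStats(m, outcome = "R")
  expect_identical(cs$nArcs, 3L)
  expect_identical(cs$outcomeDegree, 2L)
  expect_identical(sum(cs$degree), 2L * cs$nArcs)  # handshake identity
  # the published post-antivenom fixture topology
  vars <- c("age", "antihistamines", "WBC", "HGF", "CCL5", "VEGF", "R")
  d2 <- as.data.frame(lapply(vars, function(v) factor(c(0, 1))))
  names(d2) <- vars
  fix <- rbind(c("age", "R"), c("antihistamines", "R"), c("R", "HGF"),
               c("R", "CCL5"), c("R", "VEGF"), c("WBC", "R"))
  m2 <- fitCPTs(fix, d2)
  expect_identical(firstDegreeAssociates(m2, "R"),
                   sort(c("age", "antihistamines", "WBC", "HGF", "CCL5",
                          "VEGF")))
  expect_identical(connectivityStats(m2, outcome = "R")$outcomeDegree, 6L)
  # isolated target
  expect_identical(firstDegreeAssociates(fitCPTs(NULL, d), "R"), character())
})

test_that("network serialization writes readable GraphML and DOT", {
  d <- data.frame(X = factor(c(0, 1, 0, 1)), R = factor(c(0, 1, 1, 1)))
  m <- fitCPTs(rbind(c("X", "R")), d)
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "m.graphml")
  writeGraphML(m, gml, outcome = "R")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_identical(sort(igraph::V(g)$name), c("R", "X"))
  expect_identical(igraph::V(g)$outcome[igraph::V(g)$name == "R"], TRUE)
  dot <- file.path(dir, "m.dot")
  writeDOT(m, dot)
  expect_true(any(grepl("->", readLines(dot))))
  js <- file.path(dir, "m.json")
  writeCPTs(m, js)
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$R$parents, "X")
})
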