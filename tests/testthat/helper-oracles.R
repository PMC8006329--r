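# Independent oracles used across the suite.  Each recomputes a quantity by
# brute force (enumeration, pair counting, full-joint summation), never by
# calling the code path it checks.

# all DAGs on three labeled nodes (there are 25), as from/to arc matrices
enumerate_dags3 <- function(vars = c("A", "B", "C")) {
  pairs <- t(combn(vars, 2L))
  all_arcs <- rbind(pairs, pairs[, 2:1])  # 6 possible directed arcs
  out <- list()
  for (bits in 0:(2^6 - 1)) {
    take <- as.logical(bitwAnd(bits, 2^(0:5)))
    a <- all_arcs[take, , drop = FALSE]
    colnames(a) <- c("from", "to")
    und <- paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2]))
    if (anyDuplicated(und)) next               # 2-cycle
    if (nrow(a) == 3L) {                       # only 3-arc cyclicity possible
      # cyclic iff every node has in-degree exactly 1
      if (all(table(factor(a[, 2], levels = vars)) == 1L)) next
    }
    out[[length(out) + 1L]] <- a
  }
  out
}

# P(query | evidence) by summing the full joint table of a BBNModel
joint_enum_posterior <- function(model, evidence, query) {
  lv <- model@levels
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  names(grid) <- names(lv)
  p <- vapply(seq_len(nrow(grid)), function(r) {
    pr <- 1
    for (v in names(lv)) {
      cp <- model@cpts[[v]]
      idx <- c(match(grid[r, v], lv[[v]]),
               vapply(cp$parents, function(u) match(grid[r, u], lv[[u]]),
                      integer(1)))
      pr <- pr * cp$prob[matrix(idx, nrow = 1L)]
    }
    pr
  }, numeric(1))
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  num <- tapply(p[keep], factor(grid[[query]][keep], levels = lv[[query]]),
                sum, default = 0)
  as.numeric(num) / sum(p[keep])
}

# random valid BBNModel: random DAG over 2..maxNodes nodes with 2..maxBins
# levels each, CPTs fitted on random data (so they are proper)
random_model <- function(seed, maxNodes = 6L, maxBins = 3L) {
  set.seed(seed)
  p <- sample(2:maxNodes, 1L)
  vars <- paste0("V", seq_len(p))
  bins <- sample(2:maxBins, p, replace = TRUE)
  ord <- sample(vars)
  arcs <- matrix(character(), ncol = 2L,
                 dimnames = list(NULL, c("from", "to")))
  if (p > 1L)
    for (j in 2:p)
      for (i in 1:(j - 1L))
        if (stats::runif(1) < 0.45)
          arcs <- rbind(arcs, c(ord[i], ord[j]))
  d <- as.data.frame(lapply(seq_len(p), function(k)
    factor(sample(seq_len(bins[k]), 40L, replace = TRUE),
           levels = seq_len(bins[k]))))
  names(d) <- vars
  fitCPTs(arcs, d, alpha = 1)
}

# AUC by explicit (good, poor) pair counting, ties as half
pair_count_auc <- function(scores, labels) {
  g <- scores[labels == "good"]; p <- scores[labels == "poor"]
  tot <- 0
  for (a in g) for (b in p)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(g) * length(p))
}

trapezoid_area <- function(points) {
  sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
}

# data from a fixed planted 6-node chain/fork DAG; each child copies its
# parent with 5% flip noise, roots uniform over 3 levels
planted_six_node <- function(n, seed) {
  set.seed(seed)
  lv <- as.character(1:3)
  noisy_copy <- function(parent) {
    flip <- stats::runif(n) < 0.05
    out <- parent
    out[flip] <- vapply(parent[flip], function(v)
      sample(setdiff(lv, v), 1L), character(1))
    out
  }
  A <- sample(lv, n, replace = TRUE)
  B <- noisy_copy(A)
  C <- noisy_copy(B)
  D <- noisy_copy(A)
  E <- noisy_copy(D)
  F_ <- noisy_copy(C)
  d <- data.frame(A = factor(A, lv), B = factor(B, lv), C = factor(C, lv),
                  D = factor(D, lv), E = factor(E, lv), F = factor(F_, lv))
  truth <- cbind(from = c("A", "B", "A", "D", "C"),
                 to = c("B", "C", "D", "E", "F"))
  list(data = d, arcs = truth)
}

skeleton_f1 <- function(learned, truth) {
  und <- function(a) if (nrow(a) == 0L) character() else
    unique(paste(pmin(a[, 1], a[, 2]), pmax(a[, 1], a[, 2])))
  L <- und(learned); T_ <- und(truth)
  tp <- length(intersect(L, T_))
  if (tp == 0L) return(0)
  prec <- tp / length(L); rec <- tp / length(T_)
  2 * prec * rec / (prec + rec)
}

# labeled feature table from a simulated cohort, ready for the pipeline
pipeline_table <- function(cohort, timepoint = "pre") {
  out <- dichotomizeAtMedian(psfsOutcomes(psfsScores(cohort)))
  tbl <- logTransformAnalytes(cohortTable(cohort, timepoint))
  tbl$recovery <- out$label[match(rownames(tbl), out$patient_id)]
  tbl
}

# order-stable plain-text fingerprint of a data frame (content + rownames)
digest_rows <- function(df) {
  cols <- vapply(df, function(x) paste(as.character(x), collapse = ","),
                 character(1))
  paste(paste(rownames(df), collapse = ","), paste(cols, collapse = ";"),
        sep = "|")
}

# random 3-variable discrete dataset with a randomly drawn dependence
# pattern (used to compare greedy search against DAG enumeration)
random_three_var <- function(seed, n = 200) {
  set.seed(seed)
  a <- sample(0:1, n, TRUE)
  b <- if (runif(1) < 0.5) ifelse(runif(n) < runif(1, 0.6, 0.95), a, 1 - a)
       else sample(0:1, n, TRUE)
  c_ <- if (runif(1) < 0.5) ifelse(runif(n) < runif(1, 0.6, 0.95), b, 1 - b)
        else sample(0:1, n, TRUE)
  data.frame(A = factor(a, levels = 0:1), B = factor(b, levels = 0:1),
             C = factor(c_, levels = 0:1))
}
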