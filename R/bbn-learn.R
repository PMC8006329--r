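# Structure learning: greedy hill climbing over {add, delete, reverse}
# from the empty (or required-arc) graph, scored by total description
# length.  The sparsity gate lambda is the minimum *relative* improvement
# a move must buy: a move is accepted only when it shortens the
# description length of the families it modifies by more than lambda
# times their current length.  Gating on the affected families rather
# than the whole-table total keeps the evidence bar per arc independent
# of how many unrelated variables sit in the table.  lambda = 0 recovers
# plain MDL hill climbing; the default 0.01 matches the complexity
# setting used for small-cohort prognostic modeling.

#' Learn a Bayesian belief network structure
#'
#' Deterministic greedy search: starting from the required arcs, repeatedly
#' apply the single arc addition, deletion or reversal that most reduces
#' the total description length, provided the reduction exceeds `lambda`
#' times the current description length of the families the move touches,
#' the graph stays acyclic, and no node exceeds `maxParents` parents.  Ties break by a fixed enumeration order
#' (add, then delete, then reverse; within an operator by column order), so
#' equal inputs always yield the same structure.  Conditional probability
#' tables are then fitted with Laplace smoothing.
#'
#' @param data data frame of factors (discretized features); `NA` = missing.
#' @param lambda nonnegative relative-improvement gate (default 0.01).
#' @param maxParents parent-count cap per node (default 3; bounds CPT size
#'   at small cohort sizes).
#' @param forbidden,required optional two-column `from`/`to` arc matrices.
#' @param alpha Laplace pseudo-count for the fitted CPTs.
#' @return a [BBNModel][BBNModel-class] with structure, CPTs and MDL bits.
#' @export
learnStructure <- function(data, lambda = 0.01, maxParents = 3L,
                           forbidden = NULL, required = NULL, alpha = 1) {
  if (nrow(data) < 2L) stop("need at least 2 records")
  if (ncol(data) < 2L) stop("need at least 2 variables")
  if (lambda < 0) stop("lambda must be nonnegative")
  m <- .as_discrete_matrix(data)
  vars <- colnames(m)
  arity <- attr(m, "arity")
  toMat <- function(a) {
    out <- matrix(FALSE, length(vars), length(vars))
    a <- .as_arcs(a)
    if (nrow(a) > 0L) {
      if (!all(a %in% vars)) stop("arc constraint names unknown variable")
      out[cbind(match(a[, 1L], vars), match(a[, 2L], vars))] <- TRUE
    }
    out
  }
  res <- cpp_hc(m, as.integer(arity), lambda, as.integer(maxParents),
                toMat(forbidden), toMat(required))
  adj <- res$adjacency
  idx <- which(adj, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  arcs <- if (nrow(idx)) cbind(from = vars[idx[, 1L]], to = vars[idx[, 2L]])
          else .empty_arcs()
  fitCPTs(arcs, data, alpha = alpha)
}

#' Fit conditional probability tables for a fixed structure
#'
#' Counts come from records complete on each node's family; each CPT cell
#' is `(count + alpha) / (slice total + alpha * bins)`.  Parent
#' configurations with no observations fall back to the uniform
#' distribution (the pure prior).
#'
#' @param dag a [BBNModel][BBNModel-class] or two-column arc matrix.
#' @param data data frame of factors.
#' @param alpha Laplace pseudo-count (0 gives maximum-likelihood CPTs).
#' @return a [BBNModel][BBNModel-class].
#' @export
fitCPTs <- function(dag, data, alpha = 1) {
  if (alpha < 0) stop("alpha must be nonnegative")
  m <- .as_discrete_matrix(data)
  vars <- colnames(m)
  lv <- attr(m, "levels")
  arcs <- .as_arcs(dag)
  if (nrow(arcs) > 0L && !all(arcs %in% vars))
    stop("arc endpoint absent from data")
  if (!.is_acyclic(vars, arcs)) stop("graph contains a cycle")
  cpts <- list()
  for (v in vars) {
    parents <- unname(arcs[arcs[, 2L] == v, 1L])
    parents <- vars[sort(match(parents, vars))]  # canonical order
    fac <- lapply(c(v, parents), function(u)
      factor(lv[[u]][m[, u]], levels = lv[[u]]))
    names(fac) <- c(v, parents)
    counts <- do.call(table, c(fac, list(useNA = "no")))
    k <- length(lv[[v]])
    cmat <- matrix(as.numeric(counts), nrow = k)
    tot <- rep(colSums(cmat), each = k)
    prob <- (cmat + alpha) / (tot + alpha * k)
    prob[, colSums(cmat) == 0] <- 1 / k  # unobserved slice -> uniform
    arr <- array(prob, dim = dim(counts), dimnames = dimnames(counts))
    cpts[[v]] <- list(parents = parents, prob = arr)
  }
  sc <- mdlScore(arcs, data)
  methods::new("BBNModel", nodes = vars, arcs = arcs, levels = lv,
               cpts = cpts, nRecords = nrow(data),
               mdl = c(data = sc$dataBits, model = sc$modelBits,
                       total = sc$total))
}
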