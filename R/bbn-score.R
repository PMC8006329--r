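# Minimum description length scoring of discrete networks.
# For each node family (child + parents):
#   data bits  = - sum over records of log2 P(child | parents) under
#                maximum-likelihood CPTs, counted on records complete for
#                that family only (no imputation);
#   model bits = (log2 N)/2 per free parameter, i.e. (bins - 1) times the
#                product of parent bin counts, with N the records the
#                family was counted on.
# The total decomposes node-wise, which is what makes incremental greedy
# search exact.

# data.frame of factors -> integer matrix (1..arity, NA = missing)
.as_discrete_matrix <- function(data) {
  if (!is.data.frame(data)) stop("data must be a data frame")
  lv <- list()
  cols <- lapply(names(data), function(v) {
    x <- data[[v]]
    if (is.character(x)) x <- factor(x)
    if (is.logical(x)) x <- factor(x, levels = c("FALSE", "TRUE"))
    if (!is.factor(x))
      stop(sprintf("variable '%s' is not discrete; discretize first", v))
    if (nlevels(x) < 1L) stop(sprintf("variable '%s' has no levels", v))
    lv[[v]] <<- levels(x)
    as.integer(x)
  })
  m <- matrix(NA_integer_, nrow = nrow(data), ncol = ncol(data),
              dimnames = list(rownames(data), names(data)))
  for (k in seq_along(cols)) m[, k] <- cols[[k]]
  attr(m, "levels") <- lv
  attr(m, "arity") <- vapply(lv, length, integer(1))
  m
}

# arcs argument -> canonical two-column character matrix
.as_arcs <- function(arcs) {
  if (methods::is(arcs, "BBNModel")) return(arcs@arcs)
  if (is.null(arcs) || length(arcs) == 0L) return(.empty_arcs())
  arcs <- as.matrix(arcs)
  if (ncol(arcs) != 2L) stop("arcs must be a two-column (from, to) matrix")
  colnames(arcs) <- c("from", "to")
  arcs
}

#' Minimum description length of a network structure on discrete data
#'
#' @param dag a [BBNModel][BBNModel-class] or a two-column `from`/`to` arc
#'   matrix over the data's variables (`NULL` = empty graph).
#' @param data data frame of factors; `NA` = missing.  Records missing any
#'   variable of a family are excluded from that family's counts only.
#' @return list with `dataBits`, `modelBits`, `total` (bits) and
#'   `perFamily`, a data frame of node-wise scores (the node-wise totals
#'   sum to `total`).
#' @export
mdlScore <- function(dag, data) {
  if (nrow(data) == 0L) stop("empty data set")
  m <- .as_discrete_matrix(data)
  arcs <- .as_arcs(dag)
  vars <- colnames(m)
  if (nrow(arcs) > 0L && !all(arcs %in% vars))
    stop("arc endpoint absent from data: ",
         paste(setdiff(as.vector(arcs), vars), collapse = ", "))
  if (!.is_acyclic(vars, arcs)) stop("graph contains a cycle")
  arity <- attr(m, "arity")
  fam <- data.frame(node = vars, dataBits = 0, modelBits = 0, n = 0L,
                    stringsAsFactors = FALSE)
  for (k in seq_along(vars)) {
    parents <- arcs[arcs[, 2L] == vars[k], 1L]
    pk <- match(parents, vars) - 1L
    b <- cpp_family_bits(m, as.integer(arity), k - 1L, as.integer(pk))
    fam$dataBits[k] <- b[1L]; fam$modelBits[k] <- b[2L]
    fam$n[k] <- as.integer(b[3L])
  }
  list(dataBits = sum(fam$dataBits), modelBits = sum(fam$modelBits),
       total = sum(fam$dataBits) + sum(fam$modelBits), perFamily = fam)
}
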