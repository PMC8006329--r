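# Exact posterior inference by variable elimination over the CPT factors.
# Factors are dense arrays over small state spaces (the networks here have
# few nodes and 2-3 bins per node), so a greedy smallest-intermediate-
# factor elimination order is ample.

.f_new <- function(vars, values) list(vars = vars, values = values)

# drop variable `var` from factor `f` by fixing it at level index `li`
.f_reduce <- function(f, var, li) {
  k <- match(var, f$vars)
  d <- dim(f$values)
  if (is.null(d)) d <- length(f$values)
  idx <- lapply(d, seq_len)
  idx[[k]] <- li
  vals <- do.call(`[`, c(list(f$values), idx, list(drop = FALSE)))
  if (length(d) == 1L) return(.f_new(character(), as.numeric(vals)))
  .f_new(f$vars[-k], array(vals, dim = d[-k]))
}

# sum variable `var` out of factor `f`
.f_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  d <- dim(f$values)
  if (is.null(d)) d <- length(f$values)
  if (length(d) == 1L) return(.f_new(character(), sum(f$values)))
  vals <- apply(f$values, setdiff(seq_along(d), k), sum)
  .f_new(f$vars[-k], array(vals, dim = d[-k]))
}

# pointwise product on the union variable set
.f_product <- function(f1, f2, arity) {
  if (length(f1$vars) == 0L)
    return(.f_new(f2$vars, f2$values * as.numeric(f1$values)))
  if (length(f2$vars) == 0L)
    return(.f_new(f1$vars, f1$values * as.numeric(f2$values)))
  vars <- union(f1$vars, f2$vars)
  d <- arity[vars]
  expand <- function(f) {
    miss <- setdiff(vars, f$vars)
    arr <- f$values
    if (length(miss)) {
      arr <- array(rep(as.numeric(arr), prod(arity[miss])),
                   dim = c(arity[f$vars], arity[miss]))
      arr <- aperm(arr, match(vars, c(f$vars, miss)))
    } else {
      arr <- array(as.numeric(arr), dim = arity[f$vars])
      arr <- aperm(arr, match(vars, f$vars))
    }
    arr
  }
  .f_new(vars, array(expand(f1) * expand(f2), dim = d))
}

#' Exact posterior over one variable given partial evidence
#'
#' Computes `P(query | evidence)` by variable elimination; variables not in
#' the evidence are marginalized, so missing measurements need no special
#' handling.  Evidence whose joint probability under the model is zero is
#' refused with a `degenerateEvidence` error.
#'
#' @param model a [BBNModel][BBNModel-class].
#' @param evidence named character vector or list of observed level labels
#'   (may be empty).
#' @param query variable to query; must not be in the evidence.
#' @return named probability vector over the query's levels (sums to 1).
#' @export
inferPosterior <- function(model, evidence = NULL, query) {
  vars <- model@nodes
  if (!query %in% vars) stop("unknown query variable: ", query)
  ev <- unlist(evidence)
  if (length(ev)) {
    if (is.null(names(ev)) || any(!nzchar(names(ev))))
      stop("evidence must be named")
    if (!all(names(ev) %in% vars))
      stop("evidence variable not in model: ",
           paste(setdiff(names(ev), vars), collapse = ", "))
    if (query %in% names(ev)) stop("query variable is in the evidence")
  }
  arity <- vapply(model@levels, length, integer(1))
  factors <- lapply(vars, function(v) {
    cp <- model@cpts[[v]]
    .f_new(c(v, cp$parents), array(as.numeric(cp$prob),
                                   dim = arity[c(v, cp$parents)]))
  })
  for (v in names(ev)) {
    li <- match(ev[[v]], model@levels[[v]])
    if (is.na(li))
      stop(sprintf("'%s' is not a level of '%s'", ev[[v]], v))
    factors <- lapply(factors, function(f)
      if (v %in% f$vars) .f_reduce(f, v, li) else f)
  }
  hidden <- setdiff(vars, c(query, names(ev)))
  while (length(hidden)) {
    # greedy: eliminate the variable whose combined factor is smallest
    cost <- vapply(hidden, function(h) {
      inv <- unique(unlist(lapply(factors,
        function(f) if (h %in% f$vars) f$vars)))
      prod(arity[inv])
    }, numeric(1))
    h <- hidden[[which.min(cost)]]
    touch <- vapply(factors, function(f) h %in% f$vars, logical(1))
    combined <- Reduce(function(a, b) .f_product(a, b, arity),
                       factors[touch])
    factors <- c(factors[!touch], list(.f_marginalize(combined, h)))
    hidden <- setdiff(hidden, h)
  }
  final <- Reduce(function(a, b) .f_product(a, b, arity), factors)
  vals <- as.numeric(final$values)
  if (length(final$vars) == 0L || final$vars[1L] != query)
    stop("internal error: query variable eliminated")
  z <- sum(vals)
  if (!is.finite(z) || z <= 0)
    stop(structure(class = c("degenerateEvidence", "error", "condition"),
                   list(message = "evidence has probability zero under the model",
                        call = sys.call())))
  stats::setNames(vals / z, model@levels[[query]])
}
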