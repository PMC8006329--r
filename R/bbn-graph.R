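# Neighborhood queries, connectivity statistics and serialization of
# learned networks.  igraph does the file-format work (GraphML, DOT); the
# model itself stays a plain arc list + CPTs.

#' First-degree associates of a node
#'
#' Variables directly adjacent to the target (parents and children,
#' direction-agnostic).  In prognostic use the target is the recovery
#' outcome and these are the candidate predictors carried into final
#' modeling.
#'
#' @param model a [BBNModel][BBNModel-class].
#' @param target node label.
#' @return sorted character vector (possibly empty).
#' @export
firstDegreeAssociates <- function(model, target) {
  if (!target %in% model@nodes) stop("unknown target: ", target)
  a <- model@arcs
  sort(unique(c(a[a[, 2L] == target, 1L], a[a[, 1L] == target, 2L])))
}

#' Connectivity statistics of a network
#'
#' @param model a [BBNModel][BBNModel-class].
#' @param outcome optional node whose degree is reported separately.
#' @return list with `nNodes`, `nArcs`, `degree` (named, in + out) and
#'   `outcomeDegree` (`NA` when `outcome` is absent).
#' @export
connectivityStats <- function(model, outcome = "recovery") {
  a <- model@arcs
  deg <- stats::setNames(integer(length(model@nodes)), model@nodes)
  if (nrow(a)) {
    tab <- table(factor(c(a[, 1L], a[, 2L]), levels = model@nodes))
    deg[names(tab)] <- as.integer(tab)
  }
  list(nNodes = length(model@nodes), nArcs = nrow(a), degree = deg,
       outcomeDegree = if (outcome %in% model@nodes) deg[[outcome]]
                       else NA_integer_)
}

#' Per-arc influence as description-length increase
#'
#' For each arc, the increase in total description length when that single
#' arc is removed (structure otherwise unchanged, scored on the same
#' data).  Larger values mark arcs whose removal hurts compression more —
#' a transparent influence proxy for ranking associations.
#'
#' @param model a [BBNModel][BBNModel-class].
#' @param data the discrete data frame the model was fitted on.
#' @return data frame (`from`, `to`, `deltaBits`) sorted by decreasing
#'   `deltaBits`.
#' @export
arcInfluence <- function(model, data) {
  a <- model@arcs
  if (nrow(a) == 0L)
    return(data.frame(from = character(), to = character(),
                      deltaBits = numeric()))
  base <- mdlScore(a, data)$total
  delta <- vapply(seq_len(nrow(a)), function(k)
    mdlScore(a[-k, , drop = FALSE], data)$total - base, numeric(1))
  out <- data.frame(from = a[, 1L], to = a[, 2L], deltaBits = delta,
                    stringsAsFactors = FALSE)
  out[order(-out$deltaBits, out$from, out$to), , drop = FALSE]
}

#' Convert a model to an igraph object
#'
#' Vertices carry an `outcome` logical attribute flagging the outcome node.
#'
#' @param model a [BBNModel][BBNModel-class].
#' @param outcome node label to flag.
#' @return an [igraph][igraph::graph_from_data_frame] directed graph.
#' @export
asIgraph <- function(model, outcome = "recovery") {
  vertices <- data.frame(name = model@nodes,
                         outcome = model@nodes == outcome,
                         stringsAsFactors = FALSE)
  edges <- as.data.frame(model@arcs, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Serialize a network
#'
#' `writeGraphML()` and `writeDOT()` write the structure (outcome node
#' flagged by a vertex attribute); `writeCPTs()` writes the conditional
#' probability tables as JSON.
#'
#' @param model a [BBNModel][BBNModel-class].
#' @param file output path.
#' @param outcome node label flagged in the vertex attributes.
#' @return the file path, invisibly.
#' @export
writeGraphML <- function(model, file, outcome = "recovery") {
  igraph::write_graph(asIgraph(model, outcome), file, format = "graphml")
  invisible(file)
}

#' @rdname writeGraphML
#' @export
writeDOT <- function(model, file, outcome = "recovery") {
  g <- asIgraph(model, outcome)
  # DOT has no boolean attribute type; write the flag as 0/1
  igraph::V(g)$outcome <- as.integer(igraph::V(g)$outcome)
  igraph::write_graph(g, file, format = "dot")
  invisible(file)
}

#' @rdname writeGraphML
#' @export
writeCPTs <- function(model, file) {
  obj <- lapply(model@cpts, function(cp)
    list(parents = cp$parents,
         levels = dimnames(cp$prob)[[1L]],
         prob = cp$prob))
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(file)
}
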