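#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setGeneric("psfsScores", function(x) standardGeneric("psfsScores"))

#' @export
setGeneric("analyteNames", function(x) standardGeneric("analyteNames"))

#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @export
setGeneric("cpts", function(x) standardGeneric("cpts"))

#' @export
setGeneric("mdlBits", function(x) standardGeneric("mdlBits"))

#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @export
setGeneric("binCuts", function(x) standardGeneric("binCuts"))

#' @export
setGeneric("injectMissingness", function(x, rates, seed)
  standardGeneric("injectMissingness"))

#' Cohort container for envenoming recovery studies
#'
#' `RecoveryCohort` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' each assay is an analyte-by-patient concentration matrix for one sampling
#' timepoint (`"pre"` and/or `"post"` antivenom, `NA` = missing measurement),
#' `colData` holds the clinical variables, and the metadata carries the
#' longitudinal Patient-Specific Functional Scale (PSFS) table plus, for
#' simulated cohorts, the generator's ground truth (planted dependency arcs,
#' per-patient latent severity, and true recovery labels).
#'
#' @seealso [simulateCohort()], [cohortTable()], [writeCohort()]
#' @aliases RecoveryCohort
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass RecoveryCohort
setClass("RecoveryCohort", contains = "SummarizedExperiment")

setValidity("RecoveryCohort", function(object) {
  msg <- character()
  anames <- SummarizedExperiment::assayNames(object)
  if (length(anames) == 0L || !all(anames %in% c("pre", "post")))
    msg <- c(msg, "assays must be named from {'pre', 'post'}")
  ps <- S4Vectors::metadata(object)$psfs
  if (!is.null(ps)) {
    if (!is.data.frame(ps) ||
        !all(c("patient_id", "day", "score") %in% names(ps)))
      msg <- c(msg, "metadata$psfs must have columns patient_id, day, score")
    else if (nrow(ps) > 0L && (any(ps$score < 0 | ps$score > 10, na.rm = TRUE)))
      msg <- c(msg, "PSFS scores must lie in [0, 10]")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RecoveryCohort the generator's ground truth (`NULL` for
#'   cohorts read from disk without one).
#' @param x a `RecoveryCohort`
#' @export
setMethod("groundTruth", "RecoveryCohort", function(x)
  S4Vectors::metadata(x)$groundTruth)

#' @describeIn RecoveryCohort long-format PSFS table
#'   (`patient_id`, `day`, `score`).
#' @export
setMethod("psfsScores", "RecoveryCohort", function(x)
  S4Vectors::metadata(x)$psfs)

#' @describeIn RecoveryCohort the analyte labels (assay row names).
#' @export
setMethod("analyteNames", "RecoveryCohort", function(x) rownames(x))

#' @describeIn RecoveryCohort patient identifiers (assay column names).
#' @export
setMethod("patientIds", "RecoveryCohort", function(x) colnames(x))

setMethod("show", "RecoveryCohort", function(object) {
  cat("RecoveryCohort:", ncol(object), "patients,",
      nrow(object), "analytes\n")
  cat("  timepoints:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  cat("  clinical:",
      paste(names(SummarizedExperiment::colData(object)), collapse = ", "),
      "\n")
  ps <- psfsScores(object)
  cat("  PSFS observations:", if (is.null(ps)) 0L else nrow(ps), "\n")
  gt <- groundTruth(object)
  if (!is.null(gt))
    cat("  simulated cohort with", nrow(gt$plantedDag), "planted arcs\n")
})

#' Per-variable discretization learned on training rows only
#'
#' Stores, for every continuous variable, the interior quantile cut points
#' fitted on a stated set of training rows, and for every categorical
#' variable its fixed level set.  Applying the map never consults values
#' outside the training rows, which is what makes leave-one-out evaluation
#' leakage-free.
#'
#' @slot cuts named list; strictly increasing interior cut points per
#'   continuous variable
#' @slot levelsMap named list; level labels per categorical variable
#' @slot varType named character; `"continuous"` or `"categorical"`
#' @slot fittedOn character; identifiers of the training rows used
#' @slot flagged character; variables given fewer bins than requested
#'   (too few distinct training values)
#' @slot unusable character; variables with no usable training values
#' @seealso [fitDiscretizer()], [applyDiscretizer()]
#' @exportClass DiscretizationMap
setClass("DiscretizationMap",
  representation(cuts = "list", levelsMap = "list", varType = "character",
                 fittedOn = "character", flagged = "character",
                 unusable = "character"))

setValidity("DiscretizationMap", function(object) {
  for (v in names(object@cuts)) {
    cc <- object@cuts[[v]]
    if (length(cc) > 1L && any(diff(cc) <= 0))
      return(sprintf("cut points for '%s' are not strictly increasing", v))
  }
  TRUE
})

#' @describeIn DiscretizationMap named list of interior cut points.
#' @param x a `DiscretizationMap`
#' @export
setMethod("binCuts", "DiscretizationMap", function(x) x@cuts)

setMethod("show", "DiscretizationMap", function(object) {
  cat("DiscretizationMap:", length(object@cuts), "continuous,",
      length(object@levelsMap), "categorical variables;",
      "fitted on", length(object@fittedOn), "rows\n")
  if (length(object@flagged))
    cat("  reduced bins:", paste(object@flagged, collapse = ", "), "\n")
  if (length(object@unusable))
    cat("  unusable:", paste(object@unusable, collapse = ", "), "\n")
})

#' Discrete Bayesian belief network
#'
#' A directed acyclic graph over discretized features (and, in prognostic
#' use, one recovery-outcome node), with one conditional probability table
#' per node.  Arcs encode probabilistic association — each arc carries a
#' joint probability distribution between its endpoints — not causal claims.
#'
#' @slot nodes character; variable labels
#' @slot arcs two-column character matrix (`from`, `to`); may have 0 rows
#' @slot levels named list; category labels per node (bins or factor levels)
#' @slot cpts named list; per node a list with elements `parents` (character)
#'   and `prob`, an array whose first dimension is the node's own levels and
#'   remaining dimensions are the parents' levels; every conditional slice
#'   sums to 1
#' @slot nRecords integer; records available when the model was fitted
#' @slot mdl named numeric with elements `data`, `model`, `total`:
#'   description length in bits (NA before scoring)
#' @seealso [learnStructure()], [fitCPTs()], [inferPosterior()]
#' @exportClass BBNModel
setClass("BBNModel",
  representation(nodes = "character", arcs = "matrix", levels = "list",
                 cpts = "list", nRecords = "integer", mdl = "numeric"))

setValidity("BBNModel", function(object) {
  a <- object@arcs
  if (ncol(a) != 2L) return("arcs must be a two-column matrix")
  if (nrow(a) > 0L && !all(a %in% object@nodes))
    return("arc endpoints must be model nodes")
  if (!.is_acyclic(object@nodes, a)) return("arc set contains a cycle")
  for (v in names(object@cpts)) {
    cp <- object@cpts[[v]]
    pr <- cp$prob
    k <- length(object@levels[[v]])
    m <- matrix(pr, nrow = k)
    if (any(abs(colSums(m) - 1) > 1e-9))
      return(sprintf("CPT for '%s' has a conditional slice not summing to 1", v))
    if (!setequal(cp$parents, a[a[, 2L] == v, 1L]))
      return(sprintf("CPT parents for '%s' disagree with the arc set", v))
  }
  TRUE
})

#' @describeIn BBNModel node labels.
#' @param x a `BBNModel`
#' @export
setMethod("nodes", "BBNModel", function(x) x@nodes)

#' @describeIn BBNModel two-column `from`/`to` arc matrix.
#' @export
setMethod("arcs", "BBNModel", function(x) x@arcs)

#' @describeIn BBNModel named list of conditional probability tables.
#' @export
setMethod("cpts", "BBNModel", function(x) x@cpts)

#' @describeIn BBNModel description length in bits
#'   (`data`, `model`, `total`).
#' @export
setMethod("mdlBits", "BBNModel", function(x) x@mdl)

#' @describeIn BBNModel number of training records.
#' @export
setMethod("nRecords", "BBNModel", function(x) x@nRecords)

setMethod("show", "BBNModel", function(object) {
  cat("BBNModel:", length(object@nodes), "nodes,", nrow(object@arcs),
      "arcs,", object@nRecords, "records\n")
  if (!is.na(object@mdl["total"]))
    cat(sprintf("  description length: %.2f bits (data %.2f + model %.2f)\n",
                object@mdl["total"], object@mdl["data"], object@mdl["model"]))
  if (nrow(object@arcs) > 0L) {
    shown <- utils::head(apply(object@arcs, 1L, paste, collapse = " -> "), 8L)
    cat("  ", paste(shown, collapse = "; "),
        if (nrow(object@arcs) > 8L) "; ..." else "", "\n", sep = "")
  }
})

# internal: Kahn's algorithm on a node/arc list
.is_acyclic <- function(nodes, arcs) {
  if (nrow(arcs) == 0L) return(TRUE)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(arcs[, 2L], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  alive <- rep(TRUE, nrow(arcs))
  queue <- nodes[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]
    removed <- removed + 1L
    out <- which(alive & arcs[, 1L] == u)
    for (k in out) {
      alive[k] <- FALSE
      v <- arcs[k, 2L]
      indeg[[v]] <- indeg[[v]] - 1L
      if (indeg[[v]] == 0L) queue <- c(queue, v)
    }
  }
  removed == length(nodes)
}

.empty_arcs <- function() {
  matrix(character(), ncol = 2L, dimnames = list(NULL, c("from", "to")))
}
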