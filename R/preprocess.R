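# Raw cohort tables -> model-ready discrete tables: natural-log transform
# of analyte concentrations, removal of over-missing variables, and
# training-only quantile discretization (the network engine is discrete).

#' Natural-log transform of analyte columns
#'
#' Replaces each analyte value x by `log(max(x, floor))`; the configurable
#' positive floor guards values at or below the assay's quantitation limit.
#' Missing stays missing.  Tables carry a `"logTransformed"` flag and a
#' second application is refused.
#'
#' @param table feature data frame.
#' @param analytes columns to transform; defaults to the table's
#'   `"analytes"` attribute.
#' @param floor positive constant applied before the log.
#' @return the transformed table (flag set).
#' @export
logTransformAnalytes <- function(table, analytes = attr(table, "analytes"),
                                 floor = 0.5) {
  if (isTRUE(attr(table, "logTransformed")))
    stop("table is already log-transformed")
  if (floor <= 0) stop("floor must be positive")
  analytes <- intersect(analytes, names(table))
  for (v in analytes) {
    x <- table[[v]]
    bad <- which(!is.na(x) & x < 0)
    if (length(bad))
      stop(sprintf("negative analyte value: %s, row %s", v,
                   rownames(table)[bad[1L]]))
    table[[v]] <- log(pmax(x, floor))
  }
  attr(table, "logTransformed") <- TRUE
  table
}

#' Drop variables missing in more than a fraction of records
#'
#' A variable is dropped iff its missing fraction is strictly greater than
#' the threshold (a variable missing in exactly 20% of records survives the
#' default rule).
#'
#' @param table feature data frame.
#' @param threshold fraction in \[0, 1\]; default 0.20.
#' @return list with `table` (kept columns), `dropped` (names) and
#'   `fraction` (named missing fractions of all input columns).
#' @export
filterMissingVariables <- function(table, threshold = 0.20) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (ncol(table) == 0L || nrow(table) == 0L)
    return(list(table = table, dropped = character(),
                fraction = stats::setNames(numeric(ncol(table)),
                                           names(table))))
  frac <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  dropped <- names(table)[frac > threshold]
  kept <- table[, frac <= threshold, drop = FALSE]
  attr(kept, "analytes") <- intersect(attr(table, "analytes"), names(kept))
  attr(kept, "logTransformed") <- attr(table, "logTransformed")
  list(table = kept, dropped = dropped, fraction = frac)
}

#' Fit a quantile discretizer on training rows only
#'
#' Continuous variables get interior cut points at training quantiles
#' (linear-interpolation quantiles, equal-frequency bins; default
#' tertiles).  Variables with fewer distinct training values than requested
#' bins get fewer bins and are flagged; variables with no usable training
#' value are marked unusable.  Categorical variables (factors, characters,
#' logicals) pass through with their level sets recorded.
#'
#' @param table feature data frame.
#' @param trainingRows row names (or indices) to fit on; defaults to all.
#' @param bins requested number of bins per continuous variable.
#' @return a [DiscretizationMap][DiscretizationMap-class].
#' @export
fitDiscretizer <- function(table, trainingRows = rownames(table), bins = 3L) {
  if (is.numeric(trainingRows)) trainingRows <- rownames(table)[trainingRows]
  if (is.null(trainingRows)) trainingRows <- character()
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be at least 2")
  train <- table[trainingRows, , drop = FALSE]
  cuts <- list(); levelsMap <- list()
  varType <- character(); flagged <- character(); unusable <- character()
  for (v in names(table)) {
    x <- table[[v]]
    if (is.numeric(x)) {
      varType[v] <- "continuous"
      vals <- train[[v]][!is.na(train[[v]])]
      if (length(vals) == 0L) {
        unusable <- c(unusable, v)
        cuts[[v]] <- numeric()
        next
      }
      d <- length(unique(vals))
      nb <- min(bins, d)
      cc <- if (nb > 1L)
        unique(as.numeric(stats::quantile(vals, probs = seq_len(nb - 1L) / nb,
                                          type = 7, names = FALSE)))
      else numeric()
      if (length(cc) + 1L < bins) flagged <- c(flagged, v)
      cuts[[v]] <- cc
    } else {
      varType[v] <- "categorical"
      levelsMap[[v]] <- if (is.factor(x)) levels(x)
        else if (is.logical(x)) c("FALSE", "TRUE")
        else sort(unique(as.character(x[!is.na(x)])))
    }
  }
  methods::new("DiscretizationMap", cuts = cuts, levelsMap = levelsMap,
               varType = varType, fittedOn = as.character(trainingRows),
               flagged = flagged, unusable = unusable)
}

#' Apply a fitted discretizer
#'
#' Every non-missing continuous cell becomes a bin label (`"1"` = lowest);
#' values outside the training range clamp to the outer bins.  Categorical
#' columns become factors over their recorded level sets.  Missing stays
#' missing.  Variables marked unusable at fit time are dropped.
#'
#' @param map a [DiscretizationMap][DiscretizationMap-class].
#' @param table feature data frame whose columns all appear in the map.
#' @return data frame of factors with the full level set per column (so
#'   bin arity is stable across folds even when a level is unobserved).
#' @export
applyDiscretizer <- function(map, table) {
  unknown <- setdiff(names(table), names(map@varType))
  if (length(unknown))
    stop("unknown variable: ", paste(unknown, collapse = ", "))
  out <- list()
  for (v in names(table)) {
    if (v %in% map@unusable) next
    x <- table[[v]]
    if (map@varType[[v]] == "continuous") {
      cc <- map@cuts[[v]]
      nb <- length(cc) + 1L
      bin <- findInterval(x, cc) + 1L
      bin[bin > nb] <- nb  # guard against ties at the top cut
      out[[v]] <- factor(as.character(bin), levels = as.character(seq_len(nb)))
    } else {
      out[[v]] <- factor(as.character(x), levels = map@levelsMap[[v]])
    }
  }
  res <- if (length(out))
    as.data.frame(out, check.names = FALSE)
  else
    as.data.frame(matrix(nrow = nrow(table), ncol = 0L))
  rownames(res) <- rownames(table)
  res
}
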