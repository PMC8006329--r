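# Two-stage prognostic modeling per timepoint, mirroring small-cohort BBN
# practice: (1) learn a network on the full data set and one per
# leave-one-out subset, collect the variables that appear as first-degree
# associates of the recovery node in any of them, and refit a final model
# on that selection; (2) score every patient by leave-one-out posterior
# P(recovery = good), rebuilding the whole pipeline (filter, discretize,
# select, fit) inside each fold so the held-out patient never leaks into
# training.

.discretize_fit <- function(table, bins) {
  map <- fitDiscretizer(table, trainingRows = rownames(table), bins = bins)
  list(map = map, data = applyDiscretizer(map, table))
}

#' Full-data and leave-one-out structure learning
#'
#' Learns one network on all rows and, for each patient, one on all rows
#' but theirs.  Discretization is refitted within every training subset so
#' no held-out value influences any cut point.
#'
#' @param table feature data frame (continuous and categorical columns,
#'   including the outcome factor), patients as row names.
#' @param lambda,maxParents,bins see [learnStructure()] and
#'   [fitDiscretizer()].
#' @return list with `full` (a [BBNModel][BBNModel-class]) and `loo`
#'   (named list of models, one per held-out patient).
#' @export
buildFullAndLooModels <- function(table, lambda = 0.01, maxParents = 3L,
                                  bins = 3L) {
  if (nrow(table) < 3L) stop("need at least 3 patients")
  full <- learnStructure(.discretize_fit(table, bins)$data, lambda,
                         maxParents)
  loo <- lapply(seq_len(nrow(table)), function(i)
    learnStructure(.discretize_fit(table[-i, , drop = FALSE], bins)$data,
                   lambda, maxParents))
  names(loo) <- rownames(table)
  list(full = full, loo = loo)
}

#' Aggregate first-degree associates across models
#'
#' For every variable, the fraction of models (full + leave-one-out) in
#' which it is directly adjacent to the target.  The default
#' `minFrequency = 0` selects the union — any variable adjacent in at
#' least one model; raising it moves toward the intersection.  Reporting
#' the frequencies exposes selection volatility at small n.
#'
#' @param models list as returned by [buildFullAndLooModels()], or a plain
#'   list of [BBNModel][BBNModel-class]s.
#' @param target outcome node label.
#' @param minFrequency selection threshold (strict inequality).
#' @return list with `frequency` (named, decreasing, ties alphabetical)
#'   and `selected` (sorted character vector).
#' @export
selectFirstDegreeAssociates <- function(models, target = "recovery",
                                        minFrequency = 0) {
  if (!is.null(models$full))
    models <- c(list(models$full), unname(models$loo))
  vars <- unique(unlist(lapply(models, nodes)))
  hits <- stats::setNames(numeric(length(setdiff(vars, target))),
                          setdiff(vars, target))
  for (m in models) {
    fd <- firstDegreeAssociates(m, target)
    hits[fd] <- hits[fd] + 1
  }
  freq <- hits / length(models)
  freq <- freq[order(-freq, names(freq))]
  list(frequency = freq, selected = sort(names(freq)[freq > minFrequency]))
}

#' Fit the final prognostic model on the selected variables
#'
#' @param table feature data frame including the outcome column.
#' @param selected nonempty character vector of selected variables.
#' @param outcome outcome column name.
#' @inheritParams buildFullAndLooModels
#' @return a [BBNModel][BBNModel-class] over `selected` plus the outcome.
#' @export
fitFinalModel <- function(table, selected, lambda = 0.01, maxParents = 3L,
                          bins = 3L, outcome = "recovery") {
  if (length(selected) == 0L)
    stop("empty selection: no first-degree associates of '", outcome,
         "' survived; no final model can be fitted")
  missingVars <- setdiff(c(selected, outcome), names(table))
  if (length(missingVars))
    stop("selected variable absent from table: ",
         paste(missingVars, collapse = ", "))
  sub <- table[, c(sort(selected), outcome), drop = FALSE]
  learnStructure(.discretize_fit(sub, bins)$data, lambda, maxParents)
}

# selection on one training table: filter over-missing variables, then
# full + LOO structure learning, then first-degree aggregation
.select_on <- function(table, outcome, lambda, maxParents, bins,
                       missingThreshold, minFrequency) {
  feats <- table[, setdiff(names(table), outcome), drop = FALSE]
  flt <- filterMissingVariables(feats, missingThreshold)
  kept <- cbind(flt$table, table[, outcome, drop = FALSE])
  attr(kept, "analytes") <- attr(flt$table, "analytes")
  models <- buildFullAndLooModels(kept, lambda, maxParents, bins)
  sel <- selectFirstDegreeAssociates(models, outcome, minFrequency)
  list(table = kept, dropped = flt$dropped, models = models,
       frequency = sel$frequency, selected = sel$selected)
}

#' Leave-one-out cross-validated posterior scores
#'
#' For each patient, the entire pipeline is retrained without them
#' (missingness filter, discretization, associate selection, final model)
#' and the held-out patient is scored as the posterior probability of good
#' recovery given their discretized non-outcome evidence (missing values
#' marginalized).  Folds whose training labels are single-class are
#' degenerate and score 0.5 by convention, flagged in the output.  With
#' `nested = FALSE` the associate selection is computed once on the full
#' data and reused in every fold (faster, but the selection step is then
#' not cross-validated).
#'
#' The reported score is the posterior under the *design* prior
#' (`priorPolicy = "balanced"`, the default): because the outcome is a
#' median split, the cohort is balanced between good and poor by
#' construction, while the training fold's label marginal is a biased
#' estimate of that prevalence under leave-one-out (removing a good
#' patient always lowers it), which anti-orders the labels of otherwise
#' uninformative folds.  The balanced-prior score replaces the fold
#' prevalence with 1/2 via the posterior-odds identity
#' `odds(score) = odds(posterior) / odds(fold marginal)`, a per-fold
#' monotone transform.  `priorPolicy = "fold"` reports the raw posterior.
#'
#' @param table feature data frame including the outcome factor column
#'   with levels `good`/`poor`.
#' @param outcome outcome column name.
#' @param nested recompute the selection inside each fold (default).
#' @param missingThreshold per-fold missingness filter threshold.
#' @param minFrequency associate-selection threshold.
#' @param priorPolicy `"balanced"` (default) or `"fold"`; see Details.
#' @inheritParams buildFullAndLooModels
#' @return data frame with one row per patient: `patient_id`, `score`,
#'   `true_label`, `degenerate`, `n_evidence`.
#' @export
looCvScores <- function(table, lambda = 0.01, maxParents = 3L, bins = 3L,
                        outcome = "recovery", nested = TRUE,
                        missingThreshold = 0.20, minFrequency = 0,
                        priorPolicy = c("balanced", "fold")) {
  priorPolicy <- match.arg(priorPolicy)
  if (nrow(table) < 4L) stop("need at least 4 patients")
  lab <- table[[outcome]]
  if (length(unique(lab[!is.na(lab)])) < 2L)
    stop("both labels must be represented")
  goodLevel <- "good"
  presel <- if (!nested)
    .select_on(table, outcome, lambda, maxParents, bins, missingThreshold,
               minFrequency)$selected
  rows <- rownames(table)
  out <- data.frame(patient_id = rows, score = NA_real_,
                    true_label = as.character(lab), degenerate = FALSE,
                    n_evidence = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(table))) {
    train <- table[-i, , drop = FALSE]
    if (length(unique(train[[outcome]][!is.na(train[[outcome]])])) < 2L) {
      out$score[i] <- 0.5; out$degenerate[i] <- TRUE
      next
    }
    feats <- train[, setdiff(names(train), outcome), drop = FALSE]
    flt <- filterMissingVariables(feats, missingThreshold)
    kept <- cbind(flt$table, train[, outcome, drop = FALSE])
    sel <- if (nested) {
      models <- buildFullAndLooModels(kept, lambda, maxParents, bins)
      selectFirstDegreeAssociates(models, outcome, minFrequency)$selected
    } else intersect(presel, names(kept))
    if (length(sel) == 0L) {
      # no associate of the outcome in this fold: there is no model to
      # score with, so the fold is uninformative by construction.  The
      # training-set label marginal would NOT be a neutral fallback: under
      # leave-one-out it is systematically lower when the held-out patient
      # is good, which anti-orders the labels.  Score 0.5 and flag.
      out$score[i] <- 0.5; out$degenerate[i] <- TRUE
      next
    }
    sub <- kept[, c(sort(sel), outcome), drop = FALSE]
    fit <- .discretize_fit(sub, bins)
    model <- learnStructure(fit$data, lambda, maxParents)
    testRow <- table[i, sort(sel), drop = FALSE]
    dtest <- applyDiscretizer(fit$map, testRow)
    ev <- list()
    for (v in names(dtest)) {
      val <- dtest[[v]][1L]
      if (!is.na(val)) ev[[v]] <- as.character(val)
    }
    post <- tryCatch(inferPosterior(model, ev, outcome),
                     degenerateEvidence = function(e) NULL)
    if (is.null(post)) {
      out$score[i] <- 0.5; out$degenerate[i] <- TRUE
    } else {
      pg <- unname(post[goodLevel])
      if (priorPolicy == "balanced") {
        qg <- unname(inferPosterior(model, NULL, outcome)[goodLevel])
        odds <- (pg / (1 - pg)) / (qg / (1 - qg))
        pg <- odds / (1 + odds)
      }
      out$score[i] <- pg
      out$n_evidence[i] <- length(ev)
    }
  }
  out
}

#' Run the full prognostic pipeline for one timepoint
#'
#' Computes AUPC outcomes and median-split labels from the cohort's PSFS
#' table, assembles and log-transforms the timepoint's feature table,
#' filters over-missing variables, learns full + leave-one-out networks,
#' selects first-degree associates of recovery, fits the final model,
#' scores every patient by leave-one-out cross-validation, and evaluates
#' the ROC/AUC with the >= 0.6 discriminator rule, plus good-vs-poor log
#' analyte contrasts and connectivity statistics.
#'
#' @param cohort a [RecoveryCohort][RecoveryCohort-class].
#' @param timepoint `"pre"` or `"post"` antivenom.
#' @param logFloor positive floor applied before the natural log.
#' @param contrastThreshold log-median difference flagging threshold.
#' @inheritParams looCvScores
#' @return a list of class `PrognosticRun`; see [renderReport()].
#' @export
runPipeline <- function(cohort, timepoint = c("pre", "post"), lambda = 0.01,
                        maxParents = 3L, bins = 3L, nested = TRUE,
                        missingThreshold = 0.20, minFrequency = 0,
                        logFloor = 0.5, contrastThreshold = 0.25,
                        priorPolicy = c("balanced", "fold")) {
  timepoint <- match.arg(timepoint)
  priorPolicy <- match.arg(priorPolicy)
  outcomes <- dichotomizeAtMedian(psfsOutcomes(psfsScores(cohort)))
  tbl <- cohortTable(cohort, timepoint)
  tbl <- logTransformAnalytes(tbl, floor = logFloor)
  lab <- outcomes$label[match(rownames(tbl), outcomes$patient_id)]
  tbl$recovery <- factor(as.character(lab), levels = c("good", "poor"))
  sel <- .select_on(tbl, "recovery", lambda, maxParents, bins,
                    missingThreshold, minFrequency)
  final <- if (length(sel$selected))
    fitFinalModel(sel$table, sel$selected, lambda, maxParents, bins)
  else NULL
  scores <- looCvScores(tbl, lambda, maxParents, bins, nested = nested,
                        missingThreshold = missingThreshold,
                        minFrequency = minFrequency,
                        priorPolicy = priorPolicy)
  roc <- rocAuc(scores$score, scores$true_label)
  contrasts <- groupContrastAnalytes(
    sel$table[, intersect(attr(tbl, "analytes"), names(sel$table)),
              drop = FALSE],
    tbl$recovery, threshold = contrastThreshold)
  structure(list(
    timepoint = timepoint, nPatients = nrow(tbl), outcomes = outcomes,
    dropped = sel$dropped, models = sel$models,
    associateFrequency = sel$frequency, selected = sel$selected,
    finalModel = final, looScores = scores, roc = roc,
    verdict = classifyDiscriminator(roc$auc),
    connectivity = if (!is.null(final)) connectivityStats(final) else NULL,
    contrasts = contrasts, nested = nested,
    params = list(lambda = lambda, maxParents = maxParents, bins = bins,
                  missingThreshold = missingThreshold,
                  minFrequency = minFrequency, logFloor = logFloor,
                  contrastThreshold = contrastThreshold)),
    class = "PrognosticRun")
}

#' @export
print.PrognosticRun <- function(x, ...) {
  cat("PrognosticRun (", x$timepoint, "-antivenom), ", x$nPatients,
      " patients\n", sep = "")
  cat("  dropped for missingness:",
      if (length(x$dropped)) paste(x$dropped, collapse = ", ") else "none",
      "\n")
  cat("  selected associates:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  cat(sprintf("  LOO-CV AUC: %.3f (%s)\n", x$roc$auc, x$verdict))
  invisible(x)
}
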