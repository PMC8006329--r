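# Deterministic Markdown rendering of a pipeline run: same run object,
# byte-identical report.

.md_num <- function(x, digits = 4) formatC(x, digits = digits, format = "f")

#' Render a prognostic run as a Markdown report
#'
#' Single document covering: cohort summary (n, label split, AUPC
#' median/range), variables dropped for missingness, associate-selection
#' frequencies (so selection volatility at small n is visible), the final
#' network and its connectivity statistics, ROC points with the AUC and
#' discriminator verdict (stating whether the selection was nested inside
#' the cross-validation), and the good-vs-poor log analyte contrasts.
#' Runs with an empty selection get an explicit "no model" section.
#'
#' @param run a `PrognosticRun` from [runPipeline()].
#' @param file optional output path; when given, the lines are written
#'   there.
#' @return the report lines, invisibly (a character vector).
#' @export
renderReport <- function(run, file = NULL) {
  if (!inherits(run, "PrognosticRun")) stop("run must be a PrognosticRun")
  s <- aupcSummary(run$outcomes$aupc)
  split <- table(run$outcomes$label)
  L <- c(
    sprintf("# Prognostic BBN report (%s-antivenom)", run$timepoint),
    "",
    "## Cohort",
    "",
    sprintf("- patients modeled at this timepoint: %d", run$nPatients),
    sprintf("- recovery labels (whole cohort): %d good / %d poor",
            split[["good"]], split[["poor"]]),
    sprintf("- PSFS AUPC median %s (range %s, %s)", .md_num(s$median),
            .md_num(s$min), .md_num(s$max)),
    "",
    "## Missingness filter",
    "",
    if (length(run$dropped))
      sprintf("- dropped (> %s missing): %s",
              .md_num(run$params$missingThreshold, 2),
              paste(sort(run$dropped), collapse = ", "))
    else "- no variable exceeded the missingness threshold",
    "",
    "## First-degree associates of recovery",
    "")
  f <- run$associateFrequency
  f <- f[f > 0]
  if (length(f)) {
    L <- c(L, "| variable | frequency |", "| --- | --- |",
           sprintf("| %s | %s |", names(f), .md_num(f, 3)))
  } else L <- c(L, "- no variable was adjacent to recovery in any model")
  L <- c(L, "", "## Final model", "")
  if (is.null(run$finalModel)) {
    L <- c(L, "- **no model**: the selection was empty, so no final",
           "  prognostic network could be fitted")
  } else {
    a <- arcs(run$finalModel)
    cs <- run$connectivity
    L <- c(L,
      sprintf("- %d nodes, %d arcs; recovery-node degree %d", cs$nNodes,
              cs$nArcs, cs$outcomeDegree),
      sprintf("- description length: %s bits",
              .md_num(mdlBits(run$finalModel)[["total"]], 2)),
      if (nrow(a)) sprintf("- arc: %s -> %s", a[, 1L], a[, 2L])
      else "- the final network has no arcs")
  }
  L <- c(L, "", "## Leave-one-out cross-validation", "",
    sprintf("- selection %s inside each fold",
            if (run$nested) "re-run (nested)" else "fixed (non-nested)"),
    sprintf("- AUC = %s over %d good / %d poor patients",
            .md_num(run$roc$auc), run$roc$nGood, run$roc$nPoor),
    sprintf("- verdict (AUC >= 0.6 rule): %s", run$verdict),
    sprintf("- degenerate folds: %d", sum(run$looScores$degenerate)),
    "", "### ROC points", "", "| fpr | tpr |", "| --- | --- |",
    sprintf("| %s | %s |", .md_num(run$roc$points$fpr),
            .md_num(run$roc$points$tpr)),
    "", "## Good vs poor log analyte contrasts", "",
    sprintf("(flag: |median difference| > %s log units)",
            .md_num(run$params$contrastThreshold, 2)), "")
  ct <- run$contrasts
  if (!is.null(ct) && nrow(ct)) {
    L <- c(L,
      "| analyte | good median | poor median | diff | flagged |",
      "| --- | --- | --- | --- | --- |",
      sprintf("| %s | %s | %s | %s | %s |", ct$analyte,
              .md_num(ct$goodMedian, 3), .md_num(ct$poorMedian, 3),
              .md_num(ct$medianDiff, 3), ifelse(ct$flagged, "yes", "no")))
  } else L <- c(L, "- no analyte columns available")
  if (!is.null(file)) writeLines(L, file)
  invisible(L)
}
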