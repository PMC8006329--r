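# ROC/AUC over leave-one-out posterior scores, the AUC >= 0.6
# discriminator rule, and good-vs-poor analyte contrasts.

#' ROC curve and AUC for good/poor recovery scores
#'
#' The AUC is the tie-corrected rank-pair statistic: the fraction of
#' (good, poor) patient pairs in which the good patient scores higher,
#' counting ties as half.  ROC points come from sweeping each distinct
#' score once, descending (ties collapse to single vertices); the
#' trapezoidal area of those points equals the rank statistic.
#'
#' @param scores numeric scores (higher = more likely good recovery).
#' @param labels `good`/`poor` per score.
#' @return list with `points` (data frame `fpr`, `tpr`, starting at (0,0)
#'   and ending at (1,1)), `auc`, `nGood`, `nPoor`.
#' @examples
#' rocAuc(c(0.9, 0.7, 0.8, 0.1), c("good", "good", "poor", "poor"))$auc
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!all(labels %in% c("good", "poor"))) stop("labels must be good/poor")
  nG <- sum(labels == "good"); nP <- sum(labels == "poor")
  if (nG == 0L || nP == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties counted as half
  auc <- (sum(r[labels == "good"]) - nG * (nG + 1) / 2) / (nG * nP)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == "good") / nG,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == "poor") / nP,
                numeric(1))
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  list(points = points, auc = auc, nGood = nG, nPoor = nP)
}

#' Discriminator verdict for an AUC
#'
#' An AUC of 0.6 or above (boundary inclusive) counts as a good
#' differentiator between good and poor recovery.
#'
#' @param auc number in \[0, 1\].
#' @return `"good differentiator"` or `"not a good differentiator"`.
#' @export
classifyDiscriminator <- function(auc) {
  if (is.na(auc) || auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  if (auc >= 0.6) "good differentiator" else "not a good differentiator"
}

#' Good-vs-poor analyte contrasts on the log scale
#'
#' Per analyte: median and quartiles of the log values within each
#' recovery group (non-missing values only), the poor-minus-good median
#' difference, and a flag when its absolute value exceeds the threshold —
#' a transparent numeric stand-in for visual boxplot separation.  When one
#' group has no observed value the summaries are emitted with the flag
#' suppressed, with a warning.
#'
#' @param table data frame of log analyte columns.
#' @param labels `good`/`poor` recovery label per row.
#' @param analytes columns to summarize (default: all columns).
#' @param threshold flagging threshold in log units (default 0.25).
#' @return data frame with one row per analyte: group quartiles, `nGood`,
#'   `nPoor`, `medianDiff` (poor - good), `flagged`.
#' @export
groupContrastAnalytes <- function(table, labels, analytes = names(table),
                                  threshold = 0.25) {
  labels <- as.character(labels)
  if (length(labels) != nrow(table))
    stop("labels must match table rows")
  q3 <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  }
  rows <- lapply(analytes, function(v) {
    g <- q3(table[[v]][labels == "good"])
    p <- q3(table[[v]][labels == "poor"])
    nG <- sum(!is.na(table[[v]][labels == "good"]))
    nP <- sum(!is.na(table[[v]][labels == "poor"]))
    diff <- p[2L] - g[2L]
    flagged <- FALSE
    if (is.na(diff)) {
      warning("analyte '", v, "' unobserved in one recovery group; ",
              "flag suppressed", call. = FALSE)
    } else flagged <- abs(diff) > threshold
    data.frame(analyte = v, goodQ1 = g[1L], goodMedian = g[2L],
               goodQ3 = g[3L], poorQ1 = p[1L], poorMedian = p[2L],
               poorQ3 = p[3L], nGood = nG, nPoor = nP,
               medianDiff = diff, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
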