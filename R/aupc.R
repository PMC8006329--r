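# PSFS area under the patient curve (AUPC): the study's recovery outcome.
# Scores (0-10, higher = better function) observed over days 0..28 are
# integrated by the trapezoidal rule and normalized by the maximum possible
# area 10 x 28 = 280, so the result lies in [0, 1].

#' Area under a PSFS recovery curve
#'
#' Trapezoidal integral of the Patient-Specific Functional Scale trajectory
#' over days 0-28, divided by 280 (a constant score of 10 over the full
#' window).  When day 0 or day 28 is unobserved, the nearest observed score
#' is carried outward as a constant to the boundary; interior unobserved
#' visits are bridged by the trapezoids between observed days.
#'
#' @param days integer days in \[0, 28\], strictly increasing.
#' @param scores PSFS scores in \[0, 10\], same length as `days`; `NA`
#'   pairs are treated as unobserved visits and dropped.
#' @return AUPC in \[0, 1\].
#' @examples
#' computeAUPC(c(0, 7, 14, 21, 28), c(2, 4, 6, 8, 10))  # 0.6
#' @export
computeAUPC <- function(days, scores) {
  if (length(days) != length(scores)) stop("days and scores differ in length")
  keep <- !is.na(days) & !is.na(scores)
  days <- as.numeric(days[keep]); scores <- as.numeric(scores[keep])
  if (length(days) == 0L) stop("no observed PSFS scores")
  if (any(days < 0 | days > 28)) stop("days must lie in [0, 28]")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (any(scores < 0 | scores > 10)) stop("scores must lie in [0, 10]")
  if (days[1L] > 0) { days <- c(0, days); scores <- c(scores[1L], scores) }
  m <- length(days)
  if (days[m] < 28) { days <- c(days, 28); scores <- c(scores, scores[m]) }
  area <- sum(diff(days) * (utils::head(scores, -1) + utils::tail(scores, -1)) / 2)
  area / 280
}

#' Per-patient AUPC from a long-format PSFS table
#'
#' @param psfs data frame with columns `patient_id`, `day`, `score`.
#' @return data frame (`patient_id`, `aupc`), one row per patient in order
#'   of first appearance.
#' @export
psfsOutcomes <- function(psfs) {
  if (!all(c("patient_id", "day", "score") %in% names(psfs)))
    stop("psfs must have columns patient_id, day, score")
  ids <- unique(psfs$patient_id)
  aupc <- vapply(ids, function(id) {
    sub <- psfs[psfs$patient_id == id, ]
    sub <- sub[order(sub$day), ]
    computeAUPC(sub$day, sub$score)
  }, numeric(1))
  data.frame(patient_id = ids, aupc = unname(aupc),
             stringsAsFactors = FALSE)
}

#' Cohort AUPC summary
#'
#' @param aupc numeric AUPC values (or an outcome data frame with an
#'   `aupc` column).
#' @return list with `median` (midpoint convention at even n), `min`, `max`.
#' @export
aupcSummary <- function(aupc) {
  if (is.data.frame(aupc)) aupc <- aupc$aupc
  aupc <- aupc[!is.na(aupc)]
  if (length(aupc) == 0L) stop("no AUPC values")
  list(median = stats::median(aupc), min = min(aupc), max = max(aupc))
}

#' Good/poor recovery labels by median split
#'
#' Patients whose AUPC is greater than or equal to the cohort median are
#' labeled `good`, the rest `poor`; the median used is recorded on every
#' row.  With fewer than two patients a median split is meaningless and the
#' call is refused.
#'
#' @param outcomes data frame with columns `patient_id` and `aupc`.
#' @return the input with added `label` (factor `good`/`poor`) and
#'   `cohort_median` columns.
#' @export
dichotomizeAtMedian <- function(outcomes) {
  if (!is.data.frame(outcomes) ||
      !all(c("patient_id", "aupc") %in% names(outcomes)))
    stop("outcomes must have columns patient_id and aupc")
  if (nrow(outcomes) < 2L)
    stop("median dichotomization needs at least 2 patients")
  med <- stats::median(outcomes$aupc)
  outcomes$label <- factor(ifelse(outcomes$aupc >= med, "good", "poor"),
                           levels = c("good", "poor"))
  outcomes$cohort_median <- med
  outcomes
}
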