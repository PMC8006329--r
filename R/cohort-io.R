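# Plain-text persistence for cohorts: one CSV per timepoint assay
# (patients x analytes), clinical CSV, long-format PSFS CSV, and JSON
# sidecars for column types and (simulated cohorts) the ground truth.
# Numbers are written with 17 significant digits so a cohort round-trips
# through disk with identical values and missingness mask.

.fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

#' Write a cohort to a directory of delimited text files
#'
#' @param cohort a [RecoveryCohort][RecoveryCohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in SummarizedExperiment::assayNames(cohort)) {
    m <- t(SummarizedExperiment::assay(cohort, tp))
    df <- as.data.frame(apply(m, 2L, .fmt_num, simplify = FALSE),
                        check.names = FALSE)
    df <- cbind(patient_id = rownames(m), df)
    utils::write.csv(df, file.path(dir, paste0("analytes_", tp, ".csv")),
                     row.names = FALSE, na = "")
  }
  clin <- as.data.frame(SummarizedExperiment::colData(cohort))
  types <- lapply(clin, function(x)
    if (is.factor(x)) list(type = "factor", levels = levels(x))
    else if (is.integer(x)) list(type = "integer")
    else list(type = "numeric"))
  out <- data.frame(patient_id = rownames(clin), stringsAsFactors = FALSE)
  for (v in names(clin))
    out[[v]] <- if (is.numeric(clin[[v]]) && !is.integer(clin[[v]]))
      .fmt_num(clin[[v]]) else as.character(clin[[v]])
  utils::write.csv(out, file.path(dir, "clinical.csv"), row.names = FALSE,
                   na = "")
  ps <- psfsScores(cohort)
  if (!is.null(ps)) {
    ps$score <- .fmt_num(ps$score)
    utils::write.csv(ps, file.path(dir, "psfs.csv"), row.names = FALSE,
                     na = "")
  }
  meta <- list(analytes = rownames(cohort),
               patients = colnames(cohort),
               timepoints = SummarizedExperiment::assayNames(cohort),
               clinicalTypes = types,
               timepointAssignment =
                 S4Vectors::metadata(cohort)$timepointAssignment,
               realizedMissing =
                 as.list(S4Vectors::metadata(cohort)$realizedMissing))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  gt <- groundTruth(cohort)
  if (!is.null(gt)) {
    obj <- list(plantedFrom = unname(gt$plantedDag[, "from"]),
                plantedTo = unname(gt$plantedDag[, "to"]),
                latentSeverity = .fmt_num(gt$latentSeverity),
                severityNames = names(gt$latentSeverity),
                trueLabels = as.list(gt$trueLabels),
                aupc = .fmt_num(gt$aupc),
                aupcNames = names(gt$aupc),
                coupledVariables = gt$coupledVariables)
    jsonlite::write_json(obj, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory written by [writeCohort()].
#' @return a [RecoveryCohort][RecoveryCohort-class] with identical assay
#'   values, clinical data, PSFS table and missingness mask.
#' @export
readCohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  analytes <- meta$analytes
  patients <- as.character(meta$patients)
  assays <- list()
  for (tp in meta$timepoints) {
    df <- utils::read.csv(file.path(dir, paste0("analytes_", tp, ".csv")),
                          check.names = FALSE, colClasses = "character",
                          na.strings = "")
    m <- matrix(NA_real_, nrow = length(analytes), ncol = nrow(df),
                dimnames = list(analytes, df$patient_id))
    for (a in analytes) m[a, ] <- as.numeric(df[[a]])
    assays[[tp]] <- m[, patients, drop = FALSE]
  }
  cl <- utils::read.csv(file.path(dir, "clinical.csv"),
                        check.names = FALSE, colClasses = "character",
                        na.strings = "")
  clin <- S4Vectors::DataFrame(row.names = patients)
  for (v in names(meta$clinicalTypes)) {
    ty <- meta$clinicalTypes[[v]]
    x <- cl[[v]][match(patients, cl$patient_id)]
    clin[[v]] <- switch(ty$type,
      factor = factor(x, levels = unlist(ty$levels)),
      integer = as.integer(x),
      as.numeric(x))
  }
  psFile <- file.path(dir, "psfs.csv")
  psfs <- if (file.exists(psFile))
    utils::read.csv(psFile, colClasses = c(patient_id = "character",
                                           day = "integer",
                                           score = "character"),
                    na.strings = "")
  else NULL
  if (!is.null(psfs)) psfs$score <- as.numeric(psfs$score)
  gtFile <- file.path(dir, "ground_truth.json")
  gt <- NULL
  if (file.exists(gtFile)) {
    g <- jsonlite::read_json(gtFile, simplifyVector = TRUE)
    dag <- if (length(g$plantedFrom))
      cbind(from = as.character(g$plantedFrom),
            to = as.character(g$plantedTo))
    else .empty_arcs()
    gt <- list(plantedDag = dag,
               latentSeverity = stats::setNames(as.numeric(g$latentSeverity),
                                                g$severityNames),
               trueLabels = stats::setNames(as.character(
                 unlist(g$trueLabels)), names(g$trueLabels)),
               aupc = stats::setNames(as.numeric(g$aupc), g$aupcNames),
               coupledVariables = as.character(g$coupledVariables))
  }
  asg <- meta$timepointAssignment
  if (!is.null(asg) && length(asg))
    asg <- stats::setNames(as.character(unlist(asg)), names(asg))
  else asg <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = clin,
    metadata = list(psfs = psfs, groundTruth = gt,
                    timepointAssignment = asg,
                    realizedMissing = unlist(meta$realizedMissing)))
  methods::new("RecoveryCohort", se)
}
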