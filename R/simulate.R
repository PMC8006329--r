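# Seeded synthetic cohorts with a planted dependency structure: a latent
# envenoming-severity score drives a subset of analytes, several dynamic
# clinical variables, and the PSFS recovery trajectory, so that every
# downstream stage (outcome scoring, filtering, network learning, LOO
# evaluation) can be exercised and audited without patient-level data.

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Configuration for the synthetic cohort generator
#'
#' @param nPatients number of patients (0 allowed: empty cohort).
#' @param seed integer seed; identical configurations and seeds reproduce
#'   the cohort bit-for-bit.
#' @param severityEffect nonnegative scalar scaling every latent-severity
#'   coupling (analytes, dynamic clinical variables, and the PSFS recovery
#'   plateau). 0 disconnects the outcome from all features; 1 gives
#'   log-scale analyte contrasts of roughly 0.3-0.9 between recovery
#'   groups, the magnitude seen in serum panels of this kind.
#' @param analyteNames panel labels; must be 35 distinct names.
#' @param clinicalNames subset of [clinicalVariables()].
#' @param timepoints subset of `c("pre", "post")` (antivenom).
#' @param missingRates named vector of per-variable missing-cell rates in
#'   \[0, 1\] (missing completely at random).
#' @param psfsDays strictly increasing follow-up days starting at 0.
#' @param paired if `TRUE` every patient is sampled at all timepoints;
#'   otherwise each patient is randomly assigned a single timepoint.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nPatients = 20L, seed = 1L, severityEffect = 1,
                         analyteNames = panelAnalytes(),
                         clinicalNames = clinicalVariables(),
                         timepoints = c("pre", "post"),
                         missingRates = c("IL-3" = 0.25, "IL-17F" = 0.25,
                                          "IL-22" = 0.30, "CO2" = 0.10),
                         psfsDays = c(0L, 7L, 14L, 21L, 28L),
                         paired = TRUE) {
  nPatients <- as.integer(nPatients)
  if (is.na(nPatients) || nPatients < 0L)
    stop("nPatients must be a nonnegative integer (0 gives an empty cohort)")
  if (length(analyteNames) != 35L || anyDuplicated(analyteNames))
    stop("analyteNames must contain exactly 35 distinct labels")
  if (!all(clinicalNames %in% clinicalVariables()))
    stop("unsupported clinical variable: ",
         paste(setdiff(clinicalNames, clinicalVariables()), collapse = ", "))
  timepoints <- match.arg(timepoints, c("pre", "post"), several.ok = TRUE)
  if (severityEffect < 0) stop("severityEffect must be nonnegative")
  if (length(missingRates)) {
    if (is.null(names(missingRates)) || any(!nzchar(names(missingRates))))
      stop("missingRates must be a named vector")
    bad <- setdiff(names(missingRates), c(analyteNames, clinicalNames))
    if (length(bad))
      stop("missingRates names unknown variables: ",
           paste(bad, collapse = ", "))
    if (any(missingRates < 0 | missingRates > 1))
      stop("missingRates must lie in [0, 1]")
  }
  psfsDays <- as.integer(psfsDays)
  if (length(psfsDays) < 1L || psfsDays[1L] != 0L ||
      any(diff(psfsDays) <= 0L))
    stop("psfsDays must be strictly increasing and start at 0")
  structure(list(nPatients = nPatients, seed = as.integer(seed),
                 severityEffect = severityEffect,
                 analyteNames = analyteNames, clinicalNames = clinicalNames,
                 timepoints = timepoints, missingRates = missingRates,
                 psfsDays = psfsDays, paired = isTRUE(paired)),
            class = "CohortConfig")
}

#' Simulate a snakebite-envenoming cohort
#'
#' Draws a latent severity score per patient (standard normal) and
#' propagates it through the planted dependency graph:
#' \itemize{
#'   \item analyte concentrations are log-normal; the log value is a fixed
#'     per-analyte baseline plus `severityEffect` times a signed coupling
#'     times severity, plus Gaussian noise (post-antivenom draws are
#'     attenuated and mean-shifted to emulate treatment);
#'   \item clinical variables include age (25-80), sex, a comorbidity flag,
#'     antihistamine use, WBC, respiratory rate, and CO2, the dynamic ones
#'     coupled to severity;
#'   \item PSFS trajectories rise logistically from a day-0 level toward a
#'     plateau that decreases with severity, with observation noise,
#'     clamped to \[0, 10\].
#' }
#' Missing cells are then injected completely at random per
#' `config$missingRates`.  The planted arcs, latent severities and true
#' recovery labels (AUPC median split of the generated curves) are stored
#' as ground truth for recovery testing.
#'
#' @param config a [cohortConfig()]; alternatively pass its arguments via
#'   `...`.
#' @param ... arguments forwarded to [cohortConfig()] when `config` is
#'   missing.
#' @return a [RecoveryCohort][RecoveryCohort-class].
#' @examples
#' coh <- simulateCohort(nPatients = 6, seed = 1)
#' coh
#' @export
simulateCohort <- function(config = NULL, ...) {
  if (is.null(config)) config <- cohortConfig(...)
  if (!inherits(config, "CohortConfig")) stop("config must be a CohortConfig")
  n <- config$nPatients
  ids <- if (n > 0L) sprintf("P%03d", seq_len(n)) else character()
  sE <- config$severityEffect
  base <- .analyte_baselines()[config$analyteNames]
  base[is.na(base)] <- 3  # custom analyte labels get a neutral baseline
  names(base) <- config$analyteNames
  cpl <- .analyte_couplings()
  cpl <- ifelse(config$analyteNames %in% names(cpl),
                cpl[config$analyteNames], 0)
  names(cpl) <- config$analyteNames
  shift <- .analyte_post_shifts()
  shift <- ifelse(config$analyteNames %in% names(shift),
                  shift[config$analyteNames], 0)

  out <- .with_seed(config$seed, {
    sev <- stats::rnorm(n)
    clin <- S4Vectors::DataFrame(row.names = ids)
    if ("age" %in% config$clinicalNames)
      clin$age <- if (n) sample(25:80, n, replace = TRUE) else integer()
    if ("sex" %in% config$clinicalNames)
      clin$sex <- factor(ifelse(stats::runif(n) < 0.8, "F", "M"),
                         levels = c("F", "M"))
    if ("comorbidity" %in% config$clinicalNames)
      clin$comorbidity <- factor(ifelse(stats::runif(n) < 0.5, "yes", "no"),
                                 levels = c("no", "yes"))
    if ("antihistamines" %in% config$clinicalNames)
      clin$antihistamines <- factor(
        ifelse(stats::runif(n) < stats::plogis(-0.3 + 1.2 * sE * sev),
               "yes", "no"), levels = c("no", "yes"))
    if ("WBC" %in% config$clinicalNames)
      clin$WBC <- pmax(8 + 1.5 * sE * sev + stats::rnorm(n, 0, 2), 2)
    if ("resp_rate" %in% config$clinicalNames)
      clin$resp_rate <- pmax(round(16 + 1.2 * sE * sev +
                                     stats::rnorm(n, 0, 2)), 8)
    if ("CO2" %in% config$clinicalNames)
      clin$CO2 <- pmax(24 - 1.5 * sE * sev + stats::rnorm(n, 0, 2), 10)

    assays <- list()
    for (tp in config$timepoints) {
      attn <- if (tp == "post") 0.7 else 1
      sh <- if (tp == "post") shift else 0 * shift
      m <- if (n > 0L)
        exp(matrix(base + sh, nrow = 35L, ncol = n) +
              (attn * sE * cpl) %o% sev +
              matrix(stats::rnorm(35L * n, 0, 0.6), nrow = 35L, ncol = n))
      else matrix(numeric(), nrow = 35L, ncol = 0L)
      dimnames(m) <- list(config$analyteNames, ids)
      assays[[tp]] <- m
    }

    days <- config$psfsDays
    if (n > 0L) {
      s0 <- .clamp(stats::rnorm(n, 3, 1.2), 0, 8)
      plateau <- .clamp(9.2 - 1.8 * sE * sev, 0, 10)
      frac <- stats::plogis((days - 7) / 3)
      mu <- outer(s0, rep(1, length(days))) + outer(plateau - s0, frac)
      obs <- .clamp(mu + matrix(stats::rnorm(n * length(days), 0, 0.5),
                                nrow = n, ncol = length(days)), 0, 10)
      psfs <- data.frame(patient_id = rep(ids, each = length(days)),
                         day = rep(days, times = n),
                         score = as.numeric(t(obs)),
                         stringsAsFactors = FALSE)
    } else {
      psfs <- data.frame(patient_id = character(), day = integer(),
                         score = numeric(), stringsAsFactors = FALSE)
    }

    assignment <- NULL
    if (!config$paired && length(config$timepoints) > 1L && n > 0L) {
      assignment <- sample(config$timepoints, n, replace = TRUE)
      names(assignment) <- ids
      for (tp in config$timepoints)
        assays[[tp]][, assignment != tp] <- NA_real_
    }

    realized <- stats::setNames(numeric(0), character(0))
    for (v in names(config$missingRates)) {
      r <- config$missingRates[[v]]
      if (v %in% config$analyteNames) {
        hit <- 0L; tot <- 0L
        for (tp in config$timepoints) {
          mask <- stats::runif(n) < r
          assays[[tp]][v, mask] <- NA_real_
          hit <- hit + sum(mask); tot <- tot + n
        }
        realized[v] <- if (tot) hit / tot else 0
      } else {
        mask <- stats::runif(n) < r
        clin[[v]][mask] <- NA
        realized[v] <- if (n) mean(mask) else 0
      }
    }
    list(assays = assays, clin = clin, psfs = psfs, sev = sev,
         assignment = assignment, realized = realized)
  })

  sev <- stats::setNames(out$sev, ids)
  aupc <- if (n > 0L) {
    vapply(ids, function(id) {
      sub <- out$psfs[out$psfs$patient_id == id, ]
      computeAUPC(sub$day, sub$score)
    }, numeric(1))
  } else stats::setNames(numeric(0), character(0))
  labels <- if (n > 0L)
    stats::setNames(ifelse(aupc >= stats::median(aupc), "good", "poor"), ids)
  else stats::setNames(character(0), character(0))

  coupledAnalytes <- config$analyteNames[cpl != 0]
  coupledClinical <- intersect(c("antihistamines", "WBC", "resp_rate", "CO2"),
                               config$clinicalNames)
  coupled <- if (sE > 0) c(coupledAnalytes, coupledClinical) else character()
  dag <- if (sE > 0) {
    cbind(from = rep("latent_severity", length(coupled) + 1L),
          to = c(coupled, "recovery"))
  } else .empty_arcs()
  gt <- list(plantedDag = dag, latentSeverity = sev, trueLabels = labels,
             aupc = aupc, coupledVariables = coupled)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = out$assays, colData = out$clin,
    metadata = list(psfs = out$psfs, groundTruth = gt, config = config,
                    timepointAssignment = out$assignment,
                    realizedMissing = out$realized))
  methods::new("RecoveryCohort", se)
}

#' Inject missing values completely at random
#'
#' Each cell of a targeted variable is independently set missing with the
#' stated rate.  The realized missing fraction per variable is recorded in
#' the `"realizedMissing"` attribute (data frames) or metadata (cohorts).
#'
#' @param x a data frame of features or a
#'   [RecoveryCohort][RecoveryCohort-class].
#' @param rates named numeric vector of rates in \[0, 1\].
#' @param seed integer seed for the masking draws.
#' @return object of the same class with `NA`s injected.
#' @export
setMethod("injectMissingness", "data.frame", function(x, rates, seed) {
  if (length(rates) == 0L) {
    attr(x, "realizedMissing") <- stats::setNames(numeric(0), character(0))
    return(x)
  }
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("rates must be named")
  bad <- setdiff(names(rates), names(x))
  if (length(bad))
    stop("variable not in table: ", paste(bad, collapse = ", "))
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  realized <- .with_seed(seed, {
    out <- stats::setNames(numeric(length(rates)), names(rates))
    for (v in names(rates)) {
      mask <- stats::runif(nrow(x)) < rates[[v]]
      x[[v]][mask] <- NA
      out[v] <- if (nrow(x)) mean(mask) else 0
    }
    out
  })
  attr(x, "realizedMissing") <- realized
  x
})

#' @rdname injectMissingness-data.frame-method
#' @export
setMethod("injectMissingness", "RecoveryCohort", function(x, rates, seed) {
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  clinNames <- names(SummarizedExperiment::colData(x))
  bad <- setdiff(names(rates), c(rownames(x), clinNames))
  if (length(bad))
    stop("variable not in cohort: ", paste(bad, collapse = ", "))
  n <- ncol(x)
  realized <- .with_seed(seed, {
    out <- stats::setNames(numeric(length(rates)), names(rates))
    for (v in names(rates)) {
      r <- rates[[v]]
      if (v %in% rownames(x)) {
        hit <- 0L; tot <- 0L
        for (tp in SummarizedExperiment::assayNames(x)) {
          mask <- stats::runif(n) < r
          SummarizedExperiment::assay(x, tp)[v, mask] <- NA_real_
          hit <- hit + sum(mask); tot <- tot + n
        }
        out[v] <- if (tot) hit / tot else 0
      } else {
        mask <- stats::runif(n) < r
        SummarizedExperiment::colData(x)[[v]][mask] <- NA
        out[v] <- if (n) mean(mask) else 0
      }
    }
    out
  })
  S4Vectors::metadata(x)$realizedMissing <- realized
  x
})

#' Model-ready feature table for one timepoint
#'
#' Assembles a patient-by-feature data frame: clinical columns from
#' `colData` followed by the analyte concentrations of the requested
#' timepoint (natural scale).  In unpaired cohorts only patients assigned
#' to that timepoint are kept.
#'
#' @param cohort a [RecoveryCohort][RecoveryCohort-class].
#' @param timepoint `"pre"` or `"post"`.
#' @return data frame with patients as row names; attributes `"analytes"`
#'   (analyte column names) and `"timepoint"`.
#' @export
cohortTable <- function(cohort, timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  if (!timepoint %in% SummarizedExperiment::assayNames(cohort))
    stop("cohort has no '", timepoint, "' assay")
  keep <- patientIds(cohort)
  asg <- S4Vectors::metadata(cohort)$timepointAssignment
  if (!is.null(asg)) keep <- names(asg)[asg == timepoint]
  clin <- as.data.frame(SummarizedExperiment::colData(cohort))[keep, ,
                                                               drop = FALSE]
  a <- t(SummarizedExperiment::assay(cohort, timepoint)[, keep, drop = FALSE])
  tbl <- cbind(clin, as.data.frame(a, check.names = FALSE))
  rownames(tbl) <- keep
  attr(tbl, "analytes") <- rownames(cohort)
  attr(tbl, "timepoint") <- timepoint
  tbl
}
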