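# Persistence for discretizers and pipeline runs: JSON for the
# discretization map, and a run directory holding the scores, selection
# frequencies, ROC points, contrasts, network exports, rendered report,
# YAML config and a manifest.

#' Serialize a discretization map as JSON
#'
#' @param map a [DiscretizationMap][DiscretizationMap-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeDiscretizer <- function(map, file) {
  obj <- list(cuts = map@cuts, levelsMap = map@levelsMap,
              varType = as.list(map@varType), fittedOn = map@fittedOn,
              flagged = map@flagged, unusable = map@unusable)
  # digits = I(17): bin assignment is boundary-sensitive, so cut points
  # must survive the round trip bit-for-bit
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = FALSE)
  invisible(file)
}

#' @rdname writeDiscretizer
#' @export
readDiscretizer <- function(file) {
  g <- jsonlite::read_json(file, simplifyVector = TRUE)
  methods::new("DiscretizationMap",
               cuts = lapply(g$cuts, as.numeric),
               levelsMap = lapply(g$levelsMap, as.character),
               varType = unlist(lapply(g$varType, as.character)),
               fittedOn = as.character(g$fittedOn),
               flagged = as.character(g$flagged),
               unusable = as.character(g$unusable))
}

#' Write all artifacts of a pipeline run to a directory
#'
#' Emits the leave-one-out scores and ROC points (CSV), the
#' associate-selection frequencies (JSON), the final network (GraphML,
#' DOT, CPT JSON) when one exists, the good-vs-poor contrasts (CSV), the
#' rendered Markdown report, the run configuration (YAML) and a manifest
#' (JSON) listing everything.
#'
#' @param run a `PrognosticRun` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeRun <- function(run, dir) {
  if (!inherits(run, "PrognosticRun")) stop("run must be a PrognosticRun")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put <- function(name) { files <<- c(files, name); file.path(dir, name) }
  utils::write.csv(run$looScores, put("loo_scores.csv"), row.names = FALSE)
  utils::write.csv(run$roc$points, put("roc_points.csv"), row.names = FALSE)
  utils::write.csv(run$contrasts, put("contrasts.csv"), row.names = FALSE)
  jsonlite::write_json(as.list(run$associateFrequency),
                       put("associate_frequency.json"),
                       digits = NA, auto_unbox = TRUE)
  if (!is.null(run$finalModel)) {
    writeGraphML(run$finalModel, put("final_model.graphml"))
    writeDOT(run$finalModel, put("final_model.dot"))
    writeCPTs(run$finalModel, put("final_model_cpts.json"))
  }
  renderReport(run, put("report.md"))
  yaml::write_yaml(c(run$params,
                     list(timepoint = run$timepoint, nested = run$nested)),
                   put("config.yaml"))
  manifest <- list(timepoint = run$timepoint, nPatients = run$nPatients,
                   auc = run$roc$auc, verdict = run$verdict,
                   nested = run$nested, dropped = run$dropped,
                   selected = run$selected, files = sort(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
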