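#' Run the full comorbidity-network pipeline on a registry file
#'
#' Executes, end to end: record parsing -> first-diagnosis ages -> ten-year
#' age-gender cohorts -> one statistically validated network per cohort ->
#' ego-network extraction for the focal code -> chapter summary and
#' cross-cohort presence tables. All artifacts are written under `outdir`:
#'
#' * `svn_<gender>_<decade>.csv` / `.graphml` — validated edge lists and
#'   graphs per cohort;
#' * `ego_<gender>_<decade>.csv` / `.graphml` — ego networks per cohort
#'   (only cohorts where the focal code has neighbors get files);
#' * `cohort_<gender>_<decade>.csv` + `cohort_manifest.json` — cohort
#'   membership and cumulative histories (see [write_cohorts()]);
#' * `chapter_summary.csv` / `.json` — per-chapter counts and percentages;
#' * `presence.csv` — code x cohort presence matrix;
#' * `parse_report.json`, `config.json`, `manifest.json` — run metadata and
#'   per-stage counts.
#'
#' @param input path to a registry CSV (see [parse_records()]).
#' @param outdir output directory, created if missing.
#' @param schema column mapping passed to [parse_records()].
#' @param delim field delimiter of the input.
#' @param config a [validation_config()].
#' @param focal focal ICD code (default `"I67.1"`).
#' @param ego_mode `"induced"` or `"star"`.
#' @param carry_forward cohort membership rule, see [build_cohorts()].
#' @param write_graphml also write GraphML exports (default TRUE).
#' @return invisibly, a list with the fitted objects: `records` report,
#'   `cohorts`, `svns`, `egos`, `summary`, `presence`, `manifest`.
#' @export
run_pipeline <- function(input, outdir, schema = list(), delim = ",",
                         config = validation_config(), focal = "I67.1",
                         ego_mode = c("induced", "star"), carry_forward = FALSE,
                         write_graphml = TRUE) {
  ego_mode <- match.arg(ego_mode)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  records <- parse_records(input, schema = schema, delim = delim)
  if (nrow(records) == 0L) stop("parse stage produced no usable records from ", input)
  jsonlite::write_json(parse_report(records), file.path(outdir, "parse_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  first_dx <- first_diagnosis_ages(records)
  cohorts <- build_cohorts(first_dx, carry_forward = carry_forward)
  write_cohorts(cohorts, outdir)

  svns <- list(); egos <- list()
  for (coh in cohorts) {
    fit <- build_svn(coh, config)
    key <- .cohort_key(coh)
    svns[[key]] <- fit
    stem <- sprintf("%s_%s", tolower(coh$gender), gsub("[^0-9X]", "", coh$label))
    utils::write.csv(fit$edges, file.path(outdir, sprintf("svn_%s.csv", stem)),
                     row.names = FALSE, quote = FALSE)
    if (write_graphml && length(fit$nodes) > 0L)
      igraph::write_graph(as_igraph(fit),
                          file.path(outdir, sprintf("svn_%s.graphml", stem)),
                          format = "graphml")
    eg <- ego_network(fit, focal = focal, mode = ego_mode)
    egos[[key]] <- eg
    if (length(eg$members) > 1L) {
      utils::write.csv(eg$edges, file.path(outdir, sprintf("ego_%s.csv", stem)),
                       row.names = FALSE, quote = FALSE)
      if (write_graphml)
        igraph::write_graph(as_igraph(eg),
                            file.path(outdir, sprintf("ego_%s.graphml", stem)),
                            format = "graphml")
    }
  }

  chap <- summarize_by_chapter(egos)
  utils::write.csv(as.data.frame(chap), file.path(outdir, "chapter_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.data.frame(chap), file.path(outdir, "chapter_summary.json"),
                       digits = NA, pretty = TRUE)
  pres <- cross_cohort_presence(egos)
  utils::write.csv(data.frame(code = rownames(pres$presence),
                              pres$presence * 1L, check.names = FALSE),
                   file.path(outdir, "presence.csv"), row.names = FALSE, quote = FALSE)

  eff_config <- list(alpha = config$alpha, correction = config$correction,
                     min_cooccurrence = config$min_cooccurrence,
                     min_prevalence = config$min_prevalence,
                     test_all_pairs = config$test_all_pairs,
                     focal = focal, ego_mode = ego_mode,
                     carry_forward = carry_forward, input = input)
  jsonlite::write_json(eff_config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    stages = list(
      parse = parse_report(records),
      first_diagnoses = nrow(first_dx),
      patients = length(unique(first_dx$patient_id)),
      cohorts = length(cohorts),
      cohort_sizes = stats::setNames(
        lapply(cohorts, function(c) length(c$histories)),
        vapply(cohorts, .cohort_key, character(1))),
      pairs_tested = sum(vapply(svns, `[[`, numeric(1), "n_tested")),
      links_validated = sum(vapply(svns, function(s) nrow(s$edges), numeric(1))),
      ego_edges = sum(vapply(egos, function(e) nrow(e$edges), numeric(1))),
      ego_distinct_codes = pres$n_distinct,
      ego_code_cohort_incidences = pres$n_with_multiplicity))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(records = records, cohorts = cohorts, svns = svns, egos = egos,
                 summary = chap, presence = pres, manifest = manifest))
}
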