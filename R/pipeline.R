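#' Pipeline configuration
#'
#' Collects input paths, policy overrides and output location for a full
#' end-to-end run. All policy defaults are the package's standard values
#' (per-platform QC thresholds, 50 probes, 200/150 kb size minima, 50%
#' reciprocal clustering, 2% reclassification frequency).
#'
#' @param calls path to the CNV call table.
#' @param qc_metrics path to the sample QC metric table (optional when
#'   `qc_bypass` is set).
#' @param roster path to the analyzed-sample roster (`sample_id`,
#'   `platform`).
#' @param benign_track,affected_track,gene_track,syndrome_track paths to the
#'   four reference tracks.
#' @param cytoband_track,exclusion_track optional track paths.
#' @param outdir output directory.
#' @param dialect a [cnv_dialect()] for the call table.
#' @param qc_bypass skip sample QC.
#' @param reciprocal_threshold,frequency_threshold recurrence parameters.
#' @param min_probes,min_size_gain,min_size_loss inclusion-policy overrides.
#' @param min_gene_overlap_bp gene-containment threshold.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(calls, qc_metrics = NULL, roster, benign_track,
                            affected_track, gene_track, syndrome_track,
                            cytoband_track = NULL, exclusion_track = NULL,
                            outdir, dialect = cnv_dialect(),
                            qc_bypass = FALSE, reciprocal_threshold = 0.5,
                            frequency_threshold = 0.02, min_probes = 50,
                            min_size_gain = 200000, min_size_loss = 150000,
                            min_gene_overlap_bp = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(raw), known)
    if (length(unknown)) {
      stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
    }
    config <- do.call(pipeline_config, raw)
  }
  stopifnot(inherits(config, "pipeline_config"))
  config
}

#' Run the CNV interpretation pipeline end-to-end
#'
#' Fixed stage order: sample QC and inclusion gates, evidence gathering,
#' five-tier classification, recurrence clustering and frequency-based
#' reclassification, cohort summarization. Writes `classified.tsv`,
#' `evidence.tsv`, `attrition.tsv`, `recurrence_report.tsv`, `summary.tsv`,
#' `summary.json` and `run_log.txt` into the output directory (each file
#' written atomically); the log records input checksums, policy values and
#' per-stage counts. Identical inputs and config yield byte-identical
#' outputs. The recurrence frequency denominator is the number of
#' QC-passing roster samples.
#'
#' @param config a [pipeline_config()] or the path to a YAML file with its
#'   keys.
#' @return (invisibly) a list with the classified calls, the cohort summary,
#'   the recurrence report and the attrition table.
#' @export
run_cnv_pipeline <- function(config) {
  config <- read_pipeline_config(config)

  track_paths <- c(benign_track = config$benign_track,
                   affected_track = config$affected_track,
                   gene_track = config$gene_track,
                   syndrome_track = config$syndrome_track,
                   cytoband_track = config$cytoband_track,
                   exclusion_track = config$exclusion_track)
  inputs <- c(calls = config$calls, qc_metrics = config$qc_metrics,
              roster = config$roster, track_paths)
  for (nm in names(inputs)) {
    if (!file.exists(inputs[[nm]])) {
      stop("input stage: missing ", nm, " file: ", inputs[[nm]])
    }
  }

  log_lines <- c(sprintf("cnvtier pipeline run %s",
                         format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 "inputs (md5):",
                 sprintf("  %s: %s  %s", names(inputs), inputs,
                         unname(tools::md5sum(unname(inputs)))),
                 sprintf("policy: min_probes=%d min_size_gain=%d min_size_loss=%d",
                         config$min_probes, config$min_size_gain,
                         config$min_size_loss),
                 sprintf("policy: reciprocal=%.2f frequency=%.3f qc_bypass=%s",
                         config$reciprocal_threshold,
                         config$frequency_threshold, config$qc_bypass))

  parsed <- parse_cnv_table(config$calls, config$dialect)
  if (nrow(parsed$errors)) {
    log_lines <- c(log_lines,
                   sprintf("parse stage: %d malformed row(s) skipped (lines %s)",
                           nrow(parsed$errors),
                           paste(utils::head(parsed$errors$line, 10),
                                 collapse = ",")))
  }
  roster <- utils::read.delim(config$roster, colClasses = "character")
  qc_metrics <- if (!is.null(config$qc_metrics)) {
    utils::read.delim(config$qc_metrics)
  }
  tracks <- list(
    benign_population = parse_track(config$benign_track, "benign_population"),
    affected = parse_track(config$affected_track, "affected"),
    gene = parse_track(config$gene_track, "gene"),
    syndrome = parse_track(config$syndrome_track, "syndrome"),
    cytoband = if (!is.null(config$cytoband_track)) {
      parse_track(config$cytoband_track, "cytoband")
    })
  exclusion <- if (!is.null(config$exclusion_track)) {
    parse_track(config$exclusion_track, "exclusion")
  }

  gated <- apply_gates(
    parsed$calls, qc_metrics,
    inclusion_rules = cnv_inclusion_policy(
      min_probes = config$min_probes,
      min_size_gain = config$min_size_gain,
      min_size_loss = config$min_size_loss,
      exclusion_regions = exclusion),
    qc_bypass = config$qc_bypass)
  log_lines <- c(log_lines,
                 sprintf("gate stage: %d in, %d retained", gated$n_input,
                         gated$n_retained),
                 sprintf("  removed %s: %d", gated$attrition$reason,
                         gated$attrition$n_removed))

  evidence <- gather_evidence(gated$calls, tracks,
                              config$min_gene_overlap_bp)
  classified <- classify_cnvs(gated$calls, evidence)

  if (!config$qc_bypass && !is.null(qc_metrics)) {
    qc <- evaluate_sample_qc(qc_metrics)
    analyzed <- roster[roster$sample_id %in% qc$sample_id[qc$pass], ,
                       drop = FALSE]
  } else {
    analyzed <- roster
  }
  cohort_size <- nrow(analyzed)
  clusters <- cluster_regions(classified, cohort_size,
                              config$reciprocal_threshold)
  rec <- reclassify_recurrent(classified, clusters,
                              config$frequency_threshold,
                              cytoband_track = tracks$cytoband)
  classified <- rec$classified
  log_lines <- c(log_lines,
                 sprintf("recurrence stage: %d region(s) at frequency >= %.3f, %d call(s) reclassified",
                         nrow(rec$report), config$frequency_threshold,
                         sum(classified$reclassified)))

  summary <- summarize_cohort(classified, analyzed)
  log_lines <- c(log_lines,
                 sprintf("summary stage: %d calls over %d arrays (mean %.1f/patient)",
                         summary$n_calls, summary$n_samples,
                         summary$mean_cnvs$overall))

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outdir, f)
  write_classified_table(classified, p("classified.tsv"))
  write_evidence_table(gated$calls, evidence, p("evidence.tsv"))
  write_tsv_atomic(gated$attrition, p("attrition.tsv"))
  write_tsv_atomic(rec$report, p("recurrence_report.tsv"))
  write_cohort_summary(summary, p("summary.tsv"), p("summary.json"))
  writeLines(log_lines, p("run_log.txt"))

  invisible(list(classified = classified, summary = summary,
                 recurrence_report = rec$report,
                 attrition = gated$attrition, outdir = config$outdir))
}
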