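#' Cross-tabulate classified CNVs by tier, size bin and type
#'
#' Counts per (type, size bin, tier) cell plus "total" margins on every
#' axis. Percentages are computed column-wise: each (type, size bin) column's
#' tier counts are divided by that column's total and rounded half away from
#' zero to one decimal; columns with zero calls report counts of 0 and `NA`
#' percentages.
#'
#' @param classified classified call data.frame.
#' @param use_original_labels cross-tabulate the pre-reclassification labels
#'   instead of the current ones.
#' @return data.frame of class `cnv_crosstab` in long form: `cnv_type`
#'   (loss/gain/total), `size_bin` (bins plus "Total"), `label` (tiers plus
#'   "total"), `count`, `pct`.
#' @export
cnv_crosstab <- function(classified, use_original_labels = FALSE) {
  lab <- if (use_original_labels) classified$original_label
         else classified$label
  lab <- factor(lab, levels = CNV_LABELS)
  stopifnot(!anyNA(lab) || nrow(classified) == 0)
  bin <- size_bin(classified$end - classified$start)
  typ <- factor(classified$cnv_type, levels = c("loss", "gain"))

  counts <- table(label = lab, size_bin = bin, cnv_type = typ)
  types <- c("loss", "gain", "total")
  bins <- c(SIZE_BINS, "Total")
  labels <- c(CNV_LABELS, "total")

  rows <- list()
  for (tp in types) {
    m <- if (tp == "total") counts[, , "loss"] + counts[, , "gain"]
         else counts[, , tp]
    m <- cbind(m, Total = rowSums(m))
    m <- rbind(m, total = colSums(m))
    for (b in bins) {
      cnt <- m[, b]
      coltot <- cnt[["total"]]
      pct <- if (coltot > 0) round_half_away(100 * cnt / coltot, 1)
             else rep(NA_real_, length(cnt))
      rows[[length(rows) + 1]] <- data.frame(
        cnv_type = tp, size_bin = b, label = c(CNV_LABELS, "total"),
        count = as.integer(cnt), pct = as.numeric(pct))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cnv_crosstab", "data.frame")
  out
}

#' Mean number of CNVs per patient
#'
#' Total surviving calls divided by the roster size, overall and per
#' platform; samples with zero surviving calls stay in the denominator.
#' Values are rounded half away from zero to one decimal.
#'
#' @param classified classified (or gated) call data.frame.
#' @param roster data.frame with one row per analyzed sample: `sample_id`,
#'   `platform`. A call from a sample absent in the roster is a hard error.
#' @return list with `overall` and named vector `by_platform`.
#' @export
mean_cnvs_per_patient <- function(classified, roster) {
  if (nrow(roster) == 0) stop("empty roster: no samples to average over")
  stray <- setdiff(unique(classified$sample_id), roster$sample_id)
  if (length(stray)) {
    stop("call(s) from sample(s) absent in roster: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  overall <- round_half_away(nrow(classified) / nrow(roster), 1)
  platforms <- unique(roster$platform)
  calls_platform <- roster$platform[match(classified$sample_id,
                                          roster$sample_id)]
  by_platform <- vapply(platforms, function(p) {
    round_half_away(sum(calls_platform == p) / sum(roster$platform == p), 1)
  }, numeric(1))
  list(overall = overall, by_platform = by_platform)
}

#' Mean CNV sizes
#'
#' Arithmetic mean interval length in bp, overall, by type and by tier
#' (absent groups are absent entries).
#'
#' @param classified classified call data.frame.
#' @param use_original_labels group by pre-reclassification labels.
#' @return list with `overall`, named vectors `by_type` and `by_label`.
#' @export
mean_sizes <- function(classified, use_original_labels = FALSE) {
  len <- classified$end - classified$start
  lab <- if (use_original_labels) classified$original_label
         else classified$label
  list(overall = mean(len),
       by_type = tapply(len, classified$cnv_type, mean),
       by_label = tapply(len, factor(lab, levels = CNV_LABELS), mean)[
         !is.na(tapply(len, factor(lab, levels = CNV_LABELS), mean))])
}

#' Full cohort summary
#'
#' Bundles the cross-tabulation, per-patient call means and mean sizes into
#' one object.
#'
#' @inheritParams cnv_crosstab
#' @inheritParams mean_cnvs_per_patient
#' @return list of class `cohort_summary` with elements `crosstab`,
#'   `mean_cnvs`, `mean_size`, `n_calls`, `n_samples`.
#' @export
summarize_cohort <- function(classified, roster, use_original_labels = FALSE) {
  structure(list(crosstab = cnv_crosstab(classified, use_original_labels),
                 mean_cnvs = mean_cnvs_per_patient(classified, roster),
                 mean_size = mean_sizes(classified, use_original_labels),
                 n_calls = nrow(classified), n_samples = nrow(roster)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d CNVs across %d arrays (%.1f per patient)\n",
              x$n_calls, x$n_samples, x$mean_cnvs$overall))
  tot <- x$crosstab[x$crosstab$cnv_type == "total" &
                      x$crosstab$size_bin == "Total", ]
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %-18s %5d  (%s%%)\n", tot$label[i], tot$count[i],
                ifelse(is.na(tot$pct[i]), "-", format(tot$pct[i]))))
  }
  cat(sprintf("  mean size: %.1f kb overall", x$mean_size$overall / 1000))
  bt <- x$mean_size$by_type
  if (length(bt)) {
    cat(" (", paste(sprintf("%s %.1f kb", names(bt), bt / 1000),
                    collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Write the cohort summary as TSV and JSON
#'
#' The TSV is the long-form cross-tabulation; the JSON additionally carries
#' the per-patient means and mean sizes (kb, one decimal) for machine
#' consumption. Output is byte-identical for identical input.
#'
#' @param summary a [summarize_cohort()] result.
#' @param tsv_file,json_file output paths (`NULL` to skip one of them).
#' @export
write_cohort_summary <- function(summary, tsv_file = NULL, json_file = NULL) {
  if (!is.null(tsv_file)) {
    write_tsv_atomic(as.data.frame(summary$crosstab), tsv_file)
  }
  if (!is.null(json_file)) {
    payload <- list(
      n_calls = summary$n_calls,
      n_samples = summary$n_samples,
      mean_cnvs_per_patient = summary$mean_cnvs$overall,
      mean_cnvs_by_platform = as.list(summary$mean_cnvs$by_platform),
      mean_size_kb = round_half_away(summary$mean_size$overall / 1000, 1),
      mean_size_kb_by_type =
        as.list(round_half_away(summary$mean_size$by_type / 1000, 1)),
      mean_size_kb_by_label =
        as.list(round_half_away(summary$mean_size$by_label / 1000, 1)),
      crosstab = summary$crosstab)
    jsonlite::write_json(payload, json_file, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(summary)
}
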