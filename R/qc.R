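#' Per-platform sample QC policy
#'
#' Acceptance thresholds for array quality metrics, following the
#' manufacturer-recommended cutoffs used in clinical practice: MAPD (median of
#' absolute pairwise differences of adjacent probe log-ratios) at most 0.35 on
#' the SNP6 platform and 0.25 on the CytoScan 750K/HD platforms; for the
#' CytoScan platforms additionally SNPQC at least 15 — relaxed to 12 when both
#' MAPD and waviness SD meet their thresholds — and waviness SD at most 0.12.
#' All comparisons are inclusive.
#'
#' @param mapd_max named numeric vector of MAPD ceilings per platform.
#' @param snpqc_min,snpqc_relaxed_min SNPQC floor and its relaxed fallback.
#' @param waviness_sd_max waviness SD ceiling.
#' @return a list of class `qc_policy`.
#' @export
qc_policy <- function(mapd_max = c(SNP6 = 0.35, C750K = 0.25, CYTOHD = 0.25),
                      snpqc_min = 15, snpqc_relaxed_min = 12,
                      waviness_sd_max = 0.12) {
  stopifnot(snpqc_relaxed_min < snpqc_min, all(mapd_max > 0),
            waviness_sd_max > 0)
  structure(list(mapd_max = mapd_max, snpqc_min = snpqc_min,
                 snpqc_relaxed_min = snpqc_relaxed_min,
                 waviness_sd_max = waviness_sd_max),
            class = "qc_policy")
}

#' Evaluate sample-level QC
#'
#' SNP6 samples pass on MAPD alone; CytoScan 750K/HD samples must pass MAPD,
#' waviness SD, and SNPQC (with the relaxed SNPQC floor available only when
#' both other metrics pass). A metric that is required but absent fails with
#' reason `<metric>_absent`. Reasons list every failed criterion.
#'
#' @param metrics data.frame with `sample_id`, `platform` and numeric `mapd`,
#'   `snpqc`, `waviness_sd` columns (the latter two may be `NA`/missing for
#'   SNP6).
#' @param policy a [qc_policy()].
#' @return data.frame with `sample_id`, `platform`, `pass` (logical) and
#'   `reasons` (semicolon-joined, empty when passing).
#' @export
evaluate_sample_qc <- function(metrics, policy = qc_policy()) {
  metrics <- as.data.frame(metrics)
  stopifnot(all(c("sample_id", "platform") %in% names(metrics)))
  unknown <- setdiff(unique(metrics$platform), names(policy$mapd_max))
  if (length(unknown)) {
    stop("platform(s) not covered by QC policy: ",
         paste(unknown, collapse = ", "))
  }
  for (col in c("mapd", "snpqc", "waviness_sd")) {
    if (is.null(metrics[[col]])) metrics[[col]] <- NA_real_
    metrics[[col]] <- suppressWarnings(as.numeric(metrics[[col]]))
  }

  reasons <- character(nrow(metrics))
  pass <- logical(nrow(metrics))
  for (i in seq_len(nrow(metrics))) {
    p <- metrics$platform[i]
    m <- metrics$mapd[i]; s <- metrics$snpqc[i]; w <- metrics$waviness_sd[i]
    r <- character()
    mapd_ok <- !is.na(m) && m <= policy$mapd_max[[p]]
    if (is.na(m)) r <- c(r, "mapd_absent")
    else if (!mapd_ok) r <- c(r, "mapd_above_max")
    if (p != "SNP6") {
      wav_ok <- !is.na(w) && w <= policy$waviness_sd_max
      if (is.na(w)) r <- c(r, "waviness_sd_absent")
      else if (!wav_ok) r <- c(r, "waviness_sd_above_max")
      if (is.na(s)) {
        r <- c(r, "snpqc_absent")
      } else if (!(s >= policy$snpqc_min ||
                   (s >= policy$snpqc_relaxed_min && mapd_ok && wav_ok))) {
        r <- c(r, "snpqc_below_min")
      }
    }
    reasons[i] <- paste(r, collapse = ";")
    pass[i] <- length(r) == 0
  }
  data.frame(sample_id = metrics$sample_id, platform = metrics$platform,
             pass = pass, reasons = reasons)
}

#' Per-call inclusion policy
#'
#' Calls enter the pathogenicity analysis only if autosomal, covered by at
#' least `min_probes` probes, and at least 200 kb (gains) or 150 kb (losses)
#' long — losses get the lower floor because deletions tend to be more
#' deleterious. Optionally, calls hitting known-causative loci already
#' established by other cytogenomic tests (e.g. 18p/18q/22q11.2 deletions)
#' are excluded to avoid over-representing them; an exclusion region removes
#' only calls of its own type unless its type is "any".
#'
#' @param min_probes minimum probe coverage (inclusive).
#' @param min_size_gain,min_size_loss minimum lengths in bp (inclusive).
#' @param exclusion_regions optional [cnv_track()] of loci to drop.
#' @param autosomes_only keep only chromosomes 1..22.
#' @return a list of class `cnv_inclusion_policy`.
#' @export
cnv_inclusion_policy <- function(min_probes = 50, min_size_gain = 200000,
                                 min_size_loss = 150000,
                                 exclusion_regions = NULL,
                                 autosomes_only = TRUE) {
  stopifnot(min_probes > 0, min_size_loss <= min_size_gain)
  if (!is.null(exclusion_regions)) stopifnot(inherits(exclusion_regions,
                                                      "cnv_track"))
  structure(list(min_probes = min_probes, min_size_gain = min_size_gain,
                 min_size_loss = min_size_loss,
                 exclusion_regions = exclusion_regions,
                 autosomes_only = autosomes_only),
            class = "cnv_inclusion_policy")
}

#' Apply the per-call inclusion filter
#'
#' Always yields a decision; the reported reason is the first failing check
#' in the fixed order autosome, probe count, size, exclusion region.
#'
#' @param calls call data.frame in internal coordinates.
#' @param policy a [cnv_inclusion_policy()].
#' @return data.frame with `include` (logical) and `reason` (`NA` when
#'   included).
#' @export
include_cnv <- function(calls, policy = cnv_inclusion_policy()) {
  n <- nrow(calls)
  len <- calls$end - calls$start
  autosome_ok <- if (policy$autosomes_only) calls$chrom %in% AUTOSOMES
                 else rep(TRUE, n)
  probes_ok <- calls$probe_count >= policy$min_probes
  min_size <- ifelse(calls$cnv_type == "gain", policy$min_size_gain,
                     policy$min_size_loss)
  size_ok <- len >= min_size

  excl_hit <- rep(FALSE, n)
  ex <- policy$exclusion_regions
  if (!is.null(ex) && nrow(ex$records)) {
    h <- track_hits(calls, ex)
    type_match <- ex$records$cnv_type[h$record] == "any" |
      ex$records$cnv_type[h$record] == calls$cnv_type[h$call]
    excl_hit[unique(h$call[h$overlap_len >= 1 & type_match])] <- TRUE
  }

  reason <- rep(NA_character_, n)
  reason[excl_hit] <- "exclusion_region"
  reason[!size_ok] <- "size"
  reason[!probes_ok] <- "probe_count"
  reason[!autosome_ok] <- "non_autosomal"
  data.frame(include = is.na(reason), reason = reason)
}

#' Apply sample QC and call inclusion gates
#'
#' Drops every call from QC-failing samples (sample-level inclusion), then
#' applies [include_cnv()] to the remainder. A call whose sample has no QC
#' record is a hard error unless `qc_bypass` is set. The attrition report
#' attributes each removal to its first failing reason, in the fixed order
#' sample QC, autosome, probe count, size, exclusion region, so the
#' per-reason counts partition the removals.
#'
#' @param calls call data.frame in internal coordinates.
#' @param qc_metrics sample QC metric table (see [evaluate_sample_qc()]).
#' @param qc_rules a [qc_policy()].
#' @param inclusion_rules a [cnv_inclusion_policy()].
#' @param qc_bypass skip the sample-QC stage entirely.
#' @return list with `calls` (surviving), `removed` (dropped calls plus a
#'   `reason` column), `attrition` (per-reason counts), `n_input`,
#'   `n_retained`.
#' @export
apply_gates <- function(calls, qc_metrics = NULL, qc_rules = qc_policy(),
                        inclusion_rules = cnv_inclusion_policy(),
                        qc_bypass = FALSE) {
  n_input <- nrow(calls)
  removed <- calls[0, , drop = FALSE]
  removed$reason <- character(0)

  if (!qc_bypass) {
    if (is.null(qc_metrics)) {
      stop("QC metrics are required unless qc_bypass = TRUE")
    }
    missing <- setdiff(unique(calls$sample_id), qc_metrics$sample_id)
    if (length(missing)) {
      stop("no QC metrics for sample(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    qc <- evaluate_sample_qc(qc_metrics, qc_rules)
    failing <- qc$sample_id[!qc$pass]
    drop <- calls$sample_id %in% failing
    if (any(drop)) {
      d <- calls[drop, , drop = FALSE]
      d$reason <- "sample_qc"
      removed <- rbind(removed, d)
      calls <- calls[!drop, , drop = FALSE]
    }
  }

  inc <- include_cnv(calls, inclusion_rules)
  if (any(!inc$include)) {
    d <- calls[!inc$include, , drop = FALSE]
    d$reason <- inc$reason[!inc$include]
    removed <- rbind(removed, d)
  }
  surviving <- calls[inc$include, , drop = FALSE]
  rownames(surviving) <- rownames(removed) <- NULL

  stages <- c("sample_qc", "non_autosomal", "probe_count", "size",
              "exclusion_region")
  attrition <- data.frame(
    reason = stages,
    n_removed = vapply(stages, function(s) sum(removed$reason == s),
                       integer(1)))
  rownames(attrition) <- NULL
  list(calls = surviving, removed = removed, attrition = attrition,
       n_input = n_input, n_retained = nrow(surviving))
}
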