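#' Group recurrent CNVs into genomic regions
#'
#' Single-linkage clustering of same-type calls: two calls are linked iff
#' their pairwise overlap clears the reciprocal threshold on both sides
#' (overlap length is at least `reciprocal_threshold` of each call's own
#' length). Connected components of the link graph become regions; every
#' call belongs to exactly one region (isolated calls form singleton
#' regions). Regions are reported in genomic order, with the span of their
#' members, the number of distinct carrier samples, and the carrier
#' frequency over the analyzed cohort.
#'
#' @param classified classified call data.frame ([classify_cnvs()]).
#' @param cohort_size number of analyzed arrays (frequency denominator;
#'   samples with zero calls count).
#' @param reciprocal_threshold link threshold in (0, 1].
#' @return list with `regions` (data.frame: `region_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `n_members`, `carrier_samples`, `cohort_frequency`,
#'   `label_mix`) and `membership` (region index per call).
#' @export
cluster_regions <- function(classified, cohort_size,
                            reciprocal_threshold = 0.5) {
  if (!(reciprocal_threshold > 0 && reciprocal_threshold <= 1)) {
    stop("reciprocal_threshold must be in (0, 1]")
  }
  stopifnot(cohort_size > 0)
  n <- nrow(classified)
  empty <- data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      cnv_type = character(), n_members = integer(),
                      carrier_samples = integer(),
                      cohort_frequency = numeric(), label_mix = character())
  if (n == 0) return(list(regions = empty, membership = integer()))

  gr <- as_granges(classified)
  h <- suppressWarnings(GenomicRanges::findOverlaps(gr, gr))
  i <- S4Vectors::queryHits(h)
  j <- S4Vectors::subjectHits(h)
  keep <- i < j & classified$cnv_type[i] == classified$cnv_type[j]
  i <- i[keep]; j <- j[keep]
  ol <- pmin(classified$end[i], classified$end[j]) -
    pmax(classified$start[i], classified$start[j])
  li <- classified$end[i] - classified$start[i]
  lj <- classified$end[j] - classified$start[j]
  link <- ol / li >= reciprocal_threshold & ol / lj >= reciprocal_threshold

  g <- igraph::make_graph(as.numeric(rbind(i[link], j[link])), n = n,
                          directed = FALSE)
  memb <- igraph::components(g)$membership

  span_start <- tapply(classified$start, memb, min)
  span_end <- tapply(classified$end, memb, max)
  chrom <- tapply(classified$chrom, memb, function(x) x[1])
  ord <- order(match(chrom, AUTOSOMES), span_start)
  remap <- integer(length(ord))
  remap[as.integer(names(span_start))[ord]] <- seq_along(ord)
  memb <- remap[memb]

  mix <- vapply(split(classified$label, memb), function(lab) {
    t <- table(factor(lab, levels = CNV_LABELS))
    paste(sprintf("%s=%d", names(t)[t > 0], t[t > 0]), collapse = ";")
  }, character(1))
  carriers <- vapply(split(classified$sample_id, memb),
                     function(s) length(unique(s)), integer(1))
  regions <- data.frame(
    region_id = sprintf("R%04d", seq_along(ord)),
    chrom = unname(tapply(classified$chrom, memb, function(x) x[1])),
    start = unname(tapply(classified$start, memb, min)),
    end = unname(tapply(classified$end, memb, max)),
    cnv_type = unname(tapply(classified$cnv_type, memb, function(x) x[1])),
    n_members = as.integer(unname(table(memb))),
    carrier_samples = unname(carriers),
    cohort_frequency = unname(carriers) / cohort_size,
    label_mix = unname(mix))
  list(regions = regions, membership = as.integer(memb))
}

#' Annotate regions with cytogenetic bands
#'
#' Labels of every cytoband record overlapping the region span, hyphen-joined
#' when the span crosses several bands; empty string when no track is given.
#'
#' @param regions region data.frame from [cluster_regions()].
#' @param cytoband_track a `cytoband` [cnv_track()] or `NULL`.
#' @return character vector of band labels per region.
#' @export
annotate_cytoband <- function(regions, cytoband_track = NULL) {
  if (is.null(cytoband_track) || nrow(cytoband_track$records) == 0 ||
      nrow(regions) == 0) {
    return(character(nrow(regions)))
  }
  check_kind(cytoband_track, "cytoband")
  h <- track_hits(regions, cytoband_track)
  recs <- cytoband_track$records
  out <- character(nrow(regions))
  if (nrow(h)) {
    h <- h[order(h$call, recs$start[h$record]), ]
    lab <- tapply(recs$label[h$record], h$call, paste, collapse = "-")
    out[as.integer(names(lab))] <- as.character(lab)
  }
  out
}

#' Reclassify high-frequency recurrent CNVs as benign
#'
#' For every region whose carrier frequency is at or above the threshold
#' (2% of arrays by default), member calls currently labelled likely benign
#' or VUS become benign, with `reclassified` set and the original label
#' preserved. Benign members are untouched and pathogenic/likely-pathogenic
#' members are never reclassified. The operation is idempotent.
#'
#' @param classified classified call data.frame.
#' @param clusters result of [cluster_regions()] on the same calls.
#' @param frequency_threshold carrier-frequency cutoff (inclusive).
#' @param cytoband_track optional `cytoband` [cnv_track()] for the report.
#' @return list with `classified` (updated calls) and `report` (one row per
#'   region meeting the threshold: span in display coordinates, cytoband,
#'   type, carriers, frequency, per-label change counts, label mix).
#' @export
reclassify_recurrent <- function(classified, clusters,
                                 frequency_threshold = 0.02,
                                 cytoband_track = NULL) {
  regions <- clusters$regions
  memb <- clusters$membership
  stopifnot(length(memb) == nrow(classified))
  hot <- which(regions$cohort_frequency >= frequency_threshold)

  n_lb <- n_vus <- integer(length(hot))
  for (k in seq_along(hot)) {
    idx <- which(memb == hot[k])
    lb <- idx[classified$label[idx] == "likely_benign"]
    vs <- idx[classified$label[idx] == "vus"]
    n_lb[k] <- length(lb); n_vus[k] <- length(vs)
    chg <- c(lb, vs)
    classified$label[chg] <- "benign"
    classified$reclassified[chg] <- TRUE
  }

  hot_regions <- regions[hot, , drop = FALSE]
  report <- data.frame(
    region_id = hot_regions$region_id,
    chrom = hot_regions$chrom,
    start = internal_to_display_start(hot_regions$start),
    end = hot_regions$end,
    cytoband = annotate_cytoband(hot_regions, cytoband_track),
    cnv_type = hot_regions$cnv_type,
    n_members = hot_regions$n_members,
    carrier_samples = hot_regions$carrier_samples,
    cohort_frequency = hot_regions$cohort_frequency,
    n_reclassified_likely_benign = n_lb,
    n_reclassified_vus = n_vus,
    label_mix = hot_regions$label_mix)
  rownames(report) <- NULL
  list(classified = classified, report = report)
}
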