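# Evidence gathering by genomic-interval overlap.
#
# The overlap grammar used throughout the package distinguishes two
# fractions of a pairwise overlap: the query fraction (overlap length over
# the CNV call's own length) and the reference fraction (overlap length
# over the track record's length). The benign rule requires the call to be
# covered by more than 50% (strict) while the record's non-overlapping
# segment must not exceed 50% of the record (reference fraction >= 0.5);
# affected-database and syndrome matching use the same strict >50% query
# coverage; gene containment needs only 1 bp of overlap.

#' Pairwise overlap statistics
#'
#' Computes overlap length and the query/reference fractions for pairs of
#' intervals in internal 0-based half-open coordinates. Intervals on
#' different chromosomes overlap by zero. Inputs are recycled row-wise when
#' one side has a single row.
#'
#' @param query,ref data.frames with `chrom`, `start`, `end`.
#' @return data.frame with `overlap_len`, `query_fraction`, `ref_fraction`.
#' @export
#' @examples
#' overlap_stats(data.frame(chrom = "1", start = 100000, end = 200000),
#'               data.frame(chrom = "1", start = 150000, end = 250000))
overlap_stats <- function(query, ref) {
  query <- as.data.frame(query); ref <- as.data.frame(ref)
  n <- max(nrow(query), nrow(ref))
  ix <- function(df) df[rep_len(seq_len(nrow(df)), n), , drop = FALSE]
  q <- ix(query); r <- ix(ref)
  ol <- ifelse(normalize_chrom(q$chrom) == normalize_chrom(r$chrom),
               pmax(0, pmin(q$end, r$end) - pmax(q$start, r$start)), 0)
  data.frame(overlap_len = ol,
             query_fraction = ol / (q$end - q$start),
             ref_fraction = ol / (r$end - r$start))
}

# All (call, record) pairs overlapping by >= 1 bp, with overlap statistics.
# Candidate pairs come from GenomicRanges::findOverlaps; the statistics are
# plain interval arithmetic on the internal coordinates.
track_hits <- function(calls, track) {
  recs <- track$records
  if (nrow(calls) == 0 || nrow(recs) == 0) {
    return(data.frame(call = integer(), record = integer(),
                      overlap_len = numeric(), query_fraction = numeric(),
                      ref_fraction = numeric()))
  }
  # the two sides legitimately cover different chromosome subsets
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(calls), as_granges(recs)))
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  ol <- pmin(calls$end[qi], recs$end[si]) - pmax(calls$start[qi],
                                                 recs$start[si])
  data.frame(call = qi, record = si, overlap_len = ol,
             query_fraction = ol / (calls$end[qi] - calls$start[qi]),
             ref_fraction = ol / (recs$end[si] - recs$start[si]))
}

#' Benign-population support for each call
#'
#' A benign-track record contributes to a call iff it is of the same type
#' (deletion/duplication "nature"), covers more than 50% of the call
#' (strict), and its own non-overlapping segment does not exceed 50% of its
#' length (reference fraction >= 0.5). Support is the sum of
#' `support_individuals` (unaffected carriers) over contributing records.
#'
#' @param calls call data.frame in internal coordinates.
#' @param track a `benign_population` [cnv_track()].
#' @return integer vector of support per call, with a `contributors`
#'   attribute (data.frame of call/record index pairs).
#' @export
benign_support <- function(calls, track) {
  check_kind(track, "benign_population")
  h <- track_hits(calls, track)
  recs <- track$records
  ok <- h[recs$cnv_type[h$record] == calls$cnv_type[h$call] &
            h$query_fraction > 0.5 & h$ref_fraction >= 0.5, , drop = FALSE]
  supp <- integer(nrow(calls))
  if (nrow(ok)) {
    agg <- tapply(recs$support_individuals[ok$record], ok$call, sum)
    supp[as.integer(names(agg))] <- as.integer(agg)
  }
  attr(supp, "contributors") <- ok[c("call", "record")]
  supp
}

#' Gene content of each call
#'
#' A gene is contained iff it overlaps the call by at least 1 bp (the
#' permissive reading of "genes within" a CNV); the OMIM flag is true iff any
#' contained gene is OMIM-annotated.
#'
#' @param calls call data.frame in internal coordinates.
#' @param track a `gene` [cnv_track()].
#' @param min_overlap_bp minimum overlap to count a gene as contained.
#' @return data.frame with `contains_genes`, `contains_omim_genes`,
#'   `gene_labels` (semicolon-joined, in genomic order).
#' @export
gene_content <- function(calls, track, min_overlap_bp = 1) {
  check_kind(track, "gene")
  h <- track_hits(calls, track)
  h <- h[h$overlap_len >= min_overlap_bp, , drop = FALSE]
  recs <- track$records
  n <- nrow(calls)
  contains <- omim <- logical(n)
  labels <- character(n)
  contains[unique(h$call)] <- TRUE
  omim[unique(h$call[recs$is_omim[h$record]])] <- TRUE
  if (nrow(h)) {
    h <- h[order(h$call, recs$start[h$record]), ]
    lab <- tapply(recs$label[h$record], h$call, paste, collapse = ";")
    labels[as.integer(names(lab))] <- as.character(lab)
  }
  data.frame(contains_genes = contains, contains_omim_genes = omim,
             gene_labels = labels)
}

#' Affected-database matches for each call
#'
#' A record of the affected-patient catalogue matches a call iff its type is
#' the call's type or "any" and it covers more than 50% of the call
#' (strict). Each match carries the record's curation judgement.
#'
#' @param calls call data.frame in internal coordinates.
#' @param track an `affected` [cnv_track()].
#' @return data.frame of matches ordered by call then genomic position:
#'   `call`, `chrom`, `start`, `end`, `label`, `curation_status`,
#'   `query_fraction`.
#' @export
affected_matches <- function(calls, track) {
  check_kind(track, "affected")
  h <- track_hits(calls, track)
  recs <- track$records
  keep <- (recs$cnv_type[h$record] == "any" |
             recs$cnv_type[h$record] == calls$cnv_type[h$call]) &
    h$query_fraction > 0.5
  h <- h[keep, , drop = FALSE]
  out <- data.frame(call = h$call, chrom = recs$chrom[h$record],
                    start = recs$start[h$record], end = recs$end[h$record],
                    label = recs$label[h$record],
                    curation_status = recs$curation_status[h$record],
                    query_fraction = h$query_fraction)
  out <- out[order(out$call, match(out$chrom, AUTOSOMES), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Syndrome-region hits for each call
#'
#' True iff any microdeletion/microduplication syndrome region of matching
#' type (gain vs duplication syndrome, loss vs deletion syndrome, or "any")
#' covers more than 50% of the call.
#'
#' @param calls call data.frame in internal coordinates.
#' @param track a `syndrome` [cnv_track()].
#' @return data.frame with `hit` (logical) and `labels` (semicolon-joined).
#' @export
syndrome_hit <- function(calls, track) {
  check_kind(track, "syndrome")
  h <- track_hits(calls, track)
  recs <- track$records
  keep <- (recs$cnv_type[h$record] == "any" |
             recs$cnv_type[h$record] == calls$cnv_type[h$call]) &
    h$query_fraction > 0.5
  h <- h[keep, , drop = FALSE]
  n <- nrow(calls)
  hit <- logical(n)
  labels <- character(n)
  hit[unique(h$call)] <- TRUE
  if (nrow(h)) {
    h <- h[order(h$call, recs$start[h$record]), ]
    lab <- tapply(recs$label[h$record], h$call, paste, collapse = ";")
    labels[as.integer(names(lab))] <- as.character(lab)
  }
  data.frame(hit = hit, labels = labels)
}

#' Gather all classification evidence for a set of calls
#'
#' Pure composition of [benign_support()], [gene_content()],
#' [affected_matches()] and [syndrome_hit()] plus the call length; one row
#' per call, aligned with `calls`. Missing tracks are treated as empty.
#'
#' @param calls call data.frame in internal coordinates.
#' @param tracks named list (or track bundle) with elements
#'   `benign_population`, `affected`, `gene`, `syndrome`; any may be `NULL`.
#' @param min_gene_overlap_bp gene-containment threshold, see
#'   [gene_content()].
#' @return data.frame of class `cnv_evidence` with columns `length_bp`,
#'   `benign_support`, `contains_genes`, `contains_omim_genes`,
#'   `gene_labels`, `n_affected`, `affected_status` (list column of curation
#'   statuses), `affected_labels`, `syndrome_hit`, `syndrome_labels`.
#' @export
gather_evidence <- function(calls, tracks, min_gene_overlap_bp = 1) {
  get <- function(kind) tracks[[kind]] %||% empty_track(kind)
  n <- nrow(calls)
  supp <- benign_support(calls, get("benign_population"))
  gc <- gene_content(calls, get("gene"), min_gene_overlap_bp)
  am <- affected_matches(calls, get("affected"))
  sh <- syndrome_hit(calls, get("syndrome"))

  fcall <- factor(am$call, levels = seq_len(n))
  status_list <- unname(split(am$curation_status, fcall))
  label_join <- vapply(unname(split(am$label, fcall)), paste,
                       character(1), collapse = ";")

  ev <- data.frame(length_bp = calls$end - calls$start,
                   benign_support = as.integer(supp),
                   contains_genes = gc$contains_genes,
                   contains_omim_genes = gc$contains_omim_genes,
                   gene_labels = gc$gene_labels,
                   n_affected = lengths(status_list),
                   affected_labels = label_join,
                   syndrome_hit = sh$hit,
                   syndrome_labels = sh$labels)
  ev$affected_status <- status_list
  class(ev) <- c("cnv_evidence", "data.frame")
  ev
}

#' Write an evidence audit table
#'
#' One row per call with every evidence field, list columns flattened to
#' semicolon-joined strings.
#'
#' @param calls call data.frame the evidence was computed for.
#' @param evidence result of [gather_evidence()].
#' @param file output path.
#' @export
write_evidence_table <- function(calls, evidence, file) {
  flat <- as.data.frame(evidence[setdiff(names(evidence), "affected_status")])
  flat$affected_statuses <- vapply(evidence$affected_status, paste,
                                   character(1), collapse = ";")
  out <- cbind(calls[c("sample_id", "chrom")],
               start = internal_to_display_start(calls$start),
               end = calls$end,
               cnv_type = calls$cnv_type, flat)
  write_tsv_atomic(out, file)
}
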