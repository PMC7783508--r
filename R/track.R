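#' Reference track kinds and curation vocabulary
#'
#' `TRACK_KINDS` enumerates the typed interval collections the pipeline
#' consumes: a benign-population catalogue (DGV-like, with per-record counts
#' of unaffected carrier individuals), an affected-patient catalogue
#' (DECIPHER/ClinGen-like, with a curation judgement per record), a gene track
#' with an OMIM disease-association flag, microdeletion/microduplication
#' syndrome regions, cytogenetic bands, and known-causative exclusion loci.
#' `CURATION_LEVELS` is the vocabulary of the affected track's judgement
#' field.
#' @export
TRACK_KINDS <- c("benign_population", "affected", "gene", "syndrome",
                 "cytoband", "exclusion")

#' @rdname TRACK_KINDS
#' @export
CURATION_LEVELS <- c("consistent_pathogenic", "reported_no_clear_association",
                     "uncertain", "n/a")

#' Build a typed reference track
#'
#' A track is an interval collection of one kind with kind-specific record
#' attributes. Missing attribute columns are filled with defaults
#' (`cnv_type = "any"`, `support_individuals = 1`, `curation_status = "n/a"`,
#' `is_omim = FALSE`, `label = ""`); attributes that belong to a different
#' kind must be absent or at their default, otherwise the mismatch is a hard
#' error (e.g. a curation status on a gene track).
#'
#' @param records data.frame with `chrom`, `start`, `end` (internal 0-based
#'   half-open) and optional `cnv_type`, `support_individuals`,
#'   `curation_status`, `is_omim`, `label` columns.
#' @param kind one of [TRACK_KINDS].
#' @return an object of class `cnv_track`.
#' @export
cnv_track <- function(records, kind) {
  kind <- match.arg(kind, TRACK_KINDS)
  records <- as.data.frame(records)
  stopifnot(all(c("chrom", "start", "end") %in% names(records)))
  records$chrom <- normalize_chrom(records$chrom)
  records$start <- as.numeric(records$start)
  records$end <- as.numeric(records$end)
  if (nrow(records)) validate_intervals(records, "track record")

  n <- nrow(records)
  records$cnv_type <- as.character(records$cnv_type %||% rep("any", n))
  records$support_individuals <-
    as.integer(records$support_individuals %||% rep(1L, n))
  records$curation_status <-
    as.character(records$curation_status %||% rep("n/a", n))
  records$is_omim <- as.logical(records$is_omim %||% rep(FALSE, n))
  records$label <- as.character(records$label %||% rep("", n))

  if (n) {
    if (!all(records$cnv_type %in% c("gain", "loss", "any"))) {
      stop("track cnv_type must be one of gain/loss/any")
    }
    if (!all(records$curation_status %in% CURATION_LEVELS)) {
      stop("unknown curation_status value(s) in ", kind, " track")
    }
    if (kind == "affected") {
      if (any(records$curation_status == "n/a")) {
        stop("affected track records require a curation_status")
      }
    } else if (any(records$curation_status != "n/a")) {
      stop("curation_status is only meaningful on an affected track, not '",
           kind, "'")
    }
    if (kind == "benign_population") {
      if (any(is.na(records$support_individuals) |
              records$support_individuals < 1)) {
        stop("benign_population records need support_individuals >= 1")
      }
    } else if (any(records$support_individuals != 1L)) {
      stop("support_individuals is only meaningful on a benign_population ",
           "track, not '", kind, "'")
    }
    if (kind == "gene") {
      if (any(is.na(records$is_omim))) stop("gene track is_omim must be TRUE/FALSE")
    } else if (any(records$is_omim)) {
      stop("is_omim is only meaningful on a gene track, not '", kind, "'")
    }
  }
  rownames(records) <- NULL
  records <- records[c("chrom", "start", "end", "cnv_type",
                       "support_individuals", "curation_status", "is_omim",
                       "label")]
  structure(list(kind = kind, records = records), class = "cnv_track")
}

#' @export
print.cnv_track <- function(x, ...) {
  cat(sprintf("<cnv_track kind=%s, %d records>\n", x$kind, nrow(x$records)))
  invisible(x)
}

#' Track kind accessor
#' @param track a [cnv_track()].
#' @return the track's kind string.
#' @export
track_kind <- function(track) {
  stopifnot(inherits(track, "cnv_track"))
  track$kind
}

empty_track <- function(kind) {
  cnv_track(data.frame(chrom = character(), start = numeric(),
                       end = numeric()), kind)
}

check_kind <- function(track, kind) {
  if (!inherits(track, "cnv_track") || track$kind != kind) {
    stop("expected a '", kind, "' track, got '",
         if (inherits(track, "cnv_track")) track$kind else class(track)[1], "'")
  }
  invisible(track)
}

#' Windowed track query
#'
#' Returns exactly the track records overlapping the window by at least 1 bp
#' (equivalent to a linear scan over the records).
#'
#' @param track a [cnv_track()].
#' @param chrom chromosome name (normalized or not).
#' @param start,end window in internal 0-based half-open coordinates.
#' @return the overlapping subset of `track$records`.
#' @export
track_query <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "cnv_track"), start < end)
  r <- track$records
  hit <- r$chrom == normalize_chrom(chrom) & r$start < end & r$end > start
  r[hit, , drop = FALSE]
}
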