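# Coordinate conventions
#
# Internally every interval is 0-based half-open [start, end), so that
# length = end - start with no off-by-one arithmetic. All display and
# exchange formats (CNV tables, track TSVs, report files) use 1-based
# inclusive coordinates, matching array-analysis exports and genome-browser
# display. BED input is already 0-based half-open and is taken as-is.

#' Canonical autosome names
#'
#' Chromosomes "1".."22" in their canonical (prefix-free) form. Only calls on
#' these chromosomes survive the inclusion filter; parsing itself does not
#' filter.
#' @export
AUTOSOMES <- as.character(1:22)

#' Supported microarray platforms
#' @export
CNV_PLATFORMS <- c("SNP6", "C750K", "CYTOHD")

#' Normalize chromosome names
#'
#' Strips a leading "chr"/"Chr" prefix and whitespace; "chr7" becomes "7".
#' No filtering is done here: "X" passes through and is rejected later by the
#' autosome filter.
#'
#' @param x character vector of chromosome names.
#' @return normalized character vector.
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", trimws(as.character(x)), ignore.case = TRUE)
}

# 1-based inclusive -> internal 0-based half-open: start - 1, end unchanged.
display_to_internal_start <- function(start) start - 1
internal_to_display_start <- function(start) start + 1

# GRanges view of an internal-coordinate interval table (chrom, start, end).
# IRanges is 1-based closed, so [s, e) maps to IRanges(s + 1, e).
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- !is.finite(df$start) | !is.finite(df$end) | df$start >= df$end |
    df$start < 0
  if (any(bad)) {
    stop(sprintf("%d invalid %s(s): need 0 <= start < end", sum(bad), what))
  }
  invisible(df)
}
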