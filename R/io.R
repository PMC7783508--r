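#' Column-mapping dialect for CNV call tables
#'
#' Array-analysis software exports differ in column naming, coordinate
#' convention and how the copy-number state is encoded; the dialect maps an
#' export onto the internal call schema. The default matches the package's
#' canonical table: tab-delimited, 1-based inclusive coordinates, and a
#' `cnv_type` column holding gain/loss.
#'
#' @param sample_id,chrom,start,end,cnv_type,probe_count,platform column
#'   names in the input header.
#' @param coords coordinate convention of the input: `"1-based-inclusive"`
#'   (array exports, default) or `"0-based-half-open"`.
#' @param state_encoding `"gain_loss"` for textual states
#'   (gain/loss/dup/del/duplication/deletion, case-insensitive) or
#'   `"copy_number"` for integer states, where >2 maps to gain, <2 to loss
#'   and a copy-neutral 2 is a row error.
#' @return a list of class `cnv_dialect`.
#' @export
cnv_dialect <- function(sample_id = "sample_id", chrom = "chrom",
                        start = "start", end = "end", cnv_type = "cnv_type",
                        probe_count = "probe_count", platform = "platform",
                        coords = c("1-based-inclusive", "0-based-half-open"),
                        state_encoding = c("gain_loss", "copy_number")) {
  structure(list(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, cnv_type = cnv_type, probe_count = probe_count,
                 platform = platform, coords = match.arg(coords),
                 state_encoding = match.arg(state_encoding)),
            class = "cnv_dialect")
}

map_cnv_type <- function(x, state_encoding) {
  if (state_encoding == "copy_number") {
    cn <- suppressWarnings(as.numeric(x))
    type <- ifelse(cn > 2, "gain", ifelse(cn < 2, "loss", NA_character_))
    err <- ifelse(is.na(cn), "unparseable copy-number state",
                  ifelse(cn == 2, "copy-neutral state (2) is not a CNV",
                         NA_character_))
    list(type = type, err = err)
  } else {
    key <- tolower(trimws(x))
    type <- c(gain = "gain", dup = "gain", duplication = "gain",
              loss = "loss", del = "loss", deletion = "loss")[key]
    list(type = unname(type),
         err = ifelse(is.na(type), paste0("unknown cnv_type '", x, "'"),
                      NA_character_))
  }
}

#' Parse a CNV call table
#'
#' Reads a delimited export of CNV calls, converts coordinates to the
#' internal 0-based half-open convention and normalizes chromosome names.
#' A missing mandatory column is a hard error naming the column; a malformed
#' row (unparseable coordinate or state, inverted interval, negative probe
#' count, unknown platform) is skipped and reported with its file line
#' number. No chromosome filtering happens at parse time.
#'
#' @param file path to a tab-delimited file with a header row.
#' @param dialect a [cnv_dialect()].
#' @return list with `calls` (data.frame: `sample_id`, `chrom`, `start`,
#'   `end`, `cnv_type`, `probe_count`, `platform`) and `errors` (data.frame:
#'   `line`, `message`), where line numbers count the header as line 1.
#' @export
parse_cnv_table <- function(file, dialect = cnv_dialect()) {
  raw <- utils::read.delim(file, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  need <- unlist(dialect[c("sample_id", "chrom", "start", "end", "cnv_type",
                           "probe_count", "platform")])
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }

  n <- nrow(raw)
  line <- seq_len(n) + 1L
  err <- rep(NA_character_, n)
  note <- function(bad, msg) {
    bad <- bad & is.na(err)
    err[bad] <<- if (length(msg) == 1) msg else msg[bad]
  }

  start <- suppressWarnings(as.numeric(raw[[dialect$start]]))
  end <- suppressWarnings(as.numeric(raw[[dialect$end]]))
  note(is.na(start) | is.na(end), "unparseable coordinate")
  if (dialect$coords == "1-based-inclusive") {
    start <- display_to_internal_start(start)
  }
  note(!is.na(start) & !is.na(end) & (start >= end | start < 0),
       "empty or inverted interval")

  tp <- map_cnv_type(raw[[dialect$cnv_type]], dialect$state_encoding)
  note(!is.na(tp$err), tp$err)

  probes <- suppressWarnings(as.integer(raw[[dialect$probe_count]]))
  note(is.na(probes) | probes < 0, "probe_count must be a non-negative integer")

  platform <- trimws(raw[[dialect$platform]])
  note(!platform %in% CNV_PLATFORMS,
       paste0("unknown platform '", platform, "'"))

  keep <- is.na(err)
  calls <- data.frame(sample_id = raw[[dialect$sample_id]][keep],
                      chrom = normalize_chrom(raw[[dialect$chrom]][keep]),
                      start = start[keep], end = end[keep],
                      cnv_type = tp$type[keep], probe_count = probes[keep],
                      platform = platform[keep])
  rownames(calls) <- NULL
  list(calls = calls,
       errors = data.frame(line = line[!keep], message = err[!keep]))
}

#' Write a CNV call table
#'
#' Inverse of [parse_cnv_table()] under the default dialect: tab-delimited,
#' canonical column names, 1-based inclusive coordinates.
#'
#' @param calls call data.frame in internal coordinates.
#' @param file output path.
#' @export
write_cnv_table <- function(calls, file) {
  out <- calls[c("sample_id", "chrom", "start", "end", "cnv_type",
                 "probe_count", "platform")]
  out$start <- internal_to_display_start(out$start)
  write_tsv_atomic(out, file)
}

#' Parse a reference annotation track
#'
#' Reads BED (always 0-based half-open; columns chrom, start, end, then
#' optionally label, cnv_type and one kind-specific attribute: support count
#' for benign tracks, curation status for affected tracks, OMIM flag for gene
#' tracks) or a headered TSV with canonical column names (`chrom`, `start`,
#' `end` plus any of `label`, `cnv_type`, `support_individuals`,
#' `curation_status`, `is_omim`). TSV coordinates default to 1-based
#' inclusive; a leading comment line `# coords: 0-based-half-open` (as
#' written by [write_track()]) overrides the `coords` argument.
#'
#' @param file input path.
#' @param kind one of [TRACK_KINDS].
#' @param format `"auto"` (by extension), `"bed"`, or `"tsv"`.
#' @param coords coordinate convention for TSV input.
#' @return a [cnv_track()].
#' @export
parse_track <- function(file, kind,
                        format = c("auto", "bed", "tsv"),
                        coords = c("1-based-inclusive", "0-based-half-open")) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  kind <- match.arg(kind, TRACK_KINDS)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", file, ignore.case = TRUE)) "bed" else "tsv"
  }

  if (format == "bed") {
    tab <- tryCatch(
      utils::read.table(file, header = FALSE, colClasses = "character",
                        comment.char = "#"),
      error = function(e) data.frame())
    if (!nrow(tab)) return(empty_track(kind))
    rec <- data.frame(chrom = tab[[1]], start = as.numeric(tab[[2]]),
                      end = as.numeric(tab[[3]]))
    if (ncol(tab) >= 4) rec$label <- tab[[4]]
    if (ncol(tab) >= 5) rec$cnv_type <- tab[[5]]
    if (ncol(tab) >= 6) {
      attr_col <- tab[[6]]
      if (kind == "benign_population") {
        rec$support_individuals <- as.integer(attr_col)
      } else if (kind == "affected") {
        rec$curation_status <- attr_col
      } else if (kind == "gene") {
        rec$is_omim <- attr_col %in% c("TRUE", "true", "1")
      }
    }
    return(cnv_track(rec, kind))
  }

  first <- readLines(file, n = 1)
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("coords:\\s*(\\S+)", first))[[1]]
    if (length(m) == 2 &&
        m[2] %in% c("1-based-inclusive", "0-based-half-open")) {
      coords <- m[2]
    }
  }
  tab <- utils::read.delim(file, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (!nrow(tab)) return(empty_track(kind))
  stopifnot(all(c("chrom", "start", "end") %in% names(tab)))
  rec <- tab[intersect(c("chrom", "start", "end", "cnv_type",
                         "support_individuals", "curation_status", "is_omim",
                         "label"), names(tab))]
  rec$start <- as.numeric(rec$start)
  rec$end <- as.numeric(rec$end)
  if (!is.null(rec$support_individuals)) {
    rec$support_individuals <- as.integer(rec$support_individuals)
  }
  if (!is.null(rec$is_omim)) {
    rec$is_omim <- rec$is_omim %in% c("TRUE", "true", "1")
  }
  if (coords == "1-based-inclusive") {
    rec$start <- display_to_internal_start(rec$start)
  }
  cnv_track(rec, kind)
}

#' Write a reference track as TSV
#'
#' Writes display (1-based inclusive) coordinates with a leading comment line
#' declaring the convention, so [parse_track()] round-trips the file.
#'
#' @param track a [cnv_track()].
#' @param file output path.
#' @export
write_track <- function(track, file) {
  stopifnot(inherits(track, "cnv_track"))
  out <- track$records
  out$start <- internal_to_display_start(out$start)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# coords: 1-based-inclusive", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write classified CNV calls
#'
#' Tab-delimited audit output in display coordinates: one row per call with
#' its size, tier label, reclassification state, the rule that fired and the
#' semicolon-joined trail of rules tested.
#'
#' @param classified data.frame from [classify_cnvs()] (possibly after
#'   [reclassify_recurrent()]).
#' @param file output path.
#' @export
write_classified_table <- function(classified, file) {
  out <- data.frame(sample_id = classified$sample_id,
                    chrom = classified$chrom,
                    start = internal_to_display_start(classified$start),
                    end = classified$end,
                    size_bp = classified$end - classified$start,
                    cnv_type = classified$cnv_type,
                    probe_count = classified$probe_count,
                    platform = classified$platform,
                    label = classified$label,
                    original_label = classified$original_label,
                    reclassified = classified$reclassified,
                    rule = classified$rule,
                    rule_trail = classified$rule_trail)
  write_tsv_atomic(out, file)
}
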