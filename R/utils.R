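#' Round half away from zero
#'
#' Cohort percentages and per-patient means are reported at one decimal with
#' ties rounded away from zero (so 2.35 -> 2.4), unlike base [round()], which
#' rounds ties to even. A tiny epsilon guards against binary representation of
#' values that are exact halves in decimal.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return `x` rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(2.35, -2.35, 82.15), 1)
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Write a text table atomically: tmp file in the same directory, then rename.
write_tsv_atomic <- function(df, path, ...) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", ...)
  file.rename(tmp, path)
  invisible(path)
}
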