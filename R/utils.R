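`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x A character scalar over `A/C/G/T/N` (case-insensitive).
#' @return A character scalar, the reverse complement in upper case.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

## fast char-vector view of a sequence string
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_gap <- function(ch) ch == "-"

## runs of TRUE in a logical vector -> matrix of (start, end), 1-based closed
logical_runs <- function(keep) {
  r <- rle(keep)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  cbind(start = start[r$values], end = end[r$values])
}
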