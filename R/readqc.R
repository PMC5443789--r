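# Read-quality filter: truncate at the first base below the Phred
# threshold, then drop reads too short to be informative.

#' Truncate one read at its first low-quality base
#'
#' Keeps the longest prefix in which every quality is at least
#' `threshold`; the base below threshold and everything after it are
#' removed.  "Below" is strict, so a Q30 base is retained at the default
#' threshold.
#'
#' @param bases DNA string.
#' @param quals integer Phred scores, one per base.
#' @param threshold Phred threshold (default 30).
#' @return list with truncated `bases` and `quals` (possibly empty).
#' @export
truncate_at_first_low_quality <- function(bases, quals, threshold = 30L) {
  stopifnot(nchar(bases) == length(quals))
  if (length(quals) > 0 && (any(quals < 0L) || any(quals > 93L))) {
    stop("Phred scores must lie in [0, 93]", call. = FALSE)
  }
  first_bad <- match(TRUE, quals < threshold)
  keep <- if (is.na(first_bad)) length(quals) else first_bad - 1L
  list(bases = substr(bases, 1L, keep), quals = quals[seq_len(keep)])
}

#' Quality-truncate a whole read set
#'
#' Vectorized [truncate_at_first_low_quality()] over a read tibble with
#' Phred+33 quality strings.
#'
#' @param reads tibble with columns `bases` and `qual`.
#' @param threshold Phred threshold (default 30).
#' @return the tibble with truncated `bases`/`qual`.
#' @export
truncate_reads <- function(reads, threshold = 30L) {
  keep <- vapply(reads$qual, function(q) {
    qq <- phred_decode(q)
    fb <- match(TRUE, qq < threshold)
    if (is.na(fb)) length(qq) else fb - 1L
  }, integer(1), USE.NAMES = FALSE)
  reads$bases <- substr(reads$bases, 1L, keep)
  reads$qual <- substr(reads$qual, 1L, keep)
  reads
}

#' Drop reads shorter than a minimum length
#'
#' @param reads read tibble (after [truncate_reads()]).
#' @param min_length minimum surviving length (default 50, enough to span
#'   a 30-bp window plus anchor sequence).
#' @return list with the filtered `reads` and a `tally`
#'   (`input`, `kept`, `discarded`; `kept + discarded == input`).
#' @export
filter_short <- function(reads, min_length = 50L) {
  stopifnot(min_length >= 0L)
  ok <- nchar(reads$bases) >= min_length
  list(reads = reads[ok, , drop = FALSE],
       tally = c(input = length(ok), kept = sum(ok),
                 discarded = sum(!ok)))
}
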