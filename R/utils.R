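# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T/N (case preserved for ACGT,
#'   anything else becomes N).
#' @return the reverse-complemented string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  cpp_revcomp(x)
}

# substring by 0-based half-open interval
substr0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

# decode/encode Phred+33 quality strings
phred_decode <- function(qual) {
  if (nchar(qual) == 0L) return(integer(0))
  utf8ToInt(qual) - 33L
}

phred_encode <- function(q) {
  if (length(q) == 0L) return("")
  intToUtf8(q + 33L)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

assert_dna <- function(x, name, allow_n = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(sprintf("`%s` must be a non-empty DNA string", name), call. = FALSE)
  }
  pat <- if (allow_n) "^[ACGTNacgtn]+$" else "^[ACGTacgt]+$"
  if (!grepl(pat, x)) {
    stop(sprintf("`%s` contains non-DNA characters", name), call. = FALSE)
  }
  invisible(toupper(x))
}
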