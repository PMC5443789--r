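#' Describe an edited allele as indel events on a reference amplicon
#'
#' An allele specification is an ordered list of indel events, each a
#' deletion, an insertion, or a combination (deletion with replacement
#' bases), applied to the reference amplicon.  Events are 0-based: a
#' deletion at `position` removes the half-open interval
#' `[position, position + deleted_length)`; an insertion at `position`
#' places its bases immediately before the reference base at `position`.
#'
#' @param events data frame with columns `position` (0-based integer),
#'   `deleted_length` (non-negative integer) and `inserted_bases`
#'   (character, possibly "").  Events must be sorted by position and their
#'   deleted intervals must not overlap; an event deleting nothing and
#'   inserting nothing is rejected.
#' @param label character label for the allele (e.g. `"WT"`, `"del3"`).
#' @return an object of class `allele_spec`.
#' @examples
#' wt <- allele_spec(label = "WT")
#' del3 <- allele_spec(data.frame(position = 37, deleted_length = 3,
#'                                inserted_bases = ""), label = "del3")
#' @export
allele_spec <- function(events = NULL, label = "allele") {
  if (is.null(events) || nrow(events) == 0L) {
    events <- data.frame(position = integer(0), deleted_length = integer(0),
                         inserted_bases = character(0),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(events),
            all(c("position", "deleted_length", "inserted_bases") %in% names(events)))
  events$position <- as.integer(events$position)
  events$deleted_length <- as.integer(events$deleted_length)
  events$inserted_bases <- toupper(as.character(events$inserted_bases))
  if (any(events$position < 0L) || any(events$deleted_length < 0L)) {
    stop("event positions and deleted lengths must be non-negative", call. = FALSE)
  }
  if (any(events$deleted_length == 0L & nchar(events$inserted_bases) == 0L)) {
    stop("an event must delete or insert at least one base", call. = FALSE)
  }
  if (is.unsorted(events$position, strictly = FALSE)) {
    stop("events must be sorted by position", call. = FALSE)
  }
  if (nrow(events) > 1L) {
    ends <- events$position + events$deleted_length
    starts_next <- events$position[-1L]
    # a deletion interval may not reach into the next event; two pure
    # insertions at the same coordinate would have ambiguous order
    if (any(starts_next < ends[-nrow(events)]) ||
        any(starts_next == events$position[-nrow(events)])) {
      stop("allele events overlap", call. = FALSE)
    }
  }
  structure(list(events = events, label = label), class = "allele_spec")
}

#' @export
print.allele_spec <- function(x, ...) {
  cat(sprintf("<allele_spec> %s: %d event(s)\n", x$label, nrow(x$events)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

# total length change of an allele
allele_length_delta <- function(allele) {
  sum(nchar(allele$events$inserted_bases)) - sum(allele$events$deleted_length)
}

#' Apply an allele specification to a reference sequence
#'
#' @param reference DNA string.
#' @param allele an [allele_spec()].
#' @return the mutated DNA string; its length equals
#'   `nchar(reference) - sum(deleted) + sum(inserted)`.
#' @examples
#' apply_allele("ACGT", allele_spec(data.frame(position = 1,
#'   deleted_length = 0, inserted_bases = "TT")))  # "ATTCGT"
#' @export
apply_allele <- function(reference, allele) {
  reference <- assert_dna(reference, "reference", allow_n = TRUE)
  stopifnot(inherits(allele, "allele_spec"))
  ev <- allele$events
  if (nrow(ev) == 0L) return(reference)
  n <- nchar(reference)
  if (any(ev$position > n) || any(ev$position + ev$deleted_length > n)) {
    stop("allele event outside the reference", call. = FALSE)
  }
  pieces <- character(2L * nrow(ev) + 1L)
  cursor <- 0L
  for (k in seq_len(nrow(ev))) {
    pieces[2L * k - 1L] <- substr0(reference, cursor, ev$position[k])
    pieces[2L * k] <- ev$inserted_bases[k]
    cursor <- ev$position[k] + ev$deleted_length[k]
  }
  pieces[2L * nrow(ev) + 1L] <- substr0(reference, cursor, n)
  paste(pieces, collapse = "")
}

#' Map a reference coordinate onto allele (alternate) coordinates
#'
#' Positions inside a deleted interval map to the left edge of the deletion
#' on the alternate sequence.
#'
#' @param position 0-based reference coordinate (inter-base coordinates are
#'   also valid input).
#' @param allele an [allele_spec()].
#' @return the corresponding 0-based coordinate on the mutated sequence.
#' @export
map_ref_to_alt <- function(position, allele) {
  stopifnot(inherits(allele, "allele_spec"))
  ev <- allele$events
  vapply(position, function(pos) {
    shift <- 0
    for (k in seq_len(nrow(ev))) {
      p <- ev$position[k]
      dl <- ev$deleted_length[k]
      il <- nchar(ev$inserted_bases[k])
      if (pos >= p + dl && pos > p) {
        shift <- shift + il - dl
      } else if (pos == p && dl == 0L) {
        # insertion sits before the base at p: that base moves right
        shift <- shift + il
      } else if (pos > p && pos < p + dl) {
        return(p + shift)  # inside the deleted interval: left edge
      }
    }
    pos + shift
  }, numeric(1))
}
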