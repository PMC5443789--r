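#' Alignment scoring scheme
#'
#' Affine gap model: a gap of length L costs `gap_open + L * gap_extend`.
#' Defaults (+1 / -2 / -5 / -1) keep a single long nickase deletion
#' (tens of bp) as one event instead of fragmenting it, and make one
#' substitution always preferable to a compensating gap pair.
#'
#' @param match,mismatch,gap_open,gap_extend numeric scores; `match` must
#'   exceed `mismatch` and gap penalties must be negative.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = -5,
                           gap_extend = -1) {
  if (!(match > mismatch)) stop("match score must exceed mismatch", call. = FALSE)
  if (gap_open >= 0 || gap_extend >= 0) {
    stop("gap penalties must be negative", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

OP_KIND_NAMES <- c(M = "match", X = "mismatch", D = "deletion",
                   I = "insertion")

# cheap data.frame constructor for per-read op tables (hot path)
ops_frame <- function(raw) {
  k <- length(raw$op_kind)
  structure(list(kind = unname(OP_KIND_NAMES[as.character(raw$op_kind)]),
                 length = as.integer(raw$op_len),
                 inserted_bases = as.character(raw$op_ins)),
            class = "data.frame", row.names = seq_len(k))
}

finish_alignment <- function(raw, read, scheme, min_score_fraction, read_id) {
  ops <- ops_frame(raw)
  structure(list(read_id = read_id,
                 score = raw$score,
                 ref_start = raw$ref_start,
                 ref_end = raw$ref_end,
                 strand = raw$strand,
                 ops = ops,
                 aligned = raw$score >=
                   min_score_fraction * nchar(read) * scheme$match),
            class = "amplicon_alignment")
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  cig <- paste0(x$ops$length,
                c(match = "=", mismatch = "X", deletion = "D",
                  insertion = "I")[x$ops$kind], collapse = "")
  cat(sprintf("<amplicon_alignment> %s ref [%d,%d) score %.1f %s aligned=%s\n",
              x$strand, x$ref_start, x$ref_end, x$score, cig, x$aligned))
  invisible(x)
}

#' Semi-global alignment of a read to an amplicon
#'
#' Global in the read, with free end-gaps on the amplicon, optimal under
#' the affine-gap scheme.  The reverse complement of the read is also
#' tried and the better score wins (forward on ties).  Tie-breaking among
#' equal-scoring paths is deterministic: diagonal over deletion over
#' insertion, smallest `ref_end` at the end; [left_normalize()] then
#' canonicalizes indel placement in repeats.
#'
#' @param read,amplicon non-empty DNA strings.
#' @param scheme a [scoring_scheme()].
#' @param min_score_fraction a read is flagged `aligned = FALSE` when its
#'   score is below `min_score_fraction * nchar(read) * match`.
#' @param both_strands also try the reverse complement (default TRUE).
#' @param read_id optional identifier carried into the result.
#' @return an `amplicon_alignment`: `score`, `ref_start`/`ref_end` (0-based
#'   half-open amplicon span), `strand`, `ops` (run-length encoded
#'   match/mismatch/deletion/insertion ops) and the `aligned` flag.
#' @export
semiglobal_align <- function(read, amplicon, scheme = scoring_scheme(),
                             min_score_fraction = 0.6, both_strands = TRUE,
                             read_id = NA_character_) {
  read <- assert_dna(read, "read", allow_n = TRUE)
  amplicon <- assert_dna(amplicon, "amplicon", allow_n = TRUE)
  raw <- cpp_align_one(read, amplicon, scheme$match, scheme$mismatch,
                       scheme$gap_open, scheme$gap_extend,
                       both_strands, FALSE)
  finish_alignment(raw, read, scheme, min_score_fraction, read_id)
}

#' Align a batch of reads to one amplicon
#'
#' Same contract as [semiglobal_align()] applied to each read, with two
#' exact or conservative shortcuts for throughput: reads placeable
#' ungapped with at most one mismatch skip the dynamic program (such
#' placements are provably optimal under the default scheme), and when
#' `strand_vote = TRUE` a k-mer vote skips the reverse-complement dynamic
#' program when one orientation shares 12-mers with the amplicon and the
#' other shares none (indecisive votes fall back to aligning both).
#'
#' @param reads character vector of read sequences.
#' @inheritParams semiglobal_align
#' @param read_ids optional identifiers.
#' @param strand_vote enable the k-mer strand shortcut.
#' @return list of `amplicon_alignment` objects.
#' @export
align_reads <- function(reads, amplicon, scheme = scoring_scheme(),
                        min_score_fraction = 0.6, both_strands = TRUE,
                        strand_vote = TRUE, read_ids = NULL) {
  amplicon <- assert_dna(amplicon, "amplicon", allow_n = TRUE)
  if (length(reads) == 0L) return(list())
  raws <- cpp_align_batch(toupper(reads), amplicon, scheme$match,
                          scheme$mismatch, scheme$gap_open,
                          scheme$gap_extend, both_strands, strand_vote)
  ids <- read_ids %||% rep(NA_character_, length(reads))
  lapply(seq_along(raws), function(i) {
    finish_alignment(raws[[i]], reads[i], scheme, min_score_fraction, ids[i])
  })
}

#' Align reads against several amplicons, assigning each to its best
#'
#' Each read is assigned to the amplicon with the best alignment score
#' (k-mer pre-vote for speed); reads tied between amplicons are dropped
#' (`ref_index = NA`).
#'
#' @param amplicons named character vector of amplicon sequences.
#' @inheritParams align_reads
#' @return list of `amplicon_alignment` objects with an extra
#'   `amplicon_id` field (`NA` for dropped ties).
#' @export
align_reads_multi <- function(reads, amplicons, scheme = scoring_scheme(),
                              min_score_fraction = 0.6, both_strands = TRUE,
                              strand_vote = TRUE, read_ids = NULL) {
  stopifnot(length(amplicons) >= 1L, !is.null(names(amplicons)))
  if (length(reads) == 0L) return(list())
  raws <- cpp_align_batch_multi(toupper(reads), toupper(amplicons),
                                scheme$match, scheme$mismatch,
                                scheme$gap_open, scheme$gap_extend,
                                both_strands, strand_vote)
  ids <- read_ids %||% rep(NA_character_, length(reads))
  lapply(seq_along(raws), function(i) {
    a <- finish_alignment(raws[[i]], reads[i], scheme, min_score_fraction,
                          ids[i])
    ri <- raws[[i]]$ref_index
    a$amplicon_id <- if (ri == 0L) NA_character_ else names(amplicons)[ri]
    a
  })
}

#' Independent reference score for validation
#'
#' Recomputes the optimal semi-global score by a memoized top-down
#' recursion over sequence suffixes, sharing no code with the production
#' dynamic program.  Single strand; intended for tests and audits, not for
#' throughput.
#'
#' @inheritParams semiglobal_align
#' @return the optimal score (a single number).
#' @export
semiglobal_score_reference <- function(read, amplicon,
                                       scheme = scoring_scheme()) {
  cpp_reference_score(toupper(read), toupper(amplicon), scheme$match,
                      scheme$mismatch, scheme$gap_open, scheme$gap_extend)
}

#' Extract indel variants from an alignment
#'
#' One variant per insertion/deletion op, in amplicon coordinates.
#' Mismatches are not variants: substitutions never count as editing.
#'
#' @param aln an `amplicon_alignment` with `aligned = TRUE`.
#' @return data frame with `ref_position` (0-based; deletion start, or
#'   insertion anchor point), `kind`, `length`, `inserted_bases`.
#' @export
extract_variants <- function(aln) {
  stopifnot(inherits(aln, "amplicon_alignment"))
  if (!isTRUE(aln$aligned)) {
    stop("cannot extract variants from an unaligned read", call. = FALSE)
  }
  kind <- aln$ops$kind
  len <- aln$ops$length
  # reference position before each op: M/X/D consume reference, I does not
  adv <- ifelse(kind == "insertion", 0L, len)
  before <- aln$ref_start + c(0L, cumsum(adv))[seq_along(kind)]
  keep <- kind == "deletion" | kind == "insertion"
  structure(list(ref_position = as.integer(before[keep]),
                 kind = kind[keep],
                 length = len[keep],
                 inserted_bases = ifelse(kind[keep] == "deletion", "",
                                         aln$ops$inserted_bases[keep])),
            class = "data.frame", row.names = seq_len(sum(keep)))
}

left_normalize_one <- function(ref_position, kind, length, inserted_bases,
                               amplicon) {
  p <- ref_position
  n <- nchar(amplicon)
  base_at <- function(i) substr(amplicon, i + 1L, i + 1L)  # 0-based
  if (kind == "deletion") {
    while (p > 0L && base_at(p - 1L) == base_at(p + length - 1L)) {
      p <- p - 1L
    }
    list(ref_position = p, inserted_bases = inserted_bases)
  } else {
    s <- strsplit(inserted_bases, "")[[1]]
    k <- base::length(s)
    while (p > 0L && s[k] == base_at(p - 1L)) {
      s <- c(base_at(p - 1L), s[-k])
      p <- p - 1L
    }
    list(ref_position = p, inserted_bases = paste(s, collapse = ""))
  }
}

#' Left-normalize indel variants
#'
#' Shifts each variant to the smallest reference position that yields an
#' identical alternate sequence (the standard left-alignment used for VCF
#' normalization), so window membership is well-defined inside repeats.
#' Idempotent.
#'
#' @param variants variant tibble from [extract_variants()].
#' @param amplicon the reference amplicon the coordinates refer to.
#' @return the variant tibble with normalized positions (insertions may
#'   also have their inserted bases rotated).
#' @export
left_normalize <- function(variants, amplicon) {
  if (nrow(variants) == 0L) return(variants)
  for (k in seq_len(nrow(variants))) {
    nz <- left_normalize_one(variants$ref_position[k], variants$kind[k],
                             variants$length[k], variants$inserted_bases[k],
                             amplicon)
    variants$ref_position[k] <- nz$ref_position
    variants$inserted_bases[k] <- nz$inserted_bases
  }
  variants
}

#' Export alignments as SAM for inspection in standard viewers
#'
#' Minimal single-reference SAM: CIGAR from the ops (`M/X` emitted as `M`),
#' mapping quality 255, unaligned reads emitted as unmapped records.
#'
#' @param alignments list of `amplicon_alignment`.
#' @param reads character vector of the read sequences (aligned strand is
#'   written as stored; reverse-complemented reads get flag 16).
#' @param quals optional Phred+33 quality strings.
#' @param amplicon_id,amplicon_length reference name and length.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, quals = NULL, amplicon_id,
                      amplicon_length, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", amplicon_id, amplicon_length)),
             con)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    qid <- if (is.na(a$read_id)) sprintf("read%d", i) else a$read_id
    q <- if (is.null(quals)) "*" else quals[i]
    seqout <- if (a$strand == "-") revcomp(reads[i]) else toupper(reads[i])
    if (!isTRUE(a$aligned)) {
      writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                         qid, seqout, q), con)
      next
    }
    cig <- paste0(a$ops$length,
                  c(match = "M", mismatch = "M", deletion = "D",
                    insertion = "I")[a$ops$kind], collapse = "")
    flag <- if (a$strand == "-") 16L else 0L
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s",
                       qid, flag, amplicon_id, a$ref_start + 1L, cig,
                       seqout, q), con)
  }
  invisible(path)
}
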