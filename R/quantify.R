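# End-to-end editing quantification of one locus: QC -> alignment ->
# variant extraction -> window classification -> rates.

#' Default analysis parameters
#'
#' Quality threshold 30 (bases below Q30 truncate the read), minimum
#' surviving read length 50, editing-window halfwidth 15 (a 30-bp window),
#' 30-bp control window 50 bp away from the cut, alignment acceptance at
#' 60% of the maximum score.
#'
#' @param quality_threshold Phred truncation threshold.
#' @param min_length minimum read length after truncation.
#' @param halfwidth editing-window halfwidth in bp.
#' @param control_gap,control_size control-window geometry in bp.
#' @param min_score_fraction alignment acceptance threshold.
#' @param scheme a [scoring_scheme()].
#' @param both_strands align the reverse complement too.
#' @param strand_vote k-mer strand shortcut in batch alignment.
#' @return list of parameters.
#' @export
quant_params <- function(quality_threshold = 30L, min_length = 50L,
                         halfwidth = 15L, control_gap = 50L,
                         control_size = 30L, min_score_fraction = 0.6,
                         scheme = scoring_scheme(), both_strands = TRUE,
                         strand_vote = TRUE) {
  stopifnot(quality_threshold > 0L, min_length >= 0L, halfwidth >= 1L,
            control_gap > 0L, control_size > 0L,
            min_score_fraction > 0, min_score_fraction <= 1)
  list(quality_threshold = as.integer(quality_threshold),
       min_length = as.integer(min_length),
       halfwidth = as.integer(halfwidth),
       control_gap = as.integer(control_gap),
       control_size = as.integer(control_size),
       min_score_fraction = min_score_fraction,
       scheme = scheme, both_strands = isTRUE(both_strands),
       strand_vote = isTRUE(strand_vote))
}

# control window anchored at the rightmost cut, falling back to the left
# of the leftmost cut; always disjoint from the editing window because
# control_gap exceeds halfwidth
locus_control_window <- function(cuts, params, amplicon_length) {
  right <- max(cuts)
  if (right + params$control_gap + params$control_size <= amplicon_length) {
    return(window_spec(right + params$control_gap,
                       right + params$control_gap + params$control_size,
                       "control"))
  }
  left <- min(cuts)
  if (left - params$control_gap - params$control_size >= 0L) {
    return(window_spec(left - params$control_gap - params$control_size,
                       left - params$control_gap, "control"))
  }
  stop("control window fits on neither side of the cut(s)", call. = FALSE)
}

#' Quantify editing at one locus from a read set
#'
#' Runs the full per-locus analysis: Phred-threshold read truncation and
#' length filtering, semi-global alignment to the amplicon, indel
#' extraction with left-normalization, classification against the editing
#' window (and the displaced control window), and rate computation.
#'
#' @param reads read tibble (`read_id`, `bases`, `qual`), e.g. from
#'   [simulate_reads()] or [read_fastq()].
#' @param amplicon reference amplicon sequence.
#' @param cuts one cut coordinate (Cas9) or two (paired nickase).
#' @param locus_id locus label for the report.
#' @param params a [quant_params()] list.
#' @param control include the control window (default TRUE).
#' @return list: `report` (one-row tibble from [editing_rate()]),
#'   `tally` (read-accounting vector whose stages conserve counts), and
#'   `per_read` (read-level classifications).
#' @export
quantify_locus <- function(reads, amplicon, cuts, locus_id = "locus",
                           params = quant_params(), control = TRUE) {
  amplicon <- assert_dna(amplicon, "amplicon", allow_n = TRUE)
  n_input <- nrow(reads)
  reads <- truncate_reads(reads, params$quality_threshold)
  fl <- filter_short(reads, params$min_length)
  reads <- fl$reads
  n <- nchar(amplicon)
  win <- if (length(cuts) == 1L) {
    editing_window(cuts, params$halfwidth, n)
  } else {
    nickase_window(cuts[1], cuts[2], params$halfwidth, n)
  }
  cwin <- if (control) locus_control_window(cuts, params, n) else NULL

  alns <- align_reads(reads$bases, amplicon, params$scheme,
                      params$min_score_fraction, params$both_strands,
                      params$strand_vote, read_ids = reads$read_id)
  aligned <- vapply(alns, function(a) isTRUE(a$aligned), logical(1))

  which_al <- which(aligned)
  site_status <- character(length(which_al))
  control_status <- character(length(which_al))
  for (k in seq_along(which_al)) {
    a <- alns[[which_al[k]]]
    v <- left_normalize(extract_variants(a), amplicon)
    site_status[k] <- classify_read(v, a, win)
    if (control) control_status[k] <- classify_read(v, a, cwin)
  }
  report <- editing_rate(locus_id, sum(aligned), site_status,
                         if (control) control_status else NULL)
  tally <- c(input = n_input, qc_kept = unname(fl$tally["kept"]),
             qc_discarded = unname(fl$tally["discarded"]),
             aligned = sum(aligned), unaligned = sum(!aligned),
             edited = sum(site_status == "edited"),
             unedited = sum(site_status == "unedited"),
             uninformative = sum(site_status == "uninformative"))
  per_read <- tibble::tibble(
    read_id = reads$read_id[aligned],
    site = site_status,
    control = if (control) control_status else NA_character_)
  list(report = report, tally = tally, per_read = per_read,
       editing_window = c(win$start, win$end),
       control_window = if (control) c(cwin$start, cwin$end) else NULL)
}
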