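# Pipeline orchestration: file-level runs tying the modules together.
# All file interfaces are plain text (FASTA/FASTQ/TSV/JSON), coordinates
# 0-based half-open, and every run is a pure function of its inputs and
# seed (reports carry no timestamps, so reruns are byte-identical).

REPORT_SCHEMA_VERSION <- "1.0"

events_to_string <- function(allele) {
  ev <- allele$events
  if (nrow(ev) == 0L) return(".")
  paste(sprintf("%d:%d:%s", ev$position, ev$deleted_length,
                ifelse(ev$inserted_bases == "", "-", ev$inserted_bases)),
        collapse = ";")
}

string_to_allele <- function(x, label) {
  if (x == "." || x == "") return(allele_spec(label = label))
  parts <- strsplit(strsplit(x, ";")[[1]], ":")
  ev <- do.call(rbind, lapply(parts, function(p) {
    data.frame(position = as.integer(p[1]), deleted_length = as.integer(p[2]),
               inserted_bases = ifelse(p[3] == "-", "", p[3]),
               stringsAsFactors = FALSE)
  }))
  allele_spec(ev, label)
}

guides_from_sheet <- function(sheet_rows) {
  lapply(seq_len(nrow(sheet_rows)), function(i) {
    guide_site(sheet_rows$locus_id[i], sheet_rows$protospacer[i],
               sheet_rows$pam[i], sheet_rows$strand[i],
               sheet_rows$protospacer_start[i])
  })
}

#' Simulate a complete editing experiment to disk
#'
#' Generates `n_loci` loci, samples one edited allele per locus, simulates
#' reads at the requested edited fractions, and writes
#' `amplicons.fasta`, `reads.fastq`, `loci.tsv` and `truth_alleles.tsv`
#' (the ground-truth mixture, for validation only) into `outdir`.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; all randomness derives from it.
#' @param n_loci number of loci.
#' @param n_reads reads per locus.
#' @param edited_fractions numeric vector (recycled over loci) of true
#'   edited allele fractions.
#' @param mode `"cas9"` or `"nickase"`.
#' @param enzymes enzyme names cycled over loci.
#' @param amplicon_length amplicon length in bp.
#' @param substitution_error_rate per-base substitution error.
#' @param indel_error_rate per-base spurious-indel error (default 0).
#' @return invisibly, the list of file paths written.
#' @export
run_simulate <- function(outdir, seed = 1L, n_loci = 3L, n_reads = 2000L,
                         edited_fractions = 0.5, mode = "cas9",
                         enzymes = c("EcoRI", "SacI", "XbaI", "AgeI"),
                         amplicon_length = 300L,
                         substitution_error_rate = 0.001,
                         indel_error_rate = 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  edited_fractions <- rep_len(edited_fractions, n_loci)
  loci <- lapply(seq_len(n_loci), function(i) {
    generate_locus(seed + i, length = amplicon_length,
                   enzyme_name = enzymes[(i - 1L) %% length(enzymes) + 1L],
                   mode = mode, locus_id = sprintf("locus%02d", i))
  })
  all_reads <- list()
  truth <- list()
  for (i in seq_len(n_loci)) {
    lc <- loci[[i]]
    f <- edited_fractions[i]
    allele <- if (mode == "cas9") {
      sample_nhej_allele(lc, seed + 1000L + i, label = "edit")
    } else {
      sample_nickase_allele(lc, seed + 1000L + i, label = "edit")
    }
    fractions <- if (f >= 1) c(edit = 1) else if (f <= 0) c(WT = 1) else
      c(WT = 1 - f, edit = f)
    cfg <- read_sim_config(n_reads, fractions,
                           substitution_error_rate = substitution_error_rate,
                           indel_error_rate = indel_error_rate,
                           seed = seed + 2000L + i)
    all_reads[[i]] <- simulate_reads(lc, list(allele), cfg)
    truth[[i]] <- data.frame(locus_id = lc$locus_id,
                             label = names(fractions),
                             fraction = unname(fractions),
                             events = vapply(names(fractions), function(lb) {
                               if (lb == "WT") "." else events_to_string(allele)
                             }, character(1)),
                             stringsAsFactors = FALSE)
  }
  paths <- list(
    fasta = file.path(outdir, "amplicons.fasta"),
    fastq = file.path(outdir, "reads.fastq"),
    loci = file.path(outdir, "loci.tsv"),
    truth = file.path(outdir, "truth_alleles.tsv"))
  amps <- vapply(loci, function(lc) lc$amplicon, character(1))
  names(amps) <- vapply(loci, function(lc) lc$locus_id, character(1))
  write_amplicons_fasta(amps, paths$fasta)
  write_reads_fastq(do.call(rbind, all_reads), paths$fastq)
  write_locus_sheet(loci, paths$loci)
  write.table(do.call(rbind, truth), paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Quantify editing rates from FASTQ + FASTA + locus sheet
#'
#' The full analysis: Q30 truncation and length filtering, assignment of
#' each read to its best-scoring amplicon (ties dropped), semi-global
#' alignment, indel extraction and left-normalization, editing- and
#' control-window classification, per-locus rates, and a paired two-sided
#' t-test of site versus control rates when at least two loci report both.
#' Writes `editing_report.tsv` and `editing_report.json` into `outdir`.
#'
#' @param fastq,fasta,locus_sheet input paths.
#' @param outdir output directory.
#' @param params a [quant_params()] list.
#' @return invisibly, the report list (also serialized as JSON).
#' @export
run_quantify <- function(fastq, fasta, locus_sheet, outdir,
                         params = quant_params()) {
  for (p in c(fastq, fasta, locus_sheet)) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p),
                              call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reads <- read_fastq(fastq)
  amps_set <- Biostrings::readDNAStringSet(fasta)
  amps <- as.character(amps_set)
  names(amps) <- sub(" .*", "", names(amps_set))
  sheet <- read_locus_sheet(locus_sheet)

  n_input <- nrow(reads)
  reads <- truncate_reads(reads, params$quality_threshold)
  fl <- filter_short(reads, params$min_length)
  reads <- fl$reads

  if (length(amps) > 1L) {
    alns <- align_reads_multi(reads$bases, amps, params$scheme,
                              params$min_score_fraction,
                              params$both_strands, params$strand_vote,
                              read_ids = reads$read_id)
    assigned <- vapply(alns, function(a) a$amplicon_id %||% NA_character_,
                       character(1))
  } else {
    alns <- align_reads(reads$bases, amps[[1]], params$scheme,
                        params$min_score_fraction, params$both_strands,
                        params$strand_vote, read_ids = reads$read_id)
    assigned <- rep(names(amps), length(alns))
  }
  aligned <- vapply(alns, function(a) isTRUE(a$aligned), logical(1)) &
    !is.na(assigned)

  reports <- list()
  locus_errors <- list()
  for (lid in unique(sheet$locus_id)) {
    rows <- sheet[sheet$locus_id == lid, , drop = FALSE]
    amp_id <- rows$amplicon_id[1]
    amp <- amps[[amp_id]]
    cuts <- vapply(guides_from_sheet(rows), function(g) g$cut, integer(1))
    idx <- which(aligned & assigned == amp_id)
    win <- if (length(cuts) == 1L) {
      editing_window(cuts, params$halfwidth, nchar(amp))
    } else {
      nickase_window(min(cuts), max(cuts), params$halfwidth, nchar(amp))
    }
    cwin <- locus_control_window(cuts, params, nchar(amp))
    site <- character(length(idx)); ctrl <- character(length(idx))
    for (k in seq_along(idx)) {
      v <- left_normalize(extract_variants(alns[[idx[k]]]), amp)
      site[k] <- classify_read(v, alns[[idx[k]]], win)
      ctrl[k] <- classify_read(v, alns[[idx[k]]], cwin)
    }
    rep_i <- tryCatch(editing_rate(lid, length(idx), site, ctrl),
                      error = function(e) conditionMessage(e))
    if (is.character(rep_i)) locus_errors[[lid]] <- rep_i
    else reports[[lid]] <- rep_i
  }
  report_tab <- if (length(reports)) do.call(rbind, reports) else NULL

  ttest <- NULL
  if (!is.null(report_tab) && nrow(report_tab) >= 2L) {
    ttest <- tryCatch(
      paired_t_test(report_tab$rate, report_tab$control_rate),
      error = function(e) list(error = conditionMessage(e)))
  }
  tally <- c(input = n_input, qc_kept = unname(fl$tally["kept"]),
             qc_discarded = unname(fl$tally["discarded"]),
             aligned = sum(aligned),
             unaligned_or_unassigned = sum(!aligned))
  out <- list(schema_version = REPORT_SCHEMA_VERSION,
              parameters = params[c("quality_threshold", "min_length",
                                    "halfwidth", "control_gap",
                                    "control_size", "min_score_fraction")],
              tally = as.list(tally),
              loci = report_tab,
              locus_errors = locus_errors,
              t_test = ttest)
  if (!is.null(report_tab)) {
    write.table(report_tab, file.path(outdir, "editing_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(out, file.path(outdir, "editing_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(out)
}

#' RFLP rates for ground-truth allele mixtures
#'
#' For each locus in a truth table (as written by [run_simulate()]),
#' computes the molecule-level RFLP rate (uncut fraction) and the
#' molecule-level sequencing editing rate (fraction of alleles with an
#' indel intersecting the editing window), and their difference -- the
#' direction of the RFLP underestimation bias.  Writes `rflp_report.tsv`.
#'
#' @param truth_tsv truth allele table path.
#' @param fasta amplicon FASTA path.
#' @param locus_sheet locus sheet path.
#' @param outdir output directory.
#' @param halfwidth editing-window halfwidth.
#' @return invisibly, the report tibble.
#' @export
run_rflp <- function(truth_tsv, fasta, locus_sheet, outdir, halfwidth = 15L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- read.delim(truth_tsv, stringsAsFactors = FALSE)
  amps_set <- Biostrings::readDNAStringSet(fasta)
  amps <- as.character(amps_set)
  names(amps) <- sub(" .*", "", names(amps_set))
  sheet <- read_locus_sheet(locus_sheet)
  out <- list()
  for (lid in unique(truth$locus_id)) {
    rows <- truth[truth$locus_id == lid, , drop = FALSE]
    srow <- sheet[sheet$locus_id == lid, , drop = FALSE]
    amp <- amps[[srow$amplicon_id[1]]]
    enz <- restriction_enzyme(srow$enzyme[1])
    cuts <- vapply(guides_from_sheet(srow), function(g) g$cut, integer(1))
    win <- if (length(cuts) == 1L) {
      editing_window(cuts, halfwidth, nchar(amp))
    } else {
      nickase_window(min(cuts), max(cuts), halfwidth, nchar(amp))
    }
    sites <- find_sites(amp, enz)
    site <- sites[which.min(abs(sites - mean(cuts)))]
    alleles <- lapply(seq_len(nrow(rows)), function(i) {
      string_to_allele(rows$events[i], rows$label[i])
    })
    rr <- rflp_rate(alleles, rows$fraction, amp, enz, site)
    in_window <- vapply(alleles, function(a) {
      ev <- a$events
      any(ev$position < win$end &
            ev$position + pmax(ev$deleted_length, 0L) >= win$start)
    }, logical(1))
    sr <- sum(rows$fraction[in_window])
    out[[lid]] <- tibble::tibble(locus_id = lid, rflp_rate = rr,
                                 sequencing_rate = sr, delta = sr - rr)
  }
  tab <- do.call(rbind, out)
  write.table(tab, file.path(outdir, "rflp_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Call deletion-clone genotypes from a band-pattern table
#'
#' Input TSV columns: `clone_id`, `junction_band`, `internal_band`
#' (`present`/`absent`).  Writes `clone_calls.tsv`.
#'
#' @param clones_tsv input path.
#' @param outdir output directory.
#' @return invisibly, the calls tibble.
#' @export
run_deletion_genotype <- function(clones_tsv, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab <- read.delim(clones_tsv, stringsAsFactors = FALSE)
  stopifnot(all(c("clone_id", "junction_band", "internal_band") %in% names(tab)))
  calls <- vapply(seq_len(nrow(tab)), function(i) {
    classify_clone(tab$junction_band[i] == "present",
                   tab$internal_band[i] == "present")$call
  }, character(1))
  out <- tibble::tibble(clone_id = tab$clone_id,
                        junction_band = tab$junction_band,
                        internal_band = tab$internal_band, call = calls)
  write.table(out, file.path(outdir, "clone_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Fit episome loss from a decay-series TSV
#'
#' Writes `decay_fit.json` with the per-generation loss rate, initial
#' copies and goodness of fit.
#'
#' @param series_tsv TSV with `day` and `relative_copies`.
#' @param outdir output directory.
#' @param generation_time_hours generation time (default 24 h).
#' @return invisibly, the [fit_loss_rate()] result.
#' @export
run_decay_fit <- function(series_tsv, outdir, generation_time_hours = 24) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  series <- read_decay_series(series_tsv, generation_time_hours)
  fit <- fit_loss_rate(series)
  jsonlite::write_json(unclass(fit), file.path(outdir, "decay_fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}
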