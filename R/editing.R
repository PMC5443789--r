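#' A guide placement on an amplicon
#'
#' The protospacer occupies `[protospacer_start, protospacer_start + 20)`
#' in plus-strand amplicon coordinates regardless of strand.  SpCas9 cuts
#' bluntly 3 nt 5' of the PAM, i.e. between the 17th and 18th protospacer
#' bases, so the inter-base cut coordinate is `protospacer_start + 17` on
#' the plus strand and `protospacer_start + 3` on the minus strand.
#'
#' @param locus_id locus label.
#' @param protospacer 20-nt DNA string (as read on `strand`).
#' @param pam 3-nt PAM (NGG), as read on `strand`.
#' @param strand `"+"` or `"-"`.
#' @param protospacer_start 0-based plus-strand coordinate of the
#'   protospacer interval.
#' @return object of class `guide_site` with a `cut` field.
#' @export
guide_site <- function(locus_id, protospacer, pam, strand, protospacer_start) {
  protospacer <- assert_dna(protospacer, "protospacer")
  if (nchar(protospacer) != 20L) {
    stop("protospacer must be 20 nt", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  pam <- toupper(pam)
  g <- structure(list(locus_id = locus_id, protospacer = protospacer,
                      pam = pam, strand = strand,
                      protospacer_start = as.integer(protospacer_start)),
                 class = "guide_site")
  g$cut <- predicted_cut_site(g)
  g
}

#' @export
print.guide_site <- function(x, ...) {
  cat(sprintf("<guide_site> %s %s%s %s @%d cut=%d\n", x$locus_id, x$protospacer,
              x$pam, x$strand, x$protospacer_start, x$cut))
  invisible(x)
}

#' Predicted Cas9 cleavage coordinate for a guide
#'
#' @param guide a [guide_site()] (the `cut` field is ignored and
#'   recomputed).
#' @return 0-based inter-base coordinate of the blunt cut.
#' @export
predicted_cut_site <- function(guide) {
  stopifnot(inherits(guide, "guide_site"))
  if (nchar(guide$pam) != 3L || substr(guide$pam, 2L, 3L) != "GG") {
    stop(sprintf("PAM '%s' is not NGG", guide$pam), call. = FALSE)
  }
  if (guide$strand == "+") guide$protospacer_start + 17L
  else guide$protospacer_start + 3L
}

window_spec <- function(start, end, role) {
  structure(list(start = as.integer(start), end = as.integer(end),
                 role = role), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %s [%d,%d)\n", x$role, x$start, x$end))
  invisible(x)
}

#' Editing window around a predicted cleavage site
#'
#' A symmetric window of `halfwidth` bases on each side of the cut; the
#' default `halfwidth = 15` gives the 30-bp interval within which read
#' indels count as editing.
#'
#' @param cut 0-based inter-base cut coordinate.
#' @param halfwidth bases on each side of the cut (>= 1).
#' @param amplicon_length amplicon length; the window must fit inside.
#' @return a window of role `"editing"`.
#' @export
editing_window <- function(cut, halfwidth = 15L, amplicon_length) {
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < 1L) stop("halfwidth must be >= 1", call. = FALSE)
  s <- cut - halfwidth
  e <- cut + halfwidth
  if (s < 0L || e > amplicon_length) {
    stop("editing window exceeds the amplicon; use a longer amplicon",
         call. = FALSE)
  }
  window_spec(s, e, "editing")
}

#' Editing window spanning a pair of nick sites
#'
#' Paired-nickase indels shift between the two nick coordinates, so the
#' window runs from `halfwidth` left of the leftmost nick to `halfwidth`
#' right of the rightmost.
#'
#' @param cut_a,cut_b the two nick coordinates.
#' @inheritParams editing_window
#' @export
nickase_window <- function(cut_a, cut_b, halfwidth = 15L, amplicon_length) {
  halfwidth <- as.integer(halfwidth)
  if (halfwidth < 1L) stop("halfwidth must be >= 1", call. = FALSE)
  s <- min(cut_a, cut_b) - halfwidth
  e <- max(cut_a, cut_b) + halfwidth
  if (s < 0L || e > amplicon_length) {
    stop("nickase window exceeds the amplicon; use a longer amplicon",
         call. = FALSE)
  }
  window_spec(s, e, "editing")
}

#' Displaced background control window
#'
#' A `size`-bp interval `gap` bases downstream of the cut (upstream when
#' the amplicon is too short on the right), used to measure the background
#' sequence-variation rate away from the cleavage site.
#'
#' @param cut 0-based cut coordinate.
#' @param size window size in bp (default 30).
#' @param gap distance from the cut (default 50).
#' @param amplicon_length amplicon length.
#' @return a window of role `"control"`.
#' @export
control_window <- function(cut, size = 30L, gap = 50L, amplicon_length) {
  size <- as.integer(size); gap <- as.integer(gap)
  if (size < 1L || gap < 1L) stop("size and gap must be positive", call. = FALSE)
  if (cut + gap + size <= amplicon_length) {
    return(window_spec(cut + gap, cut + gap + size, "control"))
  }
  if (cut - gap - size >= 0L) {
    return(window_spec(cut - gap - size, cut - gap, "control"))
  }
  stop("control window fits on neither side of the cut", call. = FALSE)
}

#' Classify one aligned read against a window
#'
#' A read is informative only when its aligned reference span fully
#' contains the window.  It is `edited` when any variant's reference
#' footprint (the deleted interval, or the insertion anchor point)
#' intersects the window, otherwise `unedited`.
#'
#' @param variants variant table from [extract_variants()], ideally
#'   left-normalized with [left_normalize()].
#' @param aln the [semiglobal_align()] result the variants came from.
#' @param window a [editing_window()] / [control_window()].
#' @return `"edited"`, `"unedited"` or `"uninformative"`.
#' @export
classify_read <- function(variants, aln, window) {
  stopifnot(inherits(window, "window_spec"))
  if (aln$ref_start > window$start || aln$ref_end < window$end) {
    return("uninformative")
  }
  if (nrow(variants) == 0L) return("unedited")
  hit <- vapply(seq_len(nrow(variants)), function(k) {
    p <- variants$ref_position[k]
    if (variants$kind[k] == "deletion") {
      p < window$end && p + variants$length[k] > window$start
    } else {
      # insertion anchor is an inter-base point; boundary anchors touch
      p >= window$start && p <= window$end
    }
  }, logical(1))
  if (any(hit)) "edited" else "unedited"
}

#' Per-locus editing report from classified reads
#'
#' @param locus_id locus label.
#' @param n_aligned number of aligned reads at the locus.
#' @param site_status character vector of [classify_read()] calls against
#'   the editing window (one per aligned read).
#' @param control_status same against the control window, or `NULL` when no
#'   control window exists.
#' @return one-row tibble: `locus_id`, `n_aligned`, `n_window_covering`,
#'   `n_indel`, `rate`, `control_n_covering`, `control_n_indel`,
#'   `control_rate`.
#' @export
editing_rate <- function(locus_id, n_aligned, site_status,
                         control_status = NULL) {
  n_cov <- sum(site_status != "uninformative")
  if (n_cov == 0L) {
    stop(sprintf("locus %s: no read fully covers the editing window",
                 locus_id), call. = FALSE)
  }
  n_indel <- sum(site_status == "edited")
  if (is.null(control_status)) {
    cn <- NA_integer_; ci <- NA_integer_; cr <- NA_real_
  } else {
    cn <- sum(control_status != "uninformative")
    ci <- sum(control_status == "edited")
    cr <- if (cn > 0L) ci / cn else NA_real_
  }
  tibble::tibble(locus_id = locus_id,
                 n_aligned = as.integer(n_aligned),
                 n_window_covering = as.integer(n_cov),
                 n_indel = as.integer(n_indel),
                 rate = n_indel / n_cov,
                 control_n_covering = as.integer(cn),
                 control_n_indel = as.integer(ci),
                 control_rate = cr)
}

#' Paired two-tailed t-test of site rates against background rates
#'
#' The classic paired Student's t-test on the per-locus differences
#' `site - background`: `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom (sample standard deviation).
#'
#' @param site_rates,background_rates numeric vectors, paired by locus.
#' @return list with `t`, `df`, `p_two_sided`, `n_pairs`.
#' @export
paired_t_test <- function(site_rates, background_rates) {
  stopifnot(length(site_rates) == length(background_rates))
  n <- length(site_rates)
  if (n < 2L) stop("paired t-test needs at least 2 pairs", call. = FALSE)
  d <- site_rates - background_rates
  if (all(d == 0)) {
    stop("degenerate input: all paired differences are zero", call. = FALSE)
  }
  ht <- stats::t.test(site_rates, background_rates, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_two_sided = ht$p.value, n_pairs = n)
}
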