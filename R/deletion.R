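# Paired-guide genomic-deletion genotyping: PCR product prediction for
# deleted and intact templates, and the two-primer-pair truth table that
# calls clones WT / monoallelic / biallelic.

#' A PCR primer pair
#'
#' @param forward forward primer sequence (top strand, 5'->3').
#' @param reverse reverse primer sequence (5'->3' on the bottom strand,
#'   i.e. its reverse complement appears on the top strand).
#' @param label `"internal"` (binds inside the deleted interval, detects
#'   the non-deleted allele) or `"junction"` (flanks the interval, its
#'   product only amplifies once the deletion brings the sites together).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, label = c("internal", "junction")) {
  label <- match.arg(label)
  forward <- assert_dna(forward, "forward")
  reverse <- assert_dna(reverse, "reverse")
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    stop("primers must be at least 15 nt", call. = FALSE)
  }
  structure(list(forward = forward, reverse = reverse, label = label),
            class = "primer_pair")
}

#' Remove a genomic interval from a template
#'
#' Models the re-joining of two paired-guide cut coordinates: the output
#' length is the template length minus the interval length.
#'
#' @param template DNA string.
#' @param start,end 0-based half-open interval to delete.
#' @return the deleted template.
#' @export
apply_deletion <- function(template, start, end) {
  template <- assert_dna(template, "template", allow_n = TRUE)
  n <- nchar(template)
  if (start < 0L || end > n || start > end) {
    stop("invalid deletion interval", call. = FALSE)
  }
  paste0(substr0(template, 0L, start), substr0(template, end, n))
}

exact_sites <- function(template, primer) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                Biostrings::DNAString(template))
  Biostrings::start(m) - 1L  # 0-based
}

#' Predict the PCR product of a primer pair on a template
#'
#' Exact full-length binding: the forward primer on the top strand, the
#' reverse complement of the reverse primer downstream of it.  The product
#' runs from the forward primer start to the end of the reverse site.
#' Returns `NA` (no band) when either site is absent, the orientation is
#' wrong, or the product exceeds `max_product` -- the dropout of long
#' templates is what makes junction primers deletion-specific.
#'
#' @param template DNA string.
#' @param pair a [primer_pair()].
#' @param max_product longest amplifiable product in bp (default 3000).
#' @return product length in bp, or `NA_integer_`.
#' @export
predict_pcr <- function(template, pair, max_product = 3000L) {
  stopifnot(inherits(pair, "primer_pair"))
  template <- assert_dna(template, "template", allow_n = TRUE)
  f <- exact_sites(template, pair$forward)
  r <- exact_sites(template, revcomp(pair$reverse))
  if (length(f) > 1L || length(r) > 1L) {
    stop(sprintf("ambiguous design: %s primer binds %d sites", pair$label,
                 max(length(f), length(r))), call. = FALSE)
  }
  if (length(f) == 0L || length(r) == 0L) return(NA_integer_)
  if (f >= r) return(NA_integer_)
  product <- (r + nchar(pair$reverse)) - f
  if (product > max_product) return(NA_integer_)
  as.integer(product)
}

#' A paired-guide deletion design
#'
#' @param template reference DNA.
#' @param deletion_start,deletion_end 0-based half-open interval joined by
#'   the paired cuts.
#' @param internal_pair [primer_pair()] binding inside the interval
#'   (label `"internal"`).
#' @param junction_pair [primer_pair()] flanking the interval
#'   (label `"junction"`).
#' @param max_product amplifiable-product cutoff used for both assays.
#' @return object of class `deletion_design`.
#' @export
deletion_design <- function(template, deletion_start, deletion_end,
                            internal_pair, junction_pair,
                            max_product = 600L) {
  template <- assert_dna(template, "template", allow_n = TRUE)
  stopifnot(inherits(internal_pair, "primer_pair"),
            inherits(junction_pair, "primer_pair"),
            internal_pair$label == "internal",
            junction_pair$label == "junction")
  if (!(deletion_start < deletion_end) || deletion_start < 0L ||
      deletion_end > nchar(template)) {
    stop("invalid deletion interval", call. = FALSE)
  }
  structure(list(template = template,
                 deletion_start = as.integer(deletion_start),
                 deletion_end = as.integer(deletion_end),
                 internal_pair = internal_pair,
                 junction_pair = junction_pair,
                 max_product = as.integer(max_product)),
            class = "deletion_design")
}

#' Call a clone genotype from the two-band pattern
#'
#' Junction band present + internal band absent: both alleles deleted
#' (biallelic).  Both bands: one allele each (monoallelic).  Internal
#' only: no deletion (WT).  Neither: the assay failed.
#'
#' @param junction_band,internal_band logical band presence.
#' @return list of class `clone_call` with the bands and the `call`.
#' @export
classify_clone <- function(junction_band, internal_band) {
  stopifnot(is.logical(junction_band), is.logical(internal_band))
  call <- if (junction_band && !internal_band) "biallelic"
  else if (junction_band && internal_band) "monoallelic"
  else if (!junction_band && internal_band) "WT"
  else "assay_failure"
  structure(list(junction_band = junction_band,
                 internal_band = internal_band, call = call),
            class = "clone_call")
}

#' @export
print.clone_call <- function(x, ...) {
  cat(sprintf("<clone_call> junction=%s internal=%s -> %s\n",
              ifelse(x$junction_band, "present", "absent"),
              ifelse(x$internal_band, "present", "absent"), x$call))
  invisible(x)
}

#' Genotype a simulated clone from its two allele sequences
#'
#' Runs both PCR assays on each allele; a band is present when any allele
#' yields a product.
#'
#' @param design a [deletion_design()].
#' @param allele_deleted logical vector of length 2: is each allele
#'   deleted?
#' @return a [classify_clone()] result.
#' @export
genotype_deletion_clone <- function(design, allele_deleted) {
  stopifnot(length(allele_deleted) == 2L, is.logical(allele_deleted))
  alleles <- lapply(allele_deleted, function(del) {
    if (del) apply_deletion(design$template, design$deletion_start,
                            design$deletion_end)
    else design$template
  })
  band <- function(pair) {
    any(!is.na(vapply(alleles, predict_pcr, integer(1), pair = pair,
                      max_product = design$max_product)))
  }
  classify_clone(band(design$junction_pair), band(design$internal_pair))
}

#' Generate a random deletion design for simulation
#'
#' Random template with a deletion interval of `deletion_length` bp
#' (default 319, a typical exon-scale deletion), an internal pair inside
#' the interval and a junction pair whose intact product exceeds
#' `max_product` but whose deleted product does not.
#'
#' @param seed integer seed.
#' @param template_length template length (default 1200).
#' @param deletion_length deleted interval length (default 319).
#' @param primer_length primer length (default 20).
#' @param arm junction-primer distance from the cut coordinates
#'   (default 150 bp each side).
#' @param max_product amplifiable-product cutoff (default 600).
#' @return a [deletion_design()].
#' @export
simulate_deletion_design <- function(seed, template_length = 1200L,
                                     deletion_length = 319L,
                                     primer_length = 20L, arm = 150L,
                                     max_product = 600L) {
  stopifnot(2L * arm <= max_product,
            2L * arm + deletion_length > max_product)
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      template <- random_dna(template_length)
      dstart <- (template_length - deletion_length) %/% 2L
      dend <- dstart + deletion_length
      int_f <- substr0(template, dstart + 20L, dstart + 20L + primer_length)
      int_r <- revcomp(substr0(template, dend - 20L - primer_length, dend - 20L))
      jun_f <- substr0(template, dstart - arm, dstart - arm + primer_length)
      jun_r <- revcomp(substr0(template, dend + arm - primer_length, dend + arm))
      des <- try(deletion_design(template, dstart, dend,
                                 primer_pair(int_f, int_r, "internal"),
                                 primer_pair(jun_f, jun_r, "junction"),
                                 max_product), silent = TRUE)
      if (inherits(des, "deletion_design")) {
        # reject templates where a primer happens to bind twice
        ok <- !inherits(try(genotype_deletion_clone(des, c(FALSE, TRUE)),
                            silent = TRUE), "try-error")
        if (ok) return(des)
      }
    }
    stop("could not generate an unambiguous design", call. = FALSE)
  })
}
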