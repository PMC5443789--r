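#' Built-in restriction enzymes
#'
#' Recognition sites (IUPAC, top strand, 5'->3') and top-strand cut offsets
#' for the enzymes used in the RFLP editing assays, plus EcoRI for
#' examples.  `cut_offset` is the 0-based position of the top-strand cut
#' within the recognition site (blunt-cut approximation: only top-strand
#' cut positions define fragment lengths, which is all a gel can resolve).
#'
#' @format data frame with columns `name`, `recognition`, `cut_offset`.
#' @export
builtin_enzymes <- function() {
  data.frame(
    name        = c("SacI", "AgeI", "XbaI", "BstXI", "EcoRI"),
    recognition = c("GAGCTC", "ACCGGT", "TCTAGA", "CCANNNNNNTGG", "GAATTC"),
    cut_offset  = c(5L, 1L, 1L, 8L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Construct a restriction enzyme
#'
#' @param name enzyme name; if `recognition` is omitted it is looked up in
#'   [builtin_enzymes()].
#' @param recognition IUPAC recognition sequence (length >= 4).
#' @param cut_offset 0-based top-strand cut position within the site.
#' @return object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition = NULL, cut_offset = NULL) {
  if (is.null(recognition)) {
    tab <- builtin_enzymes()
    hit <- match(name, tab$name)
    if (is.na(hit)) {
      stop(sprintf("unknown enzyme '%s'; built-ins are %s", name,
                   paste(tab$name, collapse = ", ")), call. = FALSE)
    }
    recognition <- tab$recognition[hit]
    cut_offset <- tab$cut_offset[hit]
  }
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) {
    stop("recognition site must be at least 4 bases", call. = FALSE)
  }
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must lie within the recognition site", call. = FALSE)
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("<restriction_enzyme> %s %s^ at %d\n",
              x$name, x$recognition, x$cut_offset))
  invisible(x)
}

#' Load additional enzymes from a TSV table
#'
#' @param path TSV with columns `name`, `recognition`, `cut_offset`.
#' @return list of `restriction_enzyme` objects keyed by name.
#' @export
load_enzyme_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition", "cut_offset") %in% names(tab)))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    restriction_enzyme(tab$name[i], tab$recognition[i], tab$cut_offset[i])
  })
  names(out) <- tab$name
  out
}

iupac_palindromic <- function(recognition) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
  identical(rc, recognition)
}

#' Find restriction cut coordinates in a sequence
#'
#' IUPAC-aware search on the top strand and, for non-palindromic sites, on
#' the reverse complement projected back to top-strand coordinates.
#' Palindromic sites are reported once.
#'
#' @param sequence DNA string.
#' @param enzyme a [restriction_enzyme()].
#' @return sorted integer vector of 0-based inter-base cut coordinates
#'   strictly inside the sequence.
#' @export
find_sites <- function(sequence, enzyme) {
  sequence <- assert_dna(sequence, "sequence", allow_n = TRUE)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  subject <- Biostrings::DNAString(sequence)
  L <- nchar(enzyme$recognition)
  fwd <- Biostrings::matchPattern(Biostrings::DNAString(enzyme$recognition),
                                  subject, fixed = FALSE)
  cuts <- (Biostrings::start(fwd) - 1L) + enzyme$cut_offset
  if (!iupac_palindromic(enzyme$recognition)) {
    rcpat <- Biostrings::reverseComplement(Biostrings::DNAString(enzyme$recognition))
    rev <- Biostrings::matchPattern(rcpat, subject, fixed = FALSE)
    # the enzyme sits on the bottom strand; its top-strand cut mirrors
    cuts <- c(cuts, (Biostrings::start(rev) - 1L) + (L - enzyme$cut_offset))
  }
  cuts <- sort(unique(as.integer(cuts)))
  cuts[cuts > 0L & cuts < nchar(sequence)]
}

#' In-silico restriction digest
#'
#' @inheritParams find_sites
#' @return list with `fragment_lengths` (lengths between consecutive cuts;
#'   they always sum to the sequence length) and `cut_positions`.
#' @examples
#' digest("AAGAATTCAA", restriction_enzyme("EcoRI"))  # fragments 3 and 7
#' @export
digest <- function(sequence, enzyme) {
  cuts <- find_sites(sequence, enzyme)
  n <- nchar(sequence)
  list(fragment_lengths = diff(c(0L, cuts, n)), cut_positions = cuts)
}

#' Does an allele destroy a restriction site?
#'
#' TRUE when the mutated sequence has no cut within one recognition-site
#' length of the (coordinate-lifted) original cut position -- the molecule
#' would run as an uncut band in an RFLP assay.
#'
#' @param reference DNA string carrying the site.
#' @param allele an [allele_spec()].
#' @param enzyme a [restriction_enzyme()].
#' @param site_cut_position 0-based cut coordinate of the assayed site on
#'   the reference; must be one of `find_sites(reference, enzyme)`.
#' @return logical scalar.
#' @export
allele_destroys_site <- function(reference, allele, enzyme, site_cut_position) {
  ref_cuts <- find_sites(reference, enzyme)
  if (!(site_cut_position %in% ref_cuts)) {
    stop(sprintf("no %s cut at coordinate %d on the reference",
                 enzyme$name, site_cut_position), call. = FALSE)
  }
  alt <- apply_allele(reference, allele)
  lifted <- map_ref_to_alt(site_cut_position, allele)
  alt_cuts <- find_sites(alt, enzyme)
  !any(abs(alt_cuts - lifted) <= nchar(enzyme$recognition))
}

#' Expected uncut fraction of an allele mixture (RFLP rate)
#'
#' The molecule fraction that would migrate as the uncut band: the summed
#' fractions of alleles destroying the assayed site.  Because an indel can
#' fall inside the editing window yet leave the recognition sequence
#' intact, this rate systematically underestimates the sequencing editing
#' rate of the same mixture.
#'
#' @param alleles list of [allele_spec()].
#' @param fractions numeric vector of molecule fractions, same order as
#'   `alleles`, summing to 1.
#' @inheritParams allele_destroys_site
#' @return fraction in `[0, 1]`.
#' @export
rflp_rate <- function(alleles, fractions, reference, enzyme, site_cut_position) {
  stopifnot(length(alleles) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  destroyed <- vapply(alleles, allele_destroys_site, logical(1),
                      reference = reference, enzyme = enzyme,
                      site_cut_position = site_cut_position)
  sum(fractions[destroyed])
}

#' Interpret a digest gel pattern for a clonal sample
#'
#' @param uncut_present is a band co-migrating with the undigested product
#'   present?
#' @param cut_present are digestion fragments present?
#' @return object of class `clone_pattern`.
#' @export
clone_pattern <- function(uncut_present, cut_present) {
  stopifnot(is.logical(uncut_present), is.logical(cut_present))
  structure(list(uncut_present = uncut_present, cut_present = cut_present),
            class = "clone_pattern")
}

#' Build a clone band pattern from digest fragment lengths
#'
#' Fragments within `comigration_tol` of the full-length product are called
#' the uncut band (gels cannot resolve small indels); anything shorter is a
#' cut fragment.
#'
#' @param fragment_lengths integer vector (possibly pooled over both
#'   alleles of a clone).
#' @param full_length undigested product length.
#' @param comigration_tol band co-migration tolerance in bp (default 5).
#' @return a [clone_pattern()].
#' @export
pattern_from_fragments <- function(fragment_lengths, full_length,
                                   comigration_tol = 5L) {
  stopifnot(length(fragment_lengths) > 0L)
  uncut <- any(fragment_lengths >= full_length - comigration_tol)
  cut <- any(fragment_lengths < full_length - comigration_tol)
  clone_pattern(uncut, cut)
}

#' Genotype a clone from its RFLP band pattern
#'
#' Cut fragments only: both alleles retain the site (wild type).  Uncut
#' band only: both alleles lost it (biallelic edit).  Both band classes:
#' one allele each (heterozygous).
#'
#' @param pattern a [clone_pattern()].
#' @return one of `"WT"`, `"heterozygous"`, `"biallelic_edited"`.
#' @export
genotype_clone <- function(pattern) {
  stopifnot(inherits(pattern, "clone_pattern"))
  if (!pattern$uncut_present && !pattern$cut_present) {
    stop("empty band pattern", call. = FALSE)
  }
  if (pattern$uncut_present && pattern$cut_present) return("heterozygous")
  if (pattern$uncut_present) return("biallelic_edited")
  "WT"
}
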