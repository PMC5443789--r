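# Synthetic-data module: amplicons with guide + restriction-site geometry,
# NHEJ / paired-nickase alleles, FASTQ reads with position-dependent quality
# decay and substitution sequencing error, and qPCR-style decay series.

# ---- truncated geometric indel-size distribution -------------------------

# pmf on {lo..hi} proportional to (1-p)^(k-lo); p solved so the truncated
# mean hits `mean`.  Solutions are cached per (lo, hi, mean).
.truncgeom_cache <- new.env(parent = emptyenv())

truncgeom_pmf <- function(p, lo, hi) {
  w <- (1 - p)^(seq.int(lo, hi) - lo)
  w / sum(w)
}

truncgeom_param <- function(mean, lo, hi) {
  if (!(mean > lo && mean < (lo + hi) / 2)) {
    stop(sprintf(
      "truncated-geometric mean must lie in (%d, %g) for support [%d, %d]",
      lo, (lo + hi) / 2, lo, hi), call. = FALSE)
  }
  key <- paste(mean, lo, hi, sep = "|")
  hit <- .truncgeom_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- function(p) sum(seq.int(lo, hi) * truncgeom_pmf(p, lo, hi)) - mean
  p <- stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  .truncgeom_cache[[key]] <- p
  p
}

#' Truncated-geometric indel-size distribution
#'
#' Sizes on `[lo, hi]` with probability proportional to
#' `(1 - p)^(k - lo)`, where `p` is solved numerically so the truncated
#' mean equals `mean`.  Used for NHEJ deletion sizes (default mean 6 on
#' `[1, 30]`) and paired-nickase deletion sizes (default mean 30 on
#' `[6, 78]`).
#'
#' @param n number of draws.
#' @param mean target mean; must lie in `(lo, (lo + hi) / 2)`.
#' @param lo,hi integer support bounds.
#' @return integer vector of sizes.
#' @export
rtruncgeom <- function(n, mean, lo, hi) {
  p <- truncgeom_param(mean, lo, hi)
  pmf <- truncgeom_pmf(p, lo, hi)
  sample(seq.int(lo, hi), n, replace = TRUE, prob = pmf)
}

# exact moments of the truncated geometric, for Monte-Carlo tolerances
truncgeom_moments <- function(mean, lo, hi) {
  p <- truncgeom_param(mean, lo, hi)
  pmf <- truncgeom_pmf(p, lo, hi)
  k <- seq.int(lo, hi)
  m <- sum(k * pmf)
  list(mean = m, sd = sqrt(sum((k - m)^2 * pmf)))
}

sample_from <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

# instantiate an IUPAC pattern as concrete bases (random choice per symbol)
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

instantiate_iupac <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]],
               function(s) sample_from(IUPAC_SETS[[s]]), character(1)),
        collapse = "")
}

replace_range <- function(x, start, replacement) {  # 0-based start
  paste0(substr0(x, 0L, start), replacement,
         substr0(x, start + nchar(replacement), nchar(x)))
}

# ---- locus generation ----------------------------------------------------

#' Generate a synthetic editing locus
#'
#' Builds a random amplicon carrying a guide placement (or a PAM-out pair
#' of opposite-strand guides in nickase mode) and a restriction site
#' overlapping the editing region, the geometry every targeted locus in an
#' RFLP-verified editing experiment needs.  Deterministic per seed.
#'
#' @param seed integer seed.
#' @param length amplicon length; must be at least `2 * read_length`.
#' @param enzyme_name one of [builtin_enzymes()] names (or pass an
#'   `enzyme` object).
#' @param mode `"cas9"` (one guide, blunt cut) or `"nickase"` (two guides
#'   on opposite strands, nick-to-nick offset drawn from
#'   `nick_offset_range`).
#' @param read_length planned read length (default 150).
#' @param nick_offset_range inclusive range of nick-to-nick distances.
#' @param enzyme optional [restriction_enzyme()] overriding `enzyme_name`.
#' @param locus_id locus label.
#' @return object of class `sim_locus`: fields `locus_id`, `amplicon`,
#'   `guides` (list of [guide_site()]), `enzyme`, `mode`, `seed`.
#' @export
generate_locus <- function(seed, length = 300L, enzyme_name = "EcoRI",
                           mode = c("cas9", "nickase"), read_length = 150L,
                           nick_offset_range = c(10L, 60L), enzyme = NULL,
                           locus_id = sprintf("locus_s%d", seed)) {
  mode <- match.arg(mode)
  length <- as.integer(length)
  if (length < 2L * read_length) {
    stop(sprintf("amplicon length %d is too small: need >= 2 * read length (%d)",
                 length, 2L * read_length), call. = FALSE)
  }
  enz <- enzyme %||% restriction_enzyme(enzyme_name)
  Lrec <- nchar(enz$recognition)
  withr::with_seed(seed, {
    amp <- random_dna(length)
    if (mode == "cas9") {
      cut <- length %/% 2L
      ps <- cut - 17L
      # recognition site ends at the cut: inside the +/-15 editing window
      amp <- replace_range(amp, cut - Lrec, instantiate_iupac(enz$recognition))
      amp <- replace_range(amp, cut + 4L, "GG")  # PAM = NGG at [cut+3, cut+6)
      guides <- list(guide_site(locus_id, substr0(amp, ps, ps + 20L),
                                substr0(amp, cut + 3L, cut + 6L),
                                "+", ps))
    } else {
      offset <- sample_from(seq.int(nick_offset_range[1], nick_offset_range[2]))
      cut_a <- length %/% 2L - offset %/% 2L
      cut_b <- cut_a + offset
      mid <- (cut_a + cut_b) %/% 2L
      amp <- replace_range(amp, mid - Lrec %/% 2L,
                           instantiate_iupac(enz$recognition))
      # PAM-out geometry: minus-strand guide nicks at cut_a (PAM CCN on the
      # plus strand, left of the nick), plus-strand guide nicks at cut_b
      amp <- replace_range(amp, cut_a - 6L, "CC")
      amp <- replace_range(amp, cut_b + 4L, "GG")
      g_a <- guide_site(locus_id,
                        revcomp(substr0(amp, cut_a - 3L, cut_a + 17L)),
                        revcomp(substr0(amp, cut_a - 6L, cut_a - 3L)),
                        "-", cut_a - 3L)
      g_b <- guide_site(locus_id, substr0(amp, cut_b - 17L, cut_b + 3L),
                        substr0(amp, cut_b + 3L, cut_b + 6L),
                        "+", cut_b - 17L)
      guides <- list(g_a, g_b)
    }
    structure(list(locus_id = locus_id, amplicon = amp, guides = guides,
                   enzyme = enz, mode = mode, seed = seed,
                   read_length = as.integer(read_length)),
              class = "sim_locus")
  })
}

#' @export
print.sim_locus <- function(x, ...) {
  cat(sprintf("<sim_locus> %s %s %d bp, enzyme %s, cut(s) %s\n",
              x$locus_id, x$mode, nchar(x$amplicon), x$enzyme$name,
              paste(locus_cuts(x), collapse = "/")))
  invisible(x)
}

#' Cut coordinates of a simulated locus
#' @param locus a `sim_locus`.
#' @return integer vector of inter-base cut coordinates (1 or 2 values).
#' @export
locus_cuts <- function(locus) {
  vapply(locus$guides, function(g) g$cut, integer(1))
}

# editing window implied by the locus geometry
locus_editing_window <- function(locus, halfwidth = 15L) {
  cuts <- locus_cuts(locus)
  n <- nchar(locus$amplicon)
  if (length(cuts) == 1L) editing_window(cuts, halfwidth, n)
  else nickase_window(cuts[1], cuts[2], halfwidth, n)
}

# ---- allele sampling -----------------------------------------------------

#' Sample an NHEJ repair allele at a blunt Cas9 cut
#'
#' A single indel overlapping (or abutting) the cut: a deletion with
#' truncated-geometric size (default mean 6, max 30) placed uniformly over
#' the positions containing the cut, or with probability `insertion_prob`
#' an insertion of 1--`insertion_max` random bases anchored at the cut.
#'
#' @param locus a cas9-mode `sim_locus`.
#' @param seed integer seed (deterministic per seed).
#' @param deletion_mean,deletion_max truncated-geometric parameters.
#' @param insertion_prob probability the indel is an insertion.
#' @param insertion_max maximum insertion length.
#' @param label allele label.
#' @return an [allele_spec()].
#' @export
sample_nhej_allele <- function(locus, seed, deletion_mean = 6,
                               deletion_max = 30L, insertion_prob = 0.3,
                               insertion_max = 10L,
                               label = sprintf("nhej_s%d", seed)) {
  stopifnot(inherits(locus, "sim_locus"))
  if (locus$mode != "cas9") {
    stop("sample_nhej_allele requires a cas9-mode locus", call. = FALSE)
  }
  cut <- locus_cuts(locus)
  n <- nchar(locus$amplicon)
  withr::with_seed(seed, {
    if (stats::runif(1) < insertion_prob) {
      len <- sample_from(seq_len(insertion_max))
      ev <- data.frame(position = cut, deleted_length = 0L,
                       inserted_bases = random_dna(len))
    } else {
      L <- rtruncgeom(1, deletion_mean, 1L, deletion_max)
      start <- sample_from(seq.int(max(0L, cut - L), min(cut, n - L)))
      ev <- data.frame(position = start, deleted_length = L,
                       inserted_bases = "")
    }
    allele_spec(ev, label)
  })
}

#' Sample a paired-nickase repair allele
#'
#' One deletion whose size follows a truncated geometric on
#' `deletion_range` (default `[6, 78]` bp) with configurable mean
#' (default 30 bp), placed to intersect the interval spanned by the two
#' nick coordinates: deletions at least as long as the nick offset cover
#' both nicks; shorter ones fall between them.
#'
#' @param locus a nickase-mode `sim_locus`.
#' @param seed integer seed.
#' @param deletion_mean target mean deletion size.
#' @param deletion_range inclusive size support.
#' @param label allele label.
#' @return an [allele_spec()].
#' @export
sample_nickase_allele <- function(locus, seed, deletion_mean = 30,
                                  deletion_range = c(6L, 78L),
                                  label = sprintf("nick_s%d", seed)) {
  stopifnot(inherits(locus, "sim_locus"))
  if (locus$mode != "nickase") {
    stop("sample_nickase_allele requires a nickase-mode locus", call. = FALSE)
  }
  cuts <- sort(locus_cuts(locus))
  n <- nchar(locus$amplicon)
  withr::with_seed(seed, {
    L <- rtruncgeom(1, deletion_mean, deletion_range[1], deletion_range[2])
    d <- cuts[2] - cuts[1]
    rng <- if (L >= d) seq.int(cuts[2] - L, cuts[1]) else seq.int(cuts[1], cuts[2] - L)
    start <- sample_from(rng[rng >= 0L & rng <= n - L])
    allele_spec(data.frame(position = start, deleted_length = L,
                           inserted_bases = ""), label)
  })
}

# ---- read simulation -----------------------------------------------------

#' Configuration for the amplicon read simulator
#'
#' @param n_reads number of reads (> 0).
#' @param allele_fractions named numeric vector of allele fractions (must
#'   sum to 1 within 1e-9); the name `"WT"` denotes the unedited amplicon.
#' @param read_length read length in bp (default 150, single-end; mates of
#'   a pair are treated as independent reads).
#' @param substitution_error_rate per-base substitution sequencing error.
#' @param indel_error_rate per-base rate of spurious 1-bp sequencing/PCR
#'   indels (default 0: the generator is substitution-only unless
#'   background indel noise is explicitly requested).
#' @param quality_profile list with `q_start`, `q_end` (mean Phred at the
#'   first/last cycle; linear in between) and `sd` (per-base Gaussian
#'   spread, clamped to `[2, 40]`).
#' @param window_pad placement margin in bp: reads are placed to cover the
#'   editing window plus `window_pad` bases on each side when the allele
#'   sequence permits (default 15).  The margin guarantees alignment
#'   anchors on both sides of an indel; without it, junction-straddling
#'   reads with only a few anchor bases cannot witness their own edit,
#'   because absorbing a near-end indel as mismatches outscores opening a
#'   gap.
#' @param exact_counts allocate reads to alleles by largest-remainder
#'   rounding of the fractions instead of multinomial sampling.
#' @param both_strands emit each read from a random strand (default TRUE,
#'   modelling the two mates of an unmerged pair: reverse-strand reads
#'   appear reverse-complemented and their quality decay runs in
#'   sequencing-cycle order, i.e. from the right end of the amplicon).
#' @param seed integer seed.
#' @return object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads, allele_fractions, read_length = 150L,
                            substitution_error_rate = 0.001,
                            indel_error_rate = 0,
                            quality_profile = list(q_start = 38, q_end = 28,
                                                   sd = 3),
                            window_pad = 15L,
                            exact_counts = FALSE, both_strands = TRUE,
                            seed = 1L) {
  assert_scalar_number(n_reads, "n_reads", lower = 1)
  if (is.null(names(allele_fractions)) || any(names(allele_fractions) == "")) {
    stop("allele_fractions must be a named vector", call. = FALSE)
  }
  if (any(allele_fractions < 0) || any(allele_fractions > 1)) {
    stop("allele fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(allele_fractions) - 1) > 1e-9) {
    stop("allele fractions must sum to 1", call. = FALSE)
  }
  assert_scalar_number(substitution_error_rate, "substitution_error_rate", 0, 1)
  assert_scalar_number(indel_error_rate, "indel_error_rate", 0, 1)
  structure(list(n_reads = as.integer(n_reads),
                 allele_fractions = allele_fractions,
                 read_length = as.integer(read_length),
                 substitution_error_rate = substitution_error_rate,
                 indel_error_rate = indel_error_rate,
                 quality_profile = quality_profile,
                 window_pad = as.integer(window_pad),
                 exact_counts = isTRUE(exact_counts),
                 both_strands = isTRUE(both_strands),
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

mutate_substitutions <- function(bases, k) {
  s <- strsplit(bases, "")[[1]]
  pos <- sample.int(length(s), min(k, length(s)))
  for (p in pos) {
    s[p] <- sample_from(setdiff(DNA_BASES, s[p]))
  }
  paste(s, collapse = "")
}

mutate_indels <- function(bases, k) {
  for (i in seq_len(k)) {
    n <- nchar(bases)
    p <- sample.int(n, 1)
    if (stats::runif(1) < 0.5 && n > 1L) {
      bases <- paste0(substr(bases, 1L, p - 1L), substr(bases, p + 1L, n))
    } else {
      bases <- paste0(substr(bases, 1L, p), sample_from(DNA_BASES),
                      substr(bases, p + 1L, n))
    }
  }
  bases
}

#' Simulate amplicon sequencing reads from an allele mixture
#'
#' Each read is a contiguous window of one allele's sequence, placed so it
#' contains the editing window whenever the allele sequence permits;
#' per-base Phred qualities follow a linear decay profile, substitution
#' errors (and optional spurious 1-bp indels) are injected at the
#' configured rates, and the true allele label is recorded in the read
#' header -- a ground-truth channel for testing that the analysis pipeline
#' never reads.  Deterministic per seed.
#'
#' @param locus a `sim_locus`.
#' @param alleles list of [allele_spec()] covering every non-WT label in
#'   `config$allele_fractions` (a plain `"WT"` allele is implied).
#' @param config a [read_sim_config()].
#' @return tibble with columns `read_id`, `allele`, `strand`, `bases`,
#'   `qual` (Phred+33), carrying the locus id as an attribute.
#' @export
simulate_reads <- function(locus, alleles, config) {
  stopifnot(inherits(locus, "sim_locus"), inherits(config, "read_sim_config"))
  labels <- vapply(alleles, function(a) a$label, character(1))
  want <- names(config$allele_fractions)
  if ("WT" %in% want && !"WT" %in% labels) {
    alleles <- c(alleles, list(allele_spec(label = "WT")))
    labels <- c(labels, "WT")
  }
  if (!all(want %in% labels)) {
    stop(sprintf("no allele_spec for label(s): %s",
                 paste(setdiff(want, labels), collapse = ", ")), call. = FALSE)
  }
  alleles <- alleles[match(want, labels)]
  rl <- config$read_length
  qp <- config$quality_profile
  w <- locus_editing_window(locus)
  withr::with_seed(config$seed, {
    counts <- if (config$exact_counts) {
      largest_remainder(config$allele_fractions, config$n_reads)
    } else {
      as.integer(stats::rmultinom(1, config$n_reads, config$allele_fractions))
    }
    allele_lab <- character(0)
    bases <- character(0)
    for (k in seq_along(alleles)) {
      if (counts[k] == 0L) next
      seqa <- apply_allele(locus$amplicon, alleles[[k]])
      La <- nchar(seqa)
      if (La < rl) {
        stop(sprintf("allele %s is shorter than the read length", want[k]),
             call. = FALSE)
      }
      wa1 <- map_ref_to_alt(w$start, alleles[[k]])
      wa2 <- map_ref_to_alt(w$end, alleles[[k]])
      pad <- config$window_pad
      lo <- max(0, wa2 + pad - rl)
      hi <- min(wa1 - pad, La - rl)
      if (hi < lo) {  # padded window does not fit: drop the margin
        lo <- max(0, wa2 - rl)
        hi <- min(wa1, La - rl)
      }
      if (hi < lo) { lo <- 0; hi <- La - rl }  # window wider than a read
      starts <- sample_from(seq.int(lo, hi), counts[k])
      allele_lab <- c(allele_lab, rep(want[k], counts[k]))
      bases <- c(bases, substring(seqa, starts + 1L, starts + rl))
    }
    n <- length(bases)
    # substitution sequencing errors
    nerr <- stats::rbinom(n, nchar(bases), config$substitution_error_rate)
    for (i in which(nerr > 0L)) bases[i] <- mutate_substitutions(bases[i], nerr[i])
    # optional spurious indel noise
    if (config$indel_error_rate > 0) {
      nind <- stats::rbinom(n, nchar(bases), config$indel_error_rate)
      for (i in which(nind > 0L)) bases[i] <- mutate_indels(bases[i], nind[i])
    }
    # reverse-strand reads (the unmerged mate): reverse-complement first,
    # so the quality profile below applies in sequencing-cycle order
    strand <- rep("+", n)
    if (config$both_strands) {
      flip <- stats::runif(n) < 0.5
      for (i in which(flip)) bases[i] <- revcomp(bases[i])
      strand[flip] <- "-"
    }
    # per-cycle qualities: linear mean decay, Gaussian spread, clamped
    lens <- nchar(bases)
    qual <- character(n)
    means_std <- qp$q_start + (qp$q_end - qp$q_start) * (seq_len(rl) - 1) / (rl - 1)
    if (n > 0L && all(lens == rl)) {
      qmat <- matrix(stats::rnorm(n * rl, 0, qp$sd), n, rl, byrow = FALSE)
      qmat <- sweep(qmat, 2L, means_std, "+")
      qmat <- pmax(pmin(matrix(as.integer(round(qmat)), n, rl), 40L), 2L)
      qual <- vapply(seq_len(n), function(i) phred_encode(qmat[i, ]),
                     character(1))
    } else {
      for (i in seq_len(n)) {
        m <- if (lens[i] <= rl) means_std[seq_len(lens[i])] else
          c(means_std, rep(qp$q_end, lens[i] - rl))
        q <- round(stats::rnorm(lens[i], m, qp$sd))
        qual[i] <- phred_encode(pmin(40L, pmax(2L, as.integer(q))))
      }
    }
    ord <- sample.int(n)
    out <- tibble::tibble(
      read_id = sprintf("%s_r%06d", locus$locus_id, seq_len(n)),
      allele = allele_lab[ord],
      strand = strand[ord],
      bases = bases[ord],
      qual = qual[ord])
    attr(out, "locus_id") <- locus$locus_id
    out
  })
}

# ---- qPCR decay series ---------------------------------------------------

#' Episomal copy-number time series container
#'
#' @param timepoints days since selection withdrawal (strictly increasing).
#' @param copy_numbers positive relative copy numbers.
#' @param generation_time_hours cell generation time in hours (> 0).
#' @return object of class `decay_series`.
#' @export
decay_series <- function(timepoints, copy_numbers,
                         generation_time_hours = 24) {
  stopifnot(length(timepoints) == length(copy_numbers))
  if (generation_time_hours <= 0) {
    stop("generation time must be positive", call. = FALSE)
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing", call. = FALSE)
  }
  if (any(copy_numbers <= 0)) stop("copy numbers must be positive", call. = FALSE)
  structure(list(timepoints = as.numeric(timepoints),
                 copy_numbers = as.numeric(copy_numbers),
                 generation_time_hours = generation_time_hours),
            class = "decay_series")
}

#' Simulate a qPCR episome-loss time series
#'
#' Expected copy number at day `d` is
#' `initial * (1 - loss_rate)^(24 * d / generation_time_hours)`, times
#' mean-1 lognormal noise with the given coefficient of variation --
#' the geometric per-generation loss model of an episomal (OriP/EBNA1)
#' vector after selection withdrawal, sampled every two days by default.
#'
#' @param initial initial relative copy number (> 0).
#' @param loss_rate_per_generation loss fraction per cell generation, in
#'   (0, 1); episomal vectors are typically lost at 3 to 6 percent per
#'   generation.
#' @param days numeric vector of sampling days.
#' @param generation_time_hours cell generation time (> 0; default 24 h).
#' @param noise_cv lognormal noise CV (0 = noiseless).
#' @param seed integer seed.
#' @return a [decay_series()].
#' @export
simulate_qpcr_series <- function(initial = 100, loss_rate_per_generation = 0.05,
                                 days = seq(2, 16, by = 2),
                                 generation_time_hours = 24, noise_cv = 0,
                                 seed = 1L) {
  assert_scalar_number(initial, "initial", lower = 1e-12)
  if (loss_rate_per_generation <= 0 || loss_rate_per_generation >= 1) {
    stop("loss rate must lie in (0, 1)", call. = FALSE)
  }
  if (generation_time_hours <= 0) {
    stop("generation time must be positive", call. = FALSE)
  }
  gens <- 24 * days / generation_time_hours
  mu <- initial * (1 - loss_rate_per_generation)^gens
  copies <- if (noise_cv > 0) {
    withr::with_seed(seed, {
      sdlog <- sqrt(log1p(noise_cv^2))
      mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
  } else mu
  decay_series(days, copies, generation_time_hours)
}

# ---- writers -------------------------------------------------------------

#' Write simulated reads as FASTQ (Phred+33)
#'
#' The true allele label travels in the header comment (`allele=...`), a
#' test-only channel the pipeline ignores.
#'
#' @param reads tibble from [simulate_reads()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$bases)
  names(seqs) <- paste0(reads$read_id, " allele=", reads$allele)
  Biostrings::writeXStringSet(seqs, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file into the read tibble used throughout the package
#'
#' @param path FASTQ path (Phred+33).
#' @return tibble with `read_id`, `bases`, `qual` (and `allele` when the
#'   header carries a simulator ground-truth tag).
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  hdr <- names(seqs)
  qual <- as.character(S4Vectors::mcols(seqs)$qualities)
  allele <- ifelse(grepl("allele=", hdr),
                   sub(".*allele=([^ ]+).*", "\\1", hdr), NA_character_)
  tibble::tibble(read_id = sub(" .*", "", hdr),
                 allele = allele,
                 bases = unname(as.character(seqs)),
                 qual = unname(qual))
}

#' Write amplicon sequences as FASTA
#' @param amplicons named character vector.
#' @param path output path.
#' @export
write_amplicons_fasta <- function(amplicons, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(amplicons), path)
  invisible(path)
}

#' Write / read the locus sheet TSV
#'
#' One row per guide: `locus_id`, `amplicon_id`, `protospacer`, `pam`,
#' `strand`, `protospacer_start` (0-based), `enzyme`, `mode`.
#'
#' @param loci list of `sim_locus`.
#' @param path TSV path.
#' @export
write_locus_sheet <- function(loci, path) {
  rows <- do.call(rbind, lapply(loci, function(lc) {
    do.call(rbind, lapply(lc$guides, function(g) {
      data.frame(locus_id = lc$locus_id, amplicon_id = lc$locus_id,
                 protospacer = g$protospacer, pam = g$pam,
                 strand = g$strand, protospacer_start = g$protospacer_start,
                 enzyme = lc$enzyme$name, mode = lc$mode,
                 stringsAsFactors = FALSE)
    }))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_locus_sheet
#' @export
read_locus_sheet <- function(path) {
  tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
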