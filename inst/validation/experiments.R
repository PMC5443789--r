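# Simulation experiments validating the pipeline end to end.  Sourced by
# the acceptance test file and by scripts/acceptance.R so both run the
# same procedures.  Every function is a pure function of its seed.

#' Aligner-versus-reference-scorer agreement: exhaustive sweep over all
#' 2-letter sequence pairs up to `maxlen2`, plus random 4-letter pairs.
exp_aligner_oracle <- function(seed, maxlen2 = 8, n_random = 200,
                               maxlen4 = 12) {
  seqs <- unlist(lapply(seq_len(maxlen2), function(L) {
    apply(do.call(expand.grid, rep(list(c("A", "C")), L)), 1,
          paste, collapse = "")
  }), use.names = FALSE)
  n_pairs <- 0L; n_agree <- 0L
  for (x in seqs) {
    ax <- vapply(seqs, function(y) {
      crisprquant::semiglobal_align(x, y, both_strands = FALSE,
                                    min_score_fraction = 0)$score
    }, numeric(1))
    rx <- vapply(seqs, function(y) {
      crisprquant::semiglobal_score_reference(x, y)
    }, numeric(1))
    n_pairs <- n_pairs + length(seqs)
    n_agree <- n_agree + sum(ax == rx)
  }
  withr::with_seed(seed, {
    for (i in seq_len(n_random)) {
      x <- paste(sample(c("A", "C", "G", "T"), sample(seq_len(maxlen4), 1),
                        replace = TRUE), collapse = "")
      y <- paste(sample(c("A", "C", "G", "T"), sample(seq_len(maxlen4), 1),
                        replace = TRUE), collapse = "")
      a <- crisprquant::semiglobal_align(x, y, both_strands = FALSE,
                                         min_score_fraction = 0)$score
      n_pairs <- n_pairs + 1L
      n_agree <- n_agree +
        (a == crisprquant::semiglobal_score_reference(x, y))
    }
  })
  list(n_pairs = n_pairs, n_agree = n_agree)
}

ACCEPT_ENZYMES <- c("EcoRI", "SacI", "XbaI", "AgeI", "BstXI")

#' Parameter recovery: reported editing rate versus the true edited
#' fraction, judged against a 3-binomial-SD band per replicate.  Reads use
#' a flat high-quality profile: the binomial model presumes informativeness
#' is allele-independent, which holds when reads span the window without
#' truncation starvation (the decaying default profile differentially
#' under-covers insertion alleles, whose windows are wider in read space).
exp_recovery <- function(seed, fractions = c(0, 0.1, 0.5, 0.93),
                         n_reads = 2000, n_reps = 50) {
  out <- vector("list", length(fractions) * n_reps)
  k <- 0L
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    lc <- crisprquant::generate_locus(seed + fi, 300,
                                      ACCEPT_ENZYMES[fi %% 5 + 1], "cas9")
    allele <- crisprquant::sample_nhej_allele(lc, seed + 50 + fi,
                                              label = "edit")
    for (rep in seq_len(n_reps)) {
      mix <- if (f <= 0) c(WT = 1) else if (f >= 1) c(edit = 1) else
        c(WT = 1 - f, edit = f)
      cfg <- crisprquant::read_sim_config(
        n_reads, mix, substitution_error_rate = 0.001,
        quality_profile = list(q_start = 38, q_end = 38, sd = 3),
        seed = seed + 1000L + rep * 10L + fi)
      rd <- crisprquant::simulate_reads(lc, list(allele), cfg)
      q <- crisprquant::quantify_locus(rd, lc$amplicon,
                                       crisprquant::locus_cuts(lc))
      n_cov <- q$report$n_window_covering
      band <- 3 * sqrt(f * (1 - f) / n_cov)
      k <- k + 1L
      out[[k]] <- data.frame(fraction = f, rep = rep,
                             rate = q$report$rate, n_covering = n_cov,
                             within_band = abs(q$report$rate - f) <= band)
    }
  }
  do.call(rbind, out)
}

#' Type-I calibration of the paired t-test: no editing anywhere, site and
#' control windows both see only background indel noise.
exp_calibration <- function(seed, n_reps = 200, n_loci = 9, n_reads = 400,
                            indel_error_rate = 0.002) {
  loci <- lapply(seq_len(n_loci), function(i) {
    crisprquant::generate_locus(seed + 100L + i, 300,
                                ACCEPT_ENZYMES[i %% 5 + 1], "cas9")
  })
  p_values <- numeric(n_reps)
  bg_rates <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    site <- numeric(n_loci); ctrl <- numeric(n_loci)
    for (i in seq_len(n_loci)) {
      cfg <- crisprquant::read_sim_config(
        n_reads, c(WT = 1), substitution_error_rate = 0.001,
        indel_error_rate = indel_error_rate,
        quality_profile = list(q_start = 38, q_end = 38, sd = 3),
        seed = seed + 10000L + rep * 100L + i)
      rd <- crisprquant::simulate_reads(loci[[i]], list(), cfg)
      q <- crisprquant::quantify_locus(rd, loci[[i]]$amplicon,
                                       crisprquant::locus_cuts(loci[[i]]))
      site[i] <- q$report$rate
      ctrl[i] <- q$report$control_rate
    }
    p_values[rep] <- crisprquant::paired_t_test(site, ctrl)$p_two_sided
    bg_rates[rep] <- mean(ctrl)
  }
  list(rejection_rate = mean(p_values < 0.05), n_reps = n_reps,
       mean_background_rate = mean(bg_rates))
}

#' RFLP dominance: on allele mixtures whose enzyme site lies inside the
#' editing window, the molecule-level RFLP (uncut) rate never exceeds the
#' sequencing editing rate measured on error-free reads of that mixture.
#' Reads are 250 bp of the 300-bp amplicon -- the sequencing arm of an
#' RFLP-versus-sequencing comparison reads essentially whole amplicon
#' clones, so every indel is witnessed with long anchors on both sides.
exp_rflp_dominance <- function(seed, n_mixtures = 100, n_reads = 400,
                               read_length = 250) {
  out <- vector("list", n_mixtures)
  for (m in seq_len(n_mixtures)) {
    lc <- crisprquant::generate_locus(seed + 2000L + m, 300,
                                      ACCEPT_ENZYMES[m %% 5 + 1], "cas9")
    cut <- crisprquant::locus_cuts(lc)
    n_alleles <- m %% 3 + 1
    alleles <- lapply(seq_len(n_alleles), function(k) {
      crisprquant::sample_nhej_allele(lc, seed + 3000L + m * 10L + k,
                                      label = paste0("e", k))
    })
    fr <- withr::with_seed(seed + 4000L + m, {
      tot <- sample(10:90, 1)  # edited percent
      split <- as.integer(stats::rmultinom(1, tot, rep(1, n_alleles)))
      c(100 - tot, split) / 100
    })
    names(fr) <- c("WT", paste0("e", seq_len(n_alleles)))
    keep <- fr > 0
    cfg <- crisprquant::read_sim_config(
      n_reads, fr[keep], read_length = read_length,
      substitution_error_rate = 0,
      quality_profile = list(q_start = 40, q_end = 40, sd = 0),
      exact_counts = TRUE, seed = seed + 5000L + m)
    rd <- crisprquant::simulate_reads(lc, alleles, cfg)
    q <- crisprquant::quantify_locus(rd, lc$amplicon, cut, control = FALSE)
    sites <- crisprquant::find_sites(lc$amplicon, lc$enzyme)
    site <- sites[which.min(abs(sites - cut))]
    rflp <- crisprquant::rflp_rate(
      c(list(crisprquant::allele_spec(label = "WT")), alleles),
      unname(c(fr["WT"], fr[paste0("e", seq_len(n_alleles))])),
      lc$amplicon, lc$enzyme, site)
    out[[m]] <- data.frame(mixture = m, rflp_rate = rflp,
                           sequencing_rate = q$report$rate,
                           dominated = rflp <= q$report$rate + 1e-12)
  }
  do.call(rbind, out)
}

#' Digest conservation on random sequences for every built-in enzyme.
exp_digest_conservation <- function(seed, n_seqs = 100, seq_len = 1000) {
  enzymes <- lapply(crisprquant::builtin_enzymes()$name,
                    crisprquant::restriction_enzyme)
  n <- 0L; ok <- 0L
  withr::with_seed(seed, {
    for (i in seq_len(n_seqs)) {
      s <- paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE),
                 collapse = "")
      for (enz in enzymes) {
        d <- crisprquant::digest(s, enz)
        n <- n + 1L
        ok <- ok + (sum(d$fragment_lengths) == seq_len &&
                      length(d$fragment_lengths) ==
                        length(d$cut_positions) + 1L)
      }
    }
  })
  list(n = n, ok = ok)
}

#' Q30 truncation: prefix property, idempotence and the strict-inequality
#' boundary on randomized quality strings.
exp_q30_properties <- function(seed, n_reads = 300) {
  n <- 0L; ok <- 0L
  withr::with_seed(seed, {
    for (i in seq_len(n_reads)) {
      len <- sample(1:150, 1)
      bases <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = "")
      quals <- sample(25:35, len, replace = TRUE)  # dense around Q30
      r1 <- crisprquant::truncate_at_first_low_quality(bases, quals)
      r2 <- crisprquant::truncate_at_first_low_quality(r1$bases, r1$quals)
      kept <- nchar(r1$bases)
      pass <- identical(r1$bases, substr(bases, 1, kept)) &&   # prefix
        identical(r1, r2) &&                                   # idempotent
        all(r1$quals >= 30) &&                                 # retained
        (kept == len || quals[kept + 1] < 30)                  # boundary
      n <- n + 1L; ok <- ok + pass
    }
  })
  # the Q30 base itself is retained: the rule removes scores strictly below
  boundary <- crisprquant::truncate_at_first_low_quality(
    "ACGTA", c(35, 40, 30, 29, 33))
  list(n = n + 1L, ok = ok + identical(boundary$bases, "ACG"))
}

#' Deletion genotyping truth table on simulated clones (319-bp deletion).
exp_deletion_truthtable <- function(seed, n_clones = 100) {
  genotypes <- list(c(FALSE, FALSE), c(TRUE, FALSE), c(FALSE, TRUE),
                    c(TRUE, TRUE))
  expected <- c("WT", "monoallelic", "monoallelic", "biallelic")
  n <- 0L; ok <- 0L
  d <- 0L
  while (n < n_clones) {
    d <- d + 1L
    des <- crisprquant::simulate_deletion_design(seed + 6000L + d)
    for (g in seq_along(genotypes)) {
      if (n >= n_clones) break
      call <- crisprquant::genotype_deletion_clone(des, genotypes[[g]])
      n <- n + 1L
      ok <- ok + (call$call == expected[g])
    }
  }
  list(n = n, ok = ok)
}

#' Episome-loss recovery: exact inversion of noiseless series; median
#' error over noisy replicates with rates drawn from the 3-6% range.
exp_decay_recovery <- function(seed, n_reps = 50, noise_cv = 0.05) {
  s0 <- crisprquant::simulate_qpcr_series(100, 0.05, days = seq(2, 16, 2),
                                          noise_cv = 0)
  exact_err <- abs(crisprquant::fit_loss_rate(s0)$loss_rate_per_generation -
                     0.05)
  true_rates <- withr::with_seed(seed + 7000L,
                                 stats::runif(n_reps, 0.03, 0.06))
  errs <- vapply(seq_len(n_reps), function(r) {
    s <- crisprquant::simulate_qpcr_series(100, true_rates[r],
                                           days = seq(2, 16, 2),
                                           noise_cv = noise_cv,
                                           seed = seed + 7100L + r)
    crisprquant::fit_loss_rate(s)$loss_rate_per_generation - true_rates[r]
  }, numeric(1))
  list(exact_error = exact_err, median_error = stats::median(errs),
       n_reps = n_reps)
}

#' Nickase deletion-size spectrum over many sampled alleles.
exp_nickase_spectrum <- function(seed, n_draws = 1e4) {
  lc <- crisprquant::generate_locus(seed + 8000L, 300, "SacI", "nickase")
  sizes <- vapply(seq_len(n_draws), function(i) {
    crisprquant::sample_nickase_allele(lc, seed + 8100L + i)$
      events$deleted_length
  }, integer(1))
  mom <- crisprquant:::truncgeom_moments(30, 6, 78)
  list(n = n_draws, min = min(sizes), max = max(sizes),
       mean = mean(sizes), expected_mean = mom$mean,
       se = mom$sd / sqrt(n_draws))
}
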