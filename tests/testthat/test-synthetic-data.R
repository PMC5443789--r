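test_that("generated cas9 loci satisfy their geometric invariants", {
  for (seed in c(1, 2, 17)) {
    lc <- generate_locus(seed, 300, "EcoRI", "cas9")
    g <- lc$guides[[1]]
    cut <- locus_cuts(lc)
    # protospacer and PAM occur at the recorded coordinates
    expect_identical(substr(lc$amplicon, g$protospacer_start + 1,
                            g$protospacer_start + 20), g$protospacer)
    expect_match(g$pam, "^.GG$")
    # the recognition site intersects the +/-15 editing window
    sites <- find_sites(lc$amplicon, lc$enzyme)
    expect_true(any(abs(sites - cut) <= 15 + nchar(lc$enzyme$recognition)))
    expect_true(grepl("GAATTC", lc$amplicon))
    expect_gte(nchar(lc$amplicon), 2 * lc$read_length)
  }
})

test_that("locus generation is deterministic and validates its inputs", {
  expect_identical(generate_locus(1, 300, "EcoRI", "cas9"),
                   generate_locus(1, 300, "EcoRI", "cas9"))
  expect_error(generate_locus(1, 300, "NoSuchEnzyme"), "NoSuchEnzyme")
  expect_error(generate_locus(1, 200, "EcoRI"), "too small")
})

test_that("nickase loci carry opposite-strand guides with 10-60 bp offset", {
  for (seed in 1:5) {
    lc <- generate_locus(seed, 300, "SacI", "nickase")
    expect_length(lc$guides, 2)
    expect_setequal(vapply(lc$guides, function(g) g$strand, character(1)),
                    c("+", "-"))
    cuts <- sort(locus_cuts(lc))
    expect_true(cuts[2] - cuts[1] >= 10 && cuts[2] - cuts[1] <= 60)
    for (g in lc$guides) expect_match(g$pam, "^.GG$")
  }
})

test_that("apply_allele performs exact splice arithmetic", {
  ref <- strrep("ACGTGGTCAA", 6)  # 60 bp
  del3 <- allele_spec(data.frame(position = 37, deleted_length = 3,
                                 inserted_bases = ""))
  expect_identical(nchar(apply_allele(ref, del3)), 57L)
  expect_identical(apply_allele(ref, allele_spec()), ref)
  expect_identical(
    apply_allele("ACGT", allele_spec(data.frame(
      position = 1, deleted_length = 0, inserted_bases = "TT"))),
    "ATTCGT")
  # conservation for random multi-event alleles
  set.seed(5)
  for (i in 1:20) {
    ref <- random_seq(120)
    p1 <- sample(0:40, 1); p2 <- sample(60:100, 1)
    ev <- data.frame(position = c(p1, p2),
                     deleted_length = c(sample(0:5, 1), sample(0:5, 1)),
                     inserted_bases = c(random_seq(sample(1:4, 1)), ""))
    ev$inserted_bases[2] <- if (ev$deleted_length[2] == 0) "A" else ""
    al <- allele_spec(ev)
    expect_identical(nchar(apply_allele(ref, al)),
                     120L - sum(ev$deleted_length) +
                       sum(nchar(ev$inserted_bases)))
  }
})

test_that("overlapping or empty allele events are rejected", {
  expect_error(allele_spec(data.frame(position = c(5, 7),
                                      deleted_length = c(4, 2),
                                      inserted_bases = c("", ""))),
               "overlap")
  expect_error(allele_spec(data.frame(position = 3, deleted_length = 0,
                                      inserted_bases = "")),
               "at least one base")
})

test_that("reference-to-alternate coordinate mapping tracks indels", {
  al <- allele_spec(data.frame(position = c(10, 30),
                               deleted_length = c(5, 0),
                               inserted_bases = c("", "AAA")))
  expect_equal(map_ref_to_alt(5, al), 5)
  expect_equal(map_ref_to_alt(12, al), 10)  # inside the deletion
  expect_equal(map_ref_to_alt(20, al), 15)
  expect_equal(map_ref_to_alt(35, al), 33)  # -5 + 3
})

test_that("NHEJ alleles carry one indel overlapping the cut", {
  lc <- generate_locus(3, 300, "AgeI", "cas9")
  cut <- locus_cuts(lc)
  for (seed in 1:50) {
    al <- sample_nhej_allele(lc, seed)
    expect_identical(nrow(al$events), 1L)
    ev <- al$events
    if (ev$deleted_length > 0) {
      expect_true(ev$position <= cut && ev$position + ev$deleted_length >= cut)
      expect_lte(ev$deleted_length, 30)
    } else {
      expect_identical(ev$position, cut)
      expect_true(nchar(ev$inserted_bases) %in% 1:10)
    }
  }
  expect_identical(sample_nhej_allele(lc, 9)$events,
                   sample_nhej_allele(lc, 9)$events)
  expect_error(sample_nhej_allele(generate_locus(4, 300, "SacI", "nickase"), 1),
               "cas9")
})

test_that("truncated-geometric sizes hit the configured mean", {
  set.seed(42)
  mom <- crisprquant:::truncgeom_moments(6, 1, 30)
  draws <- rtruncgeom(1e4, 6, 1, 30)
  expect_true(all(draws >= 1 & draws <= 30))
  expect_lt(abs(mean(draws) - mom$mean), 3 * mom$sd / sqrt(1e4))
})

test_that("nickase alleles span the nick interval with sizes in [6, 78]", {
  lc <- generate_locus(11, 300, "XbaI", "nickase")
  cuts <- sort(locus_cuts(lc))
  for (seed in 1:50) {
    al <- sample_nickase_allele(lc, seed)
    ev <- al$events
    expect_identical(ev$inserted_bases, "")
    expect_true(ev$deleted_length >= 6 && ev$deleted_length <= 78)
    # the deletion intersects the interval spanned by the two nicks
    expect_true(ev$position <= cuts[2] &&
                  ev$position + ev$deleted_length >= cuts[1])
  }
  expect_identical(sample_nickase_allele(lc, 5)$events,
                   sample_nickase_allele(lc, 5)$events)
  expect_error(sample_nickase_allele(generate_locus(1, 300, "EcoRI"), 1),
               "nickase")
})

test_that("noise-free forward reads are exact substrings of the reference", {
  lc <- generate_locus(2, 300, "EcoRI", "cas9")
  cfg <- read_sim_config(100, c(WT = 1), substitution_error_rate = 0,
                         quality_profile = list(q_start = 40, q_end = 40,
                                                sd = 0),
                         both_strands = FALSE, seed = 8)
  rd <- simulate_reads(lc, list(), cfg)
  expect_true(all(vapply(rd$bases, grepl, logical(1), x = lc$amplicon,
                         fixed = TRUE)))
  expect_true(all(nchar(rd$bases) == 150))
})

test_that("allele labels recover the configured mixture binomially", {
  lc <- generate_locus(2, 300, "EcoRI", "cas9")
  al <- sample_nhej_allele(lc, 5, label = "del3")
  cfg <- read_sim_config(1000, c(WT = 0.5, del3 = 0.5), seed = 21)
  rd <- simulate_reads(lc, list(al), cfg)
  expect_lt(abs(sum(rd$allele == "del3") - 500), 3 * sqrt(1000 * 0.25))
  # exact-count mode allocates deterministically
  cfg2 <- read_sim_config(1000, c(WT = 0.37, del3 = 0.63),
                          exact_counts = TRUE, seed = 21)
  rd2 <- simulate_reads(lc, list(al), cfg2)
  expect_identical(sum(rd2$allele == "del3"), 630L)
})

test_that("read simulation is deterministic down to FASTQ bytes", {
  lc <- generate_locus(2, 300, "EcoRI", "cas9")
  al <- sample_nhej_allele(lc, 5, label = "e")
  cfg <- read_sim_config(200, c(WT = 0.6, e = 0.4), seed = 33)
  rd1 <- simulate_reads(lc, list(al), cfg)
  rd2 <- simulate_reads(lc, list(al), cfg)
  expect_identical(rd1, rd2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_reads_fastq(rd1, f1); write_reads_fastq(rd2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_fastq(f1)
  expect_identical(back$bases, rd1$bases)
  expect_identical(back$qual, rd1$qual)
  expect_identical(back$allele, rd1$allele)
  unlink(c(f1, f2))
})

test_that("fractions must sum to one and cover provided alleles", {
  lc <- generate_locus(2, 300, "EcoRI", "cas9")
  expect_error(read_sim_config(10, c(WT = 0.5, e = 0.4)), "sum to 1")
  cfg <- read_sim_config(10, c(WT = 0.5, missing = 0.5), seed = 1)
  expect_error(simulate_reads(lc, list(), cfg), "missing")
})

test_that("qPCR series follow the closed-form geometric decay", {
  s1 <- simulate_qpcr_series(100, 0.05, days = 1, generation_time_hours = 24,
                             noise_cv = 0)
  expect_equal(s1$copy_numbers, 95.0)
  s10 <- simulate_qpcr_series(100, 0.05, days = 10,
                              generation_time_hours = 24, noise_cv = 0)
  expect_equal(s10$copy_numbers, 100 * 0.95^10, tolerance = 1e-12)
  s <- simulate_qpcr_series(100, 0.04, days = seq(2, 16, 2), noise_cv = 0)
  expect_true(all(diff(s$copy_numbers) < 0))
  expect_error(simulate_qpcr_series(100, 0.05, generation_time_hours = 0),
               "positive")
  expect_error(simulate_qpcr_series(100, 1.2), "\\(0, 1\\)")
})
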