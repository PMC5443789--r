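test_that("cut sites are found at IUPAC-aware positions", {
  eco <- restriction_enzyme("EcoRI")
  expect_identical(find_sites("AAGAATTCAA", eco), 3L)
  expect_identical(find_sites("AAACCCAAA", eco), integer(0))
  # degenerate recognition (BstXI, CCANNNNNNTGG)
  bst <- restriction_enzyme("BstXI")
  seq <- paste0("TTTT", "CCA", "GATCGA", "TGG", "TTTT")
  expect_identical(find_sites(seq, bst), 4L + 8L)
})

test_that("non-palindromic sites are found on the reverse strand", {
  bsa <- restriction_enzyme("BsaI", "GGTCTC", 1L)
  # plant the motif only on the bottom strand
  seq <- paste0("AAAA", revcomp("GGTCTC"), "AAAA")
  expect_identical(find_sites(seq, bsa), 4L + (6L - 1L))
  # randomized agreement with a brute-force both-strand scan
  set.seed(19)
  for (i in 1:30) {
    s <- random_seq(400)
    for (enz_name in c("EcoRI", "BstXI")) {
      enz <- restriction_enzyme(enz_name)
      expect_identical(find_sites(s, enz),
                       brute_sites(s, enz$recognition, enz$cut_offset))
    }
    expect_identical(find_sites(s, bsa), brute_sites(s, "GGTCTC", 1L))
  }
})

test_that("digests cut between consecutive sites and conserve length", {
  d <- digest("AAGAATTCAA", restriction_enzyme("EcoRI"))
  expect_setequal(d$fragment_lengths, c(3L, 7L))
  d0 <- digest("ACACACACAC", restriction_enzyme("EcoRI"))
  expect_identical(d0$fragment_lengths, 10L)
  set.seed(29)
  for (i in 1:20) {
    s <- random_seq(1000)
    for (nm in builtin_enzymes()$name) {
      dd <- digest(s, restriction_enzyme(nm))
      expect_identical(sum(dd$fragment_lengths), 1000L)
      expect_length(dd$fragment_lengths, length(dd$cut_positions) + 1L)
    }
  }
})

test_that("alleles destroy a site exactly when no nearby cut survives", {
  eco <- restriction_enzyme("EcoRI")
  ref <- paste0(strrep("TG", 20), "GAATTC", strrep("CA", 20))  # site at 40
  cut <- find_sites(ref, eco)
  expect_identical(cut, 41L)  # G^AATTC
  in_site <- allele_spec(data.frame(position = 41, deleted_length = 3,
                                    inserted_bases = ""))
  expect_true(allele_destroys_site(ref, in_site, eco, cut))
  far_away <- allele_spec(data.frame(position = 10, deleted_length = 3,
                                     inserted_bases = ""))
  expect_false(allele_destroys_site(ref, far_away, eco, cut))
  # insertion exactly at the cut splits the motif; confirm via digest
  split_ins <- allele_spec(data.frame(position = 43, deleted_length = 0,
                                      inserted_bases = "TTAA"))
  mutated <- apply_allele(ref, split_ins)
  expect_identical(digest(mutated, eco)$cut_positions, integer(0))
  expect_true(allele_destroys_site(ref, split_ins, eco, cut))
  expect_error(allele_destroys_site(ref, in_site, eco, 99), "no EcoRI cut")
})

test_that("an allele never destroys a site its events do not touch", {
  set.seed(37)
  eco <- restriction_enzyme("EcoRI")
  for (i in 1:30) {
    ref <- paste0(random_seq(60), "GAATTC", random_seq(60))
    sites <- find_sites(ref, eco)
    site <- sites[sites >= 60 & sites <= 67][1]
    p <- sample(c(5:40, 80:110), 1)
    al <- allele_spec(data.frame(position = p,
                                 deleted_length = sample(1:5, 1),
                                 inserted_bases = ""))
    ev_end <- al$events$position + al$events$deleted_length
    if (ev_end < 60 - 6 || al$events$position > 66 + 6) {
      expect_false(allele_destroys_site(ref, al, eco, site))
    }
  }
})

test_that("mixture RFLP rates sum destroyed-allele fractions and
          underestimate the sequencing rate", {
  eco <- restriction_enzyme("EcoRI")
  ref <- paste0(strrep("TG", 25), "GAATTC", strrep("CA", 25))
  site <- find_sites(ref, eco)[1]
  wt <- allele_spec(label = "WT")
  at_site <- allele_spec(data.frame(position = site - 1, deleted_length = 3,
                                    inserted_bases = ""), "del_site")
  expect_equal(rflp_rate(list(wt), 1, ref, eco, site), 0)
  expect_equal(rflp_rate(list(wt, at_site), c(0.5, 0.5), ref, eco, site), 0.5)
  # an indel inside the editing window but clear of the recognition site
  off_site <- allele_spec(data.frame(position = site + 12,
                                     deleted_length = 2,
                                     inserted_bases = ""), "del_off")
  mix <- list(wt, at_site, off_site)
  fr <- c(0.4, 0.3, 0.3)
  rr <- rflp_rate(mix, fr, ref, eco, site)
  sequencing_rate <- 0.6  # every non-WT allele carries a window indel
  expect_equal(rr, 0.3)
  expect_lt(rr, sequencing_rate)
})

test_that("clone band patterns map onto the genotype truth table", {
  expect_identical(genotype_clone(clone_pattern(FALSE, TRUE)), "WT")
  expect_identical(genotype_clone(clone_pattern(TRUE, FALSE)),
                   "biallelic_edited")
  expect_identical(genotype_clone(clone_pattern(TRUE, TRUE)), "heterozygous")
  expect_error(genotype_clone(clone_pattern(FALSE, FALSE)), "empty")
  # fragment lengths within the co-migration tolerance read as uncut
  p <- pattern_from_fragments(c(498L, 300L, 198L), 500L)
  expect_true(p$uncut_present)
  expect_true(p$cut_present)
  expect_identical(genotype_clone(p), "heterozygous")
})

test_that("unknown enzymes and malformed tables are rejected", {
  expect_error(restriction_enzyme("FakeI"), "FakeI")
  expect_error(restriction_enzyme("x", "ACG", 1), "at least 4")
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("name\trecognition\tcut_offset", "BsaI\tGGTCTC\t1"), tf)
  enz <- load_enzyme_table(tf)
  expect_identical(enz$BsaI$recognition, "GGTCTC")
  unlink(tf)
})
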