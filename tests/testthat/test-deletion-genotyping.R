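test_that("interval deletion obeys length arithmetic", {
  set.seed(47)
  t1000 <- random_seq(1000)
  out <- apply_deletion(t1000, 400, 719)  # a 319-bp deletion
  expect_identical(nchar(out), 681L)
  expect_identical(apply_deletion(t1000, 500, 500), t1000)
  for (i in 1:20) {
    a <- sample(0:900, 1); b <- a + sample(0:99, 1)
    expect_identical(nchar(apply_deletion(t1000, a, b)), 1000L - (b - a))
  }
  expect_error(apply_deletion(t1000, 900, 1100), "invalid")
})

test_that("PCR products follow primer coordinates and the size cutoff", {
  set.seed(53)
  t1000 <- random_seq(1000)
  fwd <- substr(t1000, 351, 370)            # occupies [350, 370)
  rev <- revcomp(substr(t1000, 731, 750))   # site [730, 750)
  pr <- primer_pair(fwd, rev, "junction")
  expect_identical(predict_pcr(t1000, pr), 400L)
  deleted <- apply_deletion(t1000, 400, 719)
  expect_identical(predict_pcr(deleted, pr), 81L)      # 400 - 319
  # the size cutoff silences the junction product on the intact template
  expect_identical(predict_pcr(t1000, pr, max_product = 300L), NA_integer_)
  expect_identical(predict_pcr(deleted, pr, max_product = 300L), 81L)
  # absent site and wrong orientation give no product
  expect_identical(predict_pcr(t1000, primer_pair(random_seq(20), rev,
                                                  "junction")), NA_integer_)
  flipped <- primer_pair(revcomp(substr(t1000, 731, 750)),
                         revcomp(substr(t1000, 351, 370)), "junction")
  expect_true(is.na(predict_pcr(t1000, flipped)))
})

test_that("a primer with two binding sites is an ambiguous design", {
  motif <- "ACGTACGTACGTACGTACGT"
  tpl <- paste0(random_seq(100), motif, random_seq(100), motif,
                random_seq(100))
  pr <- primer_pair(motif, revcomp(substr(tpl, 301, 320)), "internal")
  expect_error(predict_pcr(tpl, pr), "ambiguous")
})

test_that("the two-band pattern maps onto the clone truth table", {
  expect_identical(classify_clone(TRUE, FALSE)$call, "biallelic")
  expect_identical(classify_clone(TRUE, TRUE)$call, "monoallelic")
  expect_identical(classify_clone(FALSE, TRUE)$call, "WT")
  expect_identical(classify_clone(FALSE, FALSE)$call, "assay_failure")
})

test_that("simulated clones of every genotype are classified correctly", {
  genotypes <- list(WT = c(FALSE, FALSE),
                    mono_a = c(TRUE, FALSE),
                    mono_b = c(FALSE, TRUE),
                    biallelic = c(TRUE, TRUE))
  expected <- c(WT = "WT", mono_a = "monoallelic", mono_b = "monoallelic",
                biallelic = "biallelic")
  for (seed in 1:5) {
    des <- simulate_deletion_design(seed)
    expect_identical(des$deletion_end - des$deletion_start, 319L)
    for (g in names(genotypes)) {
      call <- genotype_deletion_clone(des, genotypes[[g]])
      expect_identical(call$call, unname(expected[g]))
    }
  }
})

test_that("deleted-template products shrink by exactly the deletion length", {
  for (seed in 6:10) {
    des <- simulate_deletion_design(seed)
    intact <- predict_pcr(des$template, des$junction_pair,
                          max_product = 10000L)
    deleted <- predict_pcr(apply_deletion(des$template, des$deletion_start,
                                          des$deletion_end),
                           des$junction_pair, max_product = 10000L)
    expect_identical(intact - deleted,
                     des$deletion_end - des$deletion_start)
  }
})

test_that("primers shorter than 15 nt are rejected", {
  expect_error(primer_pair("ACGTACGTAC", strrep("A", 20), "internal"),
               "15 nt")
})
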