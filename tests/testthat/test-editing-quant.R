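mk_guide <- function(strand, ps, amp_n = 300) {
  # build a syntactically valid guide; sequence content is irrelevant to
  # the coordinate conventions under test
  guide_site("L", strrep("ACGT", 5), "AGG", strand, ps)
}

test_that("the cut falls 3 nt 5' of the PAM on either strand", {
  expect_identical(mk_guide("+", 20)$cut, 37L)
  expect_identical(mk_guide("-", 50)$cut, 53L)
  # translation equivariance
  expect_identical(mk_guide("+", 25)$cut, mk_guide("+", 20)$cut + 5L)
  expect_error(guide_site("L", strrep("ACGT", 5), "ATT", "+", 0), "NGG")
})

test_that("editing, nickase and control windows have the stated geometry", {
  w <- editing_window(37, 15, 300)
  expect_identical(c(w$start, w$end), c(22L, 52L))
  expect_identical(w$end - w$start, 30L)  # the 30-bp operative width
  expect_error(editing_window(37, 0, 300), ">= 1")
  expect_error(editing_window(10, 15, 300), "longer amplicon")

  nw <- nickase_window(40, 80, 15, 300)
  expect_identical(c(nw$start, nw$end), c(25L, 95L))
  # degenerate nick pair reduces to the blunt-cut window
  nw2 <- nickase_window(37, 37, 15, 300)
  expect_identical(c(nw2$start, nw2$end), c(22L, 52L))

  cw <- control_window(37, 30, 50, 300)
  expect_identical(c(cw$start, cw$end), c(87L, 117L))
  cw2 <- control_window(250, 30, 50, 300)
  expect_identical(c(cw2$start, cw2$end), c(170L, 200L))  # left fallback
  expect_error(control_window(40, 30, 50, 85), "neither side")
  # disjointness from the editing window is structural (gap > halfwidth)
  expect_true(cw$start >= w$end || cw$end <= w$start)
})

test_that("read classification follows the window-intersection rule", {
  w <- editing_window(37, 15, 300)  # [22, 52)
  spanning <- aln_stub(0, 150)
  expect_identical(classify_read(no_variants(), spanning, w), "unedited")
  expect_identical(
    classify_read(variant_row(36, "deletion", 3), spanning, w), "edited")
  expect_identical(
    classify_read(variant_row(100, "deletion", 6), spanning, w), "unedited")
  expect_identical(
    classify_read(variant_row(37, "insertion", 4, "ACGT"), spanning, w),
    "edited")
  # partial coverage is uninformative regardless of variants
  expect_identical(
    classify_read(variant_row(36, "deletion", 3), aln_stub(30, 150), w),
    "uninformative")
  # a deletion straddling the window boundary still counts
  expect_identical(
    classify_read(variant_row(50, "deletion", 10), spanning, w), "edited")
})

test_that("editing rates divide indel reads by window-covering reads", {
  r <- editing_rate("L", 20, c(rep("edited", 3), rep("unedited", 7),
                               rep("uninformative", 10)))
  expect_identical(r$n_window_covering, 10L)
  expect_equal(r$rate, 0.30)
  r0 <- editing_rate("L", 5, rep("unedited", 5))
  expect_equal(r0$rate, 0)
  expect_error(editing_rate("L", 5, rep("uninformative", 5)), "covers")
})

test_that("the paired t-test matches its closed form", {
  # differences (1, 2, 3): t = 2 / (1 / sqrt(3)), df = 2
  res <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_identical(res$df, 2)
  expect_equal(res$p_two_sided, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-12)
  # symmetric differences give t = 0, p = 1
  res0 <- paired_t_test(c(0.00, 0.02), c(0.01, 0.01))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_two_sided, 1)
  # antisymmetry under swapping the columns
  a <- c(0.3, 0.5, 0.2, 0.4); b <- c(0.1, 0.2, 0.25, 0.1)
  expect_equal(paired_t_test(a, b)$t, -paired_t_test(b, a)$t)
  expect_equal(paired_t_test(a, b)$p_two_sided,
               paired_t_test(b, a)$p_two_sided)
  expect_error(paired_t_test(c(1, 1), c(1, 1)), "zero")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("the pipeline recovers a 50% edited fraction binomially", {
  lc <- generate_locus(6, 300, "EcoRI", "cas9")
  al <- sample_nhej_allele(lc, 2, label = "edit")
  cfg <- read_sim_config(2000, c(WT = 0.5, edit = 0.5),
                         substitution_error_rate = 0.001, seed = 61)
  rd <- simulate_reads(lc, list(al), cfg)
  q <- quantify_locus(rd, lc$amplicon, locus_cuts(lc), lc$locus_id)
  n <- q$report$n_window_covering
  expect_gt(n, 100)
  expect_lt(abs(q$report$rate - 0.5), 3 * sqrt(0.25 / n))
  # substitution errors never masquerade as editing in the control window
  expect_equal(q$report$control_rate, 0)
})

test_that("read tallies conserve counts through every stage", {
  lc <- generate_locus(6, 300, "SacI", "cas9")
  al <- sample_nhej_allele(lc, 3, label = "edit")
  cfg <- read_sim_config(600, c(WT = 0.7, edit = 0.3), seed = 13)
  rd <- simulate_reads(lc, list(al), cfg)
  q <- quantify_locus(rd, lc$amplicon, locus_cuts(lc), lc$locus_id)
  tl <- q$tally
  expect_identical(unname(tl["input"]), unname(tl["qc_kept"] + tl["qc_discarded"]))
  expect_identical(unname(tl["qc_kept"]), unname(tl["aligned"] + tl["unaligned"]))
  expect_identical(unname(tl["aligned"]),
                   unname(tl["edited"] + tl["unedited"] + tl["uninformative"]))
})
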