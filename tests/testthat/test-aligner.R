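test_that("an exact substring aligns end-to-end with all matches", {
  amp <- "TTACGTGCAGGTACCATGAC"
  a <- semiglobal_align(substr(amp, 5, 16), amp)
  expect_true(a$aligned)
  expect_identical(a$score, 12)
  expect_identical(a$ref_start, 4L)
  expect_identical(a$ref_end, 16L)
  expect_identical(a$ops$kind, "match")
  expect_identical(nrow(extract_variants(a)), 0L)
})

test_that("a one-base deletion is recovered at the expected coordinate", {
  a <- semiglobal_align("ACGACGT", "ACGTACGT", min_score_fraction = 0)
  expect_identical(a$score,
                   semiglobal_score_reference("ACGACGT", "ACGTACGT"))
  v <- extract_variants(a)
  expect_identical(v$kind, "deletion")
  expect_identical(v$ref_position, 3L)
  expect_identical(v$length, 1L)
})

test_that("the reference scorer agrees with a plain-recursion oracle", {
  seqs <- all_seqs(4)
  for (x in seqs) for (y in seqs) {
    expect_identical(semiglobal_score_reference(x, y),
                     r_recursive_score(x, y))
  }
})

test_that("optimal scores match the reference scorer on an exhaustive
          2-letter sweep and random 4-letter pairs", {
  seqs <- all_seqs(6)
  for (x in seqs) for (y in seqs) {
    a <- semiglobal_align(x, y, both_strands = FALSE, min_score_fraction = 0)
    expect_identical(a$score, semiglobal_score_reference(x, y))
  }
  set.seed(7)
  for (i in 1:50) {
    x <- random_seq(sample(1:12, 1))
    y <- random_seq(sample(1:12, 1))
    a <- semiglobal_align(x, y, both_strands = FALSE, min_score_fraction = 0)
    expect_identical(a$score, semiglobal_score_reference(x, y))
  }
})

test_that("scores agree with Biostrings pairwiseAlignment as a third
          implementation", {
  set.seed(11)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -2,
                                                     baseOnly = TRUE)
  for (i in 1:25) {
    y <- random_seq(60)
    x <- random_seq(25)
    a <- semiglobal_align(x, y, both_strands = FALSE, min_score_fraction = 0)
    bs <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(x), subject = Biostrings::DNAString(y),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 1)
    expect_identical(a$score, Biostrings::score(bs))
  }
})

test_that("reported scores re-score from the op list and op lengths
          reconcile with the read and reference spans", {
  set.seed(23)
  for (i in 1:40) {
    amp <- random_seq(120)
    # plant a read with one indel
    s <- sample(10:40, 1)
    read <- substr(amp, s, s + 59)
    if (i %% 2 == 0) {
      p <- sample(20:40, 1); L <- sample(1:8, 1)
      read <- paste0(substr(read, 1, p), substr(read, p + L + 1, 60))
    } else {
      p <- sample(20:40, 1)
      read <- paste0(substr(read, 1, p), random_seq(sample(1:5, 1)),
                     substr(read, p + 1, 60))
    }
    a <- semiglobal_align(read, amp, min_score_fraction = 0)
    expect_equal(rescore_ops(a), a$score)
    consumed_ref <- sum(a$ops$length[a$ops$kind != "insertion"])
    consumed_read <- sum(a$ops$length[a$ops$kind != "deletion"])
    expect_identical(consumed_ref, a$ref_end - a$ref_start)
    expect_identical(consumed_read, nchar(read))
  }
})

test_that("extracted variants splice the aligned read back together", {
  set.seed(31)
  for (i in 1:25) {
    amp <- random_seq(150)
    s <- sample(5:30, 1)
    read <- substr(amp, s, s + 79)
    p <- sample(25:50, 1); L <- sample(1:10, 1)
    read <- if (i %% 2 == 0) {
      paste0(substr(read, 1, p), substr(read, p + L + 1, 80))
    } else {
      paste0(substr(read, 1, p), random_seq(L), substr(read, p + 1, 80))
    }
    a <- semiglobal_align(read, amp, min_score_fraction = 0)
    v <- extract_variants(a)  # not normalized: splice in place
    al <- allele_spec(data.frame(
      position = v$ref_position,
      deleted_length = ifelse(v$kind == "deletion", v$length, 0L),
      inserted_bases = v$inserted_bases), label = "x")
    ref_span <- substr(amp, a$ref_start + 1, a$ref_end)
    shifted <- al
    shifted$events$position <- shifted$events$position - a$ref_start
    expect_identical(apply_allele(ref_span, shifted), read)
  }
})

test_that("left normalization finds the leftmost equivalent placement", {
  amp <- "CCAAAACC"
  v <- variant_row(5, "deletion", 1)
  nv <- left_normalize(v, amp)
  expect_identical(nv$ref_position, 2L)
  expect_identical(nv$ref_position, enum_leftmost_position(amp, v))
  # non-repetitive context: unchanged
  v2 <- variant_row(3, "deletion", 2)
  expect_identical(left_normalize(v2, "ACGTCGAT")$ref_position, 3L)
  # idempotence and oracle agreement on randomized repeats
  set.seed(3)
  for (i in 1:60) {
    amp <- paste(sample(c("A", "C", "AA", "CC", "ACA"), 12, replace = TRUE),
                 collapse = "")
    n <- nchar(amp)
    if (i %% 2 == 0) {
      L <- sample(1:3, 1)
      p <- sample(1:(n - L - 1), 1)
      v <- variant_row(p, "deletion", L)
    } else {
      L <- sample(1:3, 1)
      p <- sample(1:(n - 1), 1)
      v <- variant_row(p, "insertion", L, random_seq(L, c("A", "C")))
    }
    nv <- left_normalize(v, amp)
    expect_identical(nv$ref_position, enum_leftmost_position(amp, v))
    expect_identical(left_normalize(nv, amp), nv)
  }
})

test_that("alignment is strand symmetric", {
  set.seed(41)
  for (i in 1:10) {
    amp <- random_seq(200)
    s <- sample(10:40, 1)
    read <- substr(amp, s, s + 99)
    p <- 50; L <- sample(2:6, 1)
    read <- paste0(substr(read, 1, p), substr(read, p + L + 1, 100))
    fwd <- semiglobal_align(read, amp)
    rev <- semiglobal_align(revcomp(read), amp)
    expect_identical(fwd$score, rev$score)
    expect_identical(fwd$ref_start, rev$ref_start)
    expect_identical(rev$strand, "-")
    expect_identical(extract_variants(fwd)[c("ref_position", "kind", "length")],
                     extract_variants(rev)[c("ref_position", "kind", "length")])
  }
})

test_that("degenerate and unaligned inputs raise errors", {
  expect_error(semiglobal_align("", "ACGT"), "non-empty")
  a <- semiglobal_align("TTTTTTTTTT", "ACAGCGCATG")
  expect_false(a$aligned)
  expect_error(extract_variants(a), "unaligned")
})
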