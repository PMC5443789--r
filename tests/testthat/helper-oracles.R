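# Independent oracles used across tests.  These deliberately share no code
# with the package implementation.

# plain-recursion semi-global affine-gap scorer (exponential; tiny inputs
# only).  Free amplicon end-gaps; gap of length L costs go + L * ge.
r_recursive_score <- function(x, y, match = 1, mismatch = -2,
                              go = -5, ge = -1) {
  xs <- strsplit(x, "")[[1]]
  ys <- strsplit(y, "")[[1]]
  m <- length(xs); n <- length(ys)
  rec <- function(i, j, prev) {
    if (i > m) return(0)                      # amplicon suffix is free
    best <- -Inf
    if (j <= n) {
      best <- max(best, (if (xs[i] == ys[j]) match else mismatch) +
                    rec(i + 1, j + 1, "M"))
      best <- max(best, (if (prev == "D") ge else go + ge) +
                    rec(i, j + 1, "D"))
    }
    best <- max(best, (if (prev == "I") ge else go + ge) +
                  rec(i + 1, j, "I"))
    best
  }
  max(vapply(0:n, function(j0) rec(1, j0 + 1, "M"), numeric(1)))
}

# all sequences over `alphabet` with lengths 1..maxlen
all_seqs <- function(maxlen, alphabet = c("A", "C")) {
  unlist(lapply(seq_len(maxlen), function(L) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    apply(grid, 1, paste, collapse = "")
  }), use.names = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# enumeration oracle for left-normalization: the smallest position at
# which an equivalent variant (same kind and length) yields the identical
# alternate sequence
enum_leftmost_position <- function(amplicon, variant_row) {
  alt <- crisprquant::apply_allele(
    amplicon,
    crisprquant::allele_spec(data.frame(
      position = variant_row$ref_position,
      deleted_length = ifelse(variant_row$kind == "deletion",
                              variant_row$length, 0L),
      inserted_bases = variant_row$inserted_bases)))
  n <- nchar(amplicon)
  L <- variant_row$length
  if (variant_row$kind == "deletion") {
    for (p in 0:(n - L)) {
      cand <- paste0(substr(amplicon, 1, p), substr(amplicon, p + L + 1, n))
      if (cand == alt) return(p)
    }
  } else {
    for (p in 0:n) {
      ins <- substr(alt, p + 1, p + L)
      cand <- paste0(substr(amplicon, 1, p), ins, substr(amplicon, p + 1, n))
      if (cand == alt) return(p)
    }
  }
  stop("no equivalent placement found")
}

# brute-force both-strand IUPAC site scan for restriction enzymes
IUPAC_MATCH <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

brute_sites <- function(sequence, recognition, cut_offset) {
  sc <- strsplit(sequence, "")[[1]]
  match_at <- function(patc, s) {
    all(vapply(seq_along(patc),
               function(k) sc[s + k - 1] %in% IUPAC_MATCH[[patc[k]]],
               logical(1)))
  }
  L <- nchar(recognition)
  patf <- strsplit(recognition, "")[[1]]
  patr <- strsplit(crisprquant::revcomp(recognition), "")[[1]]
  pal <- identical(paste(patr, collapse = ""), recognition)
  cuts <- integer(0)
  for (s in seq_len(nchar(sequence) - L + 1)) {
    if (match_at(patf, s)) cuts <- c(cuts, s - 1 + cut_offset)
    if (!pal && match_at(patr, s)) cuts <- c(cuts, s - 1 + (L - cut_offset))
  }
  cuts <- sort(unique(as.integer(cuts)))
  cuts[cuts > 0L & cuts < nchar(sequence)]
}

# recompute an alignment score from its op list under the default scheme
rescore_ops <- function(aln, scheme = crisprquant::scoring_scheme()) {
  s <- 0
  for (k in seq_len(nrow(aln$ops))) {
    kind <- aln$ops$kind[k]
    len <- aln$ops$length[k]
    s <- s + switch(kind,
                    match = len * scheme$match,
                    mismatch = len * scheme$mismatch,
                    scheme$gap_open + len * scheme$gap_extend)
  }
  s
}

# minimal alignment stub for window-classification tests
aln_stub <- function(ref_start, ref_end) {
  structure(list(ref_start = ref_start, ref_end = ref_end, aligned = TRUE),
            class = "amplicon_alignment")
}

variant_row <- function(pos, kind, length, ins = "") {
  data.frame(ref_position = as.integer(pos), kind = kind,
             length = as.integer(length), inserted_bases = ins,
             stringsAsFactors = FALSE)
}

no_variants <- function() {
  data.frame(ref_position = integer(0), kind = character(0),
             length = integer(0), inserted_bases = character(0))
}
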