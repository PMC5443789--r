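---
title: "Quantifying CRISPR editing from amplicon reads: models and design choices"
author: "crisprquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CRISPR editing from amplicon reads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprquant)
```

# The measurement problem

After a CRISPR/Cas9 (or paired-nickase) editing experiment, the editing
outcome at a locus is read out by deep sequencing of a PCR amplicon
spanning the target site. Error-prone end joining leaves small insertions
and deletions (indels) near the cleavage site; the quantity of interest is
the fraction of amplicon molecules carrying such an indel. This package
implements the full desk side of that experiment:

1. **Read QC** — truncate each read at its first base below a Phred
   threshold and drop reads too short to be informative.
2. **Alignment** — align each surviving read to its amplicon with a
   semi-global affine-gap aligner; extract indels and left-normalize them.
3. **Editing rate** — classify reads against a window around the predicted
   cleavage site, with a displaced control window measuring background,
   and compare site and background rates across loci with a paired t-test.
4. **In-silico RFLP** — predict restriction digests of edited alleles,
   the uncut-band fraction of a mixture, and clone genotypes from band
   patterns.
5. **Deletion genotyping** — predict the two PCR products of a
   paired-guide deletion design and call clones WT / monoallelic /
   biallelic.
6. **Episome decay** — fit the per-generation loss rate of an episomal
   (OriP/EBNA1-type) vector from qPCR time series.
7. **Synthetic data** — generate loci, edited alleles, FASTQ reads and
   decay series with the statistical structure the analysis assumes, so
   that every stage is testable without any sequencing download.

All coordinates are 0-based and half-open; cleavage sites are inter-base
coordinates (a cut at `c` falls between bases `c - 1` and `c`).

# Guides, cut sites and windows

SpCas9 guided by a 20-nt protospacer next to an NGG PAM cuts bluntly 3 nt
5′ of the PAM, i.e. between protospacer bases 17 and 18. With the
protospacer at plus-strand interval `[s, s + 20)` this puts the cut at
`s + 17` for a plus-strand guide and at `s + 3` for a minus-strand guide
(`predicted_cut_site()`); the construction is translation-equivariant and
anything without an NGG PAM is rejected.

The **editing window** is `[cut - h, cut + h)` with halfwidth `h = 15` by
default — a 30-bp interval, matching the 30-bp control fragment, which is
why the symmetric reading of a "15-bp adjacent" window was adopted over a
one-sided 15-bp window; `h` is a parameter so the one-sided reading is
runnable too. Paired nickases leave offset nicks and their indels spread
between the two nick coordinates, so `nickase_window()` spans
`[min - h, max + h)`. The **control window** is a 30-bp interval 50 bp
downstream of the cut (upstream when the amplicon is too short on the
right); because the gap exceeds the halfwidth the two windows are always
disjoint, and because most indels are well under 50 bp the control sees
only background.

A read is **uninformative** for a window unless its aligned reference
span fully contains the window; it is **edited** when a deletion interval
intersects the window or an insertion anchor touches it, and **unedited**
otherwise. Substitutions never count as editing. The editing rate is
`n_indel / n_window_covering`. This denominator deliberately deviates from
"all aligned reads": a read that does not span the window cannot be
classified either way, so including it would deflate rates by an arbitrary
coverage factor; both counts are reported so either rate can be formed.
The zero-covering case is an error, not a rate of 0.

Site-versus-background comparisons across loci use the classic paired
two-sided Student's t-test on per-locus rate differences (delegated to
`stats::t.test`; `n - 1` degrees of freedom, sample standard deviation).
Fewer than two pairs, or all-zero differences, are degenerate inputs and
raise errors.

# The aligner

Single-amplicon references make seed-and-extend mapping pointless, so the
package specifies its own alignment exactly: **global in the read, free
end-gaps on the amplicon**, affine gaps where a gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{extend}$. Defaults: match $+1$, mismatch
$-2$, open $-5$, extend $-1$. Two consequences of this scheme are load
bearing:

* a single long deletion (tens of bp, as paired nickases produce) stays
  one event rather than fragmenting, because extension is cheap;
* one substitution is always preferred to a compensating gap pair, so
  substitution-only sequencing noise essentially never fabricates indels.

The reverse complement of the read is also aligned and the better score
wins (forward on ties). Tie-breaking among equal-scoring paths is
deterministic — diagonal over deletion over insertion within a cell,
smallest reference end at the final cell — and `left_normalize()` then
shifts every indel to its smallest reference position yielding the same
alternate sequence, so window membership is well defined inside repeats.
Reads scoring below `min_score_fraction` (default 0.6) of the perfect
score are flagged unaligned and excluded from every denominator.

Implementation: a Gotoh three-state dynamic program in C++ with full
traceback. Two throughput shortcuts are used in batch mode, one exact and
one conservative. Reads placeable ungapped with at most one mismatch skip
the dynamic program — under the default scheme such a placement is
provably optimal and shares the leftmost tie-break. When the ungapped scan
fails, a 12-mer vote decides the strand: only if one orientation shares
k-mers with the amplicon and the other shares none is the losing strand
skipped; indecisive votes fall back to the exact both-strand program.
`semiglobal_align()` itself always runs both strands exactly.

Correctness is audited against an independent reference scorer
(`semiglobal_score_reference()`, a memoized top-down recursion over
suffixes that shares no code with the production DP), against a
plain-recursion oracle in the test suite, and against
`Biostrings::pairwiseAlignment` (type `"global-local"`), whose gap-cost
convention was verified to coincide. The validation sweep covers all
2-letter sequence pairs up to length 8 (260,100 pairs) plus random
4-letter pairs up to length 12.

With several amplicons, each read is assigned to its best-scoring
amplicon (k-mer pre-vote, then score comparison); reads tied between
amplicons are dropped.

# Read QC

The quality rule is strict truncation: the longest prefix in which every
Phred score is at least 30 is kept, the first base *below* 30 and
everything after it is removed — so a Q30 base itself is retained.
Truncation is idempotent and a prefix operation (never internal masking).
Reads shorter than `min_length` (default 50 bp — enough to span a 30-bp
window plus anchor sequence) are discarded and tallied; they never reach
alignment, which is the only self-consistent reading of a pipeline whose
denominators are built from aligned reads.

# In-silico RFLP

A restriction enzyme is a recognition site (IUPAC) plus the 0-based
top-strand cut offset within it; SacI, AgeI, XbaI, BstXI and EcoRI are
built in and further enzymes load from a TSV. Matching is IUPAC-aware on
both strands, with palindromic sites reported once and bottom-strand
sites of non-palindromic enzymes projected to mirrored top-strand cuts.
Only top-strand cut positions define fragment lengths (blunt-cut
approximation) — overhang geometry is invisible at gel resolution, and
digest fragment lengths always sum to the input length.

An allele **destroys** the assayed site when the digest of its mutated
sequence has no cut within one recognition length of the original cut
position (lifted through the allele's indels). The mixture-level
`rflp_rate()` is then the summed fraction of destroying alleles — the
uncut band fraction, as molecule fractions rather than densitometry,
since no band-intensity model is specified anywhere upstream. Because an
indel can sit inside the editing window yet leave the recognition
sequence intact, the RFLP rate is systematically *below* the sequencing
editing rate of the same mixture; the validation experiments confirm the
dominance on randomized mixtures. Clone genotyping reads the band
pattern: cut fragments only → WT, uncut only → biallelic edit, both →
heterozygous; bands within ±5 bp are treated as co-migrating.

# Deletion genotyping

A paired-guide deletion design carries two primer pairs: an *internal*
pair binding inside the deleted interval (reports the non-deleted allele)
and a *junction* pair flanking it (reports the deletion, because its
intact product is too long to amplify). Primer binding is exact
full-length matching — the assay is presence/absence, and exact matching
keeps the contract testable; a primer with multiple binding sites is an
ambiguous design, an error rather than a guess. `predict_pcr()` returns
the product length, or none if a site is missing, the orientation is
wrong, or the product exceeds `max_product` (the PCR-dropout knob that
makes junction primers deletion-specific). The two-band truth table then
calls clones: junction only → biallelic, both → monoallelic, internal
only → WT, neither → assay failure. The simulated design fixture uses a
319-bp deletion in a 1.2-kb template, an exon-scale deletion typical of
such experiments.

# Episome decay

An episomal vector lost at rate $r$ per cell generation follows
$N(g) = N_0 (1-r)^g$ with $g = 24\,d/T$ generations after $d$ days at
generation time $T$ hours. `fit_loss_rate()` regresses $\log N$ on $g$
by ordinary least squares and reports $r = 1 - e^{\text{slope}}$: the log
scale matches the multiplicative noise of qPCR quantification, and
noiseless series invert exactly. The default generation time of 24 h is a
typical human pluripotent stem cell doubling time and is a parameter, not
a constant. Fewer than three points, non-positive copy numbers, or a
fitted rate outside $(0,1)$ (e.g. a constant series) are errors. The
simulator draws sampling days every two days by default and applies
mean-one lognormal noise of configurable CV; generating rates in the
3–6 % per generation range are recovered with negligible median bias at
CV 5 % in the validation experiments.

# The synthetic-data generator

`generate_locus()` builds a random amplicon (default 300 bp, at least
twice the read length) carrying the geometry every RFLP-verified editing
locus needs: a guide whose cut sits mid-amplicon, an NGG PAM, and a
restriction site overlapping the editing region (ending at the cut in
Cas9 mode; centered between the nicks in nickase mode). Nickase mode
places two opposite-strand guides PAM-out with a nick-to-nick offset
drawn from 10–60 bp.

Allele samplers draw one indel per allele. NHEJ deletions follow a
truncated geometric on [1, 30] bp re-normalized to mean 6 (the parameter
is solved numerically so the *truncated* mean hits the target);
insertions of 1–10 random bases occur with probability 0.3 and anchor at
the cut. Nickase alleles are single deletions on [6, 78] bp with mean 30,
the size spectrum such experiments report, placed to intersect the
interval spanned by both nicks; the distribution family and its
parameters are configuration knobs, since only the mean and range are
known constraints.

`simulate_reads()` emits 150-bp single reads by default (the two mates of
an unmerged pair are modeled as independent reads; mate-overlap merging
is deliberately not modeled). Each read is a contiguous window of its
allele's sequence placed to contain the editing window plus a
`window_pad` margin (default 15 bp) on each side when the allele permits
— the margin mirrors primers flanking the target generously and
guarantees alignment anchors on both sides of an indel. Half the reads
are emitted reverse-complemented, with quality decay applied in
sequencing-cycle order, so reverse reads carry their good cycles at the
amplicon's right end; this is what gives the displaced control window
coverage at all. Per-cycle mean Phred decays linearly (38 to 28 by
default, so the Q30 truncation rule is genuinely exercised) with Gaussian
spread (sd 3) clamped to [2, 40]. Substitution errors are injected
per base (default $10^{-3}$); an optional `indel_error_rate` adds
spurious 1-bp indels for studies of background indel noise and defaults
to 0. The true allele label rides in the read header — a test-only
channel the pipeline never reads. Every generator is a pure function of
its seed, and an `exact_counts` mode allocates reads to alleles by
largest-remainder rounding when sampling noise itself is the nuisance.

What the generator does **not** emulate: PCR amplification bias and
chimeras, indel sequencing errors (unless explicitly switched on),
quality–error correlation, mate overlap, microhomology-directed outcome
spectra, and multi-indel alleles. Passing tests therefore show that the
estimators are correct *under the stated model*, not that real libraries
are free of these artifacts. Sequencing depth per amplicon is not a
published constraint; the pipeline-level default of 2,000 reads per locus
(5,000 in the generator's own default) is an order-of-magnitude choice
for targeted amplicon panels.

# Statistical behaviour of the containment estimator

Two properties of the denominator rule deserve explicit statement; both
were found by simulation against ground truth and are reproduced by the
validation experiments.

**Truncation starvation is allele-dependent.** An insertion widens the
editing window in read space (a read must sequence the inserted bases
*and* the window), a deletion narrows it. Under heavy quality truncation
the probability that a read still spans its window therefore differs
between alleles, and the covering-read mixture is biased — with the
default decaying profile and a mid-window 8-bp insertion allele the
reported rate at a true fraction of 0.5 runs several points low. The
parameter-recovery experiments therefore use a flat Q38 profile, under
which informativeness is essentially allele-independent and the
binomial recovery model holds; with real, harshly truncated short reads
the containment rate should be interpreted as conditional on coverage,
and both `n_aligned` and `n_window_covering` are reported for that
reason.

**Near-end indels are invisible.** Under any scheme with gap costs above
mismatch costs, an indel within roughly 10 bp of a read end is optimally
absorbed as a few mismatches — the alignment is right, the read simply
cannot witness the edit, and such reads drop out as uninformative. The
generator's `window_pad` default keeps simulated reads anchored well
clear of this regime; the RFLP-dominance experiment additionally uses
250-bp error-free reads of the 300-bp amplicon (the sequencing arm of an
RFLP-versus-sequencing comparison effectively reads whole cloned
amplicons), which makes RFLP-rate dominance an exact property of the
model rather than a race against absorption noise. Large nickase
deletions interact with the acceptance threshold the same way: a 150-bp
read spanning a deletion of more than ~55 bp scores below the default
`min_score_fraction` of 0.6; nickase studies at the top of the 6–78 bp
spectrum should lower the threshold or use longer reads.

**Background calibration needs a background.** With substitution-only
noise, site and control indel rates are both exactly zero and the paired
t-test is degenerate by construction. The type-I calibration experiments
therefore switch on a small background indel error rate
($2\times10^{-3}$ per base), the in-model analogue of the PCR/sequencing
indel noise floor that real amplicon data always shows and that the
control window exists to measure; at 9 loci and 400 reads per locus the
test's rejection rate at $\alpha = 0.05$ sits at its nominal level.

# Validation experiment sizes

The experiments in `inst/validation/experiments.R` (run by the test suite
and by `scripts/acceptance.R`) use: the full 2-letter length-≤8 pair
sweep plus 200 random 4-letter pairs for the aligner audit; 50 replicates
of 2,000 reads at true fractions {0, 0.1, 0.5, 0.93}; 200 calibration
replicates of 9 loci × 400 reads; 100 randomized RFLP mixtures of 400
reads; 100 random 1-kb digests per enzyme; 100 simulated deletion clones;
50 noisy decay series; and 10,000 nickase allele draws. These sizes give
the Monte-Carlo checks 3-sigma headroom against their tolerances while
keeping a full run in minutes on one core.

# Known limitations

* Rates are molecule/read fractions; no gel densitometry model, no
  partial digests, no methylation sensitivity.
* Best-amplicon assignment drops reads tied between amplicons rather
  than resolving them; no split or chimeric alignments.
* The containment denominator is conditional on window coverage (see
  above); with severely truncated reads it is not a simple binomial draw
  of the molecule mixture.
* HDR/knock-in outcomes, per-allele phasing and microhomology analysis
  are out of scope.
* Primer binding in deletion genotyping is exact-match; thermodynamic
  effects (Tm, dimers, mismatch tolerance) are not modeled.
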