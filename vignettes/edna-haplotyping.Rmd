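---
title: "Methods: eDNA amplicon haplotyping, error calibration and population differentiation"
author: "ednahap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eDNA amplicon haplotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Population-genetic monitoring of small, elusive cetaceans such as the
harbour porpoise (*Phocoena phocoena*) is limited by tissue sampling.
Seawater collected in the fluke print of a diving animal carries enough
shed cellular material that a hypervariable mitochondrial control-region
amplicon (~450 bp) can be PCR-amplified and sequenced at depth, and the
animal's haplotype read off against a reference database of known
haplotypes. Two things make this harder than ordinary amplicon work:

* the template is dilute and PCR-heavy, so sequencing plus polymerase error
  produces a cloud of near-true sequences whose abundance must be separated
  from genuine secondary haplotypes (a sample can contain DNA from more
  than one animal), and
* downstream inference (stock structure) needs per-sample haplotype calls
  of defensible quality, not just community composition.

`ednahap` implements the full workflow: read processing, chimera removal,
an error-frequency threshold *calibrated from positive controls of known
haplotype*, reference assignment with novel/secondary-haplotype rules,
AMOVA-based Phi~ST~ and chi-squared differentiation tests across geographic
strata, and qPCR standard-curve quantification. A built-in simulator
generates every input with known ground truth, so the whole chain is
testable offline.

## Read processing

Each mate of a pair is handled independently: adapter occurrences are
removed by simple end matching (full-length match at the 5' end, or of the
reverse complement at the 3' end, tolerating 10% mismatches), then primer
occurrences the same way, then 3' quality trimming with the BWA-style
running-sum rule at Phred threshold `q = 20`: the read is cut at the
position maximising the partial sum of `(q - q_i)` from the 3' end. Pairs
are merged by scoring every overlap of at least `min_overlap = 50` bp as
`matches - mismatches`; the best score wins, ties go to the longer overlap,
and an `N` never counts as a match (this avoids spurious merges through
uncalled stretches). A pair is rejected when the best overlap's mismatch
fraction exceeds `max_mismatch_frac = 0.1` (a configurable choice; merger
defaults elsewhere differ). At a mismatch the higher-quality base is kept
(mate 1 on ties); merged quality is the maximum of the two at matches and
the absolute difference at mismatches. Merged contigs are upper-cased,
restricted to a minimum aligned length of 379 bp, and dereplicated into
unique sequences with counts, sorted by count descending with
lexicographic tie-breaks so all downstream processing is deterministic.

Read accounting is exact at every stage
(`input = merged + merge-rejected + trim-dropped`), and per-sample
frequencies use the *surviving* reads (merge + length filter) as
denominator. Because that denominator convention is genuinely ambiguous in
field practice — "processed reads" can also mean all merged-pair contigs —
both counts are kept in the per-sample report and
`run_edna_pipeline(threshold_denominator = "merged")` switches the
convention used by the threshold stage.

## Chimera removal

PCR chimeras are detected de novo with a deterministic two-parent
perfect-crossover rule: processing unique sequences in descending
abundance, a sequence is flagged iff two earlier-accepted parents exist,
each at `abundance_skew = 2` times its count or more, such that a single
breakpoint reproduces it exactly as parent-A-prefix + parent-B-suffix while
it differs from each parent by at least `min_diffs_to_parent = 2`
substitutions. This is a simplified, exactly checkable variant of the
chunked uchime-denovo heuristic — a variant, not a clone — and is verified
in the tests against a brute-force enumeration over all breakpoints and
parent pairs. For amplicon-scale chimeras (equal-length templates, sparse
divergence) the perfect-crossover model is what the heuristic converges to;
what it will not flag are chimeras with additional post-crossover errors,
which at realistic error rates sit far below the frequency threshold anyway.

## Error calibration from positive controls

The pipeline's central statistic is empirical: each positive control is a
library amplified from tissue DNA of known haplotype, so any unique
sequence other than the known haplotype is error. The per-control error
rate is the frequency of the *most abundant* such sequence (count over the
control's denominator); the filter threshold applied to eDNA samples is a
rounding of the maximum rate across controls. The default rule rounds up to
the next whole percent — an observed maximum of 1.70% yields a 2% working
threshold — because a round working threshold is what one would defensibly
carry forward from a small number of controls; `rounding = "raw_max"` uses
the observed maximum unchanged. "Not identical to the known haplotype" is
evaluated by exact string comparison in dereplicated sequence space, which
is the space the filter operates in. Pipeline order is chimera flagging,
then calibration (on chimera-free controls), then thresholding; the
threshold retains sequences at or above it and removes chimera-flagged
sequences regardless, and is idempotent and monotone.

A sample whose surviving dereplicated depth is under 1% of its merged-pair
contigs is excluded outright (`depth_criterion_ok()`): at such depth even a
high-identity consensus is compatible with concentrated sequencing error —
e.g. 510 dereplicated reads against 221,922 contigs (0.23%) fails the rule.

## Haplotype calling

Retained sequences are assigned by global pairwise alignment (match +1,
mismatch −1, gap open −2, gap extension −1, via `Biostrings`) against every
reference haplotype and its reverse complement; identity is matches over
alignment columns, ties go to the lexicographically smallest id, and
reverse-complement hits are reported in forward orientation. Decision
rules:

* identity 1.0 — a **known** haplotype;
* identity in `[0.98, 1)` **and** at least 20% of processed reads — a
  **novel** haplotype (provisional id, shared across samples with the same
  sequence); the 20% evidence bar is the secondary-haplotype rule, applied
  symmetrically to primary sequences as well;
* identity at or above the 0.98 floor but under 20% — rejected
  (low fraction);
* identity below 0.98 — rejected as non-target (e.g. plankton
  co-amplification).

The most abundant accepted call in a sample is ranked primary, any others
secondary; a sample with no accepted call yields a single failed-sample
record. The 0.98 non-target floor is a configurable judgement call: a
single substitution over 379 bp is 99.74% identity (clearly porpoise),
while non-target hits sit far below; the floor separates those regimes with
a wide margin. Novel calls are provisional by design — confirming a
haplotype seen in one sample ultimately requires resequencing or recovery
in further samples — so they carry their identity and read-fraction
evidence rather than a verdict.

## Population differentiation

Each accepted call contributes one observation (a secondary haplotype
reflects a distinct contributing animal); sample-level treatment of
multi-haplotype samples is configurable upstream by filtering the call
table to primaries. Phi~ST~ follows the AMOVA decomposition of squared
pairwise nucleotide distances: with `SS_total = (1/N) Σ_{i<j} d²`,
`SS_within = Σ_k (1/n_k) Σ_{i<j∈k} d²`, `MS_among = SS_among/(K−1)`,
`MS_within = SS_within/(N−K)` and `n' = (N − Σn_k²/N)/(K−1)`,

    σ²_w = MS_within,  σ²_a = (MS_among − MS_within)/n',
    Phi_ST = σ²_a / (σ²_a + σ²_w).

The chi-squared statistic is the classical contingency form over
haplotype-by-stratum counts (cells with positive expectation), with an
asymptotic p at `(H−1)(K−1)` df. Both tests report permutation p-values
from seeded shuffles of stratum labels over observations, with the observed
statistic included: `p = (1 + #{perm ≥ obs})/(n_perm + 1)`, so p is never
zero and never exceeds 1. All-zero distance matrices return a
"monomorphic" status with Phi 0 and p 1 rather than 0/0.

Two numerical notes. First, permutation comparisons use a `1e-12` slack so
label orders that merely permute within strata are counted as ties rather
than lost to floating-point jitter. Second, the estimator's finite-sample
floor: when two strata have *identical* haplotype multisets, `SS_among` is
exactly zero and Phi~ST~ equals `−1/(n'−1)`, not 0 — the estimator is
centred near zero only under label exchangeability. The tests assert this
exact behaviour rather than a spurious "equals zero" claim, and the type-I
property (uniform permutation p under panmixia, rejection rate near the
nominal 5%) is checked over 200 simulated panmictic datasets.

## qPCR quantification

The relative standard curve is an ordinary least-squares fit of Ct on
log10(concentration) over a 1:10 dilution series (defaults emulate 1.3
ng/µl down to 1.3×10⁻⁵ ng/µl, six standards); amplification efficiency is
`10^(−1/slope) − 1` (slope −3.3219 is exact doubling). Unknown wells are
averaged on the Ct scale over determined replicates, called detected at or
below a 45-cycle cutoff, and converted by `10^((Ct − intercept)/slope)`;
the cohort summary covers detected non-control samples. A non-negative
fitted slope flags the curve invalid, and fewer than three usable standards
is an error.

## The simulator: what it emulates and what it does not

`simulate_cohort()` generates the complete study: a reference database
(equal-length haplotypes, each 1–30 substitutions from a random ancestral
sequence — matching observed control-region divergence), eDNA samples
drawing one or two haplotypes from per-stratum frequency vectors, positive
controls of known haplotype, negative controls, a non-target contaminant
(<70% identity to any reference), PCR chimeras with breakpoints uniform on
`[50, L−50]` (guaranteeing both parent segments are detectable), and i.i.d.
per-base substitution errors with the constant Phred quality matching the
error rate (capped at Q40). Everything is deterministic given the seed;
identical configurations give byte-identical FASTQ/FASTA/TSV output (files
are written uncompressed for byte-level reproducibility; readers accept
gzipped input transparently).

Defaults are the study conditions the package is designed around: 58
reference haplotypes; 450 bp amplicon read as 2×300 bp (so primer-flanked
templates of ~499 bp merge with ~101 bp overlaps); 20 eDNA samples across
two strata (a shared dominant haplotype, diverging minor frequencies over 8
haplotypes); 4 positive and 2 negative controls; 10,000 read pairs per
sample — a deliberate scale-down from real MiSeq depth (~240k/sample) that
preserves every frequency-based decision; multi-haplotype probability 0.10
with minor fractions in [0.20, 0.40] (observed field minors run ~21–23%
with the dominant haplotype above 59%); per-base error 0.003; chimera and
contaminant fractions 0.01 and 0.005. Negative controls emit zero reads, as
field negatives that produce no detectable PCR product are not sequenced.
Positive controls are simulated without contaminant reads (tissue-derived
libraries), so their error rates reflect sequencing/PCR substitution error
only.

What the simulator does **not** emulate — and therefore what passing tests
do not show about field data: positional quality decay and quality-score
miscalibration (qualities are constant, so quality trimming is exercised
only by constructed tests); indel sequencing errors and length-variant
haplotypes (all distances are substitution distances); the concentrated,
non-i.i.d. error spectrum of early-cycle PCR errors, which is exactly why
the empirical control calibration exists (on i.i.d. errors the calibrated
threshold is conservative: the most abundant error unique sits far below
1%, while real controls show error concentrations of 1–2%); eDNA
degradation kinetics; and cross-sample index bleed. The per-base error
default of 0.003 means ~74% of 450 bp reads carry at least one error, so
the true haplotype's dereplicated frequency is ~26% — decision thresholds
that are read *fractions of processed reads* (the 20% rule) therefore bind
against post-error frequencies, which the simulator reproduces faithfully.

## Problem sizes used by the test suite

Unit tests run on small constructed instances and oracle comparisons
(exhaustive merges, breakpoint enumeration, `N ≤ 8` exhaustive permutation
p-values). The end-to-end property test and the acceptance script run the
full default cohort (24 sequenced samples × 10,000 pairs); the type-I study
uses 200 panmictic datasets of 30 observations at 500 permutations each.
These sizes are the package's chosen desk-scale study conditions.

## Known limitations

* The chimera detector requires exact crossovers and equal-length parents;
  it is a documented variant of the chunk-vote heuristic, not a clone.
* Identity-based calling assumes the reference alignment length; novel
  haplotypes with indels relative to the references would be scored through
  gap penalties but the simulator never generates them, so that path is
  untested against truth.
* Phi~ST~ and chi-squared here are global two-or-more-stratum tests;
  pairwise stratum matrices and other F-statistics are out of scope.
* The qPCR module fits relative curves only; absolute copy-number
  quantification and amplification-curve processing are out of scope.
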