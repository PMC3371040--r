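---
title: "Methods: post-hoc variant filtering and spurious-exon detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-hoc variant filtering and spurious-exon detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfilt)
```

## Scope and assumptions

`varfilt` operates strictly downstream of mapping and calling: it consumes
VCF call sets (QUAL column, `INFO:DP`, `INFO:DP4`), BED exon intervals,
SAM/BAM alignments and tab-separated validation truth tables, and never
recomputes genotypes or pileups. The underlying assumptions are those of a
standard exome pipeline: duplicates are marked before calling (duplicate-
flagged, secondary and supplementary alignments are skipped on input),
QUAL is phred-scaled and comparable across sites within a call set, and
DP4 counts the high-quality subset of the reads contributing to DP —
a record whose DP4 sum exceeds its DP is rejected as malformed.

Coordinates follow each format's own convention (VCF/SAM 1-based, BED
0-based half-open); all internal interval arithmetic is 0-based half-open,
so a read of span $s$ at 1-based position $p$ covers $[p-1,\,p-1+s)$ and
overlaps an exon $[a,b)$ iff $p-1 < b$ and $p-1+s > a$. Multi-allelic VCF
records are split per ALT allele with QUAL/DP/DP4 duplicated (and a
warning), since the evaluation is keyed on (chrom, pos, ref, alt, sample).

## Truth-set evaluation

The evaluation universe is the truth table. A truth entry is *predicted*
when its key appears in the call set and the call passes the cutoffs
(QUAL $\ge q$ and DP $\ge d$, both inclusive — matching the conventional
"QUAL≥28, DP≥5" notation). Entries absent from the call set are false
negatives if validated and true negatives if failed; this is the only
assignment under which counts always conserve
($TP+FP+TN+FN = |\mathrm{truth}|$, property-tested).

Metrics:

$$\mathrm{recall} = \frac{TP}{TP+FN},\qquad
  \mathrm{accuracy} = \frac{TP}{TP+FP},\qquad
  F = \frac{2\,\mathrm{acc}\cdot\mathrm{rec}}{\mathrm{acc}+\mathrm{rec}}
    = \frac{2TP}{2TP+FP+FN}.$$

"Accuracy" is deliberately the validation-study usage — what machine
learning calls precision. The definition is forced by the published worked
cells this package reproduces (e.g. $50/59 = 84.75\%$ with $TP=50$,
$FP=9$); the documentation states the equivalence everywhere the name
appears. A metric with a zero denominator is encoded as `NA` ("undefined")
and excluded from maximization, never coerced to 0 — with 0 in its place a
degenerate cutoff that predicts nothing could tie or beat real cutoffs.

Design choices in `grid_search()`:

* exhaustive evaluation of the integer grid (default QUAL 15–35 ×
  DP 3–15; 273 combinations run in well under a second), cross-checked in
  the tests against an independently coded double loop;
* **all** F-maximizing combinations are reported, since tied maximizers
  are common on small truth sets and the choice between them is a
  recall-versus-accuracy judgement the analyst should see;
* maximization uses unrounded F; rounding to the 4 decimals used for
  display could merge near-ties.

`apply_filter()` carries the conventional depth-bounds pre-filter
(3 ≤ DP ≤ 10,000 by default, the `varFilter -d 3 -D 10000` convention).
Records lacking DP cannot demonstrate a depth inside active bounds and are
excluded there; with inactive bounds the filter is the identity.

## Allele/strand balance

For each variant the DP4 field gives high-quality read counts on
(ref-fwd, ref-rev, alt-fwd, alt-rev). The indicator is 1 when any
component is below the support threshold (default 1 read, configurable —
"at least one supporting read per case" is the rule being probed, but
stricter thresholds are a legitimate sensitivity analysis). The 2×2 table
of indicator × validation status is tested with a two-sided Fisher's exact
test.

The test is self-contained and explicit: conditioning on both margins, it
sums hypergeometric probabilities of all tables at most as probable as the
observed one, with a relative tolerance of $10^{-7}$ so that
floating-point noise cannot drop an exactly tied table from the two-sided
sum. The observed table is always included, hence
$p \ge P(\mathrm{observed}) > 0$; a zero margin returns $p = 1$ (no
association testable). Sidedness is two-sided by default — the deficiency
could in principle associate with either status, and the two-sided p is
the conservative report. Tests verify exact agreement (to $10^{-10}$, in
practice $\sim 10^{-15}$) with a `choose()`-based enumeration oracle over
every 2×2 table of total ≤ 40, and agreement with `stats::fisher.test`,
which serves only as a cross-check.

The indicator is reported as a diagnostic flag rather than applied as a
hard filter by default: a strong association with validation failure does
not imply that filtering on it improves recall or accuracy on a given
data set, so the decision is left to the analyst.

## Spurious exons

A spurious locus shows (1) inflated coverage — reads from a homologous
region absent from the reference are forced onto it — and (2) poor mapping
confidence, because those reads align with many mismatches. Per exon and
sample:

$$RPE_e = \frac{c_e / \ell_e}{\sum_i c_i \,/\, \sum_i \ell_i},\qquad
  P_{HQR,e} = \frac{\#\{\text{reads in } e:\ \mathrm{MAPQ}\ge 40\}}
                   {\#\{\text{reads in } e\}}$$

with $c_e$ the number of reads overlapping exon $e$ by ≥ 1 base (a read
spanning two exons counts in both) and $\ell_e$ the exon length. The RPE
denominator is the sample's mean exonic read *density*, not its raw read
total: this normalization is what makes the flagging threshold
$RPE > 1.5$ interpretable as "50% above average density", makes the same
exon comparable across samples with different yields, and yields the
algebraic conservation $\sum_e RPE_e\,\ell_e = \sum_e \ell_e$ that the
property tests assert to $10^{-9}$. It is also scale-free: duplicating
every read changes neither RPE nor $P_{HQR}$.

Numerical details: the MAPQ high-quality boundary is inclusive
(MAPQ = 40 counts as high); both flagging inequalities are strict, so an
exon sitting exactly on a threshold is not flagged; exons with zero reads
have undefined $P_{HQR}$ and are never flagged; reads with MAPQ 255
(unavailable) count toward coverage but are excluded from $P_{HQR}$ with a
warning. All thresholds (1.5, 0.4, MAPQ 40, recurrence 31) are arguments
with these defaults — they are pragmatic working values, not estimated
quantities, and a cohort with different depth or capture chemistry may
need different ones.

`recurrence_report()` counts, per exon, the samples in which it was
*flagged* (not merely covered), including matched controls — the artifact
is systematic and disease-status-independent, so controls add evidence.
The default cutoff of 31 encodes "more than 30 of 36 samples" (≈ 83%) as
an inclusive minimum.

## What the synthetic fixtures emulate — and what they do not

`gen_variant_set()` draws QUAL from class-specific truncated normals and
DP from shifted, clamped negative binomials (over-dispersed counts being
the realistic choice for sequencing depth). DP4 is built by binomially
assigning a high-quality subset of DP to ref/alt and each allele to
strands, then zeroing one uniformly chosen component with a class-specific
probability (defaults 0.05 true / 0.8 failed) — the simplest mechanism
producing a strand-deficiency enrichment among failed variants. The
default composition mirrors a published validation cohort's shape
(65 validated of 159 SNVs; 12 of 22 indels). The `"separable"` preset
plants a clean separation (true: QUAL ∈ [30, 60], DP ∈ [6, 60]; false:
QUAL ∈ [0, 25], DP ∈ [1, 4]) under which a correct grid search must reach
F = 1.

`gen_alignment_set()` writes per-sample SAM files over a default set of
10 equal-length (300 bp) exons spaced farther apart than a read length,
with Poisson read counts per exon (baseline 0.3 reads/base ≈ 90 reads per
exon), reads placed fully inside exons with exact-match CIGARs, and MAPQ
drawn from 50–60 (background, 5% low) or 0–30 (planted exons, 80% low).
Planted exons get 3× baseline density.

These fixtures validate the *machinery*, not the biology: real data have
overlapping and adjacent exons, soft-clipped and spliced reads,
correlated QUAL/DP errors, batch effects, and MAPQ distributions that are
neither bimodal nor clean at the 40 boundary. Passing the planted-recovery
tests shows the statistics and thresholds behave as specified under their
own assumptions — it does not certify any particular threshold for a real
cohort.

Problem sizes in the shipped tests were chosen to exercise every code
path at desk scale: truth sets of 140–300 variants, the full 273-cell
grid, exhaustive Fisher enumeration to table total 40 (135,751 tables),
and 36-sample × 10-exon alignment cohorts over five seeds; the whole
suite completes in about a minute.

## Known limitations

* No ROC/AUC machinery: with a single modest truth set the cutoff grid
  plus F score is the honest summary; a continuous score calibration is
  out of scope.
* The DP cutoff uses the caller's raw `INFO:DP`, not the DP4 sum; callers
  differ in how they define DP, and the choice is documented rather than
  hidden (the DP4 sum is available in the parsed records for anyone who
  prefers it).
* The spurious-exon screen detects the coverage/quality *signature*; it
  does not locate the homologous source region or attempt realignment.
* Truth tables are assumed binary (validated/failed); ambiguous Sanger
  outcomes must be resolved before import.
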