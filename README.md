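# varfilt

Post-hoc filtering and diagnostics for called sequence variants.

## The problem

Short-read variant callers (SAMtools mpileup, GATK UnifiedGenotyper and
their successors) emit far more candidate SNVs and indels than are real:
validation rates of raw call sets are routinely below 50%. Before spending
wet-lab resources confirming candidates, an analyst wants to (i) pick
quality and depth cutoffs that are justified by data rather than folklore,
(ii) screen candidates for allele/strand imbalance, and (iii) avoid
"spurious genes" — loci such as *CDC27* that accumulate artifactual calls
in project after project because reads from a homologous region missing
from the reference pile up there with mismatches.

`varfilt` implements this post-calling stage for anyone with a call set in
VCF, an orthogonal validation truth table, and (for the spurious-locus
screen) per-sample alignments.

## What it computes

**Truth-set evaluation and cutoff optimization.** Each truth entry is
classified against the call set at cutoffs (QUAL ≥ q, DP ≥ d) into
TP/FP/TN/FN, and summarized as

- recall = TP / (TP + FN)
- accuracy = TP / (TP + FP) (the validation-study convention; elsewhere
  called precision)
- F = 2·accuracy·recall / (accuracy + recall) = 2TP / (2TP + FP + FN)
- validate rate = (TP + FN) / (TP + FP + TN + FN)

`grid_search()` evaluates every cutoff pair on an integer grid (default
QUAL 15–35 × DP 3–15, 273 combinations) and reports *all* pairs attaining
the maximal F.

**Allele/strand balance.** From the VCF `DP4` field (high-quality
ref-forward, ref-reverse, alt-forward, alt-reverse read counts), a variant
is scored 1 if it lacks support in any of the four cases. The 2×2 table of
this indicator against validation status is tested with a two-sided
Fisher's exact test, implemented by direct hypergeometric enumeration
(tables with probability ≤ that of the observed table, relative tie
tolerance 1e-7).

**Spurious-exon screen.** Per exon and sample,

- RPE = (reads_in_exon / exon_length) / (total_exonic_reads /
  total_exon_length), the exon's read density relative to the sample mean
  (≈ 1 for a typical exon), and
- P_HQR = proportion of the exon's reads with MAPQ ≥ 40, where
  MAPQ = −10·log10 Pr(mapping position is wrong).

Exons with RPE > 1.5 and P_HQR < 0.4 (both strict, both configurable) are
flagged, and `recurrence_report()` ranks exons by how many samples flag
them (default: recurrent in ≥ 31 of 36 samples).

**Synthetic fixtures.** Seeded generators produce VCF + truth tables with
separable true/false classes and per-sample SAM files with planted
spurious exons, so the whole toolkit is testable without sequencing data.

## Worked example

```r
library(varfilt)

fix   <- gen_variant_set(variant_sim_params("tier1-snv", seed = 7),
                         dir = tempdir())
calls <- read_vcf(fix$vcf, sample_id = "S1")
truth <- read_truth_table(fix$truth)

grid_search(calls, truth)
#> QUAL x DP cutoff grid search: 273 combinations
#> Best F score: 0.961832 at
#>  qual_min dp_min tp fp tn fn    recall  accuracy   f_score
#>        16     11 63  3 91  2 0.9692308 0.9545455 0.9618321
#>        17     11 63  3 91  2 0.9692308 0.9545455 0.9618321
```

The fixture plants 65 validated and 94 failed SNVs with overlapping
QUAL/DP classes; the search finds that QUAL ≥ 16 (or 17) with DP ≥ 11
keeps 63 of the 65 true variants while letting only 3 false ones through,
and reports both tied maximizers. At a conventional cutoff instead:

```r
compute_metrics(confusion_counts(calls, truth, qual_min = 28, dp_min = 5))
#> $recall        0.892
#> $accuracy      0.866
#> $f_score       0.879
#> $validate_rate 0.409
```

The strand-balance diagnostic on the same fixture:

```r
tab <- build_contingency(calls, truth)
tab
#>          status
#> indicator validated failed
#>         1        16     92
#>         0        49      2
fisher_exact_two_sided(tab)
#> [1] 1.988756e-24
```

92 of 94 failed variants lack support on some allele/strand combination
versus 16 of 65 validated ones — a strong association, as the fixture
plants (the indicator is reported as a diagnostic, not applied as a hard
filter).

## Command line

```sh
exec/varfilt optimize --vcf calls.vcf --truth truth.tsv --out grid.tsv
exec/varfilt filter --vcf calls.vcf --qual-min 28 --dp-min 5 --out kept.vcf
exec/varfilt strandbias --vcf calls.vcf --truth truth.tsv --out sb.tsv
exec/varfilt spurious --bam s1.bam,s2.bam --exons exons.bed --out sp.tsv
exec/varfilt simulate-variants --preset tier1-snv --seed 1 --out-dir fx
exec/varfilt simulate-alignments --samples 36 --spurious 'GENE04|exon1' \
    --seed 1 --out-dir fx
```

Every report starts with a reproducibility header (version, config hash,
seed); flags override an optional `--config key=value` file.

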