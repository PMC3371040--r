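# Spurious-exon detection from alignment statistics.
#
# A spurious locus attracts reads that truly originate from a similar
# region absent from the reference; the signature is inflated coverage
# together with a low proportion of confidently mapped reads. Two per-exon
# statistics capture this:
#
#   RPE   = (reads_in_exon / exon_length) / (total_exonic_reads /
#           total_exon_length) — the exon's read density relative to the
#           sample's mean exonic density, so RPE ~ 1 for a typical exon and
#           the same exon is comparable across samples;
#   P_HQR = proportion of the exon's reads with MAPQ >= 40.
#
# Exons in the high-coverage / low-quality quadrant (RPE > 1.5 and
# P_HQR < 0.4 by default, both strict) are flagged, and exons flagged
# recurrently across samples are ranked for manual review.

#' Count reads overlapping each exon
#'
#' A read covering 1-based positions `[start, start + aligned_span)` counts
#' toward every exon it overlaps by at least one base (half-open interval
#' logic on matching chromosomes); a read overlapping two exons counts in
#' both, and counts at most once per exon.
#'
#' @param reads Data frame from [read_alignments()].
#' @param exons Data frame from [read_exons()].
#' @return Integer vector of counts, one per exon row, named by `exon_id`.
#' @export
count_reads_per_exon <- function(reads, exons) {
  counts <- integer(nrow(exons))
  if (nrow(reads) > 0 && nrow(exons) > 0) {
    ex_gr <- exon_granges(exons, reads)
    rd_gr <- read_granges(reads, exons)
    counts <- GenomicRanges::countOverlaps(ex_gr, rd_gr, minoverlap = 1L)
  }
  setNames(as.integer(counts), exons$exon_id)
}

# shared seqlevels so overlap queries are silent on disjoint chromosomes
exon_granges <- function(exons, reads = NULL) {
  lv <- unique(c(exons$chrom, reads$chrom))
  GenomicRanges::GRanges(factor(exons$chrom, lv),
                         IRanges::IRanges(start = exons$start + 1L,
                                          end = exons$end))
}

read_granges <- function(reads, exons = NULL) {
  lv <- unique(c(exons$chrom, reads$chrom))
  GenomicRanges::GRanges(factor(reads$chrom, lv),
                         IRanges::IRanges(start = reads$start,
                                          width = reads$aligned_span))
}

#' Length- and yield-normalized reads per exon (RPE)
#'
#' Normalizes each exon's read count by exon length (so exons of different
#' lengths are comparable) and by the sample's total exonic read yield per
#' unit exon length (so the same exon is comparable across samples). By
#' construction `sum(rpe * length) == sum(length)`.
#'
#' @param counts Per-exon read counts aligned with `exons` rows.
#' @param exons Exon data frame with a `length` column.
#' @return Numeric vector of RPE values named by `exon_id`.
#' @export
compute_rpe <- function(counts, exons) {
  total <- sum(counts)
  if (total == 0) stop("no reads mapped to exon regions; RPE undefined")
  dens <- counts / exons$length
  setNames(dens / (total / sum(exons$length)), exons$exon_id)
}

#' Proportion of high-quality reads per exon (P_HQR)
#'
#' For each exon, the fraction of its overlapping reads whose MAPQ is at
#' least `mapq_min` (default 40). Reads with missing MAPQ are excluded from
#' both numerator and denominator. Exons with no reads (or only
#' missing-MAPQ reads) get `NA` and are excluded from flagging.
#'
#' @param reads,exons As in [count_reads_per_exon()].
#' @param mapq_min High-quality MAPQ threshold (inclusive).
#' @return Numeric vector in `[0, 1]` (or `NA`), named by `exon_id`.
#' @export
compute_phqr <- function(reads, exons, mapq_min = 40L) {
  out <- rep(NA_real_, nrow(exons))
  if (nrow(reads) > 0 && nrow(exons) > 0) {
    hits <- GenomicRanges::findOverlaps(exon_granges(exons, reads),
                                        read_granges(reads, exons),
                                        minoverlap = 1L)
    mq <- reads$mapq[S4Vectors::subjectHits(hits)]
    ex <- S4Vectors::queryHits(hits)
    keep <- !is.na(mq)
    n_all <- tabulate(ex[keep], nbins = nrow(exons))
    n_hq <- tabulate(ex[keep & mq >= mapq_min], nbins = nrow(exons))
    out[n_all > 0] <- n_hq[n_all > 0] / n_all[n_all > 0]
  }
  setNames(out, exons$exon_id)
}

#' Mapping quality from a mismapping probability
#'
#' MAPQ is defined as `-10 * log10(Pr(mapping position is wrong))`, rounded
#' to the nearest integer and capped at 60 (the maximum short-read aligners
#' emit).
#'
#' @param p_wrong Probability in (0, 1] that the mapping position is wrong.
#' @param cap Upper bound (default 60).
#' @return Integer MAPQ, vectorized.
#' @export
mapq_from_error_prob <- function(p_wrong, cap = 60L) {
  if (any(p_wrong <= 0 | p_wrong > 1)) {
    stop("p_wrong must lie in (0, 1]")
  }
  as.integer(pmin(floor(-10 * log10(p_wrong) + 0.5), cap))
}

#' Per-exon coverage and mapping-quality statistics for one sample
#'
#' Combines [count_reads_per_exon()], [compute_rpe()] and [compute_phqr()]
#' into the per-sample exon summary used for spurious-locus screening.
#'
#' @param reads Data frame from [read_alignments()].
#' @param exons Data frame from [read_exons()].
#' @param mapq_min High-quality MAPQ threshold (default 40).
#' @param sample_id Sample label for the output.
#' @return Data frame with columns `sample_id, exon_id, gene, read_count,
#'   rpe, p_hqr`.
#' @export
exon_stats <- function(reads, exons, mapq_min = 40L, sample_id = "sample") {
  counts <- count_reads_per_exon(reads, exons)
  data.frame(
    sample_id = sample_id,
    exon_id = exons$exon_id,
    gene = exons$gene,
    read_count = as.integer(counts),
    rpe = as.numeric(compute_rpe(counts, exons)),
    p_hqr = as.numeric(compute_phqr(reads, exons, mapq_min)),
    stringsAsFactors = FALSE
  )
}

#' Flag exons in the spurious quadrant
#'
#' An exon is flagged when its coverage is high (`rpe > rpe_min`) and its
#' proportion of high-quality reads is low (`p_hqr < phqr_max`); both
#' comparisons are strict, so an exon sitting exactly on a threshold is not
#' flagged. Exons with undefined `p_hqr` (no reads) are never flagged.
#'
#' @param stats Data frame from [exon_stats()] (possibly several samples
#'   row-bound together).
#' @param rpe_min Relative-density threshold (default 1.5, i.e. 50% above
#'   the sample's mean exonic density).
#' @param phqr_max High-quality-proportion threshold (default 0.4).
#' @return `stats` with a logical `flagged` column appended.
#' @export
flag_spurious <- function(stats, rpe_min = 1.5, phqr_max = 0.4) {
  stats$flagged <- !is.na(stats$p_hqr) & stats$rpe > rpe_min &
    stats$p_hqr < phqr_max
  stats
}

#' Cross-sample recurrence of flagged exons
#'
#' Ranks exons by the number of samples in which they were flagged and
#' keeps those flagged in at least `min_samples` samples. The default of 31
#' encodes "more than 30 samples" for a cohort-scale screen.
#'
#' @param stats Row-bound [flag_spurious()] output across samples; must
#'   contain `sample_id`, `exon_id`, `gene`, `flagged`.
#' @param min_samples Minimum number of flagged samples to report.
#' @return Data frame `gene, exon_id, n_samples_flagged, samples` (the
#'   comma-separated flagged sample labels), sorted by descending
#'   `n_samples_flagged`, ties broken by `exon_id`.
#' @export
recurrence_report <- function(stats, min_samples = 31L) {
  if (!"flagged" %in% names(stats)) {
    stop("stats must carry a 'flagged' column; run flag_spurious() first")
  }
  fl <- stats[stats$flagged, , drop = FALSE]
  empty <- data.frame(gene = character(), exon_id = character(),
                      n_samples_flagged = integer(), samples = character(),
                      stringsAsFactors = FALSE)
  if (nrow(fl) == 0) return(empty)
  agg <- lapply(split(fl, fl$exon_id), function(d) {
    smp <- sort(unique(d$sample_id))
    data.frame(gene = d$gene[1], exon_id = d$exon_id[1],
               n_samples_flagged = length(smp),
               samples = paste(smp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, agg)
  rep_ <- rep_[rep_$n_samples_flagged >= min_samples, , drop = FALSE]
  if (nrow(rep_) == 0) return(empty)
  rep_ <- rep_[order(-rep_$n_samples_flagged, rep_$exon_id), , drop = FALSE]
  rownames(rep_) <- NULL
  rep_
}
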