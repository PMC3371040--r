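# Shared fixture builders and independent oracles. The oracles deliberately
# use different code paths than the implementation (explicit loops,
# choose()-based enumeration) so that agreement is meaningful.

# quick variant_records builder with positional defaults
make_calls <- function(qual, dp, pos = seq_along(qual),
                       rf = NA, rr = NA, af = NA, ar = NA,
                       sample_id = "S1") {
  variant_records(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                  qual = qual, dp = dp, rf = rf, rr = rr, af = af, ar = ar,
                  sample_id = sample_id)
}

make_truth <- function(calls, status) {
  data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
             alt = calls$alt, sample_id = calls$sample_id,
             status = status, stringsAsFactors = FALSE)
}

# independent per-variant loop re-classification (oracle for
# confusion_counts and grid_search)
brute_confusion <- function(calls, truth, qual_min, dp_min) {
  tp <- fp <- tn <- fn <- 0L
  ck <- paste(calls$chrom, calls$pos, calls$ref, calls$alt,
              calls$sample_id)
  for (i in seq_len(nrow(truth))) {
    k <- paste(truth$chrom[i], truth$pos[i], truth$ref[i], truth$alt[i],
               truth$sample_id[i])
    j <- which(ck == k)
    predicted <- FALSE
    if (length(j) == 1) {
      q_ok <- if (qual_min <= 0) TRUE else
        (!is.na(calls$qual[j]) && calls$qual[j] >= qual_min)
      d_ok <- if (dp_min <= 0) TRUE else
        (!is.na(calls$dp[j]) && calls$dp[j] >= dp_min)
      predicted <- q_ok && d_ok
    }
    v <- truth$status[i] == "validated"
    if (predicted && v) tp <- tp + 1L
    else if (predicted && !v) fp <- fp + 1L
    else if (!predicted && v) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# choose()-based two-sided Fisher enumeration (oracle for
# fisher_exact_two_sided, which uses dhyper internally)
enum_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  tot <- choose(m + n, k)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / tot
  p_obs <- choose(m, a) * choose(n, k - a) / tot
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# quadratic all-pairs interval overlap count (oracle for
# count_reads_per_exon); intervals compared in 0-based half-open space
quadratic_exon_counts <- function(reads, exons) {
  out <- integer(nrow(exons))
  for (e in seq_len(nrow(exons))) {
    cnt <- 0L
    for (r in seq_len(nrow(reads))) {
      r0 <- reads$start[r] - 1L
      r1 <- r0 + reads$aligned_span[r]
      if (reads$chrom[r] == exons$chrom[e] &&
          r0 < exons$end[e] && r1 > exons$start[e]) {
        cnt <- cnt + 1L
      }
    }
    out[e] <- cnt
  }
  setNames(out, exons$exon_id)
}

# write a SAM file from a reads-style data frame (flag column optional)
write_sam <- function(reads, path, contig = "chr1", contig_len = 100000L,
                      flag = NULL) {
  if (is.null(flag)) flag <- rep(0L, nrow(reads))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", contig, "\tLN:", contig_len))
  body <- paste(sprintf("r%04d", seq_len(nrow(reads))), flag, reads$chrom,
                reads$start, reads$mapq,
                paste0(reads$aligned_span, "M"), "*", 0L, 0L,
                strrep("A", reads$aligned_span),
                strrep("I", reads$aligned_span), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}
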