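# Seeded synthetic fixtures.
#
# Two generators provide the inputs every analysis in the package assumes,
# so the toolkit is fully testable without any sequencing data:
#
#   * gen_variant_set(): a VCF plus truth table in which true (validated)
#     variants come from a high-QUAL / high-DP class and false (failed)
#     variants from a low class, with strand-support deficiency planted at
#     a class-specific rate — the separability structure a QUAL/DP grid
#     search and a strand-balance test exploit.
#   * gen_alignment_set(): one SAM file per sample over a synthetic exon
#     set, with designated "spurious" exons receiving a density_factor-fold
#     read excess of which a large fraction maps with low MAPQ.
#
# Both are pure functions of their parameters and seed: identical inputs
# give byte-identical files.

#' Parameters for the synthetic variant-set generator
#'
#' Each class (true/false) draws QUAL from a truncated-at-bounds normal and
#' DP from a shifted negative binomial clamped to class bounds, then builds
#' DP4 by assigning a high-quality subset of DP to reference/alternate and
#' splitting each allele binomially between strands; with probability
#' `zero_support_prob` one uniformly chosen DP4 component is zeroed.
#'
#' Presets:
#' * `"tier1-snv"` — 65 validated / 94 failed SNVs (the composition of a
#'   validation cohort with rate 65/159), overlapping QUAL/DP classes.
#' * `"tier1-indel"` — 12 validated / 10 failed indels (rate 12/22).
#' * `"separable"` — 100/100 SNVs with zero class overlap: true variants
#'   have QUAL in \[30, 60\] and DP in \[6, 60\]; false variants have QUAL
#'   in \[0, 25\] and DP in \[1, 4\]. A grid search can reach F = 1 here.
#'
#' @param preset One of `"tier1-snv"`, `"tier1-indel"`, `"separable"`.
#' @param n_true,n_false Class sizes (override the preset's).
#' @param qual_true,qual_false Named vectors `c(mean, sd, lo, hi)`.
#' @param dp_true,dp_false Named vectors `c(mu, size, lo, hi)`.
#' @param zero_support_prob Named vector `c(true = , false = )`:
#'   per-variant probability that one DP4 component is zeroed.
#' @param vtype `"SNV"` or `"indel"` records to emit.
#' @param seed Integer seed.
#' @return A list of class `variant_sim_params`.
#' @export
variant_sim_params <- function(preset = "tier1-snv",
                               n_true = NULL, n_false = NULL,
                               qual_true = NULL, qual_false = NULL,
                               dp_true = NULL, dp_false = NULL,
                               zero_support_prob = NULL,
                               vtype = NULL, seed = 1L) {
  base <- switch(
    preset,
    "tier1-snv" = list(
      n_true = 65L, n_false = 94L,
      qual_true = c(mean = 45, sd = 12, lo = 5, hi = 120),
      qual_false = c(mean = 18, sd = 10, lo = 0, hi = 60),
      dp_true = c(mu = 20, size = 8, lo = 3, hi = 400),
      dp_false = c(mu = 6, size = 4, lo = 1, hi = 400),
      zero_support_prob = c(true = 0.05, false = 0.8),
      vtype = "SNV"),
    "tier1-indel" = list(
      n_true = 12L, n_false = 10L,
      qual_true = c(mean = 40, sd = 12, lo = 5, hi = 120),
      qual_false = c(mean = 14, sd = 8, lo = 0, hi = 50),
      dp_true = c(mu = 15, size = 8, lo = 3, hi = 400),
      dp_false = c(mu = 5, size = 4, lo = 1, hi = 400),
      zero_support_prob = c(true = 0.05, false = 0.8),
      vtype = "indel"),
    "separable" = list(
      n_true = 100L, n_false = 100L,
      qual_true = c(mean = 40, sd = 6, lo = 30, hi = 60),
      qual_false = c(mean = 14, sd = 6, lo = 0, hi = 25),
      dp_true = c(mu = 18, size = 10, lo = 6, hi = 60),
      dp_false = c(mu = 2.5, size = 10, lo = 1, hi = 4),
      zero_support_prob = c(true = 0.05, false = 0.8),
      vtype = "SNV"),
    stop("unknown preset: ", preset)
  )
  ov <- list(n_true = n_true, n_false = n_false, qual_true = qual_true,
             qual_false = qual_false, dp_true = dp_true,
             dp_false = dp_false, zero_support_prob = zero_support_prob,
             vtype = vtype)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) base[[nm]] <- ov[[nm]]
  base$seed <- as.integer(seed)
  base$preset <- preset
  p <- base$zero_support_prob
  stopifnot(base$n_true >= 0, base$n_false >= 0,
            all(p >= 0 & p <= 1))
  structure(base, class = "variant_sim_params")
}

# truncated normal via inverse-CDF (deterministic under set.seed)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

rdepth <- function(n, par) {
  x <- par[["lo"]] + rnbinom(n, size = par[["size"]],
                             mu = max(par[["mu"]] - par[["lo"]], 0.1))
  as.integer(pmin(x, par[["hi"]]))
}

#' Generate a synthetic variant call set with matching truth table
#'
#' Writes a VCF (QUAL, INFO DP and DP4) and a tab-separated truth table in
#' which the high-QUAL/high-DP class is labelled `validated` and the low
#' class `failed`. Deterministic given the seed in `params`.
#'
#' @param params A [variant_sim_params()] object.
#' @param dir Output directory (created if needed).
#' @param sample_id Sample label used in both files.
#' @param basename Stem for the output file names.
#' @return List with `vcf` and `truth` paths plus the `calls` and `truth_df`
#'   data frames.
#' @export
gen_variant_set <- function(params = variant_sim_params(),
                            dir = tempdir(), sample_id = "S1",
                            basename = "variants") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(params$seed)
  n <- params$n_true + params$n_false
  truthy <- rep(c(TRUE, FALSE), c(params$n_true, params$n_false))

  pos <- sort(sample.int(9e5, n)) + 100L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  if (params$vtype == "indel") {
    # half insertions, half deletions relative to a single-base anchor
    ins <- runif(n) < 0.5
    alt <- ifelse(ins, paste0(ref, sample(bases, n, replace = TRUE)), ref)
    ref <- ifelse(ins, ref, paste0(ref, sample(bases, n, replace = TRUE)))
  }

  qual <- numeric(n)
  qual[truthy] <- rtruncnorm(params$n_true, params$qual_true[["mean"]],
                             params$qual_true[["sd"]],
                             params$qual_true[["lo"]],
                             params$qual_true[["hi"]])
  qual[!truthy] <- rtruncnorm(params$n_false, params$qual_false[["mean"]],
                              params$qual_false[["sd"]],
                              params$qual_false[["lo"]],
                              params$qual_false[["hi"]])
  qual <- round(qual, 2)
  dp <- integer(n)
  dp[truthy] <- rdepth(params$n_true, params$dp_true)
  dp[!truthy] <- rdepth(params$n_false, params$dp_false)

  # DP4: a high-quality subset of DP split ref/alt, then by strand
  hq <- rbinom(n, dp, runif(n, 0.75, 0.95))
  nalt <- rbinom(n, hq, runif(n, 0.3, 0.7))
  nref <- hq - nalt
  rf <- rbinom(n, nref, 0.5); rr <- nref - rf
  af <- rbinom(n, nalt, 0.5); ar <- nalt - af
  p0 <- ifelse(truthy, params$zero_support_prob[["true"]],
               params$zero_support_prob[["false"]])
  zero <- runif(n) < p0
  which4 <- sample.int(4L, n, replace = TRUE)
  d4 <- cbind(rf, rr, af, ar)
  d4[cbind(which(zero), which4[zero])] <- 0L

  calls <- variant_records("chr1", pos, ref, alt, qual, dp,
                           rf = d4[, 1], rr = d4[, 2],
                           af = d4[, 3], ar = d4[, 4],
                           sample_id = sample_id)
  truth <- data.frame(chrom = calls$chrom, pos = calls$pos,
                      ref = calls$ref, alt = calls$alt,
                      sample_id = calls$sample_id,
                      status = ifelse(truthy, "validated", "failed"),
                      stringsAsFactors = FALSE)
  vcf_path <- file.path(dir, paste0(basename, ".vcf"))
  truth_path <- file.path(dir, paste0(basename, "_truth.tsv"))
  write_vcf(calls, vcf_path)
  write_truth_table(truth, truth_path)
  list(vcf = vcf_path, truth = truth_path, calls = calls, truth_df = truth)
}

#' Parameters for the synthetic alignment-set generator
#'
#' @param exons Exon data frame ([read_exons()] layout); defaults to
#'   [synthetic_exons()].
#' @param spurious Character vector of `exon_id`s to plant as spurious.
#' @param n_samples Number of per-sample SAM files (default 36, a cohort of
#'   18 tumor:normal pairs).
#' @param baseline_density Expected reads per exon base in a normal exon.
#' @param density_factor Coverage multiplier for spurious exons (> 1).
#' @param low_mapq_fraction Fraction of a spurious exon's reads drawn from
#'   the low-MAPQ (< 40) population.
#' @param bg_low_mapq_fraction Same fraction for normal exons.
#' @param read_length Read length in bases (exact-match CIGAR).
#' @param seed Integer seed.
#' @return A list of class `alignment_sim_params`.
#' @export
alignment_sim_params <- function(exons = synthetic_exons(),
                                 spurious = character(),
                                 n_samples = 36L,
                                 baseline_density = 0.3,
                                 density_factor = 3,
                                 low_mapq_fraction = 0.8,
                                 bg_low_mapq_fraction = 0.05,
                                 read_length = 100L,
                                 seed = 1L) {
  stopifnot(density_factor > 1,
            low_mapq_fraction >= 0, low_mapq_fraction <= 1,
            bg_low_mapq_fraction >= 0, bg_low_mapq_fraction <= 1,
            all(spurious %in% exons$exon_id),
            all(exons$length >= read_length))
  structure(list(exons = exons, spurious = spurious,
                 n_samples = as.integer(n_samples),
                 baseline_density = baseline_density,
                 density_factor = density_factor,
                 low_mapq_fraction = low_mapq_fraction,
                 bg_low_mapq_fraction = bg_low_mapq_fraction,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "alignment_sim_params")
}

#' A default synthetic exon set
#'
#' Equal-length exons on one contig, spaced so that a read (up to the gap
#' size) can overlap at most one exon; named `GENEk|exon1`.
#'
#' @param n Number of exons.
#' @param length Exon length in bases.
#' @param gap Gap between consecutive exons.
#' @param chrom Contig name.
#' @return Exon data frame in the [read_exons()] layout.
#' @export
synthetic_exons <- function(n = 10L, length = 300L, gap = 400L,
                            chrom = "chr1") {
  start <- 1000L + (seq_len(n) - 1L) * (length + gap)
  data.frame(chrom = chrom, start = start, end = start + length,
             exon_id = sprintf("GENE%02d|exon1", seq_len(n)),
             gene = sprintf("GENE%02d", seq_len(n)),
             length = length, stringsAsFactors = FALSE)
}

#' Generate per-sample synthetic SAM files
#'
#' For each sample, every exon receives a Poisson number of reads with mean
#' `baseline_density * length` (times `density_factor` for planted spurious
#' exons), placed uniformly and fully inside the exon with an exact-match
#' CIGAR. MAPQ is drawn from a high population (50-60) or a low population
#' (0-30) according to the exon's low-MAPQ fraction. Deterministic given
#' the seed.
#'
#' @param params An [alignment_sim_params()] object.
#' @param dir Output directory (created if needed).
#' @return List with `sam` (vector of per-sample paths, named by sample)
#'   and `exons` (the exon data frame used).
#' @export
gen_alignment_set <- function(params = alignment_sim_params(),
                              dir = tempdir()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exons <- params$exons
  contig_len <- max(exons$end) + 1000L
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", exons$chrom[1], "\tLN:", contig_len))
  seq_str <- strrep("A", params$read_length)
  qual_str <- strrep("I", params$read_length)
  cigar <- paste0(params$read_length, "M")
  set.seed(params$seed)
  paths <- character(params$n_samples)
  for (s in seq_len(params$n_samples)) {
    sample_nm <- sprintf("sample%02d", s)
    recs <- character(0)
    for (e in seq_len(nrow(exons))) {
      spur <- exons$exon_id[e] %in% params$spurious
      lambda <- params$baseline_density * exons$length[e] *
        if (spur) params$density_factor else 1
      n_reads <- rpois(1, lambda)
      if (n_reads == 0) next
      lo_frac <- if (spur) params$low_mapq_fraction
        else params$bg_low_mapq_fraction
      low <- runif(n_reads) < lo_frac
      mapq <- integer(n_reads)
      mapq[low] <- sample(0:30, sum(low), replace = TRUE)
      mapq[!low] <- sample(50:60, sum(!low), replace = TRUE)
      # 1-based start, read fully inside the exon
      pos <- exons$start[e] + 1L +
        sample.int(exons$length[e] - params$read_length + 1L, n_reads,
                   replace = TRUE) - 1L
      recs <- c(recs, paste(
        sprintf("%s_e%02d_%04d", sample_nm, e, seq_len(n_reads)),
        0L, exons$chrom[e], pos, mapq, cigar, "*", 0L, 0L,
        seq_str, qual_str, sep = "\t"))
    }
    p <- file.path(dir, paste0(sample_nm, ".sam"))
    writeLines(c(hdr, recs), p)
    paths[s] <- p
    names(paths)[s] <- sample_nm
  }
  list(sam = paths, exons = exons)
}
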