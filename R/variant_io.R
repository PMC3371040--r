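# Readers and writers for the formats the toolkit touches. Coordinate
# conventions: VCF and SAM positions are 1-based; BED is 0-based half-open.
# All internal interval logic uses 0-based half-open ([start, end)); exon
# data frames carry 0-based `start`/`end`, read data frames carry the
# 1-based SAM `start` plus `aligned_span` reference bases.

#' Construct a validated set of variant records
#'
#' The common currency of the package: one row per called variant, holding
#' the caller's QUAL score, the site read depth DP, and the four
#' high-quality strand/allele support counts DP4 (reference-forward,
#' reference-reverse, alternate-forward, alternate-reverse, following the
#' SAMtools convention).
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Reference and alternate allele strings.
#' @param qual Phred-scaled variant quality scores (non-negative; `NA` if
#'   the caller emitted "."`).
#' @param dp Total site read depth (`NA` when the INFO field lacks DP; such
#'   records are excluded from depth-based operations).
#' @param rf,rr,af,ar DP4 components (`NA` when absent; such records are
#'   excluded from strand-balance operations).
#' @param sample_id Sample label, recycled if scalar.
#'
#' @return A data frame of class `variant_records` with columns
#'   `chrom, pos, ref, alt, qual, dp, rf, rr, af, ar, vtype, sample_id`.
#'   `vtype` is `"indel"` when `nchar(ref) != nchar(alt)`, else `"SNV"`.
#' @export
variant_records <- function(chrom, pos, ref, alt, qual, dp = NA_integer_,
                            rf = NA_integer_, rr = NA_integer_,
                            af = NA_integer_, ar = NA_integer_,
                            sample_id = "sample") {
  n <- length(pos)
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    qual = as.numeric(qual),
    dp = as.integer(rep_len(dp, n)),
    rf = as.integer(rep_len(rf, n)), rr = as.integer(rep_len(rr, n)),
    af = as.integer(rep_len(af, n)), ar = as.integer(rep_len(ar, n)),
    sample_id = as.character(rep_len(sample_id, n)),
    stringsAsFactors = FALSE
  )
  df$vtype <- ifelse(nchar(df$ref) != nchar(df$alt), "indel", "SNV")
  if (any(df$pos < 1L)) stop("variant positions must be >= 1")
  if (any(df$qual < 0, na.rm = TRUE)) stop("QUAL must be non-negative")
  if (any(df$dp < 0L, na.rm = TRUE)) stop("DP must be non-negative")
  d4 <- df[c("rf", "rr", "af", "ar")]
  if (any(unlist(d4) < 0L, na.rm = TRUE)) {
    stop("DP4 components must be non-negative")
  }
  s4 <- dp4_sum(df)
  bad <- !is.na(s4) & !is.na(df$dp) & s4 > df$dp
  if (any(bad)) {
    stop("DP4 sum exceeds DP for ", sum(bad), " record(s), e.g. ",
         df$chrom[bad][1], ":", df$pos[bad][1],
         " (DP4 counts only the high-quality subset of DP)")
  }
  class(df) <- c("variant_records", "data.frame")
  df
}

dp4_sum <- function(calls) calls$rf + calls$rr + calls$af + calls$ar

#' Variant key strings
#'
#' A variant is identified by (chrom, pos, ref, alt, sample_id); the key is
#' used to match call sets against truth tables and against each other.
#'
#' @param x A `variant_records` or truth-table data frame.
#' @return Character vector of keys.
#' @export
variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, x$sample_id, sep = "\r")
}

#' Read a VCF file into variant records
#'
#' Parses the QUAL column and the INFO keys `DP` and `DP4`. Multi-allelic
#' records are split into one record per ALT allele, duplicating
#' QUAL/DP/DP4, with a warning. Records lacking DP (or DP4) keep an `NA`
#' there and are excluded, with a warning here, from depth-based (or
#' strand-based) operations downstream.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param sample_id Sample label to attach; defaults to the file base name.
#' @return A [variant_records()] data frame.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  check_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(variant_records(character(), integer(), character(), character(),
                           numeric(), sample_id = sample_id))
  }
  info <- fix[, "INFO"]
  dp <- suppressWarnings(as.integer(info_field(info, "DP")))
  dp4 <- info_field(info, "DP4")
  dp4m <- matrix(NA_integer_, nrow = length(dp4), ncol = 4)
  has4 <- !is.na(dp4)
  if (any(has4)) {
    parts <- strsplit(dp4[has4], ",", fixed = TRUE)
    ok <- lengths(parts) == 4L
    if (!all(ok)) stop("malformed DP4 value: ", dp4[has4][!ok][1])
    dp4m[has4, ] <- t(vapply(parts,
                             function(p) suppressWarnings(as.integer(p)),
                             integer(4)))
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  alt <- fix[, "ALT"]

  # split multi-allelic records per ALT, duplicating QUAL/DP/DP4
  alts <- strsplit(alt, ",", fixed = TRUE)
  nalt <- lengths(alts)
  if (any(nalt > 1L)) {
    warning(sum(nalt > 1L), " multi-allelic record(s) split per ALT allele")
  }
  idx <- rep.int(seq_along(alts), nalt)
  df <- variant_records(
    chrom = fix[idx, "CHROM"], pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"], alt = unlist(alts),
    qual = qual[idx], dp = dp[idx],
    rf = dp4m[idx, 1], rr = dp4m[idx, 2],
    af = dp4m[idx, 3], ar = dp4m[idx, 4],
    sample_id = sample_id
  )
  if (anyNA(df$dp)) {
    warning(sum(is.na(df$dp)), " record(s) lack INFO:DP and are excluded ",
            "from depth-based operations")
  }
  if (anyNA(df$rf) && !all(is.na(df$rf))) {
    warning(sum(is.na(df$rf)), " record(s) lack INFO:DP4 and are excluded ",
            "from strand-balance operations")
  }
  df
}

# Structural pre-check so parse failures name the offending line.
check_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield < 8L)) {
    stop("malformed VCF line ", which(body)[nfield < 8L][1],
         ": fewer than 8 tab-separated fields")
  }
  invisible(TRUE)
}

info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Write variant records as a VCF file
#'
#' Emits a minimal, valid VCF 4.2 with `DP` and `DP4` INFO fields; QUAL is
#' written with two decimals. An optional provenance line records the filter
#' settings that produced the file.
#'
#' @param calls A [variant_records()] data frame.
#' @param path Output path.
#' @param provenance Optional string appended as a `##varfilt_filter=` header
#'   line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, provenance = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=varfilt",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    paste0("##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"",
           "High-quality ref-forward, ref-reverse, alt-forward, ",
           "alt-reverse bases\">")
  )
  if (!is.null(provenance)) {
    hdr <- c(hdr, paste0("##varfilt_filter=", provenance))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  info <- ifelse(is.na(calls$dp), "", paste0("DP=", calls$dp))
  has4 <- !is.na(calls$rf)
  d4 <- paste0("DP4=", calls$rf, ",", calls$rr, ",", calls$af, ",", calls$ar)
  info <- ifelse(has4, ifelse(nzchar(info), paste0(info, ";", d4), d4), info)
  info[!nzchar(info)] <- "."
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                ifelse(is.na(calls$qual), ".", sprintf("%.2f", calls$qual)),
                ".", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a validation truth table
#'
#' A truth table records, for each candidate variant sent to an orthogonal
#' assay (e.g. Sanger sequencing), whether it was validated as a true
#' variant or failed validation.
#'
#' @param path Tab-separated file with header columns
#'   `chrom, pos, ref, alt, sample_id, status`.
#' @return Data frame with `status` normalized to `"validated"`/`"failed"`.
#' @export
read_truth_table <- function(path) {
  tt <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(pos = "integer"))
  need <- c("chrom", "pos", "ref", "alt", "sample_id", "status")
  miss <- setdiff(need, names(tt))
  if (length(miss)) {
    stop("truth table missing column(s): ", paste(miss, collapse = ", "))
  }
  tt <- tt[need]
  tt$status <- tolower(trimws(tt$status))
  bad <- !tt$status %in% c("validated", "failed")
  if (any(bad)) {
    stop("unknown validation status token: '", tt$status[bad][1],
         "' (expected 'validated' or 'failed')")
  }
  key <- variant_key(tt)
  if (anyDuplicated(key)) {
    d <- tt[duplicated(key), ]
    stop("duplicate truth-table key: ", d$chrom[1], ":", d$pos[1], " ",
         d$ref[1], ">", d$alt[1], " in sample ", d$sample_id[1])
  }
  tt
}

#' Write a truth table
#' @param truth Truth data frame as returned by [read_truth_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read exon intervals from a BED file
#'
#' The exon is the unit of analysis for spurious-locus detection. The BED
#' `name` column encodes the exon identity; when it contains a `|`, the part
#' before it is taken as the gene symbol (e.g. `CDC27|exon13`).
#'
#' @param path BED file with at least 4 columns.
#' @return Data frame with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `exon_id`, `gene`, `length`.
#' @export
read_exons <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), exon_id = character(),
                      gene = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  name <- as.character(gr$name)
  if (anyNA(name)) stop("BED file must have a name (4th) column")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based
    end = GenomicRanges::end(gr),
    exon_id = name,
    gene = ifelse(grepl("|", name, fixed = TRUE),
                  sub("\\|.*$", "", name), NA_character_),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) {
    stop("exon interval with end <= start: ",
         df$exon_id[df$end <= df$start][1])
  }
  df$length <- df$end - df$start
  df
}

#' Write exon intervals as BED
#' @param exons Exon data frame as returned by [read_exons()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exons_bed <- function(exons, path) {
  writeLines(paste(exons$chrom, exons$start, exons$end, exons$exon_id,
                   sep = "\t"), path)
  invisible(path)
}

#' Read mapped reads from a SAM or BAM file
#'
#' Keeps primary, mapped, non-duplicate alignments; unmapped, secondary,
#' supplementary and duplicate-flagged reads are skipped, mirroring the
#' cleanup a calling pipeline applies before variant detection. A MAPQ of
#' 255 (unavailable) is recorded as `NA` with a warning; such reads still
#' count toward coverage but are excluded from mapping-quality proportions.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly.
#' @return Data frame with columns `chrom`, `start` (1-based leftmost
#'   aligned position), `aligned_span` (reference bases covered, from the
#'   CIGAR), `mapq`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "mapq", "cigar"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  mapq <- as.integer(res$mapq)
  if (any(mapq == 255L, na.rm = TRUE)) {
    warning(sum(mapq == 255L, na.rm = TRUE),
            " read(s) with MAPQ 255 (unavailable); excluded from ",
            "mapping-quality proportions")
    mapq[mapq == 255L] <- NA_integer_
  }
  data.frame(chrom = as.character(res$rname), start = as.integer(res$pos),
             aligned_span = as.integer(span), mapq = mapq,
             stringsAsFactors = FALSE)
}
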