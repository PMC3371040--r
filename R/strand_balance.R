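# Allele/strand balance diagnostics from DP4 counts.
#
# For each variant the caller reports four high-quality read counts:
# reference-forward, reference-reverse, alternate-forward,
# alternate-reverse. A genuine heterozygous site is expected to show
# support in all four; artifacts frequently lack support in one or more.
# The association between that deficiency and validation failure is
# assessed with a classical two-sided Fisher's exact test, implemented
# here by direct hypergeometric summation so the tail rule is explicit
# and testable.

#' Allele/strand support indicator
#'
#' Indicates 1 when the variant lacks at least `min_support` reads in one
#' or more of the four allele/strand cases (i.e. some DP4 component is
#' below the threshold), else 0. With the default threshold of 1 this is
#' simply "some DP4 component is zero".
#'
#' @param dp4 A length-4 vector (RF, RR, AF, AR) or an n x 4 matrix /
#'   data frame of DP4 counts.
#' @param min_support Minimum supporting reads required per case
#'   (default 1).
#' @return Integer 0/1, vectorized over rows. `NA` components give `NA`.
#' @export
strand_indicator <- function(dp4, min_support = 1L) {
  m <- if (is.null(dim(dp4))) matrix(as.numeric(dp4), ncol = 4)
    else as.matrix(dp4)
  if (ncol(m) != 4) stop("dp4 must have four components")
  if (any(m < 0, na.rm = TRUE)) stop("DP4 components must be non-negative")
  lo <- apply(m, 1, min)
  as.integer(lo < min_support)
}

#' Contingency table of strand-support indicator versus validation status
#'
#' Builds the 2x2 table with rows indicator = 1 (lacks support on some
#' allele/strand case) / 0 and columns validated / failed, over the truth
#' entries whose matching call carries a DP4 field. Variants lacking DP4 or
#' a truth status are excluded; the exclusion count is reported via
#' `message()`.
#'
#' @param calls A [variant_records()] data frame.
#' @param truth Truth table (see [read_truth_table()]).
#' @param min_support Passed to [strand_indicator()].
#' @return 2x2 integer matrix with dimnames
#'   `indicator = c("1","0")`, `status = c("validated","failed")`.
#' @export
build_contingency <- function(calls, truth, min_support = 1L) {
  hits <- match(variant_key(truth), variant_key(calls))
  have_call <- !is.na(hits)
  d4 <- calls[hits[have_call], c("rf", "rr", "af", "ar")]
  have_dp4 <- stats::complete.cases(d4)
  n_excl <- sum(!have_call) + sum(!have_dp4)
  if (n_excl > 0) {
    message(n_excl, " truth entr(ies) excluded: no matching call or no DP4")
  }
  status <- truth$status[have_call][have_dp4]
  if (length(status) == 0) {
    stop("no truth entries with both DP4 and validation status")
  }
  ind <- strand_indicator(d4[have_dp4, , drop = FALSE], min_support)
  tab <- matrix(
    c(sum(ind == 1L & status == "validated"),
      sum(ind == 1L & status == "failed"),
      sum(ind == 0L & status == "validated"),
      sum(ind == 0L & status == "failed")),
    nrow = 2, byrow = TRUE,
    dimnames = list(indicator = c("1", "0"),
                    status = c("validated", "failed")))
  storage.mode(tab) <- "integer"
  tab
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (with a relative tolerance of 1e-7 for
#' floating-point ties). The observed table is always included, so
#' `p >= P(observed) > 0`. A zero row or column margin means no association
#' is testable and returns `p = 1` by convention.
#'
#' @param tab 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` read row-wise.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(tab) {
  x <- as.vector(t(as.matrix(tab)))
  if (length(x) != 4 || any(x < 0)) stop("need a 2x2 table of counts >= 0")
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  m <- a + b          # row 1 margin
  n <- c_ + d         # row 2 margin
  k <- a + c_         # column 1 margin
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  min(p, 1)
}
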