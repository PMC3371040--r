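# Truth-set evaluation of a call set and the QUAL x DP cutoff grid search.
#
# The evaluation universe is the set of truth entries: a truth variant is
# "predicted" when its key is present in the call set AND the call passes
# the cutoffs (qual >= qual_min and dp >= dp_min, both inclusive).
# "Accuracy" here follows the field's validation-study usage TP/(TP+FP),
# i.e. what is elsewhere called precision; the name is kept for continuity
# with the reports this toolkit reproduces.

#' Confusion counts of a call set against a truth table
#'
#' Classifies every truth entry as TP (validated and predicted), FP (failed
#' and predicted), FN (validated, not predicted — including variants absent
#' from the call set entirely), or TN (failed, not predicted). Counts always
#' sum to the number of truth entries.
#'
#' @param calls A [variant_records()] data frame.
#' @param truth Truth table (see [read_truth_table()]).
#' @param qual_min,dp_min Inclusive cutoffs. A call with missing DP fails a
#'   positive `dp_min` (it cannot demonstrate sufficient depth); likewise a
#'   missing QUAL fails a positive `qual_min`.
#' @return Named list `tp, fp, tn, fn` of non-negative integers.
#' @export
confusion_counts <- function(calls, truth, qual_min = 0, dp_min = 0) {
  ck <- variant_key(calls)
  tk <- variant_key(truth)
  hits <- match(tk, ck)
  multi <- tk %in% ck[duplicated(ck)]
  if (any(multi)) {
    stop("truth key matches more than one call record: ",
         truth$chrom[multi][1], ":", truth$pos[multi][1])
  }
  present <- !is.na(hits)
  qual <- calls$qual[hits]
  dp <- calls$dp[hits]
  pass_q <- if (qual_min <= 0) rep(TRUE, length(tk)) else
    !is.na(qual) & qual >= qual_min
  pass_d <- if (dp_min <= 0) rep(TRUE, length(tk)) else
    !is.na(dp) & dp >= dp_min
  predicted <- present & pass_q & pass_d
  validated <- truth$status == "validated"
  list(tp = sum(predicted & validated),
       fp = sum(predicted & !validated),
       tn = sum(!predicted & !validated),
       fn = sum(!predicted & validated))
}

#' Evaluation metrics from confusion counts
#'
#' * recall = TP / (TP + FN)
#' * accuracy = TP / (TP + FP) (the validation-study convention; elsewhere
#'   called precision)
#' * F score = 2 * accuracy * recall / (accuracy + recall)
#'   = 2 TP / (2 TP + FP + FN)
#' * validate rate = (TP + FN) / (TP + FP + TN + FN), the fraction of truth
#'   entries that validated — a property of the truth set, independent of
#'   any cutoff.
#'
#' A metric whose denominator is zero is undefined and returned as `NA`,
#' never silently 0.
#'
#' @param counts Named list or vector with `tp, fp, tn, fn`.
#' @return Named list `recall, accuracy, f_score, validate_rate`.
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  list(recall = rat(tp, tp + fn),
       accuracy = rat(tp, tp + fp),
       f_score = rat(2 * tp, 2 * tp + fp + fn),
       validate_rate = rat(tp + fn, tp + fp + tn + fn))
}

#' Validation rate
#'
#' Fraction of candidate variants confirmed by the orthogonal assay.
#'
#' @param n_validated Number of validated variants.
#' @param n_total Total number of candidates assayed; must be positive.
#' @return `n_validated / n_total`.
#' @export
validation_rate <- function(n_validated, n_total) {
  if (n_total == 0) stop("validation rate undefined for zero candidates")
  stopifnot(n_validated >= 0, n_validated <= n_total)
  n_validated / n_total
}

#' Exhaustive grid search over QUAL and DP cutoffs
#'
#' Evaluates every (qual_min, dp_min) combination against the truth table
#' and selects all combinations attaining the maximal F score (ties are all
#' reported; maximization uses the unrounded F). Default ranges are QUAL
#' 15..35 and DP 3..15, step 1 each.
#'
#' @param calls,truth As in [confusion_counts()].
#' @param qual_range,dp_range Integer vectors of cutoffs to try.
#' @return List of class `grid_result` with `table` (one row per
#'   combination: `qual_min, dp_min, tp, fp, tn, fn, recall, accuracy,
#'   f_score, best_flag`) and `best` (the maximizing rows).
#' @export
grid_search <- function(calls, truth, qual_range = 15:35, dp_range = 3:15) {
  if (!length(qual_range) || !length(dp_range)) {
    stop("cutoff ranges must be non-empty")
  }
  combos <- expand.grid(qual_min = as.integer(qual_range),
                        dp_min = as.integer(dp_range))
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cc <- confusion_counts(calls, truth, combos$qual_min[i],
                           combos$dp_min[i])
    m <- compute_metrics(cc)
    data.frame(qual_min = combos$qual_min[i], dp_min = combos$dp_min[i],
               tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               recall = m$recall, accuracy = m$accuracy,
               f_score = m$f_score)
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$f_score))) {
    stop("degenerate grid: no cutoff combination yields a defined F score")
  }
  fmax <- max(tab$f_score, na.rm = TRUE)
  tab$best_flag <- !is.na(tab$f_score) & tab$f_score == fmax
  structure(list(table = tab, best = tab[tab$best_flag, , drop = FALSE]),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("QUAL x DP cutoff grid search:", nrow(x$table), "combinations\n")
  cat("Best F score:", format(x$best$f_score[1], digits = 6), "at\n")
  print(x$best[c("qual_min", "dp_min", "tp", "fp", "tn", "fn",
                 "recall", "accuracy", "f_score")], row.names = FALSE)
  invisible(x)
}

#' Apply QUAL and depth-bound filters to a call set
#'
#' Retains records with `qual >= qual_min` and `dp_min <= dp <= dp_max`,
#' preserving input order. The depth bounds default to the conventional
#' pre-filter of requiring 3 or more but no more than 10,000 reads. When
#' both depth bounds are inactive (`dp_min = 0`, `dp_max = Inf`) records
#' with missing DP are retained; otherwise a record must demonstrate a
#' depth inside the bounds.
#'
#' @param calls A [variant_records()] data frame.
#' @param qual_min Minimum QUAL (default 0, inactive).
#' @param dp_min,dp_max Inclusive depth bounds.
#' @return The retained subset, same class and column order.
#' @export
apply_filter <- function(calls, qual_min = 0, dp_min = 3, dp_max = 10000) {
  if (dp_min > dp_max) stop("dp_min must not exceed dp_max")
  pass_q <- if (qual_min <= 0) rep(TRUE, nrow(calls)) else
    !is.na(calls$qual) & calls$qual >= qual_min
  pass_d <- if (dp_min <= 0 && is.infinite(dp_max)) rep(TRUE, nrow(calls))
    else !is.na(calls$dp) & calls$dp >= dp_min & calls$dp <= dp_max
  calls[pass_q & pass_d, , drop = FALSE]
}

#' QUAL concordance between two call sets
#'
#' Matches two call sets on variant key and summarizes how their quality
#' scores compare: the Pearson correlation of the matched QUAL pairs and
#' the fraction of pairs where set A scores strictly higher.
#'
#' @param set_a,set_b [variant_records()] data frames.
#' @return List `pearson_r`, `frac_a_higher`, `n_matched`.
#' @export
qual_concordance <- function(set_a, set_b) {
  hits <- match(variant_key(set_a), variant_key(set_b))
  keep <- !is.na(hits)
  qa <- set_a$qual[keep]
  qb <- set_b$qual[hits[keep]]
  ok <- !is.na(qa) & !is.na(qb)
  qa <- qa[ok]; qb <- qb[ok]
  if (length(qa) < 2) stop("need at least 2 matched QUAL pairs")
  if (stats::var(qa) == 0 || stats::var(qb) == 0) {
    stop("QUAL variance is zero in a matched set; correlation undefined")
  }
  list(pearson_r = cor(qa, qb),
       frac_a_higher = mean(qa > qb),
       n_matched = length(qa))
}
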