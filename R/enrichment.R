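#' Number of pairs in a percentile tail
#'
#' In this framework "AUC" denotes a percentile of the empirical
#' interaction-score distribution: selecting at AUC > a keeps the top
#' (100 - a)% of all pairs, and the same number from the bottom, so that
#' interacting and non-interacting sets have equal size. Fractional counts
#' are floored.
#'
#' @param n_pairs Total number of protein-transcript pairs.
#' @param auc Percentile in \[50, 99.5\].
#' @return Integer-valued tail size `floor(n_pairs * (100 - auc) / 100)`.
#' @export
#' @examples
#' tail_size(35818 * 1156, 95)
tail_size <- function(n_pairs, auc) {
  assert_number(n_pairs, "n_pairs", lower = 0)
  vapply(auc, function(a) {
    assert_number(a, "auc", 50, 99.5)
    floor(n_pairs * (100 - a) / 100)
  }, numeric(1))
}

#' Select equal-size interacting and non-interacting pair tails
#'
#' Ranks all pairs by interaction score and labels the top
#' `tail_size(n, auc)` pairs as interacting and the bottom ones as
#' non-interacting. Ties at either cut are broken lexicographically by
#' (protein, transcript) id, so the selection is deterministic.
#'
#' @param scores Long tibble `protein`, `transcript`, `score`.
#' @param auc Percentile in \[50, 99.5\].
#' @return `scores` with an added `tail_set` column
#'   (`"interacting"`, `"non_interacting"` or `NA`), carrying attributes
#'   `auc` and `n_tail`.
#' @export
select_tails <- function(scores, auc) {
  assert_columns(scores, c("protein", "transcript", "score"), "scores")
  assert_number(auc, "auc", 50, 99.5)
  if (any(!is.finite(scores$score))) {
    abort_bad_arg("scores$score", "be finite")
  }
  n <- tail_size(nrow(scores), auc)
  tail_set <- rep(NA_character_, nrow(scores))
  if (n > 0) {
    top <- c_order(-scores$score, scores$protein, scores$transcript)[seq_len(n)]
    bot <- c_order(scores$score, scores$protein, scores$transcript)[seq_len(n)]
    tail_set[top] <- "interacting"
    tail_set[bot] <- "non_interacting"
  }
  out <- scores
  out$tail_set <- tail_set
  attr(out, "auc") <- auc
  attr(out, "n_tail") <- n
  out
}

# Drop pairs with undefined correlation, then trim both tails to the common
# size by removing the least-extreme scores, preserving |int| == |no-int|.
tail_frames <- function(sel, correlations) {
  assert_columns(sel, c("protein", "transcript", "score", "tail_set"), "sel")
  assert_columns(correlations, c("protein", "transcript", "r"),
                 "correlations")
  pairs <- inner_join(
    sel[!is.na(sel$tail_set), c("protein", "transcript", "score", "tail_set")],
    correlations, by = c("protein", "transcript"))
  dropped <- sum(is.na(pairs$r))
  pairs <- pairs[!is.na(pairs$r), , drop = FALSE]
  int <- pairs[pairs$tail_set == "interacting", , drop = FALSE]
  non <- pairs[pairs$tail_set == "non_interacting", , drop = FALSE]
  m <- min(nrow(int), nrow(non))
  int <- int[c_order(-int$score, int$protein, int$transcript)[seq_len(m)], ,
             drop = FALSE]
  non <- non[c_order(non$score, non$protein, non$transcript)[seq_len(m)], ,
             drop = FALSE]
  list(int = int, non = non, dropped = dropped)
}

#' Enrichment of co-expressed pairs in the interacting tail
#'
#' For equal-size interacting and non-interacting tails, the co-expression
#' enrichment at correlation threshold `r_th > 0` is
#' `(n_int[r > r_th] - n_no_int[r > r_th]) / n_no_int[r > r_th]`:
#' the fractional excess of strongly co-expressed pairs among predicted
#' interactions over the non-interacting background. Values are bounded
#' below by -1; a zero denominator yields `NA` with a warning (the point
#' is omitted from curves).
#'
#' Pairs with undefined correlation are dropped and both tails re-trimmed
#' to the common size before counting.
#'
#' @param sel Output of [select_tails()].
#' @param correlations Long tibble `protein`, `transcript`, `r`.
#' @param r_th Positive correlation threshold.
#' @param require_sign Additionally require `score > 0` in the interacting
#'   tail and `score < 0` in the non-interacting tail (off by default:
#'   tail membership alone defines the sets).
#' @return A single enrichment value.
#' @export
enrichment_coexpressed <- function(sel, correlations, r_th,
                                   require_sign = FALSE) {
  assert_number(r_th, "r_th")
  if (r_th <= 0) abort_bad_arg("r_th", "be positive")
  enrichment_stat(sel, correlations, function(r) r > r_th, require_sign)
}

#' Enrichment of anti-expressed pairs in the interacting tail
#'
#' The mirror statistic of [enrichment_coexpressed()] for negative
#' correlation threshold `l_th < 0`, counting pairs with `r < l_th`.
#'
#' @inheritParams enrichment_coexpressed
#' @param l_th Negative correlation threshold.
#' @return A single enrichment value.
#' @export
enrichment_antiexpressed <- function(sel, correlations, l_th,
                                     require_sign = FALSE) {
  assert_number(l_th, "l_th")
  if (l_th >= 0) abort_bad_arg("l_th", "be negative")
  enrichment_stat(sel, correlations, function(r) r < l_th, require_sign)
}

enrichment_stat <- function(sel, correlations, qualifies, require_sign) {
  tf <- tail_frames(sel, correlations)
  int <- tf$int; non <- tf$non
  if (require_sign) {
    int <- int[int$score > 0, , drop = FALSE]
    non <- non[non$score < 0, , drop = FALSE]
  }
  n_int <- sum(qualifies(int$r))
  n_non <- sum(qualifies(non$r))
  if (n_non == 0) {
    warn("no qualifying pairs in the non-interacting tail; enrichment undefined")
    return(NA_real_)
  }
  (n_int - n_non) / n_non
}

#' Enrichment curves over a grid of tail percentiles and thresholds
#'
#' Evaluates the co-expression and anti-expression enrichment statistics
#' on every (AUC, threshold) grid cell. Each positive threshold in
#' `threshold_grid` feeds the co-expressed statistic and its negation the
#' anti-expressed one.
#'
#' @param scores Long tibble `protein`, `transcript`, `score`.
#' @param correlations Long tibble `protein`, `transcript`, `r`.
#' @param auc_grid Percentiles in \[50, 99.5\].
#' @param threshold_grid Positive correlation thresholds.
#' @param require_sign See [enrichment_coexpressed()].
#' @return Tibble of class `rbp_enrichment` with columns `auc`,
#'   `threshold`, `direction` (`"co"`/`"anti"`), `n_int_q`, `n_noint_q`
#'   (qualifying counts) and `enrichment` (`NA` where undefined).
#' @export
enrichment_sweep <- function(scores, correlations,
                             auc_grid = c(50, 75, 85, 90, 95, 99, 99.5),
                             threshold_grid = c(0.3, 0.5, 0.7, 0.9),
                             require_sign = FALSE) {
  if (any(threshold_grid <= 0)) {
    abort_bad_arg("threshold_grid", "contain positive thresholds only")
  }
  rows <- purrr::map(auc_grid, function(a) {
    sel <- select_tails(scores, a)
    tf <- tail_frames(sel, correlations)
    int <- tf$int; non <- tf$non
    if (require_sign) {
      int <- int[int$score > 0, , drop = FALSE]
      non <- non[non$score < 0, , drop = FALSE]
    }
    purrr::map(threshold_grid, function(th) {
      tibble(auc = a, threshold = c(th, -th), direction = c("co", "anti"),
             n_int_q = c(sum(int$r > th), sum(int$r < -th)),
             n_noint_q = c(sum(non$r > th), sum(non$r < -th)))
    }) %>% bind_rows()
  }) %>% bind_rows()
  rows <- mutate(rows, enrichment = if_else(
    n_noint_q > 0, (n_int_q - n_noint_q) / n_noint_q, NA_real_))
  class(rows) <- c("rbp_enrichment", class(rows))
  rows
}

#' Classify pairs into IC / IA / NIC / NIA subsets
#'
#' At a tail percentile `auc` (default 95) and correlation cuts `r_cut`
#' (default +0.7) and `l_cut` (default -0.7), pairs are labelled:
#' IC = interacting tail, positive score, `r >= r_cut`;
#' IA = interacting tail, positive score, `r <= l_cut`;
#' NIC = non-interacting tail, negative score, `r >= r_cut`;
#' NIA = non-interacting tail, negative score, `r <= l_cut`;
#' everything else (including tail pairs violating the score-sign
#' condition or with undefined correlation) is `unclassified`. The four
#' labelled sets are pairwise disjoint by construction.
#'
#' @param scores Long tibble `protein`, `transcript`, `score`.
#' @param correlations Long tibble `protein`, `transcript`, `r`.
#' @param auc Tail percentile, default 95 (at which the |0.7| correlation
#'   cut sits in the matched percentile of the correlation distribution).
#' @param r_cut,l_cut Correlation cuts (positive / negative).
#' @return Tibble of class `pair_classification`: `protein`, `transcript`,
#'   `score`, `r`, `tail_set`, `label`; attributes record the parameters.
#' @export
classify_pairs <- function(scores, correlations, auc = 95,
                           r_cut = 0.7, l_cut = -0.7) {
  assert_number(r_cut, "r_cut"); assert_number(l_cut, "l_cut")
  if (r_cut <= 0) abort_bad_arg("r_cut", "be positive")
  if (l_cut >= 0) abort_bad_arg("l_cut", "be negative")
  sel <- select_tails(scores, auc)
  pairs <- left_join(
    as_tibble(sel)[, c("protein", "transcript", "score", "tail_set")],
    correlations, by = c("protein", "transcript"))
  lbl <- rep("unclassified", nrow(pairs))
  it <- !is.na(pairs$tail_set) & pairs$tail_set == "interacting" &
    pairs$score > 0 & !is.na(pairs$r)
  nt <- !is.na(pairs$tail_set) & pairs$tail_set == "non_interacting" &
    pairs$score < 0 & !is.na(pairs$r)
  lbl[it & pairs$r >= r_cut] <- "IC"
  lbl[it & pairs$r <= l_cut] <- "IA"
  lbl[nt & pairs$r >= r_cut] <- "NIC"
  lbl[nt & pairs$r <= l_cut] <- "NIA"
  pairs$label <- factor(lbl, levels = c("IC", "IA", "NIC", "NIA",
                                        "unclassified"))
  attr(pairs, "auc") <- auc
  attr(pairs, "r_cut") <- r_cut
  attr(pairs, "l_cut") <- l_cut
  class(pairs) <- c("pair_classification", class(pairs))
  pairs
}

#' Correlation value at a percentile of the |r| distribution
#'
#' Returns the empirical quantile of the absolute correlation
#' distribution at `auc`%: the consistency check that the |0.7|
#' correlation cut corresponds to the 95th percentile of |r| on real
#' data. `auc = 0` returns the minimum |r|.
#'
#' @param r Numeric vector of correlations (NAs dropped).
#' @param auc Percentile in \[0, 100\].
#' @return The |r| quantile.
#' @export
correlation_percentile <- function(r, auc) {
  assert_number(auc, "auc", 0, 100)
  r <- r[!is.na(r)]
  if (length(r) == 0) abort_bad_arg("r", "contain at least one defined value")
  unname(quantile(abs(r), auc / 100, type = 7))
}
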