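#' Fisher's exact test on the top score fraction
#'
#' Cross-tabulates membership of the top `fraction` of predicted scores
#' (exactly `floor(N * fraction)` pairs; ties at the cut broken
#' lexicographically by transcript id) against the bound/unbound label
#' and applies a two-sided Fisher's exact test: the check that
#' experimentally bound targets concentrate among the strongest predicted
#' interactions.
#'
#' @param set Tibble with columns `transcript`, `score`, `bound`
#'   (logical). Positives and negatives must be disjoint, which the
#'   logical label guarantees.
#' @param fraction Top fraction to select, in (0, 1).
#' @return One-row tibble: `n`, `n_top`, `k` (bound in top), `odds_ratio`
#'   (conditional MLE), `p_value`.
#' @export
fisher_top_fraction <- function(set, fraction = 0.01) {
  assert_columns(set, c("transcript", "score", "bound"), "set")
  assert_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    abort_bad_arg("fraction", "lie strictly inside (0, 1)")
  }
  n <- nrow(set)
  n_top <- floor(n * fraction)
  top <- rep(FALSE, n)
  top[c_order(-set$score, set$transcript)[seq_len(n_top)]] <- TRUE
  tab <- table(factor(top, c(TRUE, FALSE)),
               factor(set$bound, c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate 2x2 margin; Fisher p set to 1")
    return(tibble(n = n, n_top = n_top, k = sum(top & set$bound),
                  odds_ratio = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab)
  tibble(n = n, n_top = n_top, k = tab[1, 1],
         odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Balanced bootstrap of the top-fraction Fisher test
#'
#' Repeats [fisher_top_fraction()] with the negatives resampled without
#' replacement to the size of the positive set each round — the balanced
#' resampling used to show that predictions differ from random
#' associations irrespective of the huge negative set.
#'
#' @inheritParams fisher_top_fraction
#' @param n_boot Number of bootstrap rounds.
#' @param seed Optional integer seed for reproducible resampling.
#' @return Tibble of class `bootstrap_fisher` with one row per round
#'   (`round`, `p_value`, `odds_ratio`); the median p is in
#'   `attr(, "median_p")` and via [glance()].
#' @export
bootstrap_fisher <- function(set, fraction = 0.01, n_boot = 100,
                             seed = NULL) {
  assert_columns(set, c("transcript", "score", "bound"), "set")
  assert_count(n_boot, "n_boot")
  if (!is.null(seed)) set.seed(seed)
  pos <- set[set$bound, , drop = FALSE]
  neg <- set[!set$bound, , drop = FALSE]
  if (nrow(pos) == 0) abort_bad_arg("set", "contain at least one positive")
  n_draw <- min(nrow(pos), nrow(neg))
  rows <- purrr::map(seq_len(n_boot), function(b) {
    sub <- bind_rows(pos, neg[sample.int(nrow(neg), n_draw), , drop = FALSE])
    ft <- fisher_top_fraction(sub, fraction)
    tibble(round = b, p_value = ft$p_value, odds_ratio = ft$odds_ratio)
  })
  out <- bind_rows(rows)
  attr(out, "median_p") <- stats::median(out$p_value)
  class(out) <- c("bootstrap_fisher", class(out))
  out
}

#' Compare score distributions of bound and unbound transcripts
#'
#' Two-sample t-test of the predicted scores for positives against
#' negatives (Welch by default; set `var_equal = TRUE` for the pooled
#' classic test).
#'
#' @inheritParams fisher_top_fraction
#' @param var_equal Assume equal variances.
#' @return One-row tibble: `statistic`, `p_value`, `estimate` (mean
#'   difference, positive minus negative), `df`.
#' @export
score_distribution_test <- function(set, var_equal = FALSE) {
  assert_columns(set, c("score", "bound"), "set")
  tt <- t.test(set$score[set$bound], set$score[!set$bound],
               var.equal = var_equal)
  tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
         estimate = unname(tt$estimate[1] - tt$estimate[2]),
         df = unname(tt$parameter))
}

#' Kolmogorov-Smirnov test of knock-down LFC shift in targets
#'
#' Compares the log-fold-change distribution of flagged targets with that
#' of all remaining transcripts: the check that target expression changes
#' when the protein is knocked down.
#'
#' @param kd Tibble with columns `lfc` and the flag column.
#' @param flag Name of the logical column marking targets (default
#'   `"bound"`).
#' @return One-row tibble: `statistic` (KS D), `p_value`, `n_target`,
#'   `n_rest`.
#' @export
lfc_shift_test <- function(kd, flag = "bound") {
  assert_columns(kd, c("lfc", flag), "kd")
  f <- kd[[flag]]
  if (!is.logical(f)) abort_bad_arg("flag", "name a logical column")
  x <- kd$lfc[f]; y <- kd$lfc[!f]
  if (length(x) == 0 || length(y) == 0) {
    abort_bad_arg("kd", "contain both target and non-target transcripts")
  }
  ks <- suppressWarnings(ks.test(x, y))
  tibble(statistic = unname(ks$statistic), p_value = ks$p.value,
         n_target = length(x), n_rest = length(y))
}

#' Percent of top-ranked transcripts with positive LFC
#'
#' Ranks transcripts by a chosen column (a predicted interaction score or
#' an experimental binding signal), takes the top `fraction` (floored,
#' ties broken lexicographically), and reports the percentage with
#' strictly positive log-fold change.
#'
#' @param kd Tibble with columns `transcript`, `lfc` and the ranking
#'   column.
#' @param rank_by Name of the numeric column to rank by.
#' @param fraction Top fraction, in (0, 1).
#' @return Percentage in \[0, 100\].
#' @export
top_fraction_lfc_positive <- function(kd, rank_by, fraction = 0.01) {
  assert_columns(kd, c("transcript", "lfc", rank_by), "kd")
  assert_number(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    abort_bad_arg("fraction", "lie strictly inside (0, 1)")
  }
  n_top <- floor(nrow(kd) * fraction)
  if (n_top == 0) abort_bad_arg("fraction", "select at least one transcript")
  idx <- c_order(-kd[[rank_by]], kd$transcript)[seq_len(n_top)]
  100 * mean(kd$lfc[idx] > 0)
}

#' ROC and precision-recall curves at several class-imbalance ratios
#'
#' For each positive:negative ratio, negatives are subsampled (without
#' replacement, seeded) to `n_pos / ratio`, then ROC and PR point sets
#' are computed by threshold sweep over the scores. AUROC and average
#' precision (step-function integral of the PR curve) are reported per
#' ratio.
#'
#' @inheritParams fisher_top_fraction
#' @param pos_neg_ratios Positive-to-negative ratios (e.g. `1` for
#'   balanced, `0.1` for 1:10).
#' @param seed Optional integer seed for the subsampling.
#' @return A list of class `roc_pr`: `points` (tibble `ratio`,
#'   `threshold`, `fpr`, `tpr`, `precision`, `recall`) and `summary`
#'   (tibble `ratio`, `n_pos`, `n_neg`, `auroc`, `average_precision`).
#' @export
roc_pr_curves <- function(set, pos_neg_ratios = c(1, 0.5, 0.1),
                          seed = NULL) {
  assert_columns(set, c("score", "bound"), "set")
  if (!is.null(seed)) set.seed(seed)
  pos <- set[set$bound, , drop = FALSE]
  neg <- set[!set$bound, , drop = FALSE]
  if (nrow(pos) == 0 || nrow(neg) == 0) {
    abort_bad_arg("set", "contain both positives and negatives")
  }
  res <- purrr::map(pos_neg_ratios, function(ratio) {
    assert_number(ratio, "pos_neg_ratios", lower = 1e-6)
    n_neg <- min(nrow(neg), max(1L, round(nrow(pos) / ratio)))
    sub <- bind_rows(pos, neg[sample.int(nrow(neg), n_neg), , drop = FALSE])
    roc <- pROC::roc(response = sub$bound, predictor = sub$score,
                     levels = c(FALSE, TRUE), direction = "<",
                     quiet = TRUE)
    co <- pROC::coords(roc, x = "all",
                       ret = c("threshold", "specificity", "sensitivity",
                               "precision", "recall"),
                       transpose = FALSE)
    pts <- tibble(ratio = ratio, threshold = co$threshold,
                  fpr = 1 - co$specificity, tpr = co$sensitivity,
                  precision = co$precision, recall = co$recall)
    ap <- average_precision(sub$score, sub$bound)
    list(points = pts,
         summary = tibble(ratio = ratio, n_pos = nrow(pos), n_neg = n_neg,
                          auroc = as.numeric(pROC::auc(roc)),
                          average_precision = ap))
  })
  structure(list(points = bind_rows(purrr::map(res, "points")),
                 summary = bind_rows(purrr::map(res, "summary"))),
            class = "roc_pr")
}

# step-function average precision: mean precision at each recalled positive
average_precision <- function(score, label) {
  lab <- label[order(-score)]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

#' @export
print.roc_pr <- function(x, ...) {
  cat("ROC / precision-recall curves\n")
  print(x$summary)
  invisible(x)
}
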