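# ggplot2 displays for the main result types.

#' Plot enrichment curves over tail percentiles
#'
#' One line per correlation threshold, faceted by direction
#' (co-expressed vs anti-expressed), mirroring the enrichment-vs-AUC
#' displays of the analysis.
#'
#' @param object An `rbp_enrichment` tibble from [enrichment_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rbp_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$enrichment), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = auc, y = enrichment,
                                   colour = factor(abs(threshold)),
                                   group = threshold)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~direction, labeller = ggplot2::labeller(
      direction = c(co = "co-expressed", anti = "anti-expressed"))) +
    ggplot2::labs(x = "tail percentile (AUC, %)",
                  y = "enrichment over non-interacting tail",
                  colour = "|r| threshold") +
    ggplot2::theme_minimal()
}

#' Plot ROC and precision-recall curves
#'
#' @param object A `roc_pr` object from [roc_pr_curves()].
#' @param ... Unused.
#' @return A ggplot object with ROC and PR panels.
#' @export
autoplot.roc_pr <- function(object, ...) {
  pts <- object$points
  roc_df <- mutate(pts, x = fpr, y = tpr, panel = "ROC")
  pr_df <- mutate(pts, x = recall, y = precision, panel = "precision-recall")
  df <- bind_rows(roc_df, pr_df)
  df <- df[!is.na(df$x) & !is.na(df$y), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = factor(ratio))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = "pos/neg ratio") +
    ggplot2::theme_minimal()
}

#' Plot the disorder-promoting fraction per propensity bin
#'
#' @param object A `disorder_fractions` tibble from
#'   [binned_promoting_fraction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disorder_fractions <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = bin, y = frac, colour = rbd,
                               group = rbd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#c0392b", `FALSE` = "#7f8c8d"),
      labels = c(`TRUE` = "canonical RBD", `FALSE` = "no RBD")) +
    ggplot2::labs(x = "interaction propensity bin (low to high)",
                  y = "fraction of proteins where disorder promotes",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot classified pair counts
#'
#' @param object A `pair_classification` from [classify_pairs()].
#' @param ... Unused.
#' @return A ggplot bar chart of IC/IA/NIC/NIA counts.
#' @export
autoplot.pair_classification <- function(object, ...) {
  df <- count(as_tibble(object), label)
  df <- df[df$label != "unclassified", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = label, y = n)) +
    ggplot2::geom_col(fill = "#2c3e50") +
    ggplot2::labs(x = NULL, y = "pairs") +
    ggplot2::theme_minimal()
}
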