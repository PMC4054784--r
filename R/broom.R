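# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for classification results
#'
#' `tidy()` returns the per-pair table; `glance()` a one-row summary with
#' the subset sizes and the parameters used.
#'
#' @param x A `pair_classification`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pair_classification <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.pair_classification
#' @export
glance.pair_classification <- function(x, ...) {
  tab <- table(x$label)
  tibble(n_pairs = nrow(x), n_ic = tab[["IC"]], n_ia = tab[["IA"]],
         n_nic = tab[["NIC"]], n_nia = tab[["NIA"]],
         auc = attr(x, "auc"), r_cut = attr(x, "r_cut"),
         l_cut = attr(x, "l_cut"))
}

#' Tidiers for enrichment sweeps
#'
#' `tidy()` returns the grid table; `glance()` the peak enrichment per
#' direction.
#'
#' @param x An `rbp_enrichment`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rbp_enrichment <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.rbp_enrichment
#' @export
glance.rbp_enrichment <- function(x, ...) {
  df <- as_tibble(x)
  df <- df[!is.na(df$enrichment), , drop = FALSE]
  df %>%
    group_by(direction) %>%
    summarise(max_enrichment = max(enrichment),
              at_auc = auc[which.max(enrichment)],
              at_threshold = threshold[which.max(enrichment)],
              .groups = "drop")
}

#' Tidiers for GO results
#'
#' `tidy()` returns passing rows first (sorted by focal p within
#' subset); `glance()` counts passing terms per subset.
#'
#' @param x A `go_results`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.go_results <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  arrange(out, desc(pass), subset, p_analyzed)
}

#' @rdname tidy.go_results
#' @export
glance.go_results <- function(x, ...) {
  as_tibble(x) %>%
    group_by(subset) %>%
    summarise(n_terms = dplyr::n(), n_pass = sum(pass),
              min_p = min(p_analyzed), .groups = "drop")
}

#' Tidiers for bootstrap Fisher results
#'
#' @param x A `bootstrap_fisher`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bootstrap_fisher <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @rdname tidy.bootstrap_fisher
#' @export
glance.bootstrap_fisher <- function(x, ...) {
  tibble(n_boot = nrow(x), median_p = attr(x, "median_p"),
         frac_significant = mean(x$p_value < 0.05))
}
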