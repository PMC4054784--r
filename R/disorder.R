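#' Extract structurally disordered regions from per-residue tracks
#'
#' A disordered region is a maximal run of consecutive residues with
#' disorder score strictly above `threshold` (default 0.4); runs shorter
#' than `min_len` are discarded. Regions are reported in 0-based
#' half-open coordinates, non-overlapping and sorted.
#'
#' @param tracks Tibble with columns `protein`, `position` (1-based,
#'   contiguous per protein), `score` in \[0, 1\].
#' @param threshold Strict lower score bound for disordered residues.
#' @param min_len Minimum region length in residues. The default of 50
#'   matches the lower bound of the protein analysis window, so extracted
#'   regions are themselves long enough to score.
#' @return Tibble `protein`, `start`, `end` (0-based half-open).
#' @export
#' @examples
#' extract_disordered_regions(
#'   tibble::tibble(protein = "p", position = 1:4,
#'                  score = c(0.5, 0.5, 0.3, 0.5)), min_len = 1)
extract_disordered_regions <- function(tracks, threshold = 0.4,
                                       min_len = 50) {
  assert_columns(tracks, c("protein", "position", "score"), "tracks")
  assert_number(threshold, "threshold", 0, 1)
  assert_count(min_len, "min_len")
  if (any(tracks$score < 0 | tracks$score > 1, na.rm = TRUE) ||
      any(is.na(tracks$score))) {
    abort_bad_arg("tracks$score", "lie in [0, 1]")
  }
  by_prot <- split(tracks, tracks$protein)
  out <- purrr::map(by_prot, function(tr) {
    tr <- tr[order(tr$position), , drop = FALSE]
    runs <- rle(tr$score > threshold)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= min_len
    if (!any(keep)) return(NULL)
    tibble(protein = tr$protein[[1L]],
           start = starts[keep] - 1L,      # 0-based half-open
           end = ends[keep])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(protein = character(), start = integer(),
                  end = integer()))
  }
  arrange(out, protein, start)
}

#' Does a disordered region promote RNA interaction for one protein?
#'
#' One-sided Mann-Whitney U test that the region's per-transcript
#' interaction scores exceed the full-length protein's over the same
#' transcript set; the region is called promoting when p < `alpha`.
#' Degenerate sample sizes for which the smallest achievable p exceeds
#' `alpha` are flagged underpowered rather than erroring.
#'
#' @param region_scores,full_scores Numeric vectors of per-transcript
#'   interaction scores (same transcript set, so equal length).
#' @param alpha Promotion significance level.
#' @return One-row tibble: `n`, `statistic` (U), `p_value`, `promoting`,
#'   `underpowered`.
#' @export
contribution_test <- function(region_scores, full_scores, alpha = 0.05) {
  if (length(region_scores) != length(full_scores)) {
    abort_bad_arg("region_scores", "match `full_scores` in length")
  }
  n1 <- length(region_scores); n2 <- length(full_scores)
  wt <- suppressWarnings(
    wilcox.test(region_scores, full_scores, alternative = "greater"))
  min_p <- 1 / choose(n1 + n2, n1)
  tibble(n = n1, statistic = unname(wt$statistic), p_value = wt$p.value,
         promoting = wt$p.value < alpha, underpowered = min_p > alpha)
}

#' Per-protein disorder contribution records
#'
#' Applies [contribution_test()] to every protein's region-vs-full-length
#' score pairs and attaches the per-protein mean scores used downstream
#' for propensity binning.
#'
#' @param region_scores Tibble `protein`, `transcript`, `full_score`,
#'   `region_score` (deltas are computed on the identical transcript
#'   set per protein).
#' @param alpha Promotion significance level.
#' @return Tibble, one row per protein: `protein`, `n`, `mean_full`,
#'   `mean_region`, `mean_delta`, `statistic`, `p_value`, `promoting`,
#'   `underpowered`.
#' @export
disorder_contribution <- function(region_scores, alpha = 0.05) {
  assert_columns(region_scores,
                 c("protein", "transcript", "full_score", "region_score"),
                 "region_scores")
  by_prot <- split(region_scores, region_scores$protein)
  purrr::map(by_prot, function(df) {
    ct <- contribution_test(df$region_score, df$full_score, alpha)
    tibble(protein = df$protein[[1L]], n = nrow(df),
           mean_full = mean(df$full_score),
           mean_region = mean(df$region_score),
           mean_delta = mean(df$region_score - df$full_score),
           statistic = ct$statistic, p_value = ct$p_value,
           promoting = ct$promoting, underpowered = ct$underpowered)
  }) %>% bind_rows()
}

#' Fraction of disorder-promoting proteins per propensity bin
#'
#' Bins proteins by their mean full-length interaction propensity and
#' reports, per bin and separately for proteins with and without a
#' canonical RNA-binding domain, the fraction whose disordered region
#' out-scores the full-length chain. The expected picture: the fraction
#' decays from low- to high-propensity bins and is larger in proteins
#' lacking canonical RNA-binding domains. Empty bins are absent from the
#' output, not reported as zero.
#'
#' @param records Output of [disorder_contribution()].
#' @param rbd Tibble `protein`, `rbd` (logical: canonical RNA-binding
#'   domain present).
#' @param n_bins Number of equal-count propensity bins.
#' @return Tibble of class `disorder_fractions`: `bin` (integer, low to
#'   high propensity), `rbd`, `n_prot`, `frac` (fraction promoting).
#' @export
binned_promoting_fraction <- function(records, rbd, n_bins = 4) {
  assert_columns(records, c("protein", "mean_full", "promoting"),
                 "records")
  assert_columns(rbd, c("protein", "rbd"), "rbd")
  assert_count(n_bins, "n_bins")
  df <- inner_join(records, rbd, by = "protein")
  brks <- quantile(df$mean_full, seq(0, 1, length.out = n_bins + 1),
                   names = FALSE)
  brks[1] <- -Inf; brks[length(brks)] <- Inf
  df$bin <- cut(df$mean_full, breaks = unique(brks), labels = FALSE)
  out <- df %>%
    group_by(bin, rbd) %>%
    summarise(n_prot = dplyr::n(), frac = mean(promoting),
              .groups = "drop") %>%
    arrange(bin, rbd)
  class(out) <- c("disorder_fractions", class(out))
  out
}
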