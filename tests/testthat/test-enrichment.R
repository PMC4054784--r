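test_that("tail sizes follow the floored percentile rule", {
  expect_identical(tail_size(10, 90), 1)
  expect_identical(tail_size(1000, 95), 50)
  expect_identical(tail_size(1000, 99.5), 5)
  expect_error(tail_size(100, 40), "auc")
  expect_error(tail_size(100, 99.9), "auc")
})

test_that("selected tails are equal-sized, extreme and deterministic", {
  pairs <- random_pairs(500, seed = 101)
  sel <- select_tails(pairs[, c("protein", "transcript", "score")], 90)
  tab <- table(sel$tail_set)
  expect_identical(unname(tab[["interacting"]]),
                   unname(tab[["non_interacting"]]))
  expect_identical(unname(tab[["interacting"]]), as.integer(tail_size(500, 90)))
  top <- sel$score[sel$tail_set %in% "interacting"]
  bot <- sel$score[sel$tail_set %in% "non_interacting"]
  mid <- sel$score[is.na(sel$tail_set)]
  expect_gte(min(top), max(mid))
  expect_lte(max(bot), min(mid))

  # ties at the cut: resolved by id order, stable across row shuffles
  tied <- tibble::tibble(protein = sprintf("p%02d", 1:10),
                         transcript = sprintf("t%02d", 1:10),
                         score = c(rep(1, 5), rep(-1, 5)))
  s1 <- select_tails(tied, 90)
  s2 <- select_tails(tied[sample(10), ], 90)
  expect_identical(s1$protein[s1$tail_set %in% "interacting"], "p01")
  expect_identical(
    sort(s2$protein[s2$tail_set %in% "interacting"]), "p01")
})

test_that("enrichment statistics reproduce direct substitution", {
  # build 100 interacting + 100 non-interacting pairs with exact
  # qualifying counts: 30 vs 20 above r_th, 10 vs 40 below l_th
  r_int <- c(rep(0.9, 30), rep(-0.9, 10), rep(0, 60))
  r_non <- c(rep(0.9, 20), rep(-0.9, 40), rep(0, 40))
  pairs <- tibble::tibble(
    protein = "p", transcript = sprintf("t%03d", 1:200),
    score = c(seq(10, 5, length.out = 100), seq(-5, -10, length.out = 100)))
  corr <- tibble::tibble(protein = "p", transcript = pairs$transcript,
                         r = c(r_int, r_non))
  sel <- select_tails(pairs, 50)
  expect_equal(enrichment_coexpressed(sel, corr, 0.7), (30 - 20) / 20)
  expect_equal(enrichment_antiexpressed(sel, corr, -0.7), (10 - 40) / 40)
  expect_error(enrichment_coexpressed(sel, corr, -0.1), "positive")
  expect_error(enrichment_antiexpressed(sel, corr, 0.1), "negative")
  expect_warning(out <- enrichment_coexpressed(sel, corr, 0.95),
                 "undefined")
  expect_true(is.na(out))
})

test_that("enrichment matches the loop oracle on random fixtures", {
  for (s in 1:100) {
    pairs <- random_pairs(200, seed = 200 + s)
    sel <- select_tails(pairs[, c("protein", "transcript", "score")], 75)
    corr <- pairs[, c("protein", "transcript", "r")]
    tf_int <- pairs$r[order(-pairs$score)][1:50]
    tf_non <- pairs$r[order(pairs$score)][1:50]
    th <- runif(1, 0.05, 0.9)
    expect_identical(
      suppressWarnings(enrichment_coexpressed(sel, corr, th)),
      oracle_enrichment(tf_int, tf_non, th, "co"))
    expect_identical(
      suppressWarnings(enrichment_antiexpressed(sel, corr, -th)),
      oracle_enrichment(tf_int, tf_non, -th, "anti"))
  }
})

test_that("undefined correlations are trimmed symmetrically from both tails", {
  pairs <- tibble::tibble(protein = "p",
                          transcript = sprintf("t%02d", 1:10),
                          score = 10:1)
  corr <- tibble::tibble(protein = "p", transcript = pairs$transcript,
                         r = c(NA, 0.9, 0.9, 0.9, 0.9, 0, 0, 0, 0, 0.9))
  sel <- select_tails(pairs, 50)   # 5 top, 5 bottom; one top r is NA
  # after dropping the NA pair both tails must count over 4 pairs
  expect_equal(enrichment_coexpressed(sel, corr, 0.7), (4 - 1) / 1)
})

test_that("a 1x1 sweep grid equals the scalar statistics and nulls are flat", {
  fix <- default_analysis()
  sweep1 <- enrichment_sweep(fix$scores_f, fix$corr, auc_grid = 95,
                             threshold_grid = 0.7)
  sel <- select_tails(fix$scores_f, 95)
  expect_equal(sweep1$enrichment[sweep1$direction == "co"],
               enrichment_coexpressed(sel, fix$corr, 0.7))
  expect_equal(sweep1$enrichment[sweep1$direction == "anti"],
               enrichment_antiexpressed(sel, fix$corr, -0.7))

  # null cohort: enrichment scattered around zero at a permissive threshold
  cfg <- synthetic_config(n_proteins = 40, n_transcripts = 400,
                          frac_ic = 0, frac_ia = 0, seed = 7)
  sim <- simulate_expression(cfg)
  sc <- simulate_scores(cfg, sim$truth)
  corr0 <- correlate_pairs(sim$proteins, sim$transcripts)
  sw0 <- enrichment_sweep(sc, corr0, auc_grid = c(50, 75),
                          threshold_grid = 0.3)
  expect_true(all(abs(sw0$enrichment) < 0.3, na.rm = TRUE))
})

test_that("planted signal concentrates in the extreme tail", {
  fix <- default_analysis()
  sw <- enrichment_sweep(fix$scores_f, fix$corr,
                         auc_grid = c(50, 75, 95), threshold_grid = 0.7)
  co <- sw[sw$direction == "co", ]
  expect_identical(co$enrichment, sort(co$enrichment))
  expect_gt(co$enrichment[co$auc == 95], co$enrichment[co$auc == 50])
  anti <- sw[sw$direction == "anti", ]
  expect_gt(anti$enrichment[anti$auc == 95], 1)
})

test_that("classification obeys the subset definitions and tail containment", {
  pairs <- tibble::tibble(
    protein = "p", transcript = sprintf("t%03d", 1:100),
    score = c(120, seq(50, -40, length.out = 98), -50))
  corr <- tibble::tibble(protein = "p", transcript = pairs$transcript,
                         r = c(0.9, runif(98, -0.5, 0.5), -0.8))
  cls <- classify_pairs(pairs, corr, auc = 95, r_cut = 0.7, l_cut = -0.7)
  expect_identical(as.character(cls$label[cls$transcript == "t001"]), "IC")
  expect_identical(as.character(cls$label[cls$transcript == "t100"]), "NIA")

  fix <- default_analysis()
  cls2 <- fix$cls
  # brute-force reclassification oracle
  want <- rep("unclassified", nrow(cls2))
  inter <- !is.na(cls2$tail_set) & cls2$tail_set == "interacting"
  noint <- !is.na(cls2$tail_set) & cls2$tail_set == "non_interacting"
  ok_r <- !is.na(cls2$r)
  want[inter & cls2$score > 0 & ok_r & cls2$r >= 0.7] <- "IC"
  want[inter & cls2$score > 0 & ok_r & cls2$r <= -0.7] <- "IA"
  want[noint & cls2$score < 0 & ok_r & cls2$r >= 0.7] <- "NIC"
  want[noint & cls2$score < 0 & ok_r & cls2$r <= -0.7] <- "NIA"
  expect_identical(as.character(cls2$label), want)

  # disjointness and containment
  expect_true(all(cls2$tail_set[cls2$label %in% c("IC", "IA")] ==
                    "interacting"))
  expect_true(all(cls2$tail_set[cls2$label %in% c("NIC", "NIA")] ==
                    "non_interacting"))
  g <- glance(cls2)
  expect_gt(g$n_ic, 100)   # planted IC pairs recovered
  expect_gt(g$n_ia, 100)
})

test_that("correlation percentiles follow the empirical |r| quantile", {
  expect_identical(correlation_percentile(c(-1, 0, 1), 50), 1)
  expect_identical(correlation_percentile(c(-1, 0, 1), 0), 0)
  set.seed(11)
  r <- runif(20000, -1, 1)
  expect_equal(correlation_percentile(r, 95), 0.95, tolerance = 0.02)
})
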