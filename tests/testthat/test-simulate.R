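test_that("generators are bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_proteins = 15, n_transcripts = 80, seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$scores, b$scores)
  expect_identical(a$knockdown, b$knockdown)
  expect_identical(a$disorder$tracks, b$disorder$tracks)
  expect_identical(a$go_set$go$annotation, b$go_set$go$annotation)
  expect_identical(a$identities, b$identities)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(rho_target = 1.2), "rho_target")
  expect_error(synthetic_config(rho_target = 0), "rho_target")
  expect_error(synthetic_config(frac_ic = 0.7, frac_ia = 0.6), "at most 1")
  expect_error(synthetic_config(n_proteins = 0), "n_proteins")
})

test_that("unplanted cohorts have no correlation signal", {
  cfg <- synthetic_config(n_proteins = 40, n_transcripts = 200,
                          frac_ic = 0, frac_ia = 0, seed = 5)
  sim <- simulate_expression(cfg)
  corr <- correlate_pairs(sim$proteins, sim$transcripts)
  # mean r over independent pairs: SE = sd(r)/sqrt(n_pairs); pairs sharing
  # an entity are correlated, so use a conservative n of the entity count
  se <- stats::sd(corr$r) / sqrt(40 + 200)
  expect_lt(abs(mean(corr$r)), 3 * se)
  expect_identical(nrow(sim$truth$ic_pairs), 0L)
})

test_that("planted pairs recover rho_target and match the bivariate-normal oracle", {
  fix <- default_fixture()
  corr <- correlate_pairs(fix$proteins, fix$transcripts)
  ic <- dplyr::inner_join(fix$truth$ic_pairs, corr,
                          by = c("protein", "transcript"))
  ia <- dplyr::inner_join(fix$truth$ia_pairs, corr,
                          by = c("protein", "transcript"))
  expect_gt(nrow(ic), 100)
  expect_lt(abs(mean(ic$r) - 0.8), 0.1)
  expect_lt(abs(mean(ia$r) + 0.8), 0.1)

  # Monte-Carlo oracle: mean sample r of the shared-factor construction at
  # n = 14 tissues, 1000 replicates
  set.seed(99)
  a <- sqrt(0.8); b <- sqrt(0.2)
  r_mc <- replicate(1000, {
    f <- rnorm(14)
    oracle_pearson(a * f + b * rnorm(14), a * f + b * rnorm(14))
  })
  expect_lt(abs(mean(ic$r) - mean(r_mc)), 0.05)
})

test_that("every simulated entity is expressed in at least one tissue", {
  fix <- default_fixture()
  kept <- filter_expressed(fix$proteins)
  expect_identical(nrow(kept), nrow(fix$proteins))
  # transcripts: all except the deliberately zeroed ones
  kept_tx <- filter_expressed(fix$transcripts)
  expect_setequal(setdiff(fix$transcripts$id, kept_tx$id),
                  fix$truth$zeroed_transcripts)
})

test_that("score matrix has pair-per-row shape and planted upper-tail geometry", {
  cfg <- synthetic_config(n_proteins = 30, n_transcripts = 300,
                          frac_ic = 0.005, frac_ia = 0.005, seed = 21)
  sim <- simulate_expression(cfg)
  sc <- simulate_scores(cfg, sim$truth)
  expect_identical(nrow(sc), 30L * 300L)
  expect_identical(dplyr::n_distinct(sc$protein), 30L)
  expect_identical(dplyr::n_distinct(sc$transcript), 300L)

  planted <- dplyr::bind_rows(sim$truth$ic_pairs, sim$truth$ia_pairs)
  joined <- dplyr::inner_join(planted, sc, by = c("protein", "transcript"))
  q90 <- quantile(sc$score, 0.9)
  expect_gt(mean(joined$score > q90), 0.95)
})

test_that("zero score shift leaves planted ranks uniform", {
  cfg <- synthetic_config(n_proteins = 30, n_transcripts = 300,
                          frac_ic = 0.01, frac_ia = 0.01,
                          score_shift = 0, seed = 31)
  sim <- simulate_expression(cfg)
  sc <- simulate_scores(cfg, sim$truth)
  planted <- dplyr::bind_rows(sim$truth$ic_pairs, sim$truth$ia_pairs)
  joined <- dplyr::inner_join(planted, sc, by = c("protein", "transcript"))
  u <- (rank(sc$score)[match(
    paste(joined$protein, joined$transcript),
    paste(sc$protein, sc$transcript))] - 0.5) / nrow(sc)
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("knock-down simulation displaces bound targets as configured", {
  cfg <- synthetic_config(n_proteins = 10, n_transcripts = 500,
                          frac_bound = 0.1, lfc_shift = 1, seed = 41)
  sim <- simulate_expression(cfg)
  kd <- simulate_knockdown(cfg, sim$truth)
  expect_setequal(kd$transcript[kd$bound], sim$truth$bound_targets)
  expect_gt(mean(kd$lfc[kd$bound]) - mean(kd$lfc[!kd$bound]), 0.5)

  # no bound targets at all
  cfg0 <- synthetic_config(n_proteins = 10, n_transcripts = 100,
                           frac_bound = 0, seed = 42)
  sim0 <- simulate_expression(cfg0)
  kd0 <- simulate_knockdown(cfg0, sim0$truth)
  expect_false(any(kd0$bound))
})

test_that("null knock-down shift is non-significant at the nominal level", {
  # lfc_shift = 0: the KS test should reject at alpha = 0.01 about 1% of
  # the time; require non-significance in at least 98 of 100 seeded runs
  truth <- list(bound_targets = sprintf("T%05d", 1:100),
                kd_protein = "P0001")
  hits <- vapply(1:100, function(s) {
    cfg <- synthetic_config(n_proteins = 10, n_transcripts = 2000,
                            lfc_shift = 0, seed = 1000 + s)
    kd <- simulate_knockdown(cfg, truth)
    lfc_shift_test(kd)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(!hits), 0.98)
})

test_that("disorder tracks respect lengths, thresholds and planted segments", {
  fix <- default_fixture()
  dis <- fix$disorder
  lens <- dplyr::count(dis$tracks, protein, name = "track_len")
  joined <- dplyr::inner_join(lens, dis$lengths, by = c(protein = "id"))
  expect_true(all(joined$track_len == joined$length))
  expect_true(all(joined$length >= 50 & joined$length <= 750))
  expect_true(all(dis$tracks$score >= 0 & dis$tracks$score <= 1))

  regions <- extract_disordered_regions(dis$tracks, min_len = 50)
  with_region <- unique(regions$protein)
  # every protein with a region has all region residues above 0.4 by
  # construction; proteins without one never cross 0.4
  below <- dis$tracks[!(dis$tracks$protein %in% with_region), ]
  expect_true(all(below$score < 0.4))
  expect_true(all(dis$disorder_promoting_proteins %in% with_region))
})

test_that("synthetic ontology is a DAG obeying the true-path rule", {
  fix <- default_fixture()
  go <- fix$go_set$go
  g <- igraph::graph_from_data_frame(go$edges, directed = TRUE,
                                     vertices = go$terms$term)
  expect_true(igraph::is_dag(g))
  # the BP root annotates every gene annotated anywhere in BP
  bp_root <- "SYN:0000001"
  bp_terms <- go$terms$term[go$terms$namespace == "BP"]
  bp_genes <- unique(go$annotation$gene[go$annotation$term %in% bp_terms])
  expect_setequal(go$ann_sets[[bp_root]], bp_genes)

  # planted IC term is fold-enriched in the true IC gene set
  ic_genes <- unique(fix$truth$ic_pairs$transcript)
  ann_ic <- go$ann_sets[[fix$go_set$ic_term]]
  all_genes <- fix$transcripts$id
  fold <- (length(intersect(ann_ic, ic_genes)) / length(ic_genes)) /
    (length(ann_ic) / length(all_genes))
  expect_gt(fold, 1)
})
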