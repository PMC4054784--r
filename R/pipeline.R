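#' Default end-to-end run configuration
#'
#' Bundles every threshold the pipeline applies, at the analysis'
#' canonical values: tail percentile grid 50-99.5, correlation cuts
#' +/-0.7 at the default classification percentile of 95, GO thresholds
#' (more than 2 genes; p < 0.05 significant, p > 0.1 non-significant;
#' 80% identity redundancy reduction), top 1% validation fraction with
#' 100 bootstrap rounds, and disorder threshold 0.4 with minimum region
#' length 50.
#'
#' @param auc_grid Tail percentiles for the enrichment sweep.
#' @param auc Classification tail percentile.
#' @param r_cut,l_cut Correlation cuts.
#' @param threshold_grid Positive correlation thresholds for the sweep.
#' @param go A [go_params()].
#' @param validation_fraction Top fraction for the validation battery.
#' @param n_boot Bootstrap rounds.
#' @param disorder_threshold,disorder_min_len Disorder region extraction
#'   parameters.
#' @param seed Integer seed for the stochastic validation steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(auc_grid = c(50, 75, 85, 90, 95, 99, 99.5),
                       auc = 95, r_cut = 0.7, l_cut = -0.7,
                       threshold_grid = c(0.3, 0.5, 0.7, 0.9),
                       go = go_params(),
                       validation_fraction = 0.01, n_boot = 100,
                       disorder_threshold = 0.4, disorder_min_len = 50,
                       seed = 1L) {
  structure(list(auc_grid = auc_grid, auc = auc, r_cut = r_cut,
                 l_cut = l_cut, threshold_grid = threshold_grid, go = go,
                 validation_fraction = validation_fraction, n_boot = n_boot,
                 disorder_threshold = disorder_threshold,
                 disorder_min_len = disorder_min_len,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline on a fixture directory
#'
#' Executes every stage in order on the inputs of a fixture directory
#' (as written by [simulate_dataset()]): length and expression filters,
#' per-tissue normalization, pairwise correlation, tail selection and the
#' enrichment sweep, IC/IA/NIC/NIA classification, conditional GO
#' analysis with the five-criteria filter, the knock-down validation
#' battery, and the disorder-contribution analysis. Every stage's output
#' is written as TSV (plus a JSON report for scalar statistics) under
#' `outdir`, together with a manifest recording parameters, seed and
#' input digests. Reruns with identical inputs and config are
#' byte-identical.
#'
#' @param indir Fixture directory holding the pipeline inputs.
#' @param outdir Output directory (created; existing files overwritten).
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(indir, outdir, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  need <- function(f) {
    p <- file.path(indir, f)
    if (!file.exists(p)) {
      abort(sprintf("pipeline input not found: %s", p),
            class = "rbpcoex_error_missing_input")
    }
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "rbpcoex_error_stage")
    })
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  inputs <- c("protein_expression.tsv", "transcript_expression.tsv",
              "interaction_scores.tsv", "transcript_lengths.tsv",
              "protein_lengths.tsv", "identities.tsv", "knockdown.tsv",
              "disorder_tracks.tsv", "rbd_flags.tsv", "region_scores.tsv",
              "ontology.obo", "annotations.tsv")
  paths <- vapply(inputs, need, character(1))

  prot_expr <- read_expression_tsv(paths[["protein_expression.tsv"]])
  tx_expr <- read_expression_tsv(paths[["transcript_expression.tsv"]])
  scores <- read_scores_tsv(paths[["interaction_scores.tsv"]])
  tx_len <- read_lengths_tsv(paths[["transcript_lengths.tsv"]])
  prot_len <- read_lengths_tsv(paths[["protein_lengths.tsv"]])
  idents <- read_identities_tsv(paths[["identities.tsv"]])
  kd <- read_tsv_quiet(paths[["knockdown.tsv"]])
  tracks <- read_tsv_quiet(paths[["disorder_tracks.tsv"]])
  rbd <- read_tsv_quiet(paths[["rbd_flags.tsv"]])
  region_scores <- read_tsv_quiet(paths[["region_scores.tsv"]])
  ann <- read_annotations_tsv(paths[["annotations.tsv"]])
  go <- read_obo(paths[["ontology.obo"]], ann)

  # --- filters -------------------------------------------------------
  res <- list()
  res$filters <- stage("filters", {
    tx_lenpass <- filter_length(tx_len, rna_window())
    prot_lenpass <- filter_length(prot_len, protein_window())
    tx_expressed <- filter_expressed(tx_expr)
    keep_tx <- intersect(tx_lenpass$id, tx_expressed$id)
    keep_prot <- intersect(prot_lenpass$id, filter_expressed(prot_expr)$id)
    note("length filter kept %d/%d transcripts (window 50-1200 nt), %d/%d proteins (50-750 aa)",
         nrow(tx_lenpass), nrow(tx_len), nrow(prot_lenpass), nrow(prot_len))
    note("expression filter kept %d/%d transcripts", nrow(tx_expressed),
         nrow(tx_expr))
    list(transcripts = keep_tx, proteins = keep_prot,
         length_restricted = tx_lenpass$id)
  })
  keep_tx <- res$filters$transcripts
  keep_prot <- res$filters$proteins
  tx_expr_f <- tx_expr[tx_expr$id %in% keep_tx, , drop = FALSE]
  prot_expr_f <- prot_expr[prot_expr$id %in% keep_prot, , drop = FALSE]
  scores_f <- scores[scores$protein %in% keep_prot &
                       scores$transcript %in% keep_tx, , drop = FALSE]

  # --- normalization & correlation -----------------------------------
  res$correlations <- stage("correlation", {
    correlate_pairs(prot_expr_f, tx_expr_f)
  })

  # --- enrichment sweep ----------------------------------------------
  res$enrichment <- stage("enrichment", {
    enrichment_sweep(scores_f, res$correlations,
                     auc_grid = config$auc_grid,
                     threshold_grid = config$threshold_grid)
  })

  # --- classification -------------------------------------------------
  res$classification <- stage("classification", {
    classify_pairs(scores_f, res$correlations, auc = config$auc,
                   r_cut = config$r_cut, l_cut = config$l_cut)
  })
  note("classification at AUC %s, cuts %+0.2f/%+0.2f: %s", config$auc,
       config$r_cut, config$l_cut,
       paste(sprintf("%s=%d", levels(res$classification$label),
                     table(res$classification$label)), collapse = " "))

  # --- GO analysis ----------------------------------------------------
  res$go <- stage("go", {
    cls <- res$classification
    in_tail <- unique(cls$transcript[!is.na(cls$tail_set)])
    universes <- gene_universes(
      transcriptome = tx_len$id,
      analyzed = keep_tx,
      auc_subset = intersect(in_tail, keep_tx),
      length_restricted = res$filters$length_restricted)
    run_go_analysis(cls, go, universes, params = config$go,
                    identities = idents, lengths = tx_len)
  })
  note("GO analysis: %d/%d (term, subset) rows pass all five criteria",
       sum(res$go$pass), nrow(res$go))

  # --- validation battery --------------------------------------------
  res$validation <- stage("validation", {
    kd_scores <- scores_f[scores_f$protein == scores_f$protein[[1L]], ,
                          drop = FALSE]
    vset <- inner_join(kd,
                       kd_scores[, c("transcript", "score")],
                       by = "transcript")
    list(fisher = fisher_top_fraction(vset,
                                      fraction = config$validation_fraction),
         bootstrap = bootstrap_fisher(vset,
                                      fraction = config$validation_fraction,
                                      n_boot = config$n_boot,
                                      seed = config$seed),
         t_test = score_distribution_test(vset),
         ks = lfc_shift_test(vset),
         roc_pr = roc_pr_curves(vset, seed = config$seed))
  })

  # --- disorder -------------------------------------------------------
  res$disorder <- stage("disorder", {
    regions <- extract_disordered_regions(
      tracks, threshold = config$disorder_threshold,
      min_len = config$disorder_min_len)
    contrib <- disorder_contribution(region_scores)
    list(regions = regions, contribution = contrib,
         fractions = binned_promoting_fraction(contrib, rbd))
  })

  # --- outputs --------------------------------------------------------
  w <- function(x, f) readr::write_tsv(x, file.path(outdir, f))
  w(tibble(id = keep_tx), "analyzed_transcripts.tsv")
  w(tibble(id = keep_prot), "analyzed_proteins.tsv")
  w(res$correlations, "correlations.tsv")
  w(as_tibble(res$enrichment), "enrichment_curves.tsv")
  w(as_tibble(res$classification), "classification.tsv")
  w(as_tibble(res$go), "go_results.tsv")
  w(res$disorder$regions, "disordered_regions.tsv")
  w(res$disorder$contribution, "disorder_contribution.tsv")
  w(as_tibble(res$disorder$fractions), "disorder_fractions.tsv")
  w(res$validation$roc_pr$points, "roc_pr_points.tsv")
  jsonlite::write_json(
    list(fisher = res$validation$fisher,
         bootstrap_median_p = attr(res$validation$bootstrap, "median_p"),
         t_test = res$validation$t_test, ks = res$validation$ks,
         roc_pr = res$validation$roc_pr$summary),
    file.path(outdir, "validation.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("rbpcoex")),
    seed = config$seed,
    parameters = unclass(config[setdiff(names(config), "go")]),
    go_parameters = unclass(config$go),
    input_digests = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(res)
}
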