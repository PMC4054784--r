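#' Configuration for the synthetic RBP-mRNA cohort
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' describe a desk-scale cohort with the statistical structure the analysis
#' assumes: 14 tissues, a small fraction of protein-transcript pairs planted
#' as interacting-and-co-expressed (IC) or interacting-and-anti-expressed
#' (IA) with expression correlation magnitude `rho_target`, interaction
#' scores shifted into the upper tail for planted pairs, knock-down
#' log-fold-change displacement for bound targets, and disordered protein
#' segments that out-score the full-length chain at low propensities.
#'
#' @param n_proteins,n_transcripts Number of RNA-binding proteins and
#'   transcripts in the cohort.
#' @param n_tissues Number of tissues profiled (14 in the human atlas
#'   setting this emulates).
#' @param frac_ic,frac_ia Fractions of all protein-transcript pairs planted
#'   as IC / IA. `frac_ic + frac_ia` must be at most 1 (in practice both are
#'   tiny).
#' @param rho_target Planted expression-correlation magnitude, in (0, 1).
#' @param score_shift Additive shift (in background standard deviations) of
#'   planted pairs' interaction scores.
#' @param lfc_shift Mean log-fold-change displacement of bound targets in
#'   the knock-down simulation; its sign selects up- or down-regulation.
#' @param lfc_sd Standard deviation of the knock-down LFC noise.
#' @param frac_bound Fraction of transcripts bound by the knock-down
#'   protein.
#' @param disorder_effect Probability that a disordered region out-scores
#'   its full-length protein in the lowest propensity bin.
#' @param frac_disordered Fraction of proteins carrying a disordered
#'   segment.
#' @param n_go_terms Total number of ontology terms to generate (at least
#'   12: two roots, two mid-level terms, the two planted leaves, and
#'   background leaves).
#' @param seed Integer random seed; every generator derives its stream from
#'   it.
#'
#' @return A list of class `synthetic_config`.
#' @seealso [simulate_dataset()] which runs all generators and writes a
#'   fixture directory.
#' @export
#' @examples
#' cfg <- synthetic_config(n_proteins = 20, n_transcripts = 100, seed = 1)
#' cfg$rho_target
synthetic_config <- function(n_proteins = 200,
                             n_transcripts = 2000,
                             n_tissues = 14,
                             frac_ic = 0.001,
                             frac_ia = 0.001,
                             rho_target = 0.8,
                             score_shift = 3,
                             lfc_shift = 1,
                             lfc_sd = 1,
                             frac_bound = 0.05,
                             disorder_effect = 0.66,
                             frac_disordered = 0.66,
                             n_go_terms = 21,
                             seed = 1L) {
  assert_count(n_proteins, "n_proteins")
  assert_count(n_transcripts, "n_transcripts")
  assert_count(n_tissues, "n_tissues")
  assert_number(frac_ic, "frac_ic", 0, 1)
  assert_number(frac_ia, "frac_ia", 0, 1)
  if (frac_ic + frac_ia > 1) {
    abort_bad_arg("frac_ic + frac_ia", "be at most 1")
  }
  if (rho_target <= 0 || rho_target >= 1) {
    abort_bad_arg("rho_target", "lie strictly inside (0, 1)")
  }
  assert_number(score_shift, "score_shift")
  assert_number(lfc_shift, "lfc_shift")
  assert_number(lfc_sd, "lfc_sd", lower = 0)
  assert_number(frac_bound, "frac_bound", 0, 1)
  assert_number(disorder_effect, "disorder_effect", 0, 1)
  assert_number(frac_disordered, "frac_disordered", 0, 1)
  assert_count(n_go_terms, "n_go_terms")
  if (n_go_terms < 12) abort_bad_arg("n_go_terms", "be at least 12")
  assert_count(seed, "seed", positive = FALSE)

  structure(list(
    n_proteins = as.integer(n_proteins),
    n_transcripts = as.integer(n_transcripts),
    n_tissues = as.integer(n_tissues),
    frac_ic = frac_ic, frac_ia = frac_ia,
    rho_target = rho_target, score_shift = score_shift,
    lfc_shift = lfc_shift, lfc_sd = lfc_sd, frac_bound = frac_bound,
    disorder_effect = disorder_effect, frac_disordered = frac_disordered,
    n_go_terms = as.integer(n_go_terms), seed = as.integer(seed)
  ), class = "synthetic_config")
}

protein_ids <- function(n) sprintf("P%04d", seq_len(n))
transcript_ids <- function(n) sprintf("T%05d", seq_len(n))

# Offsets keep the generators' RNG streams independent of call order.
seed_for <- function(config, offset) {
  as.integer((config$seed + offset * 10007L) %% .Machine$integer.max)
}

#' Simulate tissue-expression profiles with planted co-/anti-expression
#'
#' Background entities get independent standard-normal latent profiles over
#' tissues; each planted IC pair shares a latent tissue factor between its
#' protein and transcript so that the population Pearson correlation equals
#' `+rho_target`, and each IA pair equals `-rho_target` (factor loading
#' `sqrt(rho_target)` on both sides). Latent profiles are mapped to
#' abundances by the affine transform `10 + 2 z`, which leaves all pairwise
#' Pearson correlations untouched and keeps values positive, so every
#' entity is expressed in at least one tissue.
#'
#' Planted transcripts are distinct across pairs; a planted protein may
#' anchor several transcripts, all loading on its single factor.
#'
#' @param config A [synthetic_config()].
#' @return A list with `proteins` and `transcripts` (wide tibbles,
#'   `id` + one column per tissue) and `truth`, a list carrying `ic_pairs`
#'   and `ia_pairs` tibbles (`protein`, `transcript`) plus `bound_targets`
#'   and the knock-down protein id.
#' @export
#' @examples
#' sim <- simulate_expression(synthetic_config(n_proteins = 10,
#'                                             n_transcripts = 50, seed = 2))
#' dim(sim$proteins)
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed_for(config, 1L))

  np <- config$n_proteins; nt <- config$n_transcripts
  k <- config$n_tissues
  prot <- protein_ids(np); tx <- transcript_ids(nt)
  tissues <- sprintf("tissue_%02d", seq_len(k))

  n_pairs <- as.numeric(np) * nt
  n_ic <- round(config$frac_ic * n_pairs)
  n_ia <- round(config$frac_ia * n_pairs)
  if (n_ic + n_ia > nt) {
    abort("too many planted pairs: frac_ic/frac_ia exceed one transcript each")
  }

  # one latent factor per protein; loading sqrt(rho) on both partners gives
  # corr = rho (IC) or -rho (IA)
  a <- sqrt(config$rho_target)
  b <- sqrt(1 - config$rho_target)
  factors <- matrix(rnorm(np * k), np, k)

  zp <- a * factors + b * matrix(rnorm(np * k), np, k)
  zt <- matrix(rnorm(nt * k), nt, k)

  planted_tx <- sample(nt, n_ic + n_ia)
  ic_tx <- planted_tx[seq_len(n_ic)]
  ia_tx <- planted_tx[n_ic + seq_len(n_ia)]
  ic_prot <- if (n_ic > 0) sample(np, n_ic, replace = TRUE) else integer()
  ia_prot <- if (n_ia > 0) sample(np, n_ia, replace = TRUE) else integer()

  if (n_ic > 0) {
    zt[ic_tx, ] <- a * factors[ic_prot, , drop = FALSE] +
      b * matrix(rnorm(n_ic * k), n_ic, k)
  }
  if (n_ia > 0) {
    zt[ia_tx, ] <- -a * factors[ia_prot, , drop = FALSE] +
      b * matrix(rnorm(n_ia * k), n_ia, k)
  }

  to_tbl <- function(ids, z) {
    m <- 10 + 2 * z
    colnames(m) <- tissues
    bind_cols_id(ids, m)
  }

  kd_protein <- prot[[1L]]
  n_bound <- round(config$frac_bound * nt)
  bound <- sort(sample(tx, n_bound))

  truth <- list(
    ic_pairs = tibble(protein = prot[ic_prot], transcript = tx[ic_tx]),
    ia_pairs = tibble(protein = prot[ia_prot], transcript = tx[ia_tx]),
    bound_targets = bound,
    kd_protein = kd_protein
  )

  list(proteins = to_tbl(prot, zp),
       transcripts = to_tbl(tx, zt),
       truth = truth)
}

bind_cols_id <- function(ids, m) {
  out <- as_tibble(as.data.frame(m))
  out <- dplyr::bind_cols(tibble(id = ids), out)
  out
}

#' Simulate an interaction-propensity score matrix
#'
#' Background scores are standard normal (negative values allowed, as for
#' real propensity scores); planted IC/IA pairs and the knock-down
#' protein's bound targets are shifted upward by `score_shift` standard
#' deviations so they populate the upper tail.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth list from [simulate_expression()].
#' @return A long tibble with columns `protein`, `transcript`, `score`
#'   (one row per pair, `n_proteins * n_transcripts` rows).
#' @export
simulate_scores <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed_for(config, 2L))
  np <- config$n_proteins; nt <- config$n_transcripts
  prot <- protein_ids(np); tx <- transcript_ids(nt)

  m <- matrix(rnorm(np * nt), np, nt, dimnames = list(prot, tx))
  shift_pairs <- function(pairs) {
    if (nrow(pairs) == 0) return()
    idx <- cbind(match(pairs$protein, prot), match(pairs$transcript, tx))
    m[idx] <<- m[idx] + config$score_shift
  }
  shift_pairs(truth$ic_pairs)
  shift_pairs(truth$ia_pairs)
  if (length(truth$bound_targets) > 0) {
    idx <- cbind(match(truth$kd_protein, prot),
                 match(truth$bound_targets, tx))
    m[idx] <- m[idx] + config$score_shift
  }

  tibble(protein = rep(prot, times = nt),
         transcript = rep(tx, each = np),
         score = as.vector(m))
}

#' Simulate a knock-down experiment for the designated protein
#'
#' Unbound transcripts receive zero-centred Gaussian LFC noise; the bound
#' targets are displaced by `lfc_shift` (positive for HuR-like
#' up-regulation of targets upon knock-down, negative for LIN28B-like
#' down-regulation). A `clip_score` column emulates the cross-linking
#' read signal used to rank experimental interactions: bound transcripts
#' receive the same additive shift on a unit-variance background.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth list from [simulate_expression()].
#' @return Tibble with columns `transcript`, `lfc`, `bound` (logical) and
#'   `clip_score`.
#' @export
simulate_knockdown <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed_for(config, 3L))
  tx <- transcript_ids(config$n_transcripts)
  bound <- tx %in% truth$bound_targets
  lfc <- rnorm(length(tx), 0, config$lfc_sd) + config$lfc_shift * bound
  clip <- rnorm(length(tx)) + config$score_shift * bound
  tibble(transcript = tx, lfc = lfc, bound = bound, clip_score = clip)
}

#' Simulate per-residue disorder tracks and region-vs-full-length scores
#'
#' Protein lengths are uniform on \[50, 750\]. A fraction
#' `frac_disordered` of proteins carries one contiguous disordered segment
#' with per-residue scores above 0.4; all other residues stay below 0.4.
#' For each protein with a segment, per-transcript interaction scores are
#' drawn for the full-length chain (centred on a protein-specific mean, so
#' proteins span low to high propensity regimes) and for the region. The
#' probability that the region out-scores the full-length chain starts at
#' `disorder_effect` in the lowest-propensity protein and decays linearly
#' to zero in the highest, with a smaller effect in proteins that carry a
#' canonical RNA-binding domain — the geometry in which disorder promotes
#' low-affinity RNA contacts.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth list from [simulate_expression()].
#' @param n_score_transcripts Transcripts sampled per protein for the
#'   region/full score comparison.
#' @param min_region_len Minimum planted segment length (residues).
#' @return A list: `tracks` (tibble `protein`, `position`, `score`),
#'   `lengths` (tibble `id`, `length`), `rbd` (tibble `protein`, `rbd`),
#'   `region_scores` (tibble `protein`, `transcript`, `full_score`,
#'   `region_score`), and `disorder_promoting_proteins` (character).
#' @export
simulate_disorder <- function(config, truth, n_score_transcripts = 100,
                              min_region_len = 50) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed_for(config, 4L))
  np <- config$n_proteins
  prot <- protein_ids(np)
  lens <- sample(50:750, np, replace = TRUE)
  has_region <- runif(np) < config$frac_disordered
  # proteins shorter than the minimum region cannot carry one
  has_region[lens < min_region_len] <- FALSE
  rbd_flag <- runif(np) < 0.5

  tracks <- purrr::map(seq_len(np), function(i) {
    sc <- runif(lens[i], 0.05, 0.35)
    if (has_region[i]) {
      reg_len <- sample(min_region_len:min(lens[i], 2L * min_region_len), 1L)
      start <- sample.int(lens[i] - reg_len + 1L, 1L)
      sc[start:(start + reg_len - 1L)] <- runif(reg_len, 0.45, 0.9)
    }
    tibble(protein = prot[i], position = seq_len(lens[i]), score = sc)
  })
  tracks <- bind_rows(tracks)

  # protein-level mean propensity spans regimes; promoting probability
  # decays from disorder_effect (lowest bin) to 0 (highest), halved when a
  # canonical RNA-binding domain is present
  mu <- rnorm(np, 0, 1.5)
  pos <- rank(mu, ties.method = "first") / np
  p_promote <- config$disorder_effect * (1 - pos) *
    if_else(rbd_flag, 0.5, 1)
  promoting <- runif(np) < p_promote & has_region

  tx <- transcript_ids(config$n_transcripts)
  scored <- which(has_region)
  region_scores <- purrr::map(scored, function(i) {
    txs <- sample(tx, min(n_score_transcripts, length(tx)))
    full <- rnorm(length(txs), mu[i], 1)
    delta <- if (promoting[i]) 0.8 else -0.8
    tibble(protein = prot[i], transcript = txs, full_score = full,
           region_score = full + delta + rnorm(length(txs), 0, 0.3))
  })
  region_scores <- bind_rows(region_scores)

  list(tracks = tracks,
       lengths = tibble(id = prot, length = lens),
       rbd = tibble(protein = prot, rbd = rbd_flag),
       region_scores = region_scores,
       disorder_promoting_proteins = prot[promoting])
}

#' Simulate a rooted ontology with planted IC and IA terms
#'
#' Builds a small two-namespace DAG: a biological-process root with two
#' mid-level terms, one planted "IC" leaf preferentially annotated to
#' transcripts of planted IC pairs, one planted "IA" leaf annotated to IA
#' transcripts, and specific background leaves annotating five random
#' genes each (plus occasional genes outside the analyzed set, so the
#' transcriptome universe is exercised); a small cellular-component
#' sub-DAG exercises per-namespace testing. Annotations are direct;
#' ancestor propagation happens in [go_structure()].
#'
#' @param config A [synthetic_config()].
#' @param truth Truth list from [simulate_expression()].
#' @return A list: `go` (a [go_structure()]), `ic_term`, `ia_term`
#'   (character term ids).
#' @export
simulate_go <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed_for(config, 5L))
  tx <- transcript_ids(config$n_transcripts)

  n_bg <- config$n_go_terms - 8L   # roots, mids, planted, 2 CC leaves
  bg_ids <- sprintf("SYN:%07d", 100 + seq_len(n_bg))
  cc_ids <- c("SYN:0000201", "SYN:0000202")
  terms <- tibble(
    term = c("SYN:0000001", "SYN:0000002", "SYN:0000003",
             "SYN:0000010", "SYN:0000011", bg_ids,
             "SYN:0000200", cc_ids),
    name = c("biological process", "regulation of proliferation",
             "developmental repression", "planted IC process",
             "planted IA process", sprintf("background process %d",
                                           seq_len(n_bg)),
             "cellular component", "synthetic compartment A",
             "synthetic compartment B"),
    namespace = c(rep("BP", 5L + n_bg), rep("CC", 3L))
  )

  half <- ceiling(n_bg / 2)
  edges <- tibble(
    child = c("SYN:0000002", "SYN:0000003", "SYN:0000010", "SYN:0000011",
              bg_ids, cc_ids),
    parent = c("SYN:0000001", "SYN:0000001", "SYN:0000002", "SYN:0000003",
               c(rep("SYN:0000002", half), rep("SYN:0000003", n_bg - half)),
               rep("SYN:0000200", 2L))
  )

  annotate <- function(term, genes) tibble(gene = genes, term = term)
  ic_genes <- unique(truth$ic_pairs$transcript)
  ia_genes <- unique(truth$ia_pairs$transcript)
  ann <- list(
    annotate("SYN:0000010",
             unique(c(sample(ic_genes, round(0.7 * length(ic_genes))),
                      sample(tx, 5)))),
    annotate("SYN:0000011",
             unique(c(sample(ia_genes, round(0.7 * length(ia_genes))),
                      sample(tx, 5))))
  )
  for (b in bg_ids) ann <- c(ann, list(annotate(b, sample(tx, 5))))
  for (b in cc_ids) ann <- c(ann, list(annotate(b, sample(tx, 5))))
  annotations <- distinct(bind_rows(ann))

  list(go = go_structure(terms, edges, annotations),
       ic_term = "SYN:0000010", ia_term = "SYN:0000011")
}

#' Simulate sequence lengths and a pairwise identity table
#'
#' Transcript lengths are uniform on \[30, 1500\] so roughly a fifth fall
#' outside the 50-1200 nt analysis window. Planted transcripts draw from
#' the same length distribution as the background — annotation carries no
#' length-conditional structure, so the length-bias controls stay null.
#' A small fraction of transcripts is additionally zeroed out in
#' expression upstream (see
#' [simulate_dataset()]). The identity table lists above-threshold
#' redundant pairs only: a random 10% of transcripts are paired with a
#' partner at identity 0.85-0.99, emulating near-duplicate isoforms.
#'
#' @param config A [synthetic_config()].
#' @param truth Truth list from [simulate_expression()].
#' @return A list: `transcript_lengths` (tibble `id`, `length`),
#'   `identities` (tibble `seq_a`, `seq_b`, `identity`).
#' @export
simulate_lengths_identities <- function(config, truth) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed_for(config, 6L))
  tx <- transcript_ids(config$n_transcripts)
  lens <- sample(30:1500, length(tx), replace = TRUE)

  n_red <- floor(0.05 * length(tx))
  a <- sample(tx, n_red)
  pool <- setdiff(tx, a)
  b <- sample(pool, n_red)
  identities <- tibble(seq_a = a, seq_b = b,
                       identity = runif(n_red, 0.85, 0.99))

  list(transcript_lengths = tibble(id = tx, length = lens),
       identities = identities)
}

#' Generate the full synthetic fixture set
#'
#' Runs every generator under the configured seed and, optionally, writes
#' the fixture directory in the pipeline's plain-text exchange formats:
#' TSV matrices and tables, a minimal OBO file for the ontology, a
#' two-column annotation TSV, and a JSON sidecar with the planted truth.
#' About 1% of background transcripts are zeroed out across all tissues so
#' the expressed-in-at-least-one-tissue filter has work to do.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory to write fixtures into (created if
#'   needed). When `NULL` nothing is written.
#' @return A list with all generated objects: `proteins`, `transcripts`
#'   (expression), `truth`, `scores`, `knockdown`, `disorder`, `go_set`,
#'   `transcript_lengths`, `protein_lengths`, `identities`.
#' @export
#' @examples
#' fix <- simulate_dataset(synthetic_config(n_proteins = 10,
#'                                          n_transcripts = 60, seed = 3))
#' names(fix)
simulate_dataset <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  expr <- simulate_expression(config)
  truth <- expr$truth

  set.seed(seed_for(config, 7L))
  tx <- expr$transcripts$id
  planted <- unique(c(truth$ic_pairs$transcript, truth$ia_pairs$transcript,
                      truth$bound_targets))
  eligible <- setdiff(tx, planted)
  zeroed <- sample(eligible, floor(0.01 * length(tx)))
  tcols <- tissue_cols(expr$transcripts)
  expr$transcripts[expr$transcripts$id %in% zeroed, tcols] <- 0

  scores <- simulate_scores(config, truth)
  kd <- simulate_knockdown(config, truth)
  dis <- simulate_disorder(config, truth)
  go_set <- simulate_go(config, truth)
  li <- simulate_lengths_identities(config, truth)
  truth$disorder_promoting_proteins <- dis$disorder_promoting_proteins
  truth$zeroed_transcripts <- zeroed

  out <- list(proteins = expr$proteins, transcripts = expr$transcripts,
              truth = truth, scores = scores, knockdown = kd,
              disorder = dis, go_set = go_set,
              transcript_lengths = li$transcript_lengths,
              protein_lengths = dis$lengths,
              identities = li$identities)

  if (!is.null(dir)) write_fixture_dir(out, dir)
  out
}

write_fixture_dir <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_tsv(x, file.path(dir, f))
  w(fix$proteins, "protein_expression.tsv")
  w(fix$transcripts, "transcript_expression.tsv")
  w(fix$scores, "interaction_scores.tsv")
  w(fix$knockdown, "knockdown.tsv")
  w(fix$disorder$tracks, "disorder_tracks.tsv")
  w(fix$disorder$rbd, "rbd_flags.tsv")
  w(fix$disorder$region_scores, "region_scores.tsv")
  w(fix$transcript_lengths, "transcript_lengths.tsv")
  w(fix$protein_lengths, "protein_lengths.tsv")
  w(fix$identities, "identities.tsv")
  write_obo(fix$go_set$go, file.path(dir, "ontology.obo"))
  w(fix$go_set$go$direct, "annotations.tsv")
  truth <- fix$truth
  jsonlite::write_json(
    list(ic_pairs = truth$ic_pairs, ia_pairs = truth$ia_pairs,
         bound_targets = truth$bound_targets, kd_protein = truth$kd_protein,
         disorder_promoting_proteins = truth$disorder_promoting_proteins,
         zeroed_transcripts = truth$zeroed_transcripts,
         ic_term = fix$go_set$ic_term, ia_term = fix$go_set$ia_term),
    file.path(dir, "truth.json"))
  invisible(dir)
}
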