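# Shared fixture builders. The default cohort is generated once per test
# run and reused; smaller ad-hoc fixtures are built inline.

default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(synthetic_config(seed = 1))
    cache
  }
})

# Analysis products derived from the default cohort (filters, correlations,
# classification, universes), computed once.
default_analysis <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fix <- default_fixture()
    keep_tx <- intersect(
      filter_length(fix$transcript_lengths, rna_window())$id,
      filter_expressed(fix$transcripts)$id)
    tx_f <- fix$transcripts[fix$transcripts$id %in% keep_tx, ]
    scores_f <- fix$scores[fix$scores$transcript %in% keep_tx, ]
    corr <- correlate_pairs(fix$proteins, tx_f)
    cls <- classify_pairs(scores_f, corr)
    in_tail <- unique(cls$transcript[!is.na(cls$tail_set)])
    uni <- gene_universes(
      transcriptome = fix$transcript_lengths$id,
      analyzed = keep_tx,
      auc_subset = intersect(in_tail, keep_tx),
      length_restricted = filter_length(fix$transcript_lengths,
                                        rna_window())$id)
    cache <<- list(fix = fix, keep_tx = keep_tx, scores_f = scores_f,
                   corr = corr, cls = cls, uni = uni)
    cache
  }
})

# A small random pair table with scores and correlations.
random_pairs <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    protein = sprintf("p%03d", sample(20, n, replace = TRUE)),
    transcript = sprintf("t%04d", seq_len(n)),
    score = rnorm(n),
    r = runif(n, -1, 1))
}

# An 8-term toy DAG over two namespaces for conditional-test checks.
toy_dag <- function() {
  terms <- tibble::tibble(
    term = c("root", "mid1", "mid2", "leafA", "leafB", "leafC",
             "cc_root", "cc_leaf"),
    namespace = c(rep("BP", 6), "CC", "CC"))
  edges <- tibble::tibble(
    child = c("mid1", "mid2", "leafA", "leafB", "leafC", "cc_leaf"),
    parent = c("root", "root", "mid1", "mid1", "mid2", "cc_root"))
  list(terms = terms, edges = edges)
}
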