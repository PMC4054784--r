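#' Build an ontology structure with propagated annotations
#'
#' Assembles a directed acyclic graph of terms (is_a edges only), checks
#' acyclicity, and propagates gene annotations to all ancestor terms
#' (true-path rule: a gene annotated to a term is annotated to every
#' ancestor, so a namespace root annotates every annotated gene).
#'
#' @param terms Tibble with columns `term`, `namespace` (e.g. BP/CC/MF)
#'   and optionally `name`.
#' @param edges Tibble with columns `child`, `parent` (is_a edges).
#' @param annotations Tibble with columns `gene`, `term` (direct
#'   annotations).
#' @return A list of class `go_structure`: `terms`, `edges`, `direct`,
#'   `annotation` (propagated, tibble `gene`, `term`), `ann_sets` (named
#'   list term -> genes, propagated), `topo` (term ids, children before
#'   parents), `descendants` (named list, self excluded).
#' @export
go_structure <- function(terms, edges, annotations) {
  assert_columns(terms, c("term", "namespace"), "terms")
  assert_columns(edges, c("child", "parent"), "edges")
  assert_columns(annotations, c("gene", "term"), "annotations")
  if (anyDuplicated(terms$term)) abort_bad_arg("terms$term", "be unique")
  unknown <- setdiff(c(edges$child, edges$parent, annotations$term),
                     terms$term)
  if (length(unknown) > 0) {
    abort(sprintf("edge or annotation refers to unknown term(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$term)
  if (!igraph::is_dag(g)) {
    abort("ontology edges contain a cycle", class = "rbpcoex_error_cyclic")
  }
  topo <- names(igraph::topo_sort(g, mode = "out"))

  vs <- igraph::V(g)
  anc <- lapply(seq_along(vs), function(i) {
    names(igraph::subcomponent(g, vs[i], mode = "out"))  # ancestors + self
  })
  names(anc) <- names(vs)
  desc <- lapply(seq_along(vs), function(i) {
    setdiff(names(igraph::subcomponent(g, vs[i], mode = "in")),
            names(vs)[i])
  })
  names(desc) <- names(vs)

  annotations <- distinct(as_tibble(annotations[, c("gene", "term")]))
  prop <- tidyr::unnest(
    mutate(annotations, term = unname(anc[term])), "term")
  prop <- distinct(prop)
  ann_sets <- split(prop$gene, prop$term)

  structure(list(terms = as_tibble(terms), edges = as_tibble(edges),
                 direct = annotations, annotation = prop,
                 ann_sets = ann_sets, topo = topo, descendants = desc),
            class = "go_structure")
}

#' @export
print.go_structure <- function(x, ...) {
  cat(sprintf("ontology: %d terms (%s), %d edges, %d propagated annotations over %d genes\n",
              nrow(x$terms),
              paste(sprintf("%s=%d", names(table(x$terms$namespace)),
                            table(x$terms$namespace)), collapse = ", "),
              nrow(x$edges), nrow(x$annotation),
              dplyr::n_distinct(x$annotation$gene)))
  invisible(x)
}

#' Read / write a minimal OBO ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace` and `is_a`
#' lines (is_a edges only; other relationship types are ignored). The
#' writer emits the same minimal subset.
#'
#' @param path File path.
#' @param annotations Tibble `gene`, `term` to attach to the parsed DAG.
#' @return `read_obo()`: a [go_structure()]. `write_obo()`: `path`,
#'   invisibly.
#' @export
read_obo <- function(path, annotations) {
  lines <- readr::read_lines(path)
  in_term <- FALSE
  cur <- NULL
  terms <- list(); edges <- list()
  flush <- function() {
    if (is.null(cur)) return()
    terms[[length(terms) + 1L]] <<- tibble(
      term = cur$id, name = cur$name %||% cur$id,
      namespace = cur$namespace %||% "BP")
    for (p in cur$is_a) {
      edges[[length(edges) + 1L]] <<- tibble(child = cur$id, parent = p)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- list(is_a = character()); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    if (grepl("^namespace:", ln)) cur$namespace <- trimws(sub("^namespace:", "", ln))
    if (grepl("^is_a:", ln)) {
      tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      cur$is_a <- c(cur$is_a, tgt)
    }
  }
  flush()
  go_structure(bind_rows(terms),
               if (length(edges)) bind_rows(edges) else
                 tibble(child = character(), parent = character()),
               annotations)
}

#' @rdname read_obo
#' @param go A [go_structure()].
#' @export
write_obo <- function(go, path) {
  stopifnot(inherits(go, "go_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  edges <- split(go$edges$parent, go$edges$child)
  nm <- setNames(go$terms$name %||% go$terms$term, go$terms$term)
  for (i in seq_len(nrow(go$terms))) {
    t <- go$terms$term[i]
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", go$terms$name[i] %||% t),
                 paste0("namespace: ", go$terms$namespace[i]),
                 if (!is.null(edges[[t]]))
                   paste0("is_a: ", edges[[t]], " ! ", nm[edges[[t]]])),
               con)
  }
  invisible(path)
}

#' Upper-tail hypergeometric over-representation p-value
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, n, K)`: drawing `K` genes from a
#' universe of `N` containing `n` annotated ones, the probability of
#' seeing at least the observed `k` annotated genes.
#'
#' @param k Annotated genes observed in the sample.
#' @param K Sample size.
#' @param n Annotated genes in the universe.
#' @param N Universe size.
#' @return The upper-tail p-value.
#' @export
#' @examples
#' hypergeom_test(3, 5, 4, 20)
hypergeom_test <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (!is.numeric(v) || any(v != floor(v)) || any(v < 0)) {
      abort_bad_arg("k, K, n, N", "be non-negative integers")
    }
  }
  if (any(n > N) || any(K > N) || any(k > pmin(K, n))) {
    abort("infeasible hypergeometric counts (need k <= min(K, n), n <= N, K <= N)",
          class = "rbpcoex_error_bad_arg")
  }
  phyper(k - 1, n, N - n, K, lower.tail = FALSE)
}

#' Conditional term-by-term over-representation tests
#'
#' Hypergeometric over-representation of every term in `genes` against
#' `universe`, conditioned on the DAG: terms are processed children
#' before parents (per namespace), and when a term is tested, the genes
#' annotated to any of its already-significant descendants
#' (p < `alpha_child`) are removed from both the sample and the universe
#' counts, so a parent is only called enriched on evidence its children
#' do not already explain.
#'
#' @param go A [go_structure()].
#' @param genes Character vector, the gene set of interest (must be a
#'   subset of `universe`).
#' @param universe Character vector, the background gene set.
#' @param alpha_child Significance level below which a descendant's genes
#'   are removed from its ancestors' counts.
#' @return Tibble with one row per term: `term`, `namespace`, `k_raw`
#'   (annotated genes in the sample before decrementing), `k`, `K`, `n`,
#'   `N` (decremented counts actually tested) and `p`.
#' @export
conditional_go_test <- function(go, genes, universe, alpha_child = 0.05) {
  stopifnot(inherits(go, "go_structure"))
  genes <- unique(genes); universe <- unique(universe)
  if (length(setdiff(genes, universe)) > 0) {
    abort_bad_arg("genes", "be a subset of `universe`")
  }
  ann <- lapply(go$ann_sets, intersect, y = universe)
  ns <- setNames(go$terms$namespace, go$terms$term)

  p_out <- k_out <- kr_out <- n_out <- K_out <- N_out <-
    setNames(numeric(length(go$topo)), go$topo)
  sig <- setNames(logical(length(go$topo)), go$topo)

  for (t in go$topo) {
    a <- ann[[t]] %||% character()
    kr_out[t] <- length(intersect(genes, a))
    sig_desc <- go$descendants[[t]]
    sig_desc <- sig_desc[ns[sig_desc] == ns[t]]
    sig_desc <- sig_desc[sig[sig_desc]]
    removed <- if (length(sig_desc) > 0) {
      unique(unlist(ann[sig_desc], use.names = FALSE))
    } else character()
    a_dec <- setdiff(a, removed)
    sample_dec <- setdiff(genes, removed)
    k <- length(intersect(sample_dec, a_dec))
    K <- length(sample_dec)
    n <- length(a_dec)
    N <- length(universe) - length(removed)
    p <- if (N == 0 || K == 0 || n == 0) 1 else hypergeom_test(k, K, n, N)
    p_out[t] <- p; k_out[t] <- k; K_out[t] <- K
    n_out[t] <- n; N_out[t] <- N
    sig[t] <- p < alpha_child
  }
  tibble(term = go$topo, namespace = unname(ns[go$topo]),
         k_raw = unname(kr_out), k = unname(k_out), K = unname(K_out),
         n = unname(n_out), N = unname(N_out), p = unname(p_out))
}

#' Transcript-length bias control
#'
#' Unconditional hypergeometric test of every term in the set of genes
#' passing only the length filter against the full transcriptome. A term
#' significant here (p <= `p_cut`) is enriched merely because of the
#' length window, and is excluded a priori from subset enrichment claims.
#'
#' @param go A [go_structure()].
#' @param length_restricted Genes passing the length window.
#' @param transcriptome All genes.
#' @param p_cut Exclusion threshold (default 0.1).
#' @return Tibble `term`, `namespace`, `p`, `excluded`.
#' @export
length_bias_control <- function(go, length_restricted, transcriptome,
                                p_cut = 0.1) {
  stopifnot(inherits(go, "go_structure"))
  length_restricted <- unique(length_restricted)
  transcriptome <- unique(transcriptome)
  if (length(setdiff(length_restricted, transcriptome)) > 0) {
    abort_bad_arg("length_restricted", "be a subset of `transcriptome`")
  }
  N <- length(transcriptome); K <- length(length_restricted)
  res <- purrr::map(go$topo, function(t) {
    a <- intersect(go$ann_sets[[t]] %||% character(), transcriptome)
    k <- length(intersect(a, length_restricted))
    n <- length(a)
    p <- if (n == 0 || K == 0) 1 else hypergeom_test(k, K, n, N)
    tibble(term = t, p = p)
  }) %>% bind_rows()
  res$namespace <- setNames(go$terms$namespace, go$terms$term)[res$term]
  res$excluded <- res$p <= p_cut
  res[, c("term", "namespace", "p", "excluded")]
}

#' Thresholds for the gene-ontology analysis
#'
#' @param min_genes A term must be reported for strictly more than this
#'   many genes in the focal subset (criterion 1; default 2, i.e. at
#'   least 3 genes).
#' @param p_sig Significance threshold (criteria 2, 3, 5).
#' @param p_nonsig Non-significance threshold for the other subsets and
#'   the bias controls (criteria 2, 4).
#' @param alpha_child Child-significance level of the conditional test.
#' @param redundancy_cutoff Identity threshold of the criterion-5
#'   redundancy reduction.
#' @return A list of class `go_params`.
#' @export
go_params <- function(min_genes = 2, p_sig = 0.05, p_nonsig = 0.1,
                      alpha_child = 0.05, redundancy_cutoff = 0.8) {
  assert_count(min_genes, "min_genes", positive = FALSE)
  assert_number(p_sig, "p_sig", 0, 1)
  assert_number(p_nonsig, "p_nonsig", 0, 1)
  assert_number(alpha_child, "alpha_child", 0, 1)
  assert_number(redundancy_cutoff, "redundancy_cutoff", 0, 1)
  structure(list(min_genes = min_genes, p_sig = p_sig,
                 p_nonsig = p_nonsig, alpha_child = alpha_child,
                 redundancy_cutoff = redundancy_cutoff),
            class = "go_params")
}

#' Gene universes for the over-representation analysis
#'
#' The nested backgrounds against which subset enrichment must be
#' conserved: the entire transcriptome (no filters), the analyzed set
#' (length and expression filters applied), all genes under the same tail
#' percentile (both tails pooled), and the length-restricted set (length
#' filter only; used by the bias control).
#'
#' @param transcriptome,analyzed,auc_subset,length_restricted Character
#'   vectors of gene ids; `analyzed` and `length_restricted` must be
#'   subsets of `transcriptome`, `auc_subset` of `analyzed`.
#' @return A list of class `gene_universes`.
#' @export
gene_universes <- function(transcriptome, analyzed, auc_subset,
                           length_restricted) {
  u <- lapply(list(transcriptome = transcriptome, analyzed = analyzed,
                   auc_subset = auc_subset,
                   length_restricted = length_restricted), unique)
  if (length(setdiff(u$analyzed, u$transcriptome)) > 0) {
    abort_bad_arg("analyzed", "be a subset of `transcriptome`")
  }
  if (length(setdiff(u$auc_subset, u$analyzed)) > 0) {
    abort_bad_arg("auc_subset", "be a subset of `analyzed`")
  }
  if (length(setdiff(u$length_restricted, u$transcriptome)) > 0) {
    abort_bad_arg("length_restricted", "be a subset of `transcriptome`")
  }
  structure(u, class = "gene_universes")
}

#' Evaluate the five acceptance criteria for subset over-representation
#'
#' A term is accepted for a focal subset only when all five hold:
#' c1 — annotated to strictly more than `min_genes` genes of the subset;
#' c2 — significant (p < `p_sig`) in the focal subset and non-significant
#' (p > `p_nonsig`) in the other three subsets;
#' c3 — significant against all three universes (transcriptome, analyzed,
#' same-AUC);
#' c4 — non-significant for the two bias controls (analyzed vs
#' transcriptome, length-restricted vs transcriptome);
#' c5 — still significant after redundancy reduction of the gene sets.
#' Missing components make the term fail with a reason rather than error.
#'
#' @param results Tibble with one row per (term, subset) holding the
#'   component p-values: `k_subset`, `p_analyzed`, `p_transcriptome`,
#'   `p_auc_subset`, `p_other_1..3`, `p_bias_analyzed`, `p_bias_length`,
#'   `p_redundancy`.
#' @param params A [go_params()].
#' @return `results` with added logical columns `c1`..`c5`, `pass` and a
#'   `reason` column for failures.
#' @export
evaluate_go_criteria <- function(results, params = go_params()) {
  assert_columns(results,
                 c("k_subset", "p_analyzed", "p_transcriptome",
                   "p_auc_subset", "p_other_1", "p_other_2", "p_other_3",
                   "p_bias_analyzed", "p_bias_length", "p_redundancy"),
                 "results")
  gt <- function(p, th) !is.na(p) & p > th
  lt <- function(p, th) !is.na(p) & p < th
  out <- mutate(
    results,
    c1 = !is.na(k_subset) & k_subset > params$min_genes,
    c2 = lt(p_analyzed, params$p_sig) &
      gt(p_other_1, params$p_nonsig) & gt(p_other_2, params$p_nonsig) &
      gt(p_other_3, params$p_nonsig),
    c3 = lt(p_transcriptome, params$p_sig) &
      lt(p_analyzed, params$p_sig) & lt(p_auc_subset, params$p_sig),
    c4 = gt(results$p_bias_analyzed, params$p_nonsig) &
      gt(results$p_bias_length, params$p_nonsig),
    c5 = lt(p_redundancy, params$p_sig)
  )
  out$pass <- out$c1 & out$c2 & out$c3 & out$c4 & out$c5
  out$reason <- dplyr::case_when(
    out$pass ~ "",
    !out$c1 ~ "too few subset genes",
    !out$c2 ~ "not specific to the subset",
    !out$c3 ~ "not conserved across universes",
    !out$c4 ~ "bias control failed",
    TRUE ~ "lost after redundancy reduction")
  out
}

#' Run the full conditional GO over-representation analysis
#'
#' For each classified subset (IC, IA, NIC, NIA) at the classification's
#' tail percentile, runs the conditional test against the three nested
#' universes, the two bias controls, the criterion-5 redundancy
#' recomputation, and evaluates the five acceptance criteria. A
#' Benjamini-Hochberg column over the focal (analyzed-universe) p-values
#' is emitted for information; the acceptance rule itself uses raw
#' p-values gated by the criteria, as in the original procedure.
#'
#' @param classification A [classify_pairs()] result.
#' @param go A [go_structure()].
#' @param universes A [gene_universes()].
#' @param params A [go_params()].
#' @param identities,lengths Optional identity records and transcript
#'   lengths for the criterion-5 redundancy reduction; when absent the
#'   reduction keeps every gene (p_redundancy equals the focal p).
#' @return Tibble of class `go_results`, one row per (term, subset), with
#'   component p-values, `c1`..`c5`, `pass`, `reason` and `p_bh`.
#' @export
run_go_analysis <- function(classification, go, universes,
                            params = go_params(), identities = NULL,
                            lengths = NULL) {
  stopifnot(inherits(go, "go_structure"),
            inherits(universes, "gene_universes"))
  cls <- as_tibble(classification)
  subsets <- lapply(c(IC = "IC", IA = "IA", NIC = "NIC", NIA = "NIA"),
                    function(l) {
    intersect(unique(cls$transcript[cls$label == l]), universes$analyzed)
  })

  reps <- NULL
  if (!is.null(identities)) {
    if (is.null(lengths)) {
      abort_bad_arg("lengths", "be supplied alongside `identities`")
    }
    lens <- lengths[lengths$id %in% universes$analyzed, , drop = FALSE]
    reps <- reduce_redundancy(lens, identities,
                              cutoff = params$redundancy_cutoff)
  }

  cond <- function(genes, universe) {
    conditional_go_test(go, intersect(genes, universe), universe,
                        alpha_child = params$alpha_child)
  }

  per_subset <- lapply(subsets, function(genes) {
    list(transcriptome = cond(genes, universes$transcriptome),
         analyzed = cond(genes, universes$analyzed),
         auc_subset = cond(genes, universes$auc_subset))
  })

  bias_analyzed <- length_bias_control(go, universes$analyzed,
                                       universes$transcriptome,
                                       p_cut = params$p_nonsig)
  bias_length <- length_bias_control(go, universes$length_restricted,
                                     universes$transcriptome,
                                     p_cut = params$p_nonsig)

  subset_names <- names(subsets)
  rows <- purrr::map(subset_names, function(s) {
    others <- setdiff(subset_names, s)
    focal <- per_subset[[s]]
    tab <- tibble(
      term = focal$analyzed$term,
      namespace = focal$analyzed$namespace,
      subset = s,
      k_subset = focal$analyzed$k_raw,
      p_analyzed = focal$analyzed$p,
      p_transcriptome = focal$transcriptome$p[
        match(focal$analyzed$term, focal$transcriptome$term)],
      p_auc_subset = focal$auc_subset$p[
        match(focal$analyzed$term, focal$auc_subset$term)],
      p_other_1 = per_subset[[others[1]]]$analyzed$p[
        match(focal$analyzed$term, per_subset[[others[1]]]$analyzed$term)],
      p_other_2 = per_subset[[others[2]]]$analyzed$p[
        match(focal$analyzed$term, per_subset[[others[2]]]$analyzed$term)],
      p_other_3 = per_subset[[others[3]]]$analyzed$p[
        match(focal$analyzed$term, per_subset[[others[3]]]$analyzed$term)],
      p_bias_analyzed = bias_analyzed$p[
        match(focal$analyzed$term, bias_analyzed$term)],
      p_bias_length = bias_length$p[
        match(focal$analyzed$term, bias_length$term)]
    )
    if (is.null(reps)) {
      tab$p_redundancy <- tab$p_analyzed
    } else {
      red <- cond(intersect(subsets[[s]], reps),
                  intersect(universes$analyzed, reps))
      tab$p_redundancy <- red$p[match(tab$term, red$term)]
    }
    tab$p_bh <- p.adjust(tab$p_analyzed, method = "BH")
    tab
  })
  out <- evaluate_go_criteria(bind_rows(rows), params)
  attr(out, "params") <- params
  attr(out, "auc") <- attr(classification, "auc")
  class(out) <- c("go_results", class(out))
  out
}
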