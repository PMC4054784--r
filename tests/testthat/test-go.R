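test_that("hypergeometric edge cases and enumeration agreement", {
  expect_identical(hypergeom_test(1, 1, 1, 1), 1)
  expect_identical(hypergeom_test(0, 5, 4, 20), 1)
  expect_error(hypergeom_test(5, 4, 4, 20), "infeasible")
  expect_error(hypergeom_test(2, 5, 6, 5), "infeasible")

  # full enumeration over all C(20, 5) draws
  expect_equal(hypergeom_test(3, 5, 4, 20), oracle_hyper_enum(3, 5, 4, 20),
               tolerance = 1e-12)
  # combinatorial sum oracle on a batch of feasible instances
  for (s in 1:50) {
    set.seed(300 + s)
    N <- sample(2:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_test(k, K, n, N), oracle_hyper_sum(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("go_structure propagates annotations and rejects cycles", {
  dag <- toy_dag()
  ann <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        term = c("leafA", "leafC", "cc_leaf"))
  go <- go_structure(dag$terms, dag$edges, ann)
  expect_setequal(go$ann_sets[["root"]], c("g1", "g2"))
  expect_setequal(go$ann_sets[["mid1"]], "g1")
  expect_setequal(go$ann_sets[["cc_root"]], "g3")
  expect_true(all(go$direct$gene %in% go$annotation$gene))

  cyc <- tibble::tibble(child = c("a", "b"), parent = c("b", "a"))
  expect_error(
    go_structure(tibble::tibble(term = c("a", "b"), namespace = "BP"),
                 cyc, ann[0, ]),
    class = "rbpcoex_error_cyclic")
})

test_that("a single-term ontology reduces to the unconditional test", {
  terms <- tibble::tibble(term = "only", namespace = "BP")
  edges <- tibble::tibble(child = character(), parent = character())
  ann <- tibble::tibble(gene = sprintf("g%02d", 1:8), term = "only")
  go <- go_structure(terms, edges, ann)
  universe <- sprintf("g%02d", 1:30)
  genes <- sprintf("g%02d", c(1:5, 20:24))
  res <- conditional_go_test(go, genes, universe)
  expect_equal(res$p, hypergeom_test(5, 10, 8, 30), tolerance = 1e-12)
})

test_that("a significant child empties its parent's evidence", {
  terms <- tibble::tibble(term = c("parent", "child"), namespace = "BP")
  edges <- tibble::tibble(child = "child", parent = "parent")
  # parent's only annotated genes come through the child
  ann <- tibble::tibble(gene = sprintf("g%02d", 1:6), term = "child")
  go <- go_structure(terms, edges, ann)
  universe <- sprintf("g%02d", 1:40)
  genes <- sprintf("g%02d", 1:6)       # all child genes in the sample
  res <- conditional_go_test(go, genes, universe)
  expect_lt(res$p[res$term == "child"], 0.05)
  expect_identical(res$p[res$term == "parent"], 1)
  expect_identical(res$k[res$term == "parent"], 0)
  # conditioning can only weaken the parent
  uncond <- hypergeom_test(6, 6, 6, 40)
  expect_gte(res$p[res$term == "parent"], uncond)
})

test_that("conditional tests match the naive reference on a toy DAG", {
  dag <- toy_dag()
  for (s in 1:25) {
    set.seed(400 + s)
    universe <- sprintf("g%02d", 1:30)
    ann <- tibble::tibble(
      gene = sample(universe, 25, replace = TRUE),
      term = sample(c("leafA", "leafB", "leafC", "mid1", "mid2", "cc_leaf"),
                    25, replace = TRUE))
    ann <- dplyr::distinct(ann)
    genes <- sample(universe, 12)
    go <- go_structure(dag$terms, dag$edges, ann)
    got <- conditional_go_test(go, genes, universe)
    want <- oracle_conditional(dag$terms, dag$edges, ann, genes, universe)
    expect_equal(setNames(got$p, got$term)[names(want)], want,
                 tolerance = 1e-12)
  }
})

test_that("length-bias control flags length-driven terms only", {
  terms <- tibble::tibble(term = c("short_term", "long_term", "mixed"),
                          namespace = "BP")
  edges <- tibble::tibble(child = character(), parent = character())
  transcriptome <- sprintf("g%03d", 1:100)
  short_genes <- sprintf("g%03d", 1:40)        # pass the length filter
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = short_genes[1:10], term = "short_term"),
    tibble::tibble(gene = sprintf("g%03d", 91:100), term = "long_term"),
    tibble::tibble(gene = sprintf("g%03d", c(1:3, 60:62)), term = "mixed"))
  go <- go_structure(terms, edges, ann)
  res <- length_bias_control(go, short_genes, transcriptome)
  expect_true(res$excluded[res$term == "short_term"])
  # term annotating only filtered-out genes: k = 0, p = 1, not excluded
  expect_identical(res$p[res$term == "long_term"], 1)
  expect_false(res$excluded[res$term == "long_term"])
  # a filter that removes nothing leaves every term at p = 1
  res2 <- length_bias_control(go, transcriptome, transcriptome)
  expect_true(all(res2$p == 1))
})

test_that("the five criteria gate exactly as stated", {
  base <- tibble::tibble(
    k_subset = 5, p_analyzed = 0.001, p_transcriptome = 0.001,
    p_auc_subset = 0.001, p_other_1 = 0.5, p_other_2 = 0.5,
    p_other_3 = 0.5, p_bias_analyzed = 0.5, p_bias_length = 0.5,
    p_redundancy = 0.001)
  expect_true(evaluate_go_criteria(base)$pass)

  two_genes <- dplyr::mutate(base, k_subset = 2)
  expect_false(evaluate_go_criteria(two_genes)$c1)   # strictly more than 2
  expect_true(evaluate_go_criteria(dplyr::mutate(base, k_subset = 3))$c1)

  # significant in another subset kills specificity for both
  both_sig <- dplyr::mutate(base, p_other_1 = 0.01)
  expect_false(evaluate_go_criteria(both_sig)$c2)

  for (col in c("p_transcriptome", "p_auc_subset")) {
    broken <- base
    broken[[col]] <- 0.2
    expect_false(evaluate_go_criteria(broken)$c3)
  }
  expect_false(evaluate_go_criteria(
    dplyr::mutate(base, p_bias_length = 0.05))$c4)
  expect_false(evaluate_go_criteria(
    dplyr::mutate(base, p_redundancy = 0.2))$c5)

  # pure function: same input, same output, row-order free
  two <- dplyr::bind_rows(base, two_genes)
  expect_identical(evaluate_go_criteria(two)$pass, c(TRUE, FALSE))
  expect_identical(evaluate_go_criteria(two[2:1, ])$pass, c(FALSE, TRUE))
})

test_that("empty subsets yield no passing rows without error", {
  fix <- default_analysis()
  cls <- fix$cls
  # blank out every IC label
  cls$label[cls$label == "IC"] <- "unclassified"
  res <- run_go_analysis(cls, fix$fix$go_set$go, fix$uni)
  ic_rows <- res[res$subset == "IC", ]
  expect_identical(sum(ic_rows$pass), 0L)
  expect_true(all(ic_rows$k_subset == 0))
})

test_that("OBO files round-trip through the reader and writer", {
  fix <- default_fixture()
  go <- fix$go_set$go
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(go, path)
  back <- read_obo(path, go$direct)
  expect_setequal(back$terms$term, go$terms$term)
  expect_identical(
    dplyr::arrange(back$edges, child, parent),
    dplyr::arrange(go$edges, child, parent))
  expect_identical(
    dplyr::arrange(back$annotation, gene, term),
    dplyr::arrange(go$annotation, gene, term))
  expect_identical(
    setNames(back$terms$namespace, back$terms$term)[go$terms$term],
    setNames(go$terms$namespace, go$terms$term))
})

test_that("universe nesting is validated", {
  expect_error(
    gene_universes(transcriptome = c("a", "b"), analyzed = c("a", "c"),
                   auc_subset = "a", length_restricted = "a"),
    "analyzed")
  expect_error(
    gene_universes(transcriptome = c("a", "b", "c"),
                   analyzed = c("a", "b"),
                   auc_subset = c("a", "c"), length_restricted = "a"),
    "auc_subset")
})
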