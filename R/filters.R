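#' Sequence-length analysis windows
#'
#' Length windows used when building the analyzed datasets: predictions of
#' pairwise interaction propensity are only available for proteins of 50
#' to 750 residues and transcripts of 50 to 1,200 nucleotides, so both
#' datasets are restricted to those windows (boundaries inclusive).
#'
#' @param min_len,max_len Window bounds (inclusive).
#' @param alphabet Either `"protein"` or `"rna"`; only recorded for
#'   provenance.
#' @return A list of class `length_window`.
#' @export
#' @examples
#' protein_window()
#' rna_window()
length_window <- function(min_len, max_len, alphabet = c("protein", "rna")) {
  alphabet <- arg_match(alphabet)
  assert_count(min_len, "min_len")
  assert_count(max_len, "max_len")
  if (min_len > max_len) abort_bad_arg("min_len", "be at most max_len")
  structure(list(min_len = min_len, max_len = max_len, alphabet = alphabet),
            class = "length_window")
}

#' @rdname length_window
#' @export
protein_window <- function() length_window(50, 750, "protein")

#' @rdname length_window
#' @export
rna_window <- function() length_window(50, 1200, "rna")

#' Keep entities whose sequence length falls inside a window
#'
#' @param lengths Tibble with columns `id` and `length`.
#' @param window A [length_window()].
#' @return The rows of `lengths` whose length satisfies
#'   `min_len <= length <= max_len`. Records with non-positive length are
#'   dropped with a warning before filtering.
#' @export
#' @examples
#' filter_length(tibble::tibble(id = c("a", "b"), length = c(49, 50)),
#'               rna_window())
filter_length <- function(lengths, window) {
  assert_columns(lengths, c("id", "length"), "lengths")
  stopifnot(inherits(window, "length_window"))
  bad <- !is.finite(lengths$length) | lengths$length <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d record(s) with non-positive length: %s",
                 sum(bad), paste(head(lengths$id[bad], 5), collapse = ", ")))
    lengths <- lengths[!bad, , drop = FALSE]
  }
  as_tibble(lengths[lengths$length >= window$min_len &
                      lengths$length <= window$max_len, , drop = FALSE])
}

#' Keep entities expressed in at least one tissue
#'
#' Operates on the raw (pre-normalization) abundance scale: an entity is
#' retained when any tissue value is strictly positive.
#'
#' @param expr Wide expression tibble (`id` + tissue columns).
#' @return The retained rows of `expr`.
#' @export
filter_expressed <- function(expr) {
  assert_columns(expr, "id", "expr")
  tcols <- tissue_cols(expr)
  if (length(tcols) == 0) abort_bad_arg("expr", "have tissue columns")
  m <- as.matrix(expr[, tcols])
  keep <- rowSums(m > 0, na.rm = TRUE) > 0
  as_tibble(expr[keep, , drop = FALSE])
}

#' Greedy longest-first redundancy reduction over supplied identities
#'
#' Reproduces the cluster-representative logic of greedy sequence
#' clustering: iterate entities longest first (ties broken
#' lexicographically by id) and keep an entity iff its identity to every
#' already-kept entity is below `cutoff`. Pair identities are read from a
#' symmetric lookup of the supplied records; absent pairs count as 0
#' (non-redundant), matching tools that only report above-threshold
#' matches. The identity computation itself (alignments) is an input, not
#' recomputed here.
#'
#' @param lengths Tibble with columns `id`, `length` (one row per entity).
#' @param identities Tibble with columns `seq_a`, `seq_b`, `identity`
#'   (fractions in \[0, 1\]).
#' @param cutoff Identity threshold in (0, 1\]; entities at or above it to
#'   a kept representative are discarded.
#' @return Character vector of representative ids (in the greedy order).
#' @export
#' @examples
#' reduce_redundancy(
#'   tibble::tibble(id = c("a", "b"), length = c(100, 80)),
#'   tibble::tibble(seq_a = "a", seq_b = "b", identity = 0.9),
#'   cutoff = 0.8)
reduce_redundancy <- function(lengths, identities, cutoff = 0.8) {
  assert_columns(lengths, c("id", "length"), "lengths")
  assert_columns(identities, c("seq_a", "seq_b", "identity"), "identities")
  assert_number(cutoff, "cutoff")
  if (cutoff <= 0 || cutoff > 1) {
    abort_bad_arg("cutoff", "lie in (0, 1]")
  }
  ord <- c_order(-lengths$length, lengths$id)
  ids <- lengths$id[ord]

  # adjacency restricted to redundant (>= cutoff) pairs; everything else
  # can never block a candidate
  red <- identities[identities$identity >= cutoff, , drop = FALSE]
  nbr <- new.env(parent = emptyenv())
  add_edge <- function(x, y) {
    assign(x, c(get0(x, envir = nbr, ifnotfound = character()), y),
           envir = nbr)
  }
  if (nrow(red) > 0) {
    for (i in seq_len(nrow(red))) {
      a <- red$seq_a[i]; b <- red$seq_b[i]
      if (identical(a, b)) next
      add_edge(a, b); add_edge(b, a)
    }
  }

  kept <- new.env(parent = emptyenv())
  reps <- character()
  for (id in ids) {
    blockers <- get0(id, envir = nbr, ifnotfound = character())
    if (!any(vapply(blockers, exists, logical(1), envir = kept,
                    inherits = FALSE))) {
      assign(id, TRUE, envir = kept)
      reps <- c(reps, id)
    }
  }
  reps
}
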