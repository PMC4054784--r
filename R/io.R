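# Readers/writers for the plain-text exchange formats. All tables are TSV
# with a header row; matrices are wide (one row per entity, id first).

#' Read pipeline input tables
#'
#' Thin readers over TSV for the pipeline's exchange formats:
#' expression matrices (`id` + tissue columns), long score tables
#' (`protein`, `transcript`, `score`), length tables (`id`, `length`),
#' identity records (`seq_a`, `seq_b`, `identity`), gene-term annotations
#' (`gene`, `term`) and knock-down tables (`transcript`, `lfc`, ...).
#'
#' @param path File path.
#' @return A tibble of the expected shape (validated).
#' @name readers
NULL

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' @rdname readers
#' @export
read_expression_tsv <- function(path) {
  assert_columns(read_tsv_quiet(path), "id", "path")
}

#' @rdname readers
#' @export
read_scores_tsv <- function(path) {
  assert_columns(read_tsv_quiet(path), c("protein", "transcript", "score"),
                 "path")
}

#' @rdname readers
#' @export
read_lengths_tsv <- function(path) {
  assert_columns(read_tsv_quiet(path), c("id", "length"), "path")
}

#' @rdname readers
#' @export
read_identities_tsv <- function(path) {
  assert_columns(read_tsv_quiet(path), c("seq_a", "seq_b", "identity"),
                 "path")
}

#' @rdname readers
#' @export
read_annotations_tsv <- function(path) {
  assert_columns(read_tsv_quiet(path), c("gene", "term"), "path")
}

#' Sequence ids and lengths from a FASTA file
#'
#' @param path FASTA file path.
#' @return Tibble `id`, `length` suitable for [filter_length()] and
#'   [reduce_redundancy()].
#' @export
read_fasta_lengths <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readBStringSet(path)
  tibble(id = sub("\\s.*$", "", names(seqs)),
         length = Biostrings::width(seqs))
}
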