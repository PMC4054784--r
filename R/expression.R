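#' Encode ordinal immunohistochemistry calls as numbers
#'
#' Maps the four-level vocabulary "no" / "low" / "intermediate" / "high"
#' (case-insensitive) to 0 / 1 / 2 / 3, the encoding applied to protein
#' atlas staining calls before per-tissue Z-normalization.
#'
#' @param labels Wide tibble: `id` column plus one character column of
#'   level calls per tissue.
#' @return Wide numeric expression tibble of the same shape.
#' @export
#' @examples
#' encode_ihc_levels(tibble::tibble(id = "p1", brain = "High", liver = "no"))
encode_ihc_levels <- function(labels) {
  assert_columns(labels, "id", "labels")
  tcols <- tissue_cols(labels)
  lut <- c(no = 0, low = 1, intermediate = 2, high = 3)
  out <- labels
  for (col in tcols) {
    v <- tolower(trimws(as.character(labels[[col]])))
    unknown <- !(v %in% names(lut))
    if (any(unknown)) {
      i <- which(unknown)[1L]
      abort(sprintf(
        "unknown expression level %s for id '%s', tissue '%s'",
        encodeString(labels[[col]][i], quote = "'"), labels$id[i], col),
        class = "rbpcoex_error_bad_level")
    }
    out[[col]] <- unname(lut[v])
  }
  as_tibble(out)
}

#' Z-normalize an expression matrix per tissue
#'
#' Standardizes every tissue column to mean 0, SD 1 using the population
#' (divide-by-n) standard deviation: the tissue panel is the full universe
#' of the study, not a sample from a larger one. Constant columns map to
#' all zeros and are reported. Already-normalized input (flagged by a
#' previous call) is returned unchanged, which makes the operation
#' idempotent; downstream correlations are therefore identical whether or
#' not the input was pre-normalized.
#'
#' @param expr Wide expression tibble (`id` + numeric tissue columns).
#' @param population_sd Use the population (n) SD; set `FALSE` for the
#'   sample (n - 1) SD.
#' @return The normalized tibble, with attribute `normalized = TRUE`.
#' @export
#' @examples
#' normalize_tissues(tibble::tibble(id = c("a", "b", "c"),
#'                                  brain = c(1, 2, 3)))
normalize_tissues <- function(expr, population_sd = TRUE) {
  assert_columns(expr, "id", "expr")
  if (nrow(expr) == 0) abort_bad_arg("expr", "have at least one row")
  if (isTRUE(attr(expr, "normalized"))) return(expr)
  tcols <- tissue_cols(expr)
  if (length(tcols) == 0) abort_bad_arg("expr", "have tissue columns")
  n <- nrow(expr)
  constant <- character()
  out <- expr
  for (col in tcols) {
    x <- expr[[col]]
    mu <- mean(x)
    s <- if (population_sd) sqrt(sum((x - mu)^2) / n) else sd(x)
    if (!is.finite(s) || s == 0) {
      out[[col]] <- rep(0, n)
      constant <- c(constant, col)
    } else {
      out[[col]] <- (x - mu) / s
    }
  }
  if (length(constant) > 0) {
    inform(sprintf("constant tissue column(s) mapped to zeros: %s",
                   paste(constant, collapse = ", ")))
  }
  attr(out, "normalized") <- TRUE
  out
}

#' Pairwise Pearson correlation of protein and transcript profiles
#'
#' Computes the Pearson correlation between every protein profile and
#' every transcript profile over the shared tissue panel. Matrices are
#' per-tissue Z-normalized first (see [normalize_tissues()]; a no-op for
#' already-normalized input), matching the pipeline in which correlations
#' are taken on normalized relative abundances. Pairs in which either
#' profile is constant across tissues have undefined correlation and get
#' `NA`; they are excluded from downstream enrichment.
#'
#' @param proteins,transcripts Wide expression tibbles sharing identical
#'   tissue columns in identical order.
#' @param normalize Per-tissue Z-normalize before correlating (default).
#' @return Long tibble `protein`, `transcript`, `r` with one row per pair.
#' @export
correlate_pairs <- function(proteins, transcripts, normalize = TRUE) {
  assert_columns(proteins, "id", "proteins")
  assert_columns(transcripts, "id", "transcripts")
  pt <- tissue_cols(proteins); tt <- tissue_cols(transcripts)
  if (!identical(pt, tt)) {
    abort("`proteins` and `transcripts` must share identical tissue columns",
          class = "rbpcoex_error_tissue_mismatch")
  }
  if (normalize) {
    proteins <- normalize_tissues(proteins)
    transcripts <- normalize_tissues(transcripts)
  }
  rp <- row_standardize(as.matrix(proteins[, pt]))
  rt <- row_standardize(as.matrix(transcripts[, tt]))
  r <- tcrossprod(rp, rt)            # rows unit-norm & centred => Pearson
  r[r > 1] <- 1; r[r < -1] <- -1
  tibble(protein = rep(proteins$id, times = nrow(transcripts)),
         transcript = rep(transcripts$id, each = nrow(proteins)),
         r = as.vector(r))
}

# centre rows and scale to unit norm; constant rows become NA
row_standardize <- function(m) {
  ctr <- m - rowMeans(m)
  nrm <- sqrt(rowSums(ctr^2))
  nrm[nrm == 0] <- NA_real_
  ctr / nrm
}

#' Assign an expression profile to a novel sequence by homology
#'
#' Implements the homology-based profile transfer rule: among the ten
#' top-ranked alignment hits, candidates are those with e-value at most
#' 0.01 and whole-sequence similarity of at least 75% (proteins) or 95%
#' (transcripts); the best-ranked candidate's profile is returned, with
#' all candidates listed as provenance. When no hit qualifies the result
#' is an explicit no-assignment, not an error.
#'
#' @param query Query id (used only for provenance).
#' @param records Tibble of hits: `query`, `hit`, `e_value`, `similarity`
#'   (percent), `rank` (unique positive integers per query).
#' @param profiles Wide expression tibble holding the hit profiles.
#' @param kind `"protein"` (similarity >= 75) or `"transcript"`
#'   (similarity >= 95).
#' @return A list of class `profile_assignment`: `query`, `assigned`
#'   (logical), `hit` (id or `NA`), `profile` (one-row tibble or `NULL`),
#'   `candidates` (tibble of qualifying hits).
#' @export
assign_profile_by_homology <- function(query, records, profiles,
                                       kind = c("protein", "transcript")) {
  kind <- arg_match(kind)
  assert_columns(records, c("query", "hit", "e_value", "similarity", "rank"),
                 "records")
  assert_columns(profiles, "id", "profiles")
  rec <- records[records$query == query, , drop = FALSE]
  if (anyDuplicated(rec$rank)) {
    abort_bad_arg("records", "have unique ranks per query")
  }
  rec <- rec[order(rec$rank), , drop = FALSE]
  rec <- head(rec, 10L)                       # rule: top ten ranks first
  min_sim <- if (kind == "protein") 75 else 95
  cand <- rec[rec$e_value <= 0.01 & rec$similarity >= min_sim, ,
              drop = FALSE]
  if (nrow(cand) == 0) {
    return(structure(list(query = query, assigned = FALSE, hit = NA_character_,
                          profile = NULL, candidates = as_tibble(cand)),
                     class = "profile_assignment"))
  }
  best <- cand$hit[[1L]]
  prof <- profiles[profiles$id == best, , drop = FALSE]
  if (nrow(prof) == 0) {
    abort(sprintf("profile for hit '%s' not found in `profiles`", best))
  }
  structure(list(query = query, assigned = TRUE, hit = best,
                 profile = as_tibble(prof), candidates = as_tibble(cand)),
            class = "profile_assignment")
}

#' @export
print.profile_assignment <- function(x, ...) {
  if (x$assigned) {
    cat(sprintf("profile assignment: %s <- %s (%d candidate hit(s))\n",
                x$query, x$hit, nrow(x$candidates)))
  } else {
    cat(sprintf("profile assignment: %s — no qualifying hit\n", x$query))
  }
  invisible(x)
}

#' Bin continuous expression into the four ordinal levels
#'
#' Emulates qualitative staining read-outs from continuous abundances:
#' per tissue, values are cut at their quartiles into
#' no / low / intermediate / high. Useful to check that ordinal and
#' continuous encodings of the same cohort give the same qualitative
#' trends.
#'
#' @param expr Wide continuous expression tibble.
#' @return Wide character tibble of level calls.
#' @export
expression_to_ihc <- function(expr) {
  assert_columns(expr, "id", "expr")
  tcols <- tissue_cols(expr)
  out <- expr
  lv <- c("no", "low", "intermediate", "high")
  for (col in tcols) {
    q <- quantile(expr[[col]], c(0.25, 0.5, 0.75), names = FALSE)
    out[[col]] <- lv[findInterval(expr[[col]], q) + 1L]
  }
  as_tibble(out)
}
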