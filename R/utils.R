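# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(arg, must, not = NULL) {
  msg <- sprintf("`%s` must %s", arg, must)
  if (!is.null(not)) msg <- sprintf("%s, not %s", msg, not)
  abort(msg, class = "rbpcoex_error_bad_arg")
}

assert_number <- function(x, arg, lower = -Inf, upper = Inf,
                          allow_null = FALSE) {
  if (is.null(x) && allow_null) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(arg, "be a single finite number")
  }
  if (x < lower || x > upper) {
    abort_bad_arg(arg, sprintf("be in [%s, %s]", lower, upper),
                  format(x))
  }
  invisible(x)
}

assert_count <- function(x, arg, positive = TRUE) {
  assert_number(x, arg)
  if (x != floor(x) || (positive && x < 1) || (!positive && x < 0)) {
    abort_bad_arg(arg, "be a non-negative whole number")
  }
  invisible(x)
}

assert_columns <- function(df, cols, arg) {
  if (!is.data.frame(df)) abort_bad_arg(arg, "be a data frame")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf("`%s` is missing required column(s): %s", arg,
                  paste0("`", missing_cols, "`", collapse = ", ")),
          class = "rbpcoex_error_bad_arg")
  }
  invisible(df)
}

# Tissue columns of a wide expression tibble: everything but the id column.
tissue_cols <- function(df, id_col = "id") {
  setdiff(names(df), id_col)
}

# Deterministic lexicographic order independent of the session locale.
c_order <- function(...) order(..., method = "radix")
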