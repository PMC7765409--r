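#' Well identifiers for a multiwell plate
#'
#' Builds the standard row-letter/column-number well ids ("A01" ... "P24")
#' in row-major order.
#'
#' @param n_rows,n_cols Plate dimensions (default 16 x 24, i.e. 384 wells).
#' @return Character vector of length `n_rows * n_cols`.
#' @export
#' @examples
#' head(well_ids())
well_ids <- function(n_rows = 16L, n_cols = 24L) {
  stopifnot(n_rows >= 1, n_rows <= 26, n_cols >= 1)
  as.vector(t(outer(LETTERS[seq_len(n_rows)],
                    sprintf("%02d", seq_len(n_cols)), paste0)))
}

#' @rdname well_ids
#' @param well Well id(s) such as `"B03"`.
#' @export
well_row <- function(well) match(substr(well, 1, 1), LETTERS)

#' @rdname well_ids
#' @export
well_col <- function(well) as.integer(substr(well, 2, 3))

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stream-specific child seed from a base seed; keeps values well
# inside 32-bit integer range.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(k) %% 1000L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scalar numeric check used by the spec constructors.
assert_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
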