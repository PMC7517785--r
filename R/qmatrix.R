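#' Construct and validate a Q-matrix
#'
#' A Q-matrix declares which latent attributes each item requires: entry
#' `q[j, k] = 1` means item `j` cannot be solved without attribute `k`.
#' Rows are items, columns attributes; all entries must be 0/1 and every
#' item must require at least one attribute.
#'
#' @param x a 0/1 matrix or data frame (items x attributes). A data frame
#'   whose first column is non-numeric is treated as an item-id column.
#' @param item_ids,attribute_ids optional labels; defaults are taken from
#'   dimnames or generated (`Y1..`, `A1..`).
#' @return an integer matrix of class `qmatrix` with item/attribute dimnames.
#' @examples
#' q <- qmatrix(matrix(c(1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE))
#' @export
qmatrix <- function(x, item_ids = NULL, attribute_ids = NULL) {
  if (is.data.frame(x)) {
    if (ncol(x) > 1 && !is.numeric(x[[1]])) {
      item_ids <- item_ids %||% as.character(x[[1]])
      x <- x[-1]
    }
    attribute_ids <- attribute_ids %||% names(x)
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) abort("`x` must be a matrix or data frame.")
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x %in% c(0L, 1L))) {
    abort("Q-matrix entries must all be 0 or 1.")
  }
  if (any(rowSums(x) == 0)) {
    abort("every Q-matrix row (item) must require at least one attribute.")
  }
  if (nrow(x) < ncol(x)) {
    warn("Q-matrix has fewer items than attributes; the model is unlikely to be identified.")
  }
  rownames(x) <- item_ids %||% rownames(x) %||% paste0("Y", seq_len(nrow(x)))
  colnames(x) <- attribute_ids %||% colnames(x) %||% paste0("A", seq_len(ncol(x)))
  class(x) <- c("qmatrix", class(x))
  x
}

#' Read a Q-matrix from CSV
#'
#' Expects a header row of attribute names; the first column holds item ids
#' and the remaining columns the 0/1 loadings.
#'
#' @param path CSV file path.
#' @return a [qmatrix()].
#' @export
read_qmatrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  qmatrix(df)
}

#' @export
print.qmatrix <- function(x, ...) {
  cat("<qmatrix> ", nrow(x), " items x ", ncol(x), " attributes\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

is_single_attribute <- function(q) all(rowSums(q) == 1L)

#' Enumerate the attribute-pattern space
#'
#' All `2^K` binary mastery patterns for `K` attributes, in binary counting
#' order (first attribute varies fastest).
#'
#' @param K number of attributes.
#' @return a `2^K x K` 0/1 matrix.
#' @export
attribute_patterns <- function(K) {
  stopifnot(K >= 1, K <= 20)
  m <- as.matrix(expand.grid(rep(list(0:1), K), KEEP.OUT.ATTRS = FALSE))
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, paste0("A", seq_len(K)))
  m
}

# item-wise ideal responses for every pattern: 2^K x J matrix
eta_table <- function(q, patterns = attribute_patterns(ncol(q))) {
  need <- rowSums(q)
  have <- patterns %*% t(q)
  (have == matrix(need, nrow(patterns), nrow(q), byrow = TRUE)) * 1L
}
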