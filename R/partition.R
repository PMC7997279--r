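BLOCKS <- c("psi", "s", "a", "lambda")

#' Coordinate partition into external, sensory, active and internal blocks
#'
#' Fixes the block structure `x = (psi, s, a, lambda)` used to index every
#' matrix in the package: `psi` are the external coordinates, `s` sensory,
#' `a` active and `lambda` internal. Block order is fixed; index ranges are
#' contiguous, disjoint, and cover `1..d`.
#'
#' @param n_psi,n_s,n_a,n_lambda positive integer block sizes.
#' @return an object of class `coordinate_partition` with fields `n` (named
#'   sizes), `d` (total dimension) and `idx` (named list of index vectors).
#' @examples
#' p <- coordinate_partition(2, 1, 1, 1)
#' p$idx$lambda
#' @export
coordinate_partition <- function(n_psi, n_s, n_a, n_lambda) {
  n <- c(psi = n_psi, s = n_s, a = n_a, lambda = n_lambda)
  if (any(n < 1) || any(n != round(n))) {
    abort_blanket("all four block sizes must be positive integers", "dimension_error")
  }
  n <- stats::setNames(as.integer(n), BLOCKS)
  ends <- cumsum(n)
  starts <- c(1L, ends[-4] + 1L)
  idx <- Map(seq.int, starts, ends)
  names(idx) <- BLOCKS
  structure(list(n = n, d = sum(n), idx = idx), class = "coordinate_partition")
}

#' @export
print.coordinate_partition <- function(x, ...) {
  cat(sprintf(
    "<coordinate_partition> d = %d  (psi=%d, s=%d, a=%d, lambda=%d)\n",
    x$d, x$n["psi"], x$n["s"], x$n["a"], x$n["lambda"]
  ))
  invisible(x)
}

#' @keywords internal
check_blocks <- function(blocks) {
  bad <- setdiff(blocks, BLOCKS)
  if (length(bad) > 0) {
    abort_blanket(
      sprintf("unknown block name(s): %s", paste(bad, collapse = ", ")),
      "block_error"
    )
  }
  # canonical order
  BLOCKS[BLOCKS %in% blocks]
}

#' @keywords internal
block_idx <- function(partition, blocks) {
  unlist(partition$idx[check_blocks(blocks)], use.names = FALSE)
}

#' Extract a sub-matrix by block labels
#'
#' Accessor for the sixteen blocks `X_ab` of any `d x d` matrix under a
#' coordinate partition; writing back all sixteen blocks reassembles the
#' matrix exactly.
#'
#' @param X a `d x d` matrix.
#' @param partition a [coordinate_partition()].
#' @param rows,cols block labels among `"psi"`, `"s"`, `"a"`, `"lambda"`
#'   (one or several).
#' @return the sub-matrix `X[rows-block, cols-block]`, always a matrix.
#' @export
block <- function(X, partition, rows, cols = rows) {
  X[block_idx(partition, rows), block_idx(partition, cols), drop = FALSE]
}

#' Replace a sub-matrix by block labels
#'
#' @inheritParams block
#' @param value replacement sub-matrix of matching dimension.
#' @return the modified matrix.
#' @export
`block<-` <- function(X, partition, rows, cols = rows, value) {
  X[block_idx(partition, rows), block_idx(partition, cols)] <- value
  X
}

# Is X block-diagonal with respect to the partition?
#' @keywords internal
is_block_diagonal <- function(X, partition, tol = ZERO_TOL) {
  for (i in BLOCKS) {
    for (j in BLOCKS) {
      if (i != j && maxabs(block(X, partition, i, j)) > tol) return(FALSE)
    }
  }
  TRUE
}
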