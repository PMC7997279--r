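#' @keywords internal
abort_blanket <- function(message, class, ...) {
  stop(structure(
    class = c(class, "blanketlab_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# Tolerance policy used package-wide (matrices are O(1)):
#  - structural zeros: absolute max-entry tolerance 1e-10
#  - a block counts as a genuine violation only above 1e-3 (well separated
#    from the satisfaction tolerance, so boolean verdicts are robust)
#  - cross-checks between algebraic routes: relative 1e-8
#  - Hurwitz margin: max real part of eigenvalues < -1e-8
ZERO_TOL <- 1e-10
VIOLATION_THRESHOLD <- 1e-3
CROSSCHECK_RTOL <- 1e-8
HURWITZ_MARGIN <- -1e-8

#' Maximum absolute entry of a matrix or vector
#'
#' The residual norm used for all structural-zero verdicts. It is invariant
#' under the independent-copies lift (the lift of a block is `I_n %x% B`,
#' which has the same largest entry), so lifted systems report exactly the
#' base residuals.
#'
#' @param x numeric vector or matrix (possibly empty).
#' @return a single non-negative number; `0` for empty input.
#' @export
maxabs <- function(x) {
  if (length(x) == 0) return(0)
  max(abs(x))
}

#' @keywords internal
relerr <- function(x, ref) {
  nref <- sqrt(sum(ref^2))
  if (nref == 0) sqrt(sum(x^2)) else sqrt(sum(x^2)) / nref
}

# Evaluate expr with a temporary RNG seed, restoring global RNG state.
#' @keywords internal
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  expr
}

#' @keywords internal
is_symmetric_tol <- function(X, tol = ZERO_TOL) maxabs(X - t(X)) <= tol

#' @keywords internal
is_antisymmetric_tol <- function(X, tol = ZERO_TOL) maxabs(X + t(X)) <= tol

#' @keywords internal
min_eigval_sym <- function(X) min(eigen((X + t(X)) / 2, symmetric = TRUE, only.values = TRUE)$values)
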