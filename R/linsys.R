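#' Linear Ornstein-Uhlenbeck system with a coordinate partition
#'
#' Represents the stochastic differential equation `dx = M x dt + dW` with
#' white Gaussian noise of autocovariance `2 Gamma delta(t - t')`. The drift
#' Jacobian `M` must be Hurwitz (ergodicity) and the diffusion matrix `Gamma`
#' symmetric positive definite and block-diagonal with respect to the
#' partition. The solenoidal matrix `R` and stationary precision `U` can be
#' supplied (when the system was assembled from a potential) or derived on
#' demand with [with_stationary()].
#'
#' @param M `d x d` drift matrix.
#' @param Gamma `d x d` SPD block-diagonal diffusion matrix; defaults to the
#'   identity.
#' @param partition a [coordinate_partition()] whose total dimension matches.
#' @param R,U optional solenoidal matrix and stationary precision, when known
#'   by construction.
#' @param check validate invariants (default `TRUE`).
#' @return an object of class `ou_system`.
#' @export
ou_system <- function(M, Gamma = diag(nrow(M)), partition, R = NULL, U = NULL,
                      check = TRUE) {
  M <- as.matrix(M)
  Gamma <- as.matrix(Gamma)
  d <- partition$d
  if (!all(dim(M) == d) || !all(dim(Gamma) == d)) {
    abort_blanket(
      sprintf("M and Gamma must be %d x %d to match the partition", d, d),
      "dimension_error"
    )
  }
  if (check) {
    if (!is_symmetric_tol(Gamma)) {
      abort_blanket("Gamma must be symmetric", "invariant_error", field = "Gamma")
    }
    if (min_eigval_sym(Gamma) <= 0) {
      abort_blanket("Gamma must be positive definite", "not_spd_error", field = "Gamma")
    }
    if (!is_block_diagonal(Gamma, partition)) {
      abort_blanket("Gamma must be block-diagonal over the partition",
                    "invariant_error", field = "Gamma")
    }
    ev <- eigen(M, only.values = TRUE)$values
    if (max(Re(ev)) >= HURWITZ_MARGIN) {
      abort_blanket("M is not Hurwitz: the system has no ergodic density",
                    "non_ergodic_error", field = "M")
    }
  }
  structure(list(partition = partition, M = M, Gamma = Gamma, R = R, U = U),
            class = "ou_system")
}

#' @export
print.ou_system <- function(x, ...) {
  cat(sprintf("<ou_system> d = %d (psi=%d, s=%d, a=%d, lambda=%d)%s\n",
              x$partition$d, x$partition$n["psi"], x$partition$n["s"],
              x$partition$n["a"], x$partition$n["lambda"],
              if (!is.null(x$U)) "  [R, U attached]" else ""))
  invisible(x)
}

# Solve A X + X B = Q by the dense Kronecker route (vec(AX) = (I (x) A) vec X,
# vec(XB) = (B' (x) I) vec X). Adequate for the package's d <= ~50 envelope.
#' @keywords internal
solve_sylvester_dense <- function(A, B, Q) {
  d1 <- nrow(A); d2 <- ncol(B)
  K <- diag(d2) %x% A + t(B) %x% diag(d1)
  matrix(solve(K, as.vector(Q)), d1, d2)
}

#' Solenoidal matrix of the drift decomposition
#'
#' Solves `M R + R M' = M Gamma - Gamma M'` for the antisymmetric matrix `R`
#' appearing in the Helmholtz-type decomposition `f(x) = (Gamma + R) grad
#' ln p*(x)` of the drift of an ergodic linear system. The right-hand side is
#' antisymmetric and the solution unique for Hurwitz `M`, so `R` is
#' antisymmetric.
#'
#' @param M drift matrix (typically Hurwitz).
#' @param Gamma SPD diffusion matrix.
#' @param tol eigenvalue-collision guard tolerance.
#' @return the `d x d` antisymmetric solenoidal matrix.
#' @seealso [stationary_precision()], [assemble_from_potential()]
#' @export
solve_solenoidal <- function(M, Gamma, tol = ZERO_TOL) {
  M <- as.matrix(M); Gamma <- as.matrix(Gamma)
  ev <- eigen(M, only.values = TRUE)$values
  scale <- max(Mod(ev), 1)
  sums <- outer(ev, ev, `+`)
  if (min(Mod(sums)) < max(tol, 1e-12) * scale) {
    abort_blanket(
      "M and -M' share an eigenvalue (lambda_i + lambda_j = 0): the solenoidal equation has no unique solution",
      "solvability_error"
    )
  }
  rhs <- M %*% Gamma - Gamma %*% t(M)
  solve_sylvester_dense(M, t(M), rhs)
}

#' Stationary covariance from the Lyapunov equation
#'
#' Solves `M C + C M' + 2 Gamma = 0` for the covariance `C` of the stationary
#' Gaussian density of the system `dx = M x dt + dW`, with noise
#' autocovariance `2 Gamma delta(t - t')`.
#'
#' @inheritParams solve_solenoidal
#' @return the SPD stationary covariance matrix.
#' @export
lyapunov_covariance <- function(M, Gamma) {
  M <- as.matrix(M); Gamma <- as.matrix(Gamma)
  ev <- eigen(M, only.values = TRUE)$values
  if (max(Re(ev)) >= HURWITZ_MARGIN) {
    abort_blanket("M is not Hurwitz: no stationary covariance exists",
                  "non_ergodic_error")
  }
  C <- solve_sylvester_dense(M, t(M), -2 * Gamma)
  (C + t(C)) / 2
}

#' Stationary Gaussian density of a linear system
#'
#' Container for the zero-mean stationary Gaussian, holding both the
#' precision `U` and the covariance `C = U^-1`. The Gibbs energy is
#' `G(x) = -ln p*(x) = x' U x / 2 + ln Z`.
#'
#' @param U SPD precision matrix.
#' @param C covariance; computed as `solve(U)` when omitted.
#' @return an object of class `stationary_gaussian`.
#' @export
stationary_gaussian <- function(U, C = NULL) {
  U <- (as.matrix(U) + t(as.matrix(U))) / 2
  if (min_eigval_sym(U) <= 0) {
    abort_blanket("precision U has a non-positive eigenvalue", "not_spd_error",
                  field = "U")
  }
  if (is.null(C)) C <- solve(U)
  C <- (as.matrix(C) + t(as.matrix(C))) / 2
  structure(list(U = U, C = C), class = "stationary_gaussian")
}

#' Stationary precision from the potential form of the drift
#'
#' Computes `U = -(Gamma + R)^-1 M`, the precision of the stationary Gaussian
#' when the drift decomposes as `f(x) = (Gamma + R) grad ln p*(x)`, and
#' cross-checks it against the inverse of the Lyapunov covariance. The
#' cross-check pins the noise convention (autocovariance `2 Gamma`): the two
#' routes agree only under it.
#'
#' @inheritParams solve_solenoidal
#' @param R antisymmetric solenoidal matrix, e.g. from [solve_solenoidal()].
#' @param rtol relative tolerance for the two-route consistency check.
#' @return a [stationary_gaussian()].
#' @export
stationary_precision <- function(M, Gamma, R, rtol = CROSSCHECK_RTOL) {
  U <- -solve(Gamma + R, M)
  U <- (U + t(U)) / 2
  if (min_eigval_sym(U) <= 0) {
    abort_blanket("derived precision has a non-positive eigenvalue",
                  "not_spd_error", field = "U")
  }
  C <- lyapunov_covariance(M, Gamma)
  if (relerr(solve(U) - C, C) > rtol) {
    abort_blanket(
      "potential-form precision disagrees with the Lyapunov covariance beyond tolerance",
      "consistency_error"
    )
  }
  stationary_gaussian(U, C)
}

#' Assemble a linear system from its stationary potential
#'
#' Builds the drift `M = -(Gamma + R) U`, so that the decomposition
#' `f(x) = (Gamma + R) grad ln p*(x)`, the solenoidal equation and the
#' stationary precision all hold by construction. `M` is automatically
#' Hurwitz: it is similar to a matrix whose symmetric part is negative
#' definite.
#'
#' @param U SPD precision of the target stationary density.
#' @param R antisymmetric solenoidal matrix.
#' @param Gamma SPD block-diagonal diffusion matrix.
#' @param partition a [coordinate_partition()].
#' @return an [ou_system()] with `R` and `U` attached.
#' @export
assemble_from_potential <- function(U, R, Gamma, partition) {
  U <- as.matrix(U); R <- as.matrix(R); Gamma <- as.matrix(Gamma)
  if (!is_symmetric_tol(U) || min_eigval_sym(U) <= 0) {
    abort_blanket("U must be symmetric positive definite", "not_spd_error",
                  field = "U")
  }
  if (!is_antisymmetric_tol(R)) {
    abort_blanket("R must be antisymmetric", "asymmetry_error", field = "R")
  }
  M <- -(Gamma + R) %*% U
  ou_system(M, Gamma, partition, R = R, U = (U + t(U)) / 2)
}

#' Attach solenoidal matrix and stationary density to a system
#'
#' Derives `R` (solenoidal equation) and `U`, `C` (Lyapunov / potential-form
#' cross-check) for a system specified only through `(M, Gamma)`; systems
#' assembled from a potential already carry them.
#'
#' @param system an [ou_system()].
#' @return the system with `$R`, `$U`, `$C` fields populated.
#' @export
with_stationary <- function(system) {
  if (is.null(system$R)) system$R <- solve_solenoidal(system$M, system$Gamma)
  if (is.null(system$U) || is.null(system$C)) {
    sg <- stationary_precision(system$M, system$Gamma, system$R)
    system$U <- sg$U
    system$C <- sg$C
  }
  system
}

#' @keywords internal
system_covariance <- function(system) {
  if (!is.null(system$C)) return(system$C)
  if (!is.null(system$U)) return(solve(system$U))
  lyapunov_covariance(system$M, system$Gamma)
}

#' Conditional of a stationary Gaussian over partition blocks
#'
#' For a zero-mean Gaussian with precision `U`, returns the conditional
#' distribution of the `target` blocks given the `given` blocks, with any
#' remaining blocks marginalised out. The conditional is Gaussian with a
#' constant precision `P` and a mean affine in the conditioning coordinates,
#' `mu = K y`. When `target` and `given` together cover all four blocks,
#' `P` is exactly the `U_tt` sub-block and `K = -U_tt^-1 U_t,given`; the
#' central example is the "posterior" `p*(Psi | s, a, lambda)`.
#'
#' @param U SPD precision matrix (or a [stationary_gaussian()]).
#' @param partition a [coordinate_partition()].
#' @param target,given disjoint sets of block labels; `target` nonempty.
#' @return an object of class `gaussian_conditional` with fields `P`
#'   (precision), `Sigma` (covariance), `K` (gain), `target`, `given`,
#'   `partition`.
#' @export
conditional_gaussian <- function(U, partition, target, given) {
  if (inherits(U, "stationary_gaussian")) U <- U$U
  target <- check_blocks(target)
  given <- if (length(given)) check_blocks(given) else character(0)
  if (length(target) == 0) {
    abort_blanket("target block set must be nonempty", "block_error")
  }
  if (length(intersect(target, given)) > 0) {
    abort_blanket("target and given block sets must be disjoint", "block_error")
  }
  keep <- c(target, given)
  Um <- U
  if (length(setdiff(BLOCKS, keep)) > 0) {
    # marginalise the remaining blocks via the covariance route
    idx <- block_idx(partition, keep)
    Um <- matrix(0, partition$d, partition$d)
    Um[idx, idx] <- solve(solve(U)[idx, idx, drop = FALSE])
  }
  ti <- block_idx(partition, target)
  P <- Um[ti, ti, drop = FALSE]
  P <- (P + t(P)) / 2
  if (min_eigval_sym(P) <= 0) {
    abort_blanket("conditional precision is not positive definite",
                  "not_spd_error")
  }
  if (length(given) > 0) {
    gi <- block_idx(partition, given)
    K <- -solve(P, Um[ti, gi, drop = FALSE])
  } else {
    K <- matrix(0, length(ti), 0)
  }
  structure(
    list(P = P, Sigma = solve(P), K = K, target = target, given = given,
         partition = partition),
    class = "gaussian_conditional"
  )
}

#' Precision of a Gaussian marginal over partition blocks
#'
#' Inverts the covariance restricted to the requested blocks; equals the
#' Schur complement `U_bb - U_br U_rr^-1 U_rb` of the removed blocks in the
#' precision. Used for the marginalised stationary density `p*(s, a, lambda)`.
#'
#' @param C covariance matrix (or a [stationary_gaussian()]).
#' @param partition a [coordinate_partition()].
#' @param blocks nonempty set of block labels to keep.
#' @return the SPD precision of the marginal, indexed in block order.
#' @export
marginal_precision <- function(C, partition, blocks) {
  if (inherits(C, "stationary_gaussian")) C <- C$C
  blocks <- check_blocks(blocks)
  if (length(blocks) == 0) {
    abort_blanket("block set must be nonempty", "block_error")
  }
  idx <- block_idx(partition, blocks)
  V <- solve(C[idx, idx, drop = FALSE])
  (V + t(V)) / 2
}
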