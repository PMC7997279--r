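#' Gaussian variational density over external coordinates
#'
#' The variational family used throughout the lemma analysis:
#' `q(Psi | lambda) = N(A lambda + b, S)` — Gaussian with mean affine in the
#' internal coordinates and constant covariance. By construction `q` depends
#' on `lambda` only, never on `(s, a)` (the "at face value" reading of a
#' belief parameterised by internal coordinates). This family is exhaustive
#' for matching a Gaussian conditional with lambda-affine mean, so
#' infeasibility verdicts within it are meaningful for the Gaussian-linear
#' setting.
#'
#' @param A `n_psi x n_lambda` mean-gain matrix.
#' @param b length-`n_psi` offset.
#' @param S `n_psi x n_psi` SPD covariance.
#' @param partition a [coordinate_partition()].
#' @return an object of class `variational_gaussian`.
#' @export
variational_gaussian <- function(A, b, S, partition) {
  n_psi <- partition$n["psi"]; n_l <- partition$n["lambda"]
  A <- matrix(as.numeric(A), n_psi, n_l)
  b <- as.numeric(b)
  S <- as.matrix(S)
  if (length(b) != n_psi || !all(dim(S) == n_psi)) {
    abort_blanket("variational parameter dimensions do not match the partition",
                  "dimension_error")
  }
  if (!is_symmetric_tol(S) || min_eigval_sym(S) <= 0) {
    abort_blanket("S must be symmetric positive definite", "not_spd_error",
                  field = "S")
  }
  structure(list(A = A, b = b, S = (S + t(S)) / 2, partition = partition),
            class = "variational_gaussian")
}

#' @keywords internal
logdet_spd <- function(X) as.numeric(determinant(X, logarithm = TRUE)$modulus)

#' The conditional p*(Psi | s, a, lambda) of a system
#'
#' @param system an [ou_system()].
#' @return a `gaussian_conditional` over the external block given the rest.
#' @export
posterior_conditional <- function(system) {
  system <- with_stationary(system)
  conditional_gaussian(system$U, system$partition, "psi", c("s", "a", "lambda"))
}

# Mean of q at a blanket-internal point y = (s, a, lambda).
#' @keywords internal
q_mean_at <- function(q, point) {
  p <- q$partition
  n_s <- p$n["s"]; n_a <- p$n["a"]; n_l <- p$n["lambda"]
  lam <- point[(n_s + n_a + 1):(n_s + n_a + n_l)]
  as.numeric(q$A %*% lam + q$b)
}

#' KL divergence of the variational density from a Gaussian conditional
#'
#' Closed form for `D(s,a,lambda) = KL[q(Psi|lambda) || p*(Psi|s,a,lambda)]`
#' at one point of the blanket-internal coordinates:
#' `(tr(Sigma_c^-1 S) - n_psi + d' Sigma_c^-1 d + ln det Sigma_c - ln det S)/2`
#' with `d` the mean mismatch at the point. Nonnegative, zero iff the two
#' densities coincide there.
#'
#' @param q a [variational_gaussian()].
#' @param cond a `gaussian_conditional` with target `psi` given
#'   `(s, a, lambda)` (see [posterior_conditional()]).
#' @param point numeric vector `(s, a, lambda)`.
#' @return a single nonnegative number.
#' @export
gaussian_kl <- function(q, cond, point) {
  mu_c <- as.numeric(cond$K %*% point)
  mu_q <- q_mean_at(q, point)
  d <- mu_c - mu_q
  n_psi <- nrow(cond$P)
  0.5 * (sum(diag(cond$P %*% q$S)) - n_psi +
           as.numeric(t(d) %*% cond$P %*% d) -
           logdet_spd(cond$P) - logdet_spd(q$S))
}

#' Variational free energy at a point
#'
#' `F(s,a,lambda) = -ln p*(s,a,lambda) + KL[q(Psi|lambda)||p*(Psi|s,a,lambda)]`.
#' When `q` equals the conditional, `F` reduces exactly to the negative log
#' marginal.
#'
#' @param system an [ou_system()].
#' @param q a [variational_gaussian()].
#' @param point numeric vector `(s, a, lambda)`.
#' @return a single number.
#' @export
free_energy <- function(system, q, point) {
  system <- with_stationary(system)
  p <- system$partition
  V <- marginal_precision(system_covariance(system), p, c("s", "a", "lambda"))
  n_y <- nrow(V)
  neg_log_marginal <- 0.5 * as.numeric(t(point) %*% V %*% point) +
    0.5 * (n_y * log(2 * pi) - logdet_spd(V))
  neg_log_marginal + gaussian_kl(q, posterior_conditional(system), point)
}

# Delta = K - [0 | 0 | A]: difference of the conditional's gain and q's gain
# as maps from (s, a, lambda) to the psi mean.
#' @keywords internal
gain_mismatch <- function(system, q) {
  cond <- posterior_conditional(system)
  p <- system$partition
  A_tilde <- matrix(0, p$n["psi"], sum(p$n[c("s", "a", "lambda")]))
  lam_cols <- (p$n["s"] + p$n["a"] + 1):ncol(A_tilde)
  A_tilde[, lam_cols] <- q$A
  list(Delta = cond$K - A_tilde, cond = cond)
}

#' Exact affine representation of the KL gradients
#'
#' The KL divergence of the Gaussian family is a quadratic in
#' `y = (s, a, lambda)`: `D(y) = (Delta y - b)' G (Delta y - b)/2 + const(S)`
#' with `G` the conditional precision and `Delta` the gain mismatch. Its
#' gradient is the affine map `grad_y D = (Delta' G Delta) y - Delta' G b`;
#' this function returns the `a`-block and `lambda`-block rows of that map
#' together with a "vanishes identically" verdict for each (every
#' coefficient below `tol`). Note the gradients do not involve `S` at all.
#'
#' @param system an [ou_system()].
#' @param q a [variational_gaussian()].
#' @param tol coefficient tolerance for the vanishing verdict.
#' @return list with per-gradient entries `a` and `lambda`, each holding
#'   `coef` (rows of the linear part), `const`, `vanishes`; plus the full
#'   map in `full_coef`, `full_const`.
#' @export
kl_gradient_maps <- function(system, q, tol = ZERO_TOL) {
  system <- with_stationary(system)
  gm <- gain_mismatch(system, q)
  G <- gm$cond$P
  coef <- t(gm$Delta) %*% G %*% gm$Delta
  const <- -as.numeric(t(gm$Delta) %*% G %*% q$b)
  p <- system$partition
  n_s <- p$n["s"]; n_a <- p$n["a"]; n_l <- p$n["lambda"]
  a_rows <- (n_s + 1):(n_s + n_a)
  l_rows <- (n_s + n_a + 1):(n_s + n_a + n_l)
  piece <- function(rows) {
    list(coef = coef[rows, , drop = FALSE],
         const = const[rows],
         vanishes = maxabs(coef[rows, ]) < tol && maxabs(const[rows]) < tol)
  }
  list(a = piece(a_rows), lambda = piece(l_rows),
       full_coef = coef, full_const = const, tol = tol)
}

LEMMA_FAMILIES <- c("29,30", "37,38", "39,40")

# Which drift-rewriting family each free-energy family must reproduce.
#' @keywords internal
lemma_to_identity <- function(family) {
  switch(family, "29,30" = "19,20", "37,38" = "21,22", "39,40" = "17,18",
         abort_blanket(sprintf("unknown lemma family '%s'", family), "block_error"))
}

# Minimum-norm least squares via SVD, with rank and nullspace basis.
#' @keywords internal
lstsq_svd <- function(K, b, rtol = 1e-10) {
  if (ncol(K) == 0) {
    return(list(x = numeric(0), rank = 0L, nullspace = matrix(0, 0, 0),
                residual = sqrt(sum(b^2))))
  }
  sv <- svd(K, nu = min(dim(K)), nv = ncol(K))
  keep <- sv$d > rtol * max(sv$d, 1e-300)
  r <- sum(keep)
  x <- if (r == 0) rep(0, ncol(K)) else
    as.numeric(sv$v[, seq_len(r), drop = FALSE] %*%
                 ((t(sv$u[, seq_len(r), drop = FALSE]) %*% b) / sv$d[seq_len(r)]))
  ns <- if (r < ncol(K)) sv$v[, (r + 1):ncol(K), drop = FALSE] else
    matrix(0, ncol(K), 0)
  list(x = x, rank = r, nullspace = ns,
       residual = sqrt(sum((K %*% x - b)^2)))
}

#' Feasibility of the free energy lemma within the Gaussian-linear family
#'
#' For a system on which the named drift-rewriting family holds, the free
#' energy lemma requires a variational density `q(Psi|lambda)` whose
#' R-weighted KL-gradient combinations vanish identically in
#' `(s, a, lambda)`: `W grad_y D == 0` with `W` the family's coefficient
#' operator (for the diagonal family `"29,30"` with trivial nullspaces this
#' is exactly the vanishing of both gradients). Because the KL is a
#' `G`-weighted quadratic in the mismatch `Delta(A) y - b` with `G` positive
#' definite, `W (Delta' G Delta) == 0` is equivalent to the *linear*
#' constraint `Delta(A) W' = 0`; `b` and `S` then drop out of the constraint
#' entirely — `S` enters the KL only through point-independent terms, so it
#' is unconstrained whenever the `A`-constraints are satisfiable.
#'
#' @param system an [ou_system()].
#' @param family `"29,30"` (diagonal), `"37,38"` (a-lambda cross terms) or
#'   `"39,40"` (all solenoidal couplings); each is required on systems where
#'   the corresponding rewriting `"19,20"`, `"21,22"`, `"17,18"` holds.
#' @return object of class `lemma_feasibility_report`: `verdict`
#'   (`"feasible"`, `"infeasible"` or `"ambiguous"`), minimum-norm solution
#'   `A`, relative least-squares `residual`, `solution_nullity` (dimension of
#'   the feasible `A`-set), `b_unconstrained`, `S_unconstrained`, nullspace
#'   dimensions of `(Gamma+R)_aa` and `(Gamma+R)_ll`, and a `witness` q when
#'   feasible. If the prerequisite rewriting fails, `applicable` is `FALSE`.
#' @export
lemma_feasibility <- function(system, family = "29,30") {
  family <- match.arg(family, LEMMA_FAMILIES)
  system <- with_stationary(system)
  idfam <- lemma_to_identity(family)
  fc <- flow_coefficients(system, idfam)
  if (!fc$applicable || fc$residual >= ZERO_TOL) {
    return(structure(
      list(family = family, applicable = FALSE,
           reason = sprintf("rewriting family (%s) does not hold on this system", idfam)),
      class = "lemma_feasibility_report"
    ))
  }
  p <- system$partition
  W <- family_operator(system, idfam)
  gm <- gain_mismatch(system, q = variational_gaussian(
    matrix(0, p$n["psi"], p$n["lambda"]), rep(0, p$n["psi"]),
    diag(p$n["psi"]), p
  ))
  K <- gm$cond$K
  lam_cols <- (p$n["s"] + p$n["a"] + 1):ncol(K)
  X <- t(W[, lam_cols, drop = FALSE])        # n_lambda x (n_a + n_lambda)
  B <- K %*% t(W)                            # n_psi x (n_a + n_lambda)
  Kmat <- t(X) %x% diag(p$n["psi"])
  ls <- lstsq_svd(Kmat, as.numeric(B))
  scale <- max(1, sqrt(sum(B^2)))
  rel <- ls$residual / scale
  verdict <- if (rel < CROSSCHECK_RTOL) "feasible"
  else if (rel > 1e-2) "infeasible"
  else "ambiguous"
  GR <- system$Gamma + system$R
  nullity_of <- function(X) ncol(X) - qr(X)$rank
  A_hat <- matrix(ls$x, p$n["psi"], p$n["lambda"])
  witness <- NULL
  if (verdict == "feasible") {
    witness <- variational_gaussian(A_hat, rep(0, p$n["psi"]),
                                    gm$cond$Sigma, p)
  }
  structure(
    list(family = family, applicable = TRUE, verdict = verdict,
         feasible = verdict == "feasible",
         A = A_hat, residual = rel,
         solution_nullity = ncol(Kmat) - ls$rank,
         b_unconstrained = TRUE, S_unconstrained = TRUE,
         nullspace_dim_aa = nullity_of(block(GR, p, "a")),
         nullspace_dim_ll = nullity_of(block(GR, p, "lambda")),
         witness = witness),
    class = "lemma_feasibility_report"
  )
}

#' @export
print.lemma_feasibility_report <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<lemma_feasibility_report> family (%s): not applicable (%s)\n",
                x$family, x$reason))
  } else {
    cat(sprintf(
      "<lemma_feasibility_report> family (%s): %s (LS residual %.3e, A-solution-set dim %d, b and S free)\n",
      x$family, x$verdict, x$residual, x$solution_nullity
    ))
  }
  invisible(x)
}

#' Witness of unbounded KL divergence under vanishing gradients
#'
#' On a system where the lemma is feasible, constructs a variational density
#' inside the feasible set whose pointwise KL divergence from the conditional
#' exceeds any requested threshold `c`, while its KL-gradient combinations
#' still vanish identically. The construction scales the covariance,
#' `S = t Sigma_c`, which leaves the gradients untouched (they do not involve
#' `S`) and contributes `n_psi (t - 1 - ln t)/2` to the KL at every point;
#' `t` is chosen so this exceeds `c`. No threshold can therefore be
#' guaranteed, and the witness is manifestly different from the conditional
#' whenever the conditional mean varies with `(s, a)`.
#'
#' @param system an [ou_system()].
#' @param report a feasible [lemma_feasibility()] report.
#' @param c nonnegative KL threshold to exceed.
#' @return list with the witness `q`, scale `t`, probe `point`, attained
#'   `kl`, `gradient_maxabs` of the witness's KL-gradient maps, and
#'   `posterior_s_gain` (max entry of the conditional mean's `s`-gain; a
#'   nonzero value certifies `q(Psi|lambda) != p*(Psi|s,a,lambda)`).
#' @export
kl_supremum_probe <- function(system, report, c) {
  if (!isTRUE(report$feasible)) {
    abort_blanket("lemma feasibility report is not feasible: no witness exists in the family",
                  "infeasible_error")
  }
  system <- with_stationary(system)
  p <- system$partition
  cond <- posterior_conditional(system)
  n_psi <- p$n["psi"]
  target <- c + 1
  g <- function(t) 0.5 * n_psi * (t - 1 - log(t)) - target
  t_up <- 2 * target / n_psi + 2
  while (g(t_up) <= 0) t_up <- 2 * t_up
  t_star <- stats::uniroot(g, c(1 + 1e-9, t_up), tol = 1e-12)$root
  q <- variational_gaussian(report$A, rep(0, n_psi), t_star * cond$Sigma, p)
  point <- rep(0, sum(p$n[c("s", "a", "lambda")]))
  grads <- kl_gradient_maps(system, q)
  list(
    q = q, t = t_star, point = point,
    kl = gaussian_kl(q, cond, point),
    gradient_maxabs = max(maxabs(grads$a$coef), maxabs(grads$a$const),
                          maxabs(grads$lambda$coef), maxabs(grads$lambda$const)),
    posterior_s_gain = maxabs(cond$K[, seq_len(p$n["s"]), drop = FALSE])
  )
}

#' @keywords internal
gaussian_mi <- function(C11, C22, C12) {
  joint <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  0.5 * (logdet_spd(C11) + logdet_spd(C22) - logdet_spd(joint))
}

#' Data-processing inequality for the most-likely-internal parameterisation
#'
#' Newer formulations parameterise beliefs by `lambda_bar(s, a)`, the most
#' likely internal coordinate given the blanket — for Gaussians the
#' conditional mean, an affine map `lambda_bar = B (s, a)`. Since
#' `Lambda -> (S, A) -> Lambda_bar` is a Markov chain, the mutual information
#' `I(Lambda; Lambda_bar)` cannot exceed `I(Lambda; (S, A))`. Both are
#' computed in closed form from the stationary Gaussian.
#'
#' @param system an [ou_system()].
#' @return list with the gain `B`, `I_lambda_bar = I(Lambda; Lambda_bar)`,
#'   `I_lambda_sa = I(Lambda; (S, A))`, the `margin` of the inequality and
#'   the verdict `dpi_holds`.
#' @export
dpi_check <- function(system) {
  system <- with_stationary(system)
  p <- system$partition
  C <- system_covariance(system)
  zi <- block_idx(p, c("s", "a"))
  li <- p$idx$lambda
  Czz <- C[zi, zi, drop = FALSE]
  Cll <- C[li, li, drop = FALSE]
  Clz <- C[li, zi, drop = FALSE]
  B <- Clz %*% solve(Czz)
  I_sa <- gaussian_mi(Cll, Czz, Clz)
  if (maxabs(B) < 1e-12) {
    I_bar <- 0
  } else {
    Sww <- B %*% Czz %*% t(B)
    Slw <- Clz %*% t(B)
    ev <- eigen((Sww + t(Sww)) / 2, symmetric = TRUE)
    keep <- ev$values > 1e-12 * max(ev$values, 1)
    if (!any(keep)) {
      I_bar <- 0
    } else {
      Tm <- ev$vectors[, keep, drop = FALSE]
      I_bar <- gaussian_mi(Cll, t(Tm) %*% Sww %*% Tm, Slw %*% Tm)
    }
  }
  margin <- I_sa - I_bar
  list(B = B, I_lambda_bar = I_bar, I_lambda_sa = I_sa,
       margin = margin, dpi_holds = margin >= -1e-10)
}
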