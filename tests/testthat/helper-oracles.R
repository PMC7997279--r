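# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature instead of closed forms, full-matrix
# inversion instead of block algebra, sampling instead of Lyapunov solves.

# KL divergence between two 1-d Gaussians by numeric quadrature of
# q ln(q / p).
kl_quadrature_1d <- function(mu_q, s2_q, mu_p, s2_p) {
  f <- function(x) {
    q <- stats::dnorm(x, mu_q, sqrt(s2_q))
    p <- stats::dnorm(x, mu_p, sqrt(s2_p))
    ifelse(q > 0, q * (log(q) - log(p)), 0)
  }
  stats::integrate(f, mu_q - 12 * sqrt(s2_q), mu_q + 12 * sqrt(s2_q),
                   rel.tol = 1e-10)$value
}

# Conditional of a zero-mean Gaussian by the covariance (Schur) route:
# full inversion of U, no block shortcuts.
brute_conditional <- function(U, target_idx, given_idx) {
  C <- solve(U)
  Ctt <- C[target_idx, target_idx, drop = FALSE]
  Ctg <- C[target_idx, given_idx, drop = FALSE]
  Cgg <- C[given_idx, given_idx, drop = FALSE]
  list(
    Sigma = Ctt - Ctg %*% solve(Cgg) %*% t(Ctg),
    gain = Ctg %*% solve(Cgg)
  )
}

# Random SPD matrix with eigenvalues bounded away from zero.
random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d, d)
  crossprod(A) + diag(d) * 0.5
}

random_antisym <- function(d) {
  A <- matrix(stats::runif(d * d, -1, 1), d, d)
  (A - t(A)) / 2
}

# SPD block-diagonal Gamma for a partition.
random_block_diag_spd <- function(partition) {
  G <- matrix(0, partition$d, partition$d)
  for (b in c("psi", "s", "a", "lambda")) {
    idx <- partition$idx[[b]]
    G[idx, idx] <- random_spd(length(idx))
  }
  G
}

# A random assembled system on a random small partition (seeded by caller).
random_assembled_system <- function(partition = NULL, identity_gamma = FALSE) {
  if (is.null(partition)) {
    sizes <- sample(1:3, 4, replace = TRUE)
    partition <- coordinate_partition(sizes[1], sizes[2], sizes[3], sizes[4])
  }
  d <- partition$d
  Gamma <- if (identity_gamma) diag(d) else random_block_diag_spd(partition)
  assemble_from_potential(random_spd(d), random_antisym(d), Gamma, partition)
}

# Monte-Carlo mutual information between two jointly Gaussian vectors,
# using exact log-densities on sampled points.
mc_mutual_information <- function(C11, C22, C12, n = 2e5, seed = 1) {
  joint <- rbind(cbind(C11, C12), cbind(t(C12), C22))
  d1 <- nrow(C11); d <- nrow(joint)
  L <- t(chol(joint))
  ld <- function(S) as.numeric(determinant(S, logarithm = TRUE)$modulus)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  X <- L %*% matrix(stats::rnorm(d * n), d, n)
  lp_joint <- -0.5 * colSums(X * solve(joint, X)) - 0.5 * ld(joint)
  X1 <- X[seq_len(d1), , drop = FALSE]
  X2 <- X[(d1 + 1):d, , drop = FALSE]
  lp1 <- -0.5 * colSums(X1 * solve(C11, X1)) - 0.5 * ld(C11)
  lp2 <- -0.5 * colSums(X2 * solve(C22, X2)) - 0.5 * ld(C22)
  vals <- lp_joint - lp1 - lp2
  list(estimate = mean(vals), se = stats::sd(vals) / sqrt(n))
}

relerr <- function(x, ref) {
  nref <- sqrt(sum(ref^2))
  if (nref == 0) sqrt(sum(x^2)) else sqrt(sum(x^2)) / nref
}

p1111 <- coordinate_partition(1, 1, 1, 1)
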