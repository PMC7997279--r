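#' Euler-Maruyama simulation of a linear system
#'
#' Integrates `dx = M x dt + dW`, noise autocovariance `2 Gamma dt` per step
#' (`x <- x + M x dt + sqrt(2 dt) L xi`, `L L' = Gamma`, `xi` standard
#' normal). A stability guard requires `dt < 0.5 / max |eig(M)|`; the
#' trajectory is rejected if its norm overflows. Deterministic given the
#' seed; the global RNG state is restored.
#'
#' @param system an [ou_system()].
#' @param n_steps number of retained steps after burn-in (at least `1e4`).
#' @param dt time step.
#' @param seed integer seed.
#' @param burn_in steps discarded before statistics are collected.
#' @return an object of class `trajectory_summary`: `n_steps`, `dt`, `seed`,
#'   empirical `mean` and `cov`, per-coordinate autocorrelation-corrected
#'   effective sample sizes `ess` and their minimum `ess_min`.
#' @export
simulate_em <- function(system, n_steps = 2e5, dt = 0.01, seed = 0,
                        burn_in = 2000) {
  M <- system$M
  d <- nrow(M)
  ev_max <- max(Mod(eigen(M, only.values = TRUE)$values))
  if (dt >= 0.5 / ev_max) {
    abort_blanket(
      sprintf("dt = %g fails the stability guard dt < 0.5/max|eig(M)| = %g",
              dt, 0.5 / ev_max),
      "stability_error"
    )
  }
  if (n_steps < 1e4) {
    abort_blanket("n_steps after burn-in must be at least 1e4", "stability_error")
  }
  L <- t(chol(system$Gamma))
  step_M <- diag(d) + M * dt
  noise_scale <- sqrt(2 * dt)
  total <- burn_in + n_steps
  X <- local_seed(seed, {
    xi <- matrix(stats::rnorm(total * d), d, total)
    X <- matrix(0, d, n_steps)
    x <- rep(0, d)
    overflow <- 1e8 * max(1, sqrt(sum(diag(solve(system$U %||% diag(d))))))
    for (t in seq_len(total)) {
      x <- step_M %*% x + noise_scale * (L %*% xi[, t])
      if (max(abs(x)) > overflow) {
        abort_blanket("trajectory norm overflow: integration unstable",
                      "stability_error")
      }
      if (t > burn_in) X[, t - burn_in] <- x
    }
    X
  })
  emp_mean <- rowMeans(X)
  Xc <- X - emp_mean
  emp_cov <- tcrossprod(Xc) / (n_steps - 1)
  ess <- vapply(seq_len(d), function(i) {
    ac <- stats::acf(X[i, ], lag.max = min(1000, n_steps %/% 10),
                     plot = FALSE, demean = TRUE)$acf[-1]
    pos <- which(ac < 0.01)
    cut <- if (length(pos)) pos[1] else length(ac)
    n_steps / (1 + 2 * sum(ac[seq_len(cut)]))
  }, numeric(1))
  structure(
    list(n_steps = n_steps, dt = dt, seed = seed, mean = emp_mean,
         cov = emp_cov, ess = ess, ess_min = min(ess)),
    class = "trajectory_summary"
  )
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare empirical and analytic stationary covariance
#'
#' Element-wise z-scores of the simulated covariance against the analytic
#' one, with Gaussian standard errors `sqrt((C_ii C_jj + C_ij^2) / ESS)`
#' using the autocorrelation-corrected effective sample size. Passes when
#' every `|z| < 4`.
#'
#' @param summary a [simulate_em()] result.
#' @param stationary a [stationary_gaussian()] (analytic reference).
#' @return list with the `z` matrix, `max_abs_z` and `pass`.
#' @export
validate_empirical <- function(summary, stationary) {
  C <- stationary$C
  if (!all(dim(summary$cov) == dim(C))) {
    abort_blanket("summary and stationary density have different dimensions",
                  "dimension_error")
  }
  ess <- pmin(outer(summary$ess, summary$ess, pmin), summary$n_steps)
  se <- sqrt((outer(diag(C), diag(C)) + C^2) / ess)
  z <- (summary$cov - C) / se
  list(z = z, max_abs_z = maxabs(z), pass = maxabs(z) < 4)
}

#' Empirical partial correlation between two blocks given others
#'
#' Computed from the empirical covariance via the precision matrix; for
#' scalar blocks this is `-P_ij / sqrt(P_ii P_jj)`. The standard error is
#' approximately `1 / sqrt(ESS)`.
#'
#' @param summary a [simulate_em()] result.
#' @param partition the system's [coordinate_partition()].
#' @param block_i,block_j single-coordinate blocks to correlate.
#' @return list with `pcor`, `se` and `z = pcor / se` (for scalar blocks).
#' @export
empirical_partial_correlation <- function(summary, partition,
                                          block_i = "psi", block_j = "lambda") {
  P <- solve(summary$cov)
  i <- block_idx(partition, block_i)
  j <- block_idx(partition, block_j)
  pc <- -P[i, j] / sqrt(outer(diag(P)[i], diag(P)[j]))
  se <- 1 / sqrt(summary$ess_min)
  list(pcor = pc, se = se, z = pc / se)
}

#' Monte-Carlo estimate of the Gaussian KL divergence
#'
#' Estimates `KL[q || p*(Psi|s,a,lambda)]` at a point as the sample mean of
#' `ln q(psi) - ln p(psi)` over draws from `q` — an independent stochastic
#' check of the closed form in [gaussian_kl()].
#'
#' @param q a [variational_gaussian()].
#' @param cond a `gaussian_conditional` (see [posterior_conditional()]).
#' @param point numeric vector `(s, a, lambda)`.
#' @param n_samples at least `1e3`.
#' @param seed integer seed.
#' @return list with `estimate` and `se`.
#' @export
mc_kl_estimate <- function(q, cond, point, n_samples = 1e5, seed = 0) {
  if (n_samples < 1e3) {
    abort_blanket("n_samples must be at least 1e3", "stability_error")
  }
  mu_q <- q_mean_at(q, point)
  mu_c <- as.numeric(cond$K %*% point)
  n_psi <- length(mu_q)
  Lq <- t(chol(q$S))
  ldS <- logdet_spd(q$S)
  ldP <- logdet_spd(cond$P)
  vals <- local_seed(seed, {
    Z <- matrix(stats::rnorm(n_samples * n_psi), n_psi, n_samples)
    X <- mu_q + Lq %*% Z
    dq <- X - mu_q
    dp <- X - mu_c
    lq <- -0.5 * colSums(dq * solve(q$S, dq)) - 0.5 * ldS
    lp <- -0.5 * colSums(dp * (cond$P %*% dp)) + 0.5 * ldP
    lq - lp
  })
  list(estimate = mean(vals), se = stats::sd(vals) / sqrt(n_samples))
}
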