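test_that("simulated covariance matches the analytic stationary density", {
  sys <- assemble_from_potential(diag(4), matrix(0, 4, 4), diag(4), p1111)
  summ <- simulate_em(sys, n_steps = 4e4, dt = 0.01, seed = 1)
  val <- validate_empirical(summ, stationary_gaussian(sys$U))
  expect_true(val$pass)
  expect_identical(simulate_em(sys, n_steps = 4e4, dt = 0.01, seed = 1)$cov,
                   summ$cov)
  expect_lte(summ$ess_min, summ$n_steps)
})

test_that("covariance scales linearly in the diffusion matrix", {
  p <- p1111
  M <- -diag(4)
  sys1 <- with_stationary(ou_system(M, diag(4), p))
  sys4 <- with_stationary(ou_system(M, 4 * diag(4), p))
  expect_equal(solve(sys4$U), 4 * solve(sys1$U), tolerance = 1e-10)
  summ4 <- simulate_em(sys4, n_steps = 4e4, dt = 0.01, seed = 2)
  expect_true(validate_empirical(summ4, stationary_gaussian(sys4$U))$pass)
  # against the unscaled analytic density the fit must fail loudly
  expect_gt(validate_empirical(summ4, stationary_gaussian(sys1$U))$max_abs_z, 10)
})

test_that("the simulated density pins the noise normalisation", {
  # empirical covariance matches U^-1, not (2U)^-1 or (U/2)^-1
  sys <- generate_system(constraint_spec(p1111, seed = 5))
  summ <- simulate_em(sys, n_steps = 6e4, dt = 0.005, seed = 3)
  expect_true(validate_empirical(summ, stationary_gaussian(sys$U))$pass)
  expect_gt(validate_empirical(summ, stationary_gaussian(2 * sys$U))$max_abs_z, 10)
  expect_gt(validate_empirical(summ, stationary_gaussian(sys$U / 2))$max_abs_z, 10)
})

test_that("stability guards reject unusable step sizes and lengths", {
  sys <- assemble_from_potential(diag(4) * 10, matrix(0, 4, 4), diag(4), p1111)
  expect_error(simulate_em(sys, n_steps = 2e4, dt = 0.1, seed = 0),
               class = "stability_error")
  expect_error(simulate_em(sys, n_steps = 100, dt = 0.001, seed = 0),
               class = "stability_error")
  sys_ok <- assemble_from_potential(diag(4), matrix(0, 4, 4), diag(4), p1111)
  expect_error(validate_empirical(
    simulate_em(sys_ok, n_steps = 1e4, dt = 0.01, seed = 0),
    stationary_gaussian(diag(2))
  ), class = "dimension_error")
})

test_that("empirical partial correlation separates the blanket conditions", {
  # conditional independence given (s, a) on a Condition-2 system
  sys2 <- generate_system(constraint_spec(
    p1111, U_zero = list(c("psi", "lambda")), seed = 1
  ))
  summ2 <- simulate_em(sys2, n_steps = 1e5, dt = 0.01, seed = 4)
  pc2 <- empirical_partial_correlation(summ2, sys2$partition)
  expect_lt(abs(pc2$z), 4)
  # a drift-pattern-only system leaks dependence into the stationary density;
  # use a draw whose analytic partial correlation is away from the borderline
  sys1 <- NULL
  for (seed in 0:9) {
    cand <- generate_counterexample("obs1_forward", seed = seed)$system
    U <- cand$U
    pc_true <- -U[1, 4] / sqrt(U[1, 1] * U[4, 4])
    if (abs(pc_true) > 0.1) { sys1 <- cand; break }
  }
  summ1 <- simulate_em(sys1, n_steps = 1e5, dt = 0.01, seed = 4)
  pc1 <- empirical_partial_correlation(summ1, sys1$partition)
  expect_gt(abs(pc1$z), 4)
})

test_that("Monte-Carlo KL estimates agree with the closed form", {
  sys <- assemble_from_potential(diag(4), matrix(0, 4, 4), diag(4), p1111)
  cond <- posterior_conditional(sys)
  y <- c(0.3, -0.2, 0.5)
  # q equal to the conditional: estimate consistent with zero
  q_eq <- variational_gaussian(matrix(0), 0, matrix(1), p1111)
  est0 <- mc_kl_estimate(q_eq, cond, rep(0, 3), n_samples = 2e4, seed = 5)
  expect_lt(abs(est0$estimate), 3 * max(est0$se, 1e-12))
  # the variance-mismatch worked value (4 - 1 - ln 4)/2
  q4 <- variational_gaussian(matrix(0), 0, matrix(4), p1111)
  est4 <- mc_kl_estimate(q4, cond, y, n_samples = 5e4, seed = 6)
  expect_lt(abs(est4$estimate - 0.5 * (4 - 1 - log(4))), 3 * est4$se)
  # a supremum-probe witness
  cert <- generate_counterexample("obs5", seed = 0)
  rep <- lemma_feasibility(cert$system, "29,30")
  probe <- kl_supremum_probe(cert$system, rep, 10)
  cond5 <- posterior_conditional(cert$system)
  est_w <- mc_kl_estimate(probe$q, cond5, probe$point, n_samples = 5e4, seed = 7)
  expect_lt(abs(est_w$estimate - probe$kl), 3 * est_w$se)
  expect_error(mc_kl_estimate(q4, cond, y, n_samples = 10, seed = 0),
               class = "stability_error")
})
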