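test_that("Gaussian KL closed form matches quadrature and hand values", {
  set.seed(37)
  sys <- random_assembled_system(p1111, identity_gamma = TRUE)
  cond <- posterior_conditional(sys)
  y <- runif(3, -1, 1)
  # q equal to the conditional at every point: divergence zero
  q_eq <- variational_gaussian(cond$K[, 3, drop = FALSE],
                               as.numeric(cond$K[, 1:2] %*% y[1:2]),
                               cond$Sigma, p1111)
  expect_equal(gaussian_kl(q_eq, cond, y), 0, tolerance = 1e-12)

  # variance-mismatch case, against 1-d numeric quadrature
  sys_i <- assemble_from_potential(diag(4), matrix(0, 4, 4), diag(4), p1111)
  cond_i <- posterior_conditional(sys_i)
  q4 <- variational_gaussian(matrix(0), 0, matrix(4), p1111)
  kl <- gaussian_kl(q4, cond_i, rep(0, 3))
  expect_equal(kl, 0.5 * (4 - 1 - log(4)), tolerance = 1e-12)
  expect_equal(kl, kl_quadrature_1d(0, 4, 0, 1), tolerance = 1e-7)

  # mean mismatch d with identity covariances: KL = |d|^2 / 2
  q_shift <- variational_gaussian(matrix(0), 2, matrix(1), p1111)
  expect_equal(gaussian_kl(q_shift, cond_i, rep(0, 3)), 2, tolerance = 1e-12)
  expect_equal(kl_quadrature_1d(2, 1, 0, 1), 2, tolerance = 1e-7)
})

test_that("free energy decomposes into negative log marginal plus divergence", {
  sys <- assemble_from_potential(diag(4), matrix(0, 4, 4), diag(4), p1111)
  cond <- posterior_conditional(sys)
  q_std <- variational_gaussian(matrix(0), 0, matrix(1), p1111)
  # at the origin of a standard 4-d Gaussian with scalar external block:
  # q equals the conditional, so F = -ln p*(0,0,0) of a standard 3-d Gaussian
  expect_equal(free_energy(sys, q_std, rep(0, 3)), 1.5 * log(2 * pi),
               tolerance = 1e-12)
  set.seed(41)
  sys2 <- random_assembled_system(p1111, identity_gamma = TRUE)
  cond2 <- posterior_conditional(sys2)
  q2 <- variational_gaussian(matrix(0.3), -0.2, matrix(0.7), p1111)
  for (k in 1:5) {
    y <- runif(3, -2, 2)
    V <- marginal_precision(stationary_gaussian(sys2$U)$C, p1111,
                            c("s", "a", "lambda"))
    nlm <- 0.5 * sum(y * (V %*% y)) +
      0.5 * (3 * log(2 * pi) - as.numeric(determinant(V, TRUE)$modulus))
    expect_equal(free_energy(sys2, q2, y) - gaussian_kl(q2, cond2, y), nlm,
                 tolerance = 1e-10)
  }
})

test_that("KL gradient maps match a finite-difference oracle", {
  set.seed(43)
  sys <- random_assembled_system(p1111, identity_gamma = TRUE)
  cond <- posterior_conditional(sys)
  q <- variational_gaussian(matrix(0.8), 0.4, matrix(1.3), p1111)
  maps <- kl_gradient_maps(sys, q)
  h <- 1e-6
  for (k in 1:5) {
    y <- runif(3, -1, 1)
    num_grad <- vapply(1:3, function(i) {
      e <- replace(rep(0, 3), i, h)
      (gaussian_kl(q, cond, y + e) - gaussian_kl(q, cond, y - e)) / (2 * h)
    }, numeric(1))
    exact <- as.numeric(maps$full_coef %*% y + maps$full_const)
    expect_equal(exact, num_grad, tolerance = 1e-5)
  }
})

test_that("vanishing-gradient structure of the chain counterexample class", {
  cert <- generate_counterexample("obs5", seed = 0)
  sys <- cert$system
  cond <- posterior_conditional(sys)
  # A = 0: both constrained gradients vanish, the s-dependence remains
  q0 <- variational_gaussian(matrix(0), 0, cond$Sigma, p1111)
  maps <- kl_gradient_maps(sys, q0)
  expect_true(maps$a$vanishes)
  expect_true(maps$lambda$vanishes)
  expect_gt(maxabs(maps$full_coef[1, ]), 1e-3) # s row
  # generic A != 0 breaks the lambda gradient with coefficient A' P A
  qA <- variational_gaussian(matrix(0.7), 0, cond$Sigma, p1111)
  mapsA <- kl_gradient_maps(sys, qA)
  expect_false(mapsA$lambda$vanishes)
  expect_equal(mapsA$lambda$coef[1, 3], 0.7 * cond$P[1, 1] * 0.7,
               tolerance = 1e-10)
})

test_that("lemma feasibility separates the counterexample classes", {
  # strongest case: external block independent of the blanket entirely
  sys_ind <- generate_system(constraint_spec(
    p1111, U_zero = list(c("psi", "s"), c("psi", "a"), c("psi", "lambda"),
                         c("s", "lambda")),
    R_zero = utils::combn(c("psi", "s", "a", "lambda"), 2, simplify = FALSE),
    seed = 5
  ))
  rep_ind <- lemma_feasibility(sys_ind, "29,30")
  expect_true(rep_ind$feasible)
  cond_ind <- posterior_conditional(sys_ind)
  for (k in 1:5) {
    y <- runif(3, -2, 2)
    expect_equal(gaussian_kl(rep_ind$witness, cond_ind, y), 0, tolerance = 1e-10)
  }

  cert5 <- generate_counterexample("obs5", seed = 0)
  rep5 <- lemma_feasibility(cert5$system, "29,30")
  expect_true(rep5$feasible)
  expect_lt(maxabs(rep5$A), 1e-10)
  expect_equal(rep5$solution_nullity, 0)
  expect_true(rep5$S_unconstrained)

  cert4 <- generate_counterexample("obs4", seed = 0)
  rep4 <- lemma_feasibility(cert4$system, "29,30")
  expect_true(rep4$applicable)
  expect_equal(rep4$verdict, "infeasible")
  expect_gt(rep4$residual, 1e-2)

  # nullspace dimensions are trivial for SPD Gamma
  expect_equal(rep5$nullspace_dim_aa, 0)
  expect_equal(rep5$nullspace_dim_ll, 0)

  # prerequisite gating: the diagonal rewriting fails on obs2 systems
  cert2 <- generate_counterexample("obs2", seed = 0)
  expect_false(lemma_feasibility(cert2$system, "29,30")$applicable)
})

test_that("no KL bound can be guaranteed for feasible variational densities", {
  cert <- generate_counterexample("obs5", seed = 0)
  rep <- lemma_feasibility(cert$system, "29,30")
  cond <- posterior_conditional(cert$system)
  for (c_thr in c(0, 10, 1e3, 1e6)) {
    probe <- kl_supremum_probe(cert$system, rep, c_thr)
    expect_gt(probe$kl, c_thr)
    expect_lt(probe$gradient_maxabs, 1e-8)
    # the witness is not the conditional: its mean ignores s while the
    # conditional mean depends on it
    expect_gt(probe$posterior_s_gain, 1e-3)
    expect_equal(gaussian_kl(probe$q, cond, probe$point), probe$kl)
  }
  # scale follows t ~ 2c/n for large thresholds
  probe6 <- kl_supremum_probe(cert$system, rep, 1e6)
  expect_equal(probe6$t, 2e6, tolerance = 0.01)
  cert4 <- generate_counterexample("obs4", seed = 0)
  rep4 <- lemma_feasibility(cert4$system, "29,30")
  expect_error(kl_supremum_probe(cert4$system, rep4, 10),
               class = "infeasible_error")
})

test_that("feasible divergences on chain systems vary with s only", {
  cert <- generate_counterexample("obs5", seed = 1)
  rep <- lemma_feasibility(cert$system, "29,30")
  cond <- posterior_conditional(cert$system)
  q <- rep$witness
  base <- gaussian_kl(q, cond, c(0.5, 0, 0))
  # constant in (a, lambda)
  expect_equal(gaussian_kl(q, cond, c(0.5, 2, 0)), base, tolerance = 1e-10)
  expect_equal(gaussian_kl(q, cond, c(0.5, 0, -3)), base, tolerance = 1e-10)
  # non-constant in s
  expect_gt(abs(gaussian_kl(q, cond, c(2, 0, 0)) - base), 1e-3)
})

test_that("equality with an (s,a)-independent conditional makes every family feasible", {
  # when the conditional itself does not depend on (s, a), setting q equal to
  # it drives the divergence to zero identically and all gradient maps vanish
  sys <- generate_system(constraint_spec(
    p1111, U_zero = list(c("psi", "s"), c("psi", "a")),
    R_zero = utils::combn(c("psi", "s", "a", "lambda"), 2, simplify = FALSE),
    seed = 9
  ))
  cond <- posterior_conditional(sys)
  expect_lt(maxabs(cond$K[, 1:2]), 1e-10)
  q <- variational_gaussian(cond$K[, 3, drop = FALSE], 0, cond$Sigma, p1111)
  maps <- kl_gradient_maps(sys, q)
  expect_true(maps$a$vanishes && maps$lambda$vanishes)
  for (fam in c("29,30", "37,38", "39,40")) {
    rep <- lemma_feasibility(sys, fam)
    if (isTRUE(rep$applicable)) expect_true(rep$feasible)
  }
})

test_that("Gibbs inequality holds across random variational densities", {
  set.seed(47)
  for (k in 1:20) {
    sys <- random_assembled_system(p1111, identity_gamma = TRUE)
    cond <- posterior_conditional(sys)
    q <- variational_gaussian(matrix(runif(1, -2, 2)), runif(1, -2, 2),
                              matrix(runif(1, 0.1, 5)), p1111)
    y <- runif(3, -3, 3)
    expect_gte(gaussian_kl(q, cond, y), 0)
  }
})

test_that("data processing inequality for the most-likely-internal parameterisation", {
  # internal block independent of the blanket: both informations vanish
  sys0 <- generate_system(constraint_spec(
    p1111, U_zero = list(c("lambda", "s"), c("lambda", "a"),
                         c("lambda", "psi")),
    seed = 3
  ))
  rep0 <- dpi_check(sys0)
  expect_equal(rep0$I_lambda_bar, 0, tolerance = 1e-8)
  expect_equal(rep0$I_lambda_sa, 0, tolerance = 1e-8)

  for (seed in 1:10) {
    sys <- generate_system(constraint_spec(
      p1111, U_zero = list(c("psi", "lambda")), seed = seed
    ))
    rep <- dpi_check(sys)
    expect_gte(rep$I_lambda_bar, -1e-10)
    expect_true(rep$dpi_holds)
  }

  # Monte-Carlo cross-check of both closed-form informations
  sys <- generate_system(constraint_spec(
    p1111, U_zero = list(c("psi", "lambda")), seed = 2
  ))
  rep <- dpi_check(sys)
  C <- solve(sys$U)
  li <- 4L; zi <- 2:3
  mc1 <- mc_mutual_information(C[li, li, drop = FALSE], C[zi, zi],
                               C[li, zi, drop = FALSE])
  expect_lt(abs(mc1$estimate - rep$I_lambda_sa), 3 * mc1$se)
  # lambda_bar = B z: its joint with lambda by explicit change of variables
  B <- rep$B
  Sww <- B %*% C[zi, zi] %*% t(B)
  Slw <- C[li, zi, drop = FALSE] %*% t(B)
  mc2 <- mc_mutual_information(C[li, li, drop = FALSE], Sww, Slw)
  expect_lt(abs(mc2$estimate - rep$I_lambda_bar), 3 * mc2$se)
})
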