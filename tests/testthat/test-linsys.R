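M_rot <- matrix(c(-1, -1, 1, -1), 2, 2) # drift with solenoidal circulation

test_that("solenoidal solve reproduces known solutions and guards", {
  # symmetric drift: right-hand side vanishes exactly
  expect_equal(solve_solenoidal(-diag(2), diag(2)), matrix(0, 2, 2))
  # circulating drift: R is the quarter-turn generator
  R <- solve_solenoidal(M_rot, diag(2))
  expect_equal(R, matrix(c(0, 1, -1, 0), 2, 2), tolerance = 1e-12)
  # both sides of the defining equation agree
  expect_equal(M_rot %*% R + R %*% t(M_rot),
               M_rot - t(M_rot), tolerance = 1e-12)
  # purely imaginary spectrum: lambda_i + lambda_j = 0
  expect_error(solve_solenoidal(matrix(c(0, -1, 1, 0), 2, 2), diag(2)),
               class = "solvability_error")
})

test_that("Lyapunov covariance matches closed forms", {
  expect_equal(lyapunov_covariance(-diag(3), diag(3)), diag(3))
  # 1-d: C = gamma / m
  expect_equal(lyapunov_covariance(matrix(-2), matrix(1)), matrix(0.5))
  expect_equal(lyapunov_covariance(M_rot, diag(2)), diag(2), tolerance = 1e-12)
  expect_error(lyapunov_covariance(diag(2), diag(2)), class = "non_ergodic_error")
})

test_that("potential-form precision agrees with the Lyapunov route", {
  sg <- stationary_precision(-diag(2), diag(2), matrix(0, 2, 2))
  expect_equal(sg$U, diag(2))
  R <- matrix(c(0, 1, -1, 0), 2, 2)
  expect_equal(stationary_precision(M_rot, diag(2), R)$U, diag(2),
               tolerance = 1e-10)
  expect_equal(stationary_precision(matrix(-2), matrix(1), matrix(0))$U,
               matrix(2))
})

test_that("assembly from a potential inverts the decomposition", {
  p2 <- coordinate_partition(1, 1, 1, 1)
  sys <- assemble_from_potential(diag(4), matrix(0, 4, 4), diag(4), p2)
  expect_equal(sys$M, -diag(4))
  expect_error(
    assemble_from_potential(diag(c(1, 1, 1, 0)), matrix(0, 4, 4), diag(4), p2),
    class = "not_spd_error"
  )
  expect_error(
    assemble_from_potential(diag(4), diag(c(1, 0, 0, 0)), diag(4), p2),
    class = "asymmetry_error"
  )
})

test_that("assemble -> decompose round-trips U and R on random systems", {
  set.seed(7)
  for (k in 1:25) {
    sys <- random_assembled_system()
    R2 <- solve_solenoidal(sys$M, sys$Gamma)
    # antisymmetry of the derived solenoidal matrix
    expect_lt(maxabs(R2 + t(R2)) / max(maxabs(R2), 1e-300), 1e-10)
    expect_lt(relerr(R2 - sys$R, sys$R), 1e-8)
    sg <- stationary_precision(sys$M, sys$Gamma, R2)
    expect_lt(relerr(sg$U - sys$U, sys$U), 1e-8)
    # Lyapunov / potential-form equivalence
    expect_lt(relerr(solve(sg$U) - sg$C, sg$C), 1e-8)
  }
})

test_that("conditional distributions match the brute-force covariance route", {
  p2 <- coordinate_partition(1, 1, 1, 1)
  cond <- conditional_gaussian(diag(4), p2, "psi", c("s", "a", "lambda"))
  expect_equal(cond$P, diag(1))
  expect_equal(maxabs(cond$K), 0)

  # d = 2 worked example embedded as the (a, lambda) pair of a 4-d system
  U2 <- matrix(c(2, 1, 1, 2), 2, 2)
  oracle <- brute_conditional(U2, 1, 2)
  expect_equal(oracle$gain, matrix(-0.5))
  expect_equal(oracle$Sigma, matrix(0.5))

  set.seed(11)
  for (k in 1:20) {
    sizes <- sample(1:2, 4, replace = TRUE)
    p <- coordinate_partition(sizes[1], sizes[2], sizes[3], sizes[4])
    U <- random_spd(p$d)
    cond <- conditional_gaussian(U, p, "psi", c("s", "a", "lambda"))
    oracle <- brute_conditional(U, p$idx$psi,
                                unlist(p$idx[c("s", "a", "lambda")]))
    expect_equal(cond$Sigma, oracle$Sigma, tolerance = 1e-10)
    expect_equal(cond$K, oracle$gain, tolerance = 1e-10)
    # marginalised conditional (given s only) against the same oracle
    cond2 <- conditional_gaussian(U, p, "psi", "s")
    keep <- c(p$idx$psi, p$idx$s)
    Um <- solve(solve(U)[keep, keep])
    or2 <- brute_conditional(Um, seq_along(p$idx$psi),
                             length(p$idx$psi) + seq_along(p$idx$s))
    expect_equal(cond2$Sigma, or2$Sigma, tolerance = 1e-10)
    expect_equal(cond2$K, or2$gain, tolerance = 1e-10)
  }
  expect_error(conditional_gaussian(diag(4), p2, "psi", c("psi", "s")),
               class = "block_error")
  expect_error(conditional_gaussian(diag(4), p2, character(0), "s"),
               class = "block_error")
})

test_that("marginal precision equals the Schur complement of the precision", {
  p2 <- coordinate_partition(1, 1, 1, 1)
  expect_equal(marginal_precision(diag(4), p2, c("s", "a")), diag(2))
  # scalar worked example: removing the first coordinate of U=[[2,1],[1,2]]
  C2 <- solve(matrix(c(2, 1, 1, 2), 2, 2))
  expect_equal(solve(C2[2, 2, drop = FALSE]), matrix(1.5))
  set.seed(13)
  for (k in 1:20) {
    sizes <- sample(1:2, 4, replace = TRUE)
    p <- coordinate_partition(sizes[1], sizes[2], sizes[3], sizes[4])
    U <- random_spd(p$d)
    C <- solve(U)
    V <- marginal_precision(C, p, c("s", "a", "lambda"))
    b <- unlist(p$idx[c("s", "a", "lambda")]); r <- p$idx$psi
    schur <- U[b, b] - U[b, r, drop = FALSE] %*%
      solve(U[r, r, drop = FALSE]) %*% U[r, b, drop = FALSE]
    expect_equal(V, schur, tolerance = 1e-9)
    # all four blocks: the marginal is the full density
    expect_equal(marginal_precision(C, p, c("psi", "s", "a", "lambda")), U,
                 tolerance = 1e-9)
  }
})
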