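#' Constraint specification for structured system generation
#'
#' Encodes the zero-block patterns that define the Markov-blanket conditions
#' as data: blocks of `M`, `U` or `R` required to vanish, and blocks required
#' to be genuinely nonzero (norm above the violation threshold `1e-3`, so a
#' sampled system never lands in the ambiguous band between satisfaction and
#' violation).
#'
#' @param partition a [coordinate_partition()].
#' @param M_zero,U_zero,R_zero lists of `c(row_block, col_block)` pairs
#'   required to vanish (symmetric/antisymmetric partners are implied for
#'   `U`/`R`).
#' @param nonzero list of `list(matrix =, rows =, cols =)` requirements.
#' @param seed integer seed; generation is deterministic given it.
#' @param max_attempts resampling budget.
#' @param Gamma diffusion matrix (defaults to the identity).
#' @return an object of class `constraint_spec`.
#' @export
constraint_spec <- function(partition, M_zero = list(), U_zero = list(),
                            R_zero = list(), nonzero = list(), seed = 0,
                            max_attempts = 200, Gamma = diag(partition$d)) {
  canon <- function(pairs) lapply(pairs, function(p) {
    check_blocks(p[1]); check_blocks(p[2]); c(p[1], p[2])
  })
  spec <- structure(
    list(partition = partition, M_zero = canon(M_zero), U_zero = canon(U_zero),
         R_zero = canon(R_zero), nonzero = nonzero, seed = seed,
         max_attempts = max_attempts, Gamma = Gamma),
    class = "constraint_spec"
  )
  # consistency: no block both forced zero and required nonzero
  for (req in nonzero) {
    zeros <- spec[[paste0(req$matrix, "_zero")]]
    for (z in zeros) {
      sym <- req$matrix %in% c("U", "R")
      if ((z[1] == req$rows && z[2] == req$cols) ||
          (sym && z[1] == req$cols && z[2] == req$rows)) {
        abort_blanket(
          sprintf("inconsistent spec: block %s_%s.%s required both zero and nonzero",
                  req$matrix, req$rows, req$cols),
          "generation_error"
        )
      }
    }
  }
  spec
}

# Symmetric matrix with uniform(-1,1) off-diagonal entries and a diagonal
# inflated by +d to favour SPD acceptance without biasing structural zeros.
#' @keywords internal
sample_symmetric_dominant <- function(d) {
  X <- matrix(stats::runif(d * d, -1, 1), d, d)
  X <- (X + t(X)) / 2
  diag(X) <- stats::runif(d, 0, 1) + d
  X
}

#' @keywords internal
sample_antisymmetric <- function(d) {
  X <- matrix(stats::runif(d * d, -1, 1), d, d)
  (X - t(X)) / 2
}

#' @keywords internal
zero_blocks <- function(X, partition, pairs, mirror = FALSE) {
  for (p in pairs) {
    block(X, partition, p[1], p[2]) <- 0
    if (mirror) block(X, partition, p[2], p[1]) <- 0
  }
  X
}

# Free upper-triangular coordinates of a symmetric U honouring U_zero, as a
# list of (i, j) index pairs.
#' @keywords internal
free_sym_coords <- function(partition, U_zero) {
  d <- partition$d
  mask <- matrix(TRUE, d, d)
  mask <- zero_blocks(mask, partition, U_zero, mirror = TRUE)
  which(upper.tri(mask, diag = TRUE) & mask, arr.ind = TRUE)
}

#' @keywords internal
sym_from_coords <- function(u, coords, d) {
  U <- matrix(0, d, d)
  U[coords] <- u
  U[coords[, c(2, 1), drop = FALSE]] <- u
  U
}

#' Sample a system honouring a structural constraint pattern
#'
#' Sampling route: draw an antisymmetric `R` honouring the `R` pattern and a
#' diagonally inflated symmetric candidate `U0` honouring the `U` pattern;
#' where zero blocks of `M = -(Gamma+R) U` are required, project `U0` onto
#' the linear solution set of `[(Gamma+R) U]_block = 0` (R held fixed, so the
#' bilinear problem becomes linear in the free entries of `U`); accept when
#' `U` is positive definite, all required zero blocks hold, and every
#' nonzero requirement clears the violation threshold. Deterministic given
#' the seed.
#'
#' @param spec a [constraint_spec()].
#' @return an [ou_system()] with `R` and `U` attached and an `attempts`
#'   attribute.
#' @export
generate_system <- function(spec) {
  p <- spec$partition
  d <- p$d
  coords <- free_sym_coords(p, spec$U_zero)
  reject <- c(spd = 0L, structure = 0L, nonzero = 0L)
  for (attempt in seq_len(spec$max_attempts)) {
    sys <- local_seed(spec$seed * 10007 + attempt, {
      R <- zero_blocks(sample_antisymmetric(d), p, spec$R_zero, mirror = TRUE)
      U0 <- zero_blocks(sample_symmetric_dominant(d), p, spec$U_zero, mirror = TRUE)
      if (length(spec$M_zero) > 0) {
        u0 <- U0[coords]
        GR <- spec$Gamma + R
        # constraint rows: entries of the required-zero blocks of (Gamma+R) U,
        # as linear functionals of the free entries of U
        Cmat <- vapply(seq_len(nrow(coords)), function(k) {
          Uk <- sym_from_coords(
            replace(numeric(nrow(coords)), k, 1), coords, d
          )
          Mk <- GR %*% Uk
          unlist(lapply(spec$M_zero, function(z) as.numeric(block(Mk, p, z[1], z[2]))))
        }, numeric(sum(vapply(spec$M_zero, function(z) {
          p$n[z[1]] * p$n[z[2]]
        }, numeric(1)))))
        Cmat <- matrix(Cmat, ncol = nrow(coords))
        sv <- svd(Cmat, nu = 0, nv = nrow(coords))
        r <- sum(sv$d > 1e-10 * max(sv$d, 1e-300))
        if (r > 0) {
          Vr <- sv$v[, seq_len(r), drop = FALSE]
          u0 <- u0 - Vr %*% (t(Vr) %*% u0)
        }
        U0 <- sym_from_coords(as.numeric(u0), coords, d)
      }
      list(R = R, U = U0)
    })
    if (min_eigval_sym(sys$U) <= 1e-6) { reject["spd"] <- reject["spd"] + 1L; next }
    M <- -(spec$Gamma + sys$R) %*% sys$U
    ok_struct <- all(vapply(spec$M_zero, function(z) {
      maxabs(block(M, p, z[1], z[2])) < ZERO_TOL
    }, logical(1)))
    if (!ok_struct) { reject["structure"] <- reject["structure"] + 1L; next }
    mats <- list(M = M, U = sys$U, R = sys$R)
    ok_nonzero <- all(vapply(spec$nonzero, function(req) {
      maxabs(block(mats[[req$matrix]], p, req$rows, req$cols)) > VIOLATION_THRESHOLD
    }, logical(1)))
    if (!ok_nonzero) { reject["nonzero"] <- reject["nonzero"] + 1L; next }
    out <- ou_system(M, spec$Gamma, p, R = sys$R, U = sys$U)
    out$C <- solve(sys$U)
    attr(out, "attempts") <- attempt
    attr(out, "rejections") <- reject
    return(out)
  }
  abort_blanket(
    sprintf("generation failed after %d attempts (rejections: SPD %d, structure %d, nonzero %d)",
            spec$max_attempts, reject["spd"], reject["structure"], reject["nonzero"]),
    "generation_error", rejections = reject
  )
}

OBSERVATIONS <- c("obs1_forward", "obs1_reverse", "obs2", "obs4", "obs5")

#' @keywords internal
cond1_zero_pairs <- function() {
  list(c("a", "psi"), c("lambda", "psi"), c("s", "lambda"), c("psi", "lambda"))
}

#' Seeded counterexample generator with a verification certificate
#'
#' Produces a system in one of the counterexample classes together with the
#' reports establishing its claimed properties (re-verified before return;
#' generation resamples until all verdicts are clean of the ambiguous band):
#'
#' * `obs1_forward` — Condition 1 holds, Condition 2 fails: the drift
#'   dependency pattern does not imply conditional independence. Route:
#'   sample `M` with the Condition-1 zero blocks directly, keep Hurwitz
#'   draws, derive `R` and `U`.
#' * `obs1_reverse` — Condition 2 holds, Condition 1 fails: generic
#'   solenoidal coupling with `U_psi.lambda = 0`.
#' * `obs2` — Conditions 1 and 2 both hold, yet the diagonal and
#'   cross-term rewritings (`"19,20"`, `"21,22"`) both fail; only the full
#'   rewriting (`"17,18"`) survives. Route: generic `R` with nonzero
#'   `s`-couplings, `U` solved for the Condition-1 constraint.
#' * `obs4` — Conditions 1-2 hold, the diagonal rewriting `"19,20"` holds,
#'   but no Gaussian-linear variational density satisfies the lemma:
#'   `U_psi.a != 0` (arranged through a compensating `R_psi.a` block) makes
#'   the gradient constraints unsatisfiable.
#' * `obs5` — gradient-flow system (`R = 0`, `Gamma = I`) with `U` zero on
#'   the `psi`-`a`, `psi`-`lambda` and `s`-`lambda` blocks and nonzero on
#'   the chain `psi`-`s`, `s`-`a`, `a`-`lambda`: all conditions and all
#'   rewritings hold, the lemma is feasible with solution set `{A = 0}`,
#'   yet the KL divergence of every feasible `q` from the conditional is
#'   unbounded (it depends on `s`, which `q` cannot see).
#'
#' @param observation one of `"obs1_forward"`, `"obs1_reverse"`, `"obs2"`,
#'   `"obs4"`, `"obs5"`.
#' @param seed integer seed.
#' @param partition block sizes; defaults to the minimal `(1,1,1,1)`.
#' @param max_attempts resampling budget.
#' @return an object of class `counterexample_certificate`: `system`,
#'   `observation`, `seed`, `attempts` and the verifying `reports`.
#' @export
generate_counterexample <- function(observation, seed = 0,
                                    partition = coordinate_partition(1, 1, 1, 1),
                                    max_attempts = 200) {
  observation <- match.arg(observation, OBSERVATIONS)
  gen <- switch(observation,
    obs1_forward = gen_obs1_forward,
    obs1_reverse = gen_obs1_reverse,
    obs2 = gen_obs2,
    obs4 = gen_obs4,
    obs5 = gen_obs5
  )
  gen(seed, partition, max_attempts)
}

#' @keywords internal
certificate <- function(observation, system, reports, seed, attempts) {
  structure(
    list(observation = observation, system = system, reports = reports,
         seed = seed, attempts = attempts),
    class = "counterexample_certificate"
  )
}

#' @export
print.counterexample_certificate <- function(x, ...) {
  cat(sprintf("<counterexample_certificate> %s (seed %d, %d attempt(s), d = %d)\n",
              x$observation, x$seed, x$attempts, x$system$partition$d))
  invisible(x)
}

#' @keywords internal
gen_obs1_forward <- function(seed, partition, max_attempts) {
  d <- partition$d
  Gamma <- diag(d)
  for (attempt in seq_len(max_attempts)) {
    M <- local_seed(seed * 10007 + attempt, {
      zero_blocks(matrix(stats::runif(d * d, -1, 1), d, d),
                  partition, cond1_zero_pairs())
    })
    if (max(Re(eigen(M, only.values = TRUE)$values)) >= HURWITZ_MARGIN) next
    sys <- tryCatch(with_stationary(ou_system(M, Gamma, partition)),
                    blanketlab_error = function(e) NULL)
    if (is.null(sys)) next
    c1 <- check_condition(sys, 1)
    c2 <- check_condition(sys, 2)
    if (c1$max_residual < 1e-12 && c2$violated) {
      return(certificate("obs1_forward", sys,
                         list(condition_1 = c1, condition_2 = c2),
                         seed, attempt))
    }
  }
  abort_blanket("obs1_forward generation failed: no draw violated Condition 2 cleanly",
                "generation_error")
}

#' @keywords internal
gen_obs1_reverse <- function(seed, partition, max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    sys <- generate_system(constraint_spec(
      partition, U_zero = list(c("psi", "lambda")),
      seed = seed * 131 + attempt, max_attempts = 50
    ))
    c1 <- check_condition(sys, 1)
    c2 <- check_condition(sys, 2)
    if (c2$max_residual < 1e-12 && c1$violated) {
      return(certificate("obs1_reverse", sys,
                         list(condition_1 = c1, condition_2 = c2),
                         seed, attempt))
    }
  }
  abort_blanket("obs1_reverse generation failed: no draw violated Condition 1 cleanly",
                "generation_error")
}

#' @keywords internal
gen_obs2 <- function(seed, partition, max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    sys <- tryCatch(generate_system(constraint_spec(
      partition,
      M_zero = cond1_zero_pairs(),
      U_zero = list(c("psi", "lambda")),
      nonzero = list(
        list(matrix = "R", rows = "a", cols = "s"),
        list(matrix = "R", rows = "lambda", cols = "s"),
        list(matrix = "R", rows = "a", cols = "lambda")
      ),
      seed = seed * 131 + attempt, max_attempts = 50
    )), generation_error = function(e) NULL)
    if (is.null(sys)) next
    c1 <- check_condition(sys, 1); c2 <- check_condition(sys, 2)
    ir <- identity_residuals(sys)
    f <- ir$families
    if (c1$satisfied && c2$satisfied &&
        f[["13,14"]]$verdict == "holds" && f[["17,18"]]$verdict == "holds" &&
        f[["19,20"]]$verdict == "fails" && f[["21,22"]]$verdict == "fails") {
      return(certificate("obs2", sys,
                         list(condition_1 = c1, condition_2 = c2, identities = ir),
                         seed, attempt))
    }
  }
  abort_blanket("obs2 generation failed: rewriting verdicts never separated cleanly",
                "generation_error")
}

#' @keywords internal
gen_obs4 <- function(seed, partition, max_attempts) {
  # R couples psi to s and a only: the diagonal rewriting (19,20) then holds
  # exactly, while R_psi.a compensates the Condition-1 constraint so that
  # U_psi.a can stay nonzero -- which makes the lemma's gradient constraints
  # unsatisfiable.
  r_zero <- list(c("s", "a"), c("s", "lambda"), c("a", "lambda"),
                 c("psi", "lambda"))
  attempt_one <- function(part, seed2) {
    sys <- tryCatch(generate_system(constraint_spec(
      part,
      M_zero = cond1_zero_pairs(),
      U_zero = list(c("psi", "lambda")),
      R_zero = r_zero,
      nonzero = list(list(matrix = "U", rows = "psi", cols = "a")),
      seed = seed2, max_attempts = 50
    )), generation_error = function(e) NULL)
    if (is.null(sys)) return(NULL)
    c1 <- check_condition(sys, 1); c2 <- check_condition(sys, 2)
    ir <- identity_residuals(sys)
    lf <- lemma_feasibility(sys, "29,30")
    if (c1$satisfied && c2$satisfied &&
        ir$families[["19,20"]]$verdict == "holds" &&
        isTRUE(lf$applicable) && lf$verdict == "infeasible") {
      return(list(sys = sys, reports = list(
        condition_1 = c1, condition_2 = c2, identities = ir, feasibility = lf
      )))
    }
    NULL
  }
  for (attempt in seq_len(max_attempts)) {
    res <- attempt_one(partition, seed * 131 + attempt)
    if (!is.null(res)) {
      return(certificate("obs4", res$sys, res$reports, seed, attempt))
    }
  }
  # fallback with a larger external block if the constraint solve is
  # degenerate at scalar dimensions
  part2 <- coordinate_partition(2, partition$n["s"], partition$n["a"],
                                partition$n["lambda"])
  for (attempt in seq_len(max_attempts)) {
    res <- attempt_one(part2, seed * 197 + attempt)
    if (!is.null(res)) {
      return(certificate("obs4", res$sys, res$reports, seed, attempt))
    }
  }
  abort_blanket("obs4 generation failed: infeasibility never certified cleanly",
                "generation_error")
}

#' @keywords internal
gen_obs5 <- function(seed, partition, max_attempts) {
  all_pairs <- utils::combn(BLOCKS, 2, simplify = FALSE)
  for (attempt in seq_len(max_attempts)) {
    sys <- tryCatch(generate_system(constraint_spec(
      partition,
      U_zero = list(c("psi", "a"), c("psi", "lambda"), c("s", "lambda")),
      R_zero = all_pairs,
      nonzero = list(
        list(matrix = "U", rows = "psi", cols = "s"),
        list(matrix = "U", rows = "s", cols = "a"),
        list(matrix = "U", rows = "a", cols = "lambda")
      ),
      seed = seed * 131 + attempt, max_attempts = 50
    )), generation_error = function(e) NULL)
    if (is.null(sys)) next
    c1 <- check_condition(sys, 1); c2 <- check_condition(sys, 2)
    ir <- identity_residuals(sys)
    lf <- lemma_feasibility(sys, "29,30")
    verdicts_hold <- all(vapply(ir$families, function(f) f$verdict == "holds",
                                logical(1)))
    if (c1$satisfied && c2$satisfied && verdicts_hold &&
        isTRUE(lf$feasible) && maxabs(lf$A) < ZERO_TOL &&
        lf$solution_nullity == 0) {
      return(certificate("obs5", sys,
                         list(condition_1 = c1, condition_2 = c2,
                              identities = ir, feasibility = lf),
                         seed, attempt))
    }
  }
  abort_blanket("obs5 generation failed: feasible chain system never certified",
                "generation_error")
}
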