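# Zero-block patterns defining the three Markov-blanket conditions, as
# (row, col) block pairs of the matrix each condition constrains.
condition_pattern <- function(condition) {
  switch(as.character(condition),
    "1" = list(matrix = "M", pairs = list(
      c("a", "psi"), c("lambda", "psi"), c("s", "lambda"), c("psi", "lambda")
    )),
    "2" = list(matrix = "U", pairs = list(
      c("psi", "lambda"), c("lambda", "psi")
    )),
    "3" = list(matrix = "R", pairs = list(
      c("psi", "s"), c("psi", "a"), c("psi", "lambda"),
      c("s", "lambda"), c("a", "lambda"),
      c("s", "psi"), c("a", "psi"), c("lambda", "psi"),
      c("lambda", "s"), c("lambda", "a")
    )),
    abort_blanket("condition id must be 1, 2 or 3", "block_error")
  )
}

#' Check one of the three Markov-blanket conditions
#'
#' Condition 1 is the dependency pattern of the drift field: the blocks
#' `M_a.psi`, `M_lambda.psi`, `M_s.lambda`, `M_psi.lambda` vanish (external
#' coordinates do not drive active/internal dynamics directly, and internal
#' coordinates do not drive external/sensory dynamics). Condition 2 is
#' conditional independence of external and internal coordinates given the
#' blanket in the stationary density: `U_psi.lambda = 0` in the precision.
#' Condition 3 is the stronger solenoidal-coupling restriction: the blocks of
#' `R` coupling `(s, a)` to `lambda`, and `psi` to everything but itself,
#' vanish.
#'
#' A condition is *satisfied* when every required block has maximum absolute
#' entry below `tol`, and *violated* only when some block exceeds the
#' well-separated violation threshold `1e-3`; residuals in between are
#' reported as ambiguous.
#'
#' @param system an [ou_system()] (use [with_stationary()] for conditions 2
#'   and 3 if `U`/`R` were not supplied).
#' @param condition 1, 2 or 3.
#' @param tol satisfaction tolerance on block entries.
#' @return an object of class `condition_report`: fields `condition`,
#'   `satisfied`, `violated`, `residuals` (named per block), `max_residual`,
#'   `tol`.
#' @export
check_condition <- function(system, condition, tol = ZERO_TOL) {
  pat <- condition_pattern(condition)
  X <- system[[pat$matrix]]
  if (is.null(X)) {
    abort_blanket(
      sprintf("condition %s needs matrix %s, which is absent (see with_stationary())",
              condition, pat$matrix),
      "missing_matrix_error"
    )
  }
  res <- vapply(pat$pairs, function(p) {
    maxabs(block(X, system$partition, p[1], p[2]))
  }, numeric(1))
  names(res) <- vapply(pat$pairs, function(p) {
    paste0(pat$matrix, "_", p[1], ".", p[2])
  }, character(1))
  structure(
    list(
      condition = as.integer(condition),
      satisfied = all(res < tol),
      violated = any(res > VIOLATION_THRESHOLD),
      residuals = res,
      max_residual = max(res),
      tol = tol
    ),
    class = "condition_report"
  )
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> Condition %d: %s (max residual %.3e, tol %.1e)\n",
              x$condition,
              if (x$satisfied) "satisfied" else if (x$violated) "violated" else "ambiguous",
              x$max_residual, x$tol))
  invisible(x)
}

#' Time-reversal identity relating the drift to its transpose
#'
#' Computes the residual of `M = (Gamma + R) M' (Gamma - R)^-1`, an algebraic
#' consequence of the solenoidal equation. When `Gamma - R` is singular the
#' inverse is replaced by a Moore-Penrose pseudoinverse and a warning flag is
#' attached (unreachable for SPD `Gamma`).
#'
#' @param system an [ou_system()] with `R` available.
#' @return list with `residual` (max-entry norm) and `pseudoinverse_used`.
#' @export
drift_transpose_identity <- function(system) {
  system <- with_stationary(system)
  GmR <- system$Gamma - system$R
  pseudo <- FALSE
  inv <- tryCatch(solve(GmR), error = function(e) NULL)
  if (is.null(inv) || rcond(GmR) < 1e-14) {
    inv <- MASS::ginv(GmR)
    pseudo <- TRUE
  }
  M2 <- (system$Gamma + system$R) %*% t(system$M) %*% inv
  list(residual = maxabs(system$M - M2), pseudoinverse_used = pseudo)
}

#' Chain structure implied by Conditions 1 and 3 together
#'
#' For a system satisfying both Condition 1 (drift dependency pattern) and
#' Condition 3 (solenoidal coupling pattern) with block-diagonal `Gamma`, the
#' time-reversal identity forces `M_lambda.s = 0` and `M_psi.a = 0`: internal
#' coordinates cannot be driven directly by sensory ones, nor external by
#' active ones. The four blocks then interact in a chain
#' `f_psi(psi, s), f_s(psi, s, a), f_a(s, a, lambda), f_lambda(a, lambda)`,
#' which undermines reading `s` and `a` as sensory/active interface
#' coordinates.
#'
#' The implication additionally needs the sensory-active solenoidal coupling
#' to vanish (`R_sa = 0`, an assumption the criticised formulations make
#' alongside Condition 3): with `R_sa != 0` the time-reversal identity mixes
#' the `s` and `a` columns and the conclusion fails. It is therefore checked
#' as a precondition here.
#'
#' @param system an [ou_system()].
#' @param tol residual tolerance for the implied zero blocks.
#' @return an object of class `chain_report`. If a precondition fails the
#'   field `applicable` is `FALSE` and `failed_precondition` names it;
#'   otherwise `residuals` holds `M_lambda.s` and `M_psi.a` block norms,
#'   `holds` their verdict, and `transpose_identity_residual` the
#'   time-reversal identity residual.
#' @export
verify_chain_implication <- function(system, tol = 1e-8) {
  system <- with_stationary(system)
  pre <- list(
    condition_1 = check_condition(system, 1)$satisfied,
    condition_3 = check_condition(system, 3)$satisfied,
    r_sa_zero = maxabs(block(system$R, system$partition, "s", "a")) < ZERO_TOL,
    gamma_block_diagonal = is_block_diagonal(system$Gamma, system$partition)
  )
  if (!all(unlist(pre))) {
    return(structure(
      list(applicable = FALSE,
           failed_precondition = names(pre)[!unlist(pre)][1]),
      class = "chain_report"
    ))
  }
  res <- c(
    M_lambda.s = maxabs(block(system$M, system$partition, "lambda", "s")),
    M_psi.a = maxabs(block(system$M, system$partition, "psi", "a"))
  )
  ti <- drift_transpose_identity(system)
  structure(
    list(applicable = TRUE,
         residuals = res,
         holds = all(res < tol),
         tol = tol,
         transpose_identity_residual = ti$residual,
         pseudoinverse_used = ti$pseudoinverse_used),
    class = "chain_report"
  )
}

#' @export
print.chain_report <- function(x, ...) {
  if (!x$applicable) {
    cat(sprintf("<chain_report> not applicable (failed precondition: %s)\n",
                x$failed_precondition))
  } else {
    cat(sprintf("<chain_report> chain structure %s (max residual %.3e)\n",
                if (x$holds) "holds" else "VIOLATED", max(x$residuals)))
  }
  invisible(x)
}
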