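IDENTITY_FAMILIES <- c("13,14", "17,18", "19,20", "21,22")

# Coefficient operator W mapping grad ln p*(s,a,lambda) to (f_a, f_lambda)
# for the three marginalised rewriting families. Rows: (a, lambda) blocks;
# columns: (s, a, lambda) blocks.
#' @keywords internal
family_operator <- function(system, family) {
  p <- system$partition
  G <- system$Gamma; R <- system$R
  n_s <- p$n["s"]; n_a <- p$n["a"]; n_l <- p$n["lambda"]
  Z_as <- matrix(0, n_a, n_s); Z_ls <- matrix(0, n_l, n_s)
  Z_al <- matrix(0, n_a, n_l); Z_la <- matrix(0, n_l, n_a)
  Daa <- block(G, p, "a") + block(R, p, "a")
  Dll <- block(G, p, "lambda") + block(R, p, "lambda")
  switch(family,
    "17,18" = rbind(
      cbind(block(R, p, "a", "s"), Daa, block(R, p, "a", "lambda")),
      cbind(block(R, p, "lambda", "s"), block(R, p, "lambda", "a"), Dll)
    ),
    "19,20" = rbind(
      cbind(Z_as, Daa, Z_al),
      cbind(Z_ls, Z_la, Dll)
    ),
    "21,22" = rbind(
      cbind(Z_as, Daa, block(R, p, "a", "lambda")),
      cbind(Z_ls, block(R, p, "lambda", "a"), Dll)
    ),
    abort_blanket(sprintf("unknown identity family '%s'", family), "block_error")
  )
}

#' Coefficient matrices of a drift-rewriting identity
#'
#' Each rewriting of the active/internal drift components is, for a linear
#' system, an equality of linear maps and is checked as an equality of
#' coefficient matrices — exact and basis-independent, never by sampling
#' points. Family `"13,14"` rewrites `(f_a, f_lambda)` in terms of the full
#' gradient `grad ln p*(psi,s,a,lambda)` (a row selection of the potential
#' form, holds for every system). The remaining families act on the gradient
#' of the *marginal* `ln p*(s,a,lambda)`: `"17,18"` keeps all solenoidal
#' couplings within `(s,a,lambda)` (holds whenever Condition 1 makes the
#' left-hand side a function of `(s,a,lambda)`), `"19,20"` keeps only the
#' diagonal blocks, and `"21,22"` adds back the `a`-`lambda` cross terms.
#'
#' @param system an [ou_system()].
#' @param family one of `"13,14"`, `"17,18"`, `"19,20"`, `"21,22"`.
#' @return list with `left` and `right` coefficient matrices, `residual`
#'   (max-entry norm of their difference) and `applicable`. For the
#'   marginalised families the maps send `(s,a,lambda)` to
#'   `(f_a, f_lambda)`; for `"13,14"` they send the full state. When
#'   Condition 1 fails, the marginalised families return
#'   `applicable = FALSE` with a reason.
#' @export
flow_coefficients <- function(system, family) {
  family <- match.arg(family, IDENTITY_FAMILIES)
  system <- with_stationary(system)
  p <- system$partition
  al <- block_idx(p, c("a", "lambda"))
  if (family == "13,14") {
    left <- system$M[al, , drop = FALSE]
    right <- (-(system$Gamma + system$R) %*% system$U)[al, , drop = FALSE]
    return(list(family = family, applicable = TRUE, left = left, right = right,
                residual = maxabs(left - right)))
  }
  c1 <- check_condition(system, 1)
  if (!c1$satisfied) {
    return(list(family = family, applicable = FALSE,
                reason = "Condition 1 fails: (f_a, f_lambda) are not functions of (s,a,lambda), so the marginalised rewriting is undefined"))
  }
  y <- block_idx(p, c("s", "a", "lambda"))
  left <- system$M[al, y, drop = FALSE]
  V <- marginal_precision(system_covariance(system), p, c("s", "a", "lambda"))
  right <- -family_operator(system, family) %*% V
  list(family = family, applicable = TRUE, left = left, right = right,
       residual = maxabs(left - right))
}

#' Verdicts for all drift-rewriting identity families
#'
#' Aggregates [flow_coefficients()] over the four equation families. A family
#' "holds" when its coefficient residual is below `tol`, "fails" above the
#' violation threshold `1e-3`, and is "ambiguous" in between; families whose
#' precondition (Condition 1) fails are "not_applicable".
#'
#' @param system an [ou_system()].
#' @param tol satisfaction tolerance.
#' @return object of class `identity_report`: per-family entries with
#'   `residual` and `verdict`, plus the tolerance used.
#' @export
identity_residuals <- function(system, tol = ZERO_TOL) {
  system <- with_stationary(system)
  fams <- lapply(IDENTITY_FAMILIES, function(f) {
    fc <- flow_coefficients(system, f)
    if (!fc$applicable) {
      list(family = f, verdict = "not_applicable", reason = fc$reason)
    } else {
      verdict <- if (fc$residual < tol) "holds"
      else if (fc$residual > VIOLATION_THRESHOLD) "fails"
      else "ambiguous"
      list(family = f, verdict = verdict, residual = fc$residual)
    }
  })
  names(fams) <- IDENTITY_FAMILIES
  structure(list(families = fams, tol = tol), class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  cat("<identity_report>\n")
  for (f in x$families) {
    if (f$verdict == "not_applicable") {
      cat(sprintf("  (%s): not applicable\n", f$family))
    } else {
      cat(sprintf("  (%s): %s (residual %.3e)\n", f$family, f$verdict, f$residual))
    }
  }
  invisible(x)
}
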