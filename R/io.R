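SCHEMA_VERSION <- 1L
NOISE_CONVENTION <- "noise_cov=2*Gamma"

#' Write a system to the JSON interchange format
#'
#' The schema is versioned and self-describing: partition sizes, matrices in
#' row-major nested arrays, and a fixed `convention` field recording the
#' noise normalisation (`"noise_cov=2*Gamma"`), so files are unambiguous
#' about the Lyapunov scaling.
#'
#' @param system an [ou_system()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path) {
  obj <- list(
    schema_version = SCHEMA_VERSION,
    convention = NOISE_CONVENTION,
    partition = as.list(stats::setNames(as.integer(system$partition$n), BLOCKS)),
    M = system$M,
    Gamma = system$Gamma
  )
  if (!is.null(system$U)) obj$U <- system$U
  if (!is.null(system$R)) obj$R <- system$R
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a system from the JSON interchange format
#'
#' Validates the schema version, partition/matrix dimension agreement and
#' the structural invariants on load. A file carrying `(U, R, Gamma)` is
#' assembled via [assemble_from_potential()]; one carrying only `(M, Gamma)`
#' has `R` and `U` derived. Errors name the failing field.
#'
#' @param path input file path.
#' @return an [ou_system()] with `R` and `U` attached.
#' @export
read_system <- function(path) {
  if (!file.exists(path)) {
    abort_blanket(sprintf("no such file: %s", path), "schema_error")
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort_blanket(sprintf("cannot parse %s as JSON: %s",
                                          path, conditionMessage(e)),
                                  "schema_error")
                  })
  known <- c("schema_version", "convention", "partition", "M", "Gamma", "U", "R")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0) {
    abort_blanket(sprintf("unknown field(s) in system file: %s",
                          paste(extra, collapse = ", ")), "schema_error")
  }
  if (is.null(obj$schema_version) || obj$schema_version != SCHEMA_VERSION) {
    abort_blanket("missing or unsupported schema_version", "schema_error",
                  field = "schema_version")
  }
  if (!identical(sort(names(obj$partition)), sort(BLOCKS))) {
    abort_blanket("partition must have exactly the four blocks psi, s, a, lambda",
                  "schema_error", field = "partition")
  }
  p <- coordinate_partition(obj$partition$psi, obj$partition$s,
                            obj$partition$a, obj$partition$lambda)
  as_mat <- function(x, name) {
    X <- as.matrix(x)
    if (!all(dim(X) == p$d)) {
      abort_blanket(sprintf("%s is %d x %d but the partition implies d = %d",
                            name, nrow(X), ncol(X), p$d),
                    "dimension_error", field = name)
    }
    X
  }
  if (is.null(obj$Gamma)) {
    abort_blanket("Gamma is required", "schema_error", field = "Gamma")
  }
  Gamma <- as_mat(obj$Gamma, "Gamma")
  if (!is.null(obj$U) && !is.null(obj$R)) {
    sys <- assemble_from_potential(as_mat(obj$U, "U"), as_mat(obj$R, "R"),
                                   Gamma, p)
    if (!is.null(obj$M) && maxabs(as_mat(obj$M, "M") - sys$M) > 1e-8) {
      abort_blanket("supplied M disagrees with -(Gamma+R) U", "invariant_error",
                    field = "M")
    }
    sys$C <- solve(sys$U)
    return(sys)
  }
  if (is.null(obj$M)) {
    abort_blanket("either M or both U and R are required", "schema_error",
                  field = "M")
  }
  with_stationary(ou_system(as_mat(obj$M, "M"), Gamma, p))
}

#' Run the complete analysis pipeline on a system
#'
#' Orchestrates conditions, drift-rewriting identities, chain implication,
#' lemma feasibility, unbounded-KL probe and the data-processing inequality,
#' and states per observation whether this system witnesses it:
#'
#' * Observation 1 — one blanket condition holds while the other is violated;
#' * Observation 2 — both conditions hold yet a restricted rewriting fails;
#' * Observation 3 — Conditions 1 and 3 force the chain structure;
#' * Observation 4 — a rewriting holds but no Gaussian-linear variational
#'   density satisfies the lemma;
#' * Observation 5 — the lemma is feasible yet the KL divergence of every
#'   feasible density is unbounded (witnessed by a probe above `probe_c`).
#'
#' @param x an [ou_system()] or a path to a system JSON file.
#' @param lift_order optional order for a generalised-coordinates lift check.
#' @param simulate run an Euler-Maruyama cross-validation.
#' @param probe_c KL threshold for the unbounded-divergence probe.
#' @param seed seed for the optional simulation.
#' @return an object of class `analysis_report` (serialisable with
#'   [write_report()]).
#' @export
run_full_analysis <- function(x, lift_order = NULL, simulate = FALSE,
                              probe_c = 1e6, seed = 0) {
  input_hash <- NA_character_
  if (is.character(x)) {
    input_hash <- unname(tools::md5sum(x))
    x <- read_system(x)
  }
  system <- with_stationary(x)
  conditions <- lapply(1:3, function(k) check_condition(system, k))
  names(conditions) <- paste0("condition_", 1:3)
  identities <- identity_residuals(system)
  chain <- verify_chain_implication(system)
  lemma <- lapply(LEMMA_FAMILIES, function(f) lemma_feasibility(system, f))
  names(lemma) <- paste0("family_", gsub(",", "_", LEMMA_FAMILIES))
  dpi <- dpi_check(system)
  feas <- lemma$family_29_30
  probe <- NULL
  if (isTRUE(feas$feasible)) {
    probe <- kl_supremum_probe(system, feas, probe_c)
  }
  c1 <- conditions$condition_1; c2 <- conditions$condition_2
  fam <- identities$families
  witnessed <- list(
    observation_1 = (c1$satisfied && c2$violated) ||
      (c2$satisfied && c1$violated),
    observation_2 = c1$satisfied && c2$satisfied &&
      fam[["17,18"]]$verdict == "holds" &&
      (fam[["19,20"]]$verdict == "fails" || fam[["21,22"]]$verdict == "fails"),
    observation_3 = isTRUE(chain$applicable) && isTRUE(chain$holds),
    observation_4 = any(vapply(lemma, function(l) {
      isTRUE(l$applicable) && identical(l$verdict, "infeasible")
    }, logical(1))),
    observation_5 = !is.null(probe) && probe$kl > probe_c &&
      probe$gradient_maxabs < 1e-8 && probe$posterior_s_gain > VIOLATION_THRESHOLD
  )
  lift <- NULL
  if (!is.null(lift_order)) {
    lifted <- lift_generalised(system, lift_order)
    lift <- list(
      order = lift_order,
      conditions = lapply(1:3, function(k) check_condition(lifted, k)),
      identities = identity_residuals(lifted)
    )
  }
  simulation <- NULL
  if (isTRUE(simulate)) {
    summ <- simulate_em(system, seed = seed)
    simulation <- validate_empirical(summ, stationary_gaussian(system$U, system$C))
    simulation$ess_min <- summ$ess_min
  }
  structure(
    list(tool = "blanketlab",
         version = as.character(utils::packageVersion("blanketlab")),
         timestamp = format(Sys.time(), tz = "UTC"),
         input_hash = input_hash, seed = seed,
         conditions = conditions, identities = identities, chain = chain,
         lemma = lemma, probe = probe, dpi = dpi,
         lift = lift, simulation = simulation,
         witnessed = witnessed),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  for (cr in x$conditions) print(cr)
  print(x$identities)
  for (l in x$lemma) print(l)
  cat(sprintf("  DPI: I(Lambda;Lambda_bar) = %.4f <= I(Lambda;(S,A)) = %.4f : %s\n",
              x$dpi$I_lambda_bar, x$dpi$I_lambda_sa,
              if (x$dpi$dpi_holds) "holds" else "VIOLATED"))
  w <- x$witnessed
  for (nm in names(w)) {
    if (isTRUE(w[[nm]])) cat(sprintf("  %s witnessed by this system\n",
                                     gsub("_", " ", nm)))
  }
  invisible(x)
}

# Strip matrices/closures down to JSON-friendly structures.
#' @keywords internal
jsonable <- function(x) {
  if (is.matrix(x)) return(unclass(x))
  if (inherits(x, "variational_gaussian")) {
    return(list(A = unclass(x$A), b = x$b, S = unclass(x$S)))
  }
  if (is.list(x)) {
    out <- lapply(x, jsonable)
    attributes(out) <- list(names = names(x))
    return(out)
  }
  x
}

#' Serialise an analysis report (or any report object) to JSON
#'
#' Reports round-trip losslessly apart from class attributes; every numeric
#' verdict is stored next to the tolerance that produced it.
#'
#' @param report a report object from this package.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(jsonable(report), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, null = "null")
  invisible(path)
}
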