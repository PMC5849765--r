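#' Solve the mass-action / mass-balance equations
#'
#' Computes the equilibrium free concentrations \eqn{x_j} of all non-fixed
#' components such that every mass balance
#' \deqn{T_j = x_j + \sum_i \nu_{ij}\, 10^{\log\beta_i} \prod_k x_k^{\nu_{ik}}}
#' is satisfied to the requested relative tolerance, with fixed components
#' (the proton at \eqn{10^{-pH}}) held at their fixed free value exactly.
#'
#' The solve runs in log-space (variables \eqn{\log_{10} x_j}), which keeps
#' all concentrations positive across the >12 decades spanned by dilution
#' scans, with an analytic Jacobian and damped Newton steps (step halved
#' until the residual decreases, at most 30 halvings). A short multiplicative
#' mass-balance pre-conditioning loop precedes the Newton iteration to pull
#' the default initial guess \eqn{x_j = T_j/2} into the Newton basin for
#' strongly binding systems. Non-convergence is reported explicitly
#' (`converged = FALSE`), never silently.
#'
#' @param problem a [speciation_problem()].
#' @param tolerance maximum allowed relative mass-balance error
#'   (default 1e-12, the high-precision setting used throughout).
#' @param max_iter maximum Newton iterations (default 200).
#' @param start optional named vector of log10 free concentrations used as
#'   warm start (e.g. the previous point of a dilution scan).
#' @return An object of class `speciation_result`: `free` (named, mol/L,
#'   fixed components included), `species` (named concentrations, mol/L),
#'   `converged`, `residual` (max relative mass-balance error),
#'   `iterations`, and the `problem`.
#' @export
solve_equilibrium <- function(problem, tolerance = 1e-12, max_iter = 200L,
                              start = NULL) {
  stopifnot(inherits(problem, "speciation_problem"), tolerance > 0)
  comps <- problem$components
  totals <- problem$totals
  fixed <- problem$fixed_free
  S <- problem$stoich
  lb <- problem$log_beta
  nsp <- nrow(S)

  # components appearing in no retained species are free at exactly T
  in_species <- colSums(S[, comps, drop = FALSE] != 0) > 0
  solve_for <- comps[in_species]
  trivial <- comps[!in_species]

  u_fixed <- log10(fixed)
  log_t <- log10(totals[solve_for])

  species_conc <- function(u) {
    if (!nsp) return(numeric(0))
    u_all <- c(u, u_fixed, stats::setNames(log10(totals[trivial]), trivial))
    as.numeric(10^(lb + S[, names(u_all), drop = FALSE] %*% u_all))
  }
  residual_of <- function(u) {
    c_i <- species_conc(u)
    tc <- 10^u
    if (nsp && length(solve_for))
      tc <- tc + as.numeric(crossprod(S[, solve_for, drop = FALSE], c_i))
    (tc - totals[solve_for]) / totals[solve_for]
  }
  # log-scale mass-balance error: unlike the linear relative residual, which
  # saturates at -1 when Tcalc << T, this stays informative across the whole
  # concentration range and is the quantity the damping monitors
  objective_of <- function(r) {
    if (!all(is.finite(r))) return(Inf)
    max(abs(log10(pmax(r + 1, 1e-300))))
  }

  n <- length(solve_for)
  iterations <- 0L
  if (n == 0L) {
    res <- numeric(0)
    u <- stats::setNames(numeric(0), character(0))
    converged <- TRUE
  } else {
    u <- if (!is.null(start) && all(solve_for %in% names(start)))
      start[solve_for] else log_t - log10(2)
    names(u) <- solve_for

    # multiplicative pre-conditioning: x <- x * (T / T_calc)^(1/m)
    m <- pmax(1, apply(abs(S[, solve_for, drop = FALSE]), 2,
                       function(v) if (length(v)) max(v, 1) else 1))
    for (k in seq_len(15L)) {
      r <- residual_of(u)
      if (!all(is.finite(r)) || max(abs(r)) <= tolerance) break
      delta <- -log10(r + 1) / m
      # at most 2 decades per warm-up step, to avoid overshoot oscillation
      u <- u + pmin(pmax(delta, -2), 2)
      # free concentration cannot exceed the total; keep inside double range
      u <- pmin(pmax(u, log_t - 50), log_t)
    }

    res <- residual_of(u)
    if (!all(is.finite(res))) {
      u <- log_t - 10  # deep underestimate always evaluates finitely
      res <- residual_of(u)
    }
    converged <- all(is.finite(res)) && max(abs(res)) <= tolerance
    while (!converged && iterations < max_iter) {
      iterations <- iterations + 1L
      c_i <- species_conc(u)
      x <- 10^u
      # J[j,k] = d T^calc_j / d u_k, scaled by 1/T_j
      J <- diag(x, n, n)
      if (nsp) {
        Ssub <- S[, solve_for, drop = FALSE]
        J <- J + crossprod(Ssub, Ssub * c_i)
      }
      J <- log(10) * J / totals[solve_for]
      step <- tryCatch(solve(J, -res), error = function(e) NULL)
      if (is.null(step) || !all(is.finite(step))) {
        # singular Jacobian: fall back to a damped mass-balance update
        step <- -log10(pmax(res + 1, 1e-300))
      }
      # clamp to at most 6 decades per component per iteration
      step[!is.finite(step)] <- 0
      big <- max(abs(step))
      if (big > 6) step <- step * (6 / big)

      lambda <- 1
      best <- u; improved <- FALSE
      obj0 <- objective_of(res)
      norm0 <- max(abs(res))
      for (h in seq_len(30L)) {
        u_try <- u + lambda * step
        r_try <- residual_of(u_try)
        if (all(is.finite(r_try)) &&
            (objective_of(r_try) < obj0 || max(abs(r_try)) < norm0)) {
          best <- u_try; res <- r_try; improved <- TRUE
          break
        }
        lambda <- lambda / 2
      }
      if (!improved) {
        # accept the most damped step anyway; occasionally needed to
        # escape a flat region, still deterministic
        u_try <- u + lambda * step
        r_try <- residual_of(u_try)
        if (all(is.finite(r_try))) { best <- u_try; res <- r_try }
      }
      u <- best
      converged <- max(abs(res)) <= tolerance
    }
  }

  # a poor warm start can strand the iteration on a near-singular ridge
  # (e.g. totals where only a sum of log-concentrations is well determined);
  # the default initialisation is more robust, so fall back to it once
  if (!converged && !is.null(start))
    return(solve_equilibrium(problem, tolerance = tolerance,
                             max_iter = max_iter, start = NULL))

  free <- c(10^u, fixed, totals[trivial])
  c_i <- species_conc(u)
  names(c_i) <- rownames(S)
  structure(
    list(free = free[c(comps, names(fixed))],
         species = c_i,
         converged = converged,
         residual = if (length(res)) max(abs(res)) else 0,
         iterations = iterations,
         problem = problem),
    class = "speciation_result"
  )
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("<speciation_result>",
      if (x$converged) "converged" else "NOT CONVERGED",
      sprintf("(residual %.2e, %d iterations)\n", x$residual, x$iterations))
  invisible(x)
}

#' Species distribution of a component
#'
#' Percentage of a component's total held by each species that contains it,
#' including the free ion; the percentages sum to 100.
#'
#' @param result a converged [solve_equilibrium()] result.
#' @param group_by name of a non-fixed component.
#' @return Named numeric vector of percentages (the free ion is labelled
#'   `<component>_free`).
#' @export
species_distribution <- function(result, group_by) {
  stopifnot(inherits(result, "speciation_result"))
  if (!result$converged)
    stop("species_distribution requires a converged result", call. = FALSE)
  pr <- result$problem
  if (!group_by %in% pr$components)
    stop("'", group_by, "' is not a free component of this problem",
         call. = FALSE)
  total <- pr$totals[[group_by]]
  nu <- pr$stoich[, group_by]
  has <- nu != 0
  pct <- c(stats::setNames(result$free[[group_by]] / total * 100,
                           paste0(group_by, "_free")),
           nu[has] * result$species[has] / total * 100)
  pct
}

#' Fraction of a metal bound by a chelator
#'
#' Sum of the metal content of all species containing both the metal and the
#' chelator, divided by the metal total. Returns 0 when the chelator is
#' absent from the problem (zero total).
#'
#' @param result a converged [solve_equilibrium()] result.
#' @param metal,chelator component names.
#' @return Fraction in \[0, 1\].
#' @export
bound_fraction <- function(result, metal, chelator) {
  stopifnot(inherits(result, "speciation_result"))
  if (!result$converged)
    stop("bound_fraction requires a converged result", call. = FALSE)
  pr <- result$problem
  if (!metal %in% pr$components)
    stop("metal '", metal, "' has no (nonzero) total in this problem",
         call. = FALSE)
  if (!chelator %in% colnames(pr$stoich)) return(0)
  both <- pr$stoich[, metal] != 0 & pr$stoich[, chelator] != 0
  sum(pr$stoich[both, metal] * result$species[both]) / pr$totals[[metal]]
}
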