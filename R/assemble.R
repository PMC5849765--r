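#' Speciation problem
#'
#' Couples a constants table to the experimental condition: total
#' concentrations for the free components and fixed free concentrations for
#' components buffered externally (the proton, fixed at \eqn{10^{-pH}}).
#' Components with a total of exactly zero are admitted and dropped from the
#' solve, together with every species that requires them; this is how
#' metal-free and chelator-free controls are expressed.
#'
#' Only species whose stoichiometric support lies inside the active component
#' set (nonzero totals plus fixed components) are retained, mirroring the way
#' speciation programs assemble a simulation from the subset of equilibria
#' reachable under the given condition.
#'
#' @param table a [thermo_table()].
#' @param totals named numeric vector of total concentrations (mol/L) for
#'   non-fixed components; zeros allowed (component dropped), negatives not.
#' @param fixed_free named numeric vector of fixed free concentrations
#'   (mol/L), typically just the proton.
#' @return An object of class `speciation_problem` with elements
#'   `components` (active non-fixed), `totals`, `fixed_free`, `species`,
#'   `stoich`, `log_beta`, and `dropped` (zero-total components).
#' @export
speciation_problem <- function(table, totals, fixed_free = numeric(0)) {
  stopifnot(inherits(table, "thermo_table"))
  totals <- unlist(totals)
  fixed_free <- unlist(fixed_free)
  all_names <- table$components$name
  unknown <- setdiff(c(names(totals), names(fixed_free)), all_names)
  if (length(unknown))
    stop("total given for undeclared component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (any(!is.finite(totals)) || any(totals < 0))
    stop("totals must be finite and >= 0", call. = FALSE)
  if (any(fixed_free <= 0))
    stop("fixed free concentrations must be > 0", call. = FALSE)
  overlap <- intersect(names(totals), names(fixed_free))
  if (length(overlap))
    stop("component(s) both fixed and given a total: ",
         paste(overlap, collapse = ", "), call. = FALSE)

  dropped <- names(totals)[totals == 0]
  totals <- totals[totals > 0]
  active <- c(names(totals), names(fixed_free))
  if (!length(active)) stop("at least one component required", call. = FALSE)

  keep <- apply(table$stoich != 0, 1L, function(nz) all(colnames(table$stoich)[nz] %in% active))
  stoich <- table$stoich[keep, active, drop = FALSE]
  structure(
    list(components = names(totals), totals = totals, fixed_free = fixed_free,
         species = table$species[keep, , drop = FALSE],
         stoich = stoich,
         log_beta = table$species$log_beta[keep],
         dropped = dropped),
    class = "speciation_problem"
  )
}

#' @export
print.speciation_problem <- function(x, ...) {
  cat("<speciation_problem>\n")
  cat("  free components:", length(x$components),
      sprintf("(%s)", paste(x$components, collapse = ", ")), "\n")
  if (length(x$fixed_free))
    cat("  fixed:", paste(sprintf("%s = %.3g M", names(x$fixed_free),
                                  x$fixed_free), collapse = ", "), "\n")
  cat("  equilibria:", count_equilibria(x), "\n")
  invisible(x)
}

#' Assemble a speciation system from a medium plus extra totals
#'
#' Builds the [speciation_problem()] for a constants table under a
#' physiological medium, optionally adding further totals (the metal and the
#' synthetic chelator of a dilution point, a competing metal, ...). The proton
#' is handled as a fixed free concentration of \eqn{10^{-pH}}.
#'
#' @param table a [thermo_table()].
#' @param medium a [physiological_medium()].
#' @param extra_totals named numeric vector of additional totals (mol/L);
#'   names must be declared components. Values add to any medium total of the
#'   same name.
#' @return A [speciation_problem()].
#' @export
assemble_system <- function(table, medium, extra_totals = numeric(0)) {
  stopifnot(inherits(table, "thermo_table"),
            inherits(medium, "physiological_medium"))
  extra_totals <- unlist(extra_totals)
  totals <- medium$totals
  for (nm in names(extra_totals)) {
    totals[nm] <- (if (nm %in% names(totals)) totals[[nm]] else 0) +
      extra_totals[[nm]]
  }
  hname <- proton_name(table)
  if (hname %in% names(totals))
    stop("the proton is fixed by pH; give no total for '", hname, "'",
         call. = FALSE)
  fixed <- stats::setNames(10^(-medium$pH), hname)
  speciation_problem(table, totals, fixed_free = fixed)
}

#' Number of formation equilibria in a problem
#'
#' Counts the formation species retained in an assembled problem (free
#' components themselves are not equilibria).
#'
#' @param problem a [speciation_problem()].
#' @return Non-negative integer.
#' @export
count_equilibria <- function(problem) {
  stopifnot(inherits(problem, "speciation_problem"))
  nrow(problem$stoich)
}

#' pH-conditional stability constant
#'
#' Effective metal-chelator formation constant at fixed pH, discounting
#' ligand protonation (and metal hydrolysis where hydroxide species of the
#' metal are present in the table) through side-reaction coefficients:
#' \deqn{\log K_{cond} = \log\beta_{ML} - \log\alpha_{L(H)} - \log\alpha_{M(OH)}}
#' with \eqn{\alpha_{L(H)} = 1 + \sum_n 10^{\log\beta(H_nL) - n\,pH}} and the
#' hydroxide sum analogous over species \eqn{M(OH)_n} encoded with negative
#' proton stoichiometry.
#'
#' @param table a [thermo_table()].
#' @param metal,chelator component names.
#' @param pH the fixed pH.
#' @return The conditional constant, log10 scale.
#' @export
conditional_stability_constant <- function(table, metal, chelator, pH) {
  stopifnot(inherits(table, "thermo_table"))
  nm <- table$components$name
  if (!metal %in% nm) stop("unknown component '", metal, "'", call. = FALSE)
  if (!chelator %in% nm) stop("unknown component '", chelator, "'", call. = FALSE)
  hname <- proton_name(table)
  S <- table$stoich
  others <- setdiff(colnames(S), c(metal, chelator, hname))

  is_ml <- S[, metal] == 1 & S[, chelator] == 1 & S[, hname] == 0 &
    rowSums(abs(S[, others, drop = FALSE])) == 0
  if (!any(is_ml))
    stop("no 1:1 ", metal, "-", chelator, " species in the table", call. = FALSE)
  log_beta_ml <- table$species$log_beta[which(is_ml)[1]]

  # ligand protonation ladder H_nL (n > 0), no other components involved
  oth_l <- setdiff(colnames(S), c(chelator, hname))
  is_hl <- S[, chelator] == 1 & S[, hname] > 0 &
    rowSums(abs(S[, oth_l, drop = FALSE])) == 0
  alpha_l <- 1 + sum(10^(table$species$log_beta[is_hl] -
                           S[is_hl, hname] * pH))

  # metal hydrolysis M(OH)_n encoded as negative proton stoichiometry
  oth_m <- setdiff(colnames(S), c(metal, hname))
  is_moh <- S[, metal] == 1 & S[, hname] < 0 &
    rowSums(abs(S[, oth_m, drop = FALSE])) == 0
  alpha_m <- 1 + sum(10^(table$species$log_beta[is_moh] +
                           abs(S[is_moh, hname]) * pH))

  log_beta_ml - log10(alpha_l) - log10(alpha_m)
}
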