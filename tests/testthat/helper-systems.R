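# Small thermodynamic fixtures built in code, plus the independent
# brute-force oracle used to verify the Newton solver.

# 1:1 M + L = ML toy with log beta = 6 (closed-form quadratic solution)
toy_ml_table <- function(log_beta = 6) {
  thermo_table(
    components = data.frame(
      name = c("H", "M", "L"), charge = c(1L, 2L, -2L),
      kind = c("proton", "metal", "endogenous_ligand"),
      stringsAsFactors = FALSE),
    species = data.frame(label = "ML", log_beta = log_beta,
                         stringsAsFactors = FALSE),
    stoich = matrix(c(0L, 1L, 1L), 1, 3,
                    dimnames = list(NULL, c("H", "M", "L")))
  )
}

# closed form for M + L = ML with equal totals C: free u = (-1+sqrt(1+4KC))/(2K)
closed_form_ml <- function(log_beta, C) {
  K <- 10^log_beta
  u <- (-1 + sqrt(1 + 4 * K * C)) / (2 * K)
  list(free = u, ML = K * u^2, bound_fraction = K * u^2 / C)
}

# metal with two competing 1:1 ligands
toy_competition_table <- function(log_beta1, log_beta2) {
  thermo_table(
    components = data.frame(
      name = c("H", "M", "L1", "L2"), charge = c(1L, 2L, -2L, -2L),
      kind = c("proton", "metal", "endogenous_ligand", "endogenous_ligand"),
      stringsAsFactors = FALSE),
    species = data.frame(label = c("ML1", "ML2"),
                         log_beta = c(log_beta1, log_beta2),
                         stringsAsFactors = FALSE),
    stoich = matrix(c(0L, 1L, 1L, 0L,
                      0L, 1L, 0L, 1L), 2, 4, byrow = TRUE,
                    dimnames = list(NULL, c("H", "M", "L1", "L2")))
  )
}

# Brute-force grid-search oracle: minimizes the summed squared relative
# mass-balance residual over a log-spaced grid of free concentrations,
# optionally refining once around the coarse argmin (still pure argmin over
# an enumerated grid; no derivative information shared with the solver).
grid_search_oracle <- function(problem, n_per_dim = NULL, span = 26,
                               refine = TRUE) {
  comps <- problem$components
  totals <- problem$totals
  S <- problem$stoich[, comps, drop = FALSE]
  lb <- problem$log_beta
  d <- length(comps)
  if (is.null(n_per_dim))
    n_per_dim <- switch(d, 2000L, 500L, 64L)

  eval_grid <- function(lo, hi) {
    axes <- lapply(seq_len(d), function(j) seq(lo[j], hi[j],
                                               length.out = n_per_dim))
    U <- as.matrix(expand.grid(axes))
    X <- 10^U
    Tcalc <- X
    if (nrow(S)) {
      C <- 10^(matrix(lb, nrow(U), length(lb), byrow = TRUE) + U %*% t(S))
      Tcalc <- Tcalc + C %*% S
    }
    R2 <- rowSums(((Tcalc - matrix(totals, nrow(U), d, byrow = TRUE)) /
                     matrix(totals, nrow(U), d, byrow = TRUE))^2)
    U[which.min(R2), ]
  }

  lt <- log10(totals)
  best <- eval_grid(lt - span, lt)
  spacing <- span / (n_per_dim - 1)
  if (refine) {
    best <- eval_grid(best - 1.5 * spacing, best + 1.5 * spacing)
    spacing <- 3 * spacing / (n_per_dim - 1)
  }
  list(log10_free = stats::setNames(best, comps), spacing = spacing)
}
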