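#' Dilution scan of a Gd-chelator pair against constant endogenous ligands
#'
#' Emulates progressive clearance of a metal-chelator complex from the blood
#' stream: the total metal and the synthetic chelator are co-diluted at a
#' fixed mol/mol ratio while pH and the endogenous ligand pool stay constant,
#' and the fraction of the metal bound by the chelator is recorded at each
#' grid point. As the pair is diluted the endogenous ligands eventually win
#' and the metal is released; the concentration at which this happens
#' measures the chelator's effective in-vivo stability.
#'
#' Each grid point is one converged speciation solve, warm-started from the
#' previous point (continuation), making the scan robust across the full
#' concentration range. A non-converged point aborts the scan with the
#' failing concentration in the error message.
#'
#' @param table a [thermo_table()].
#' @param medium a [physiological_medium()] held constant across the scan.
#' @param chelator name of the synthetic chelator component.
#' @param metal name of the diluted metal (default `"Gd"`).
#' @param grid descending vector of total metal concentrations (mol/L).
#'   Default: 1e-3 to 1e-17 M, 10 points per decade.
#' @param ratio metal:chelator ratio in mol/mol (default 1: chelator total
#'   equals metal total at every point).
#' @param extra_totals named vector of additional constant totals (a
#'   competing metal in a transmetallation scan).
#' @param tolerance,max_iter passed to [solve_equilibrium()].
#' @return An object of class `dilution_scan`: data.frame `points`
#'   (`total_metal`, `bound_fraction`, `iterations`, `residual`), plus
#'   `chelator`, `metal`, `ratio`, `medium`, `extra_totals`.
#' @export
dilution_scan <- function(table, medium, chelator, metal = "Gd",
                          grid = default_dilution_grid(), ratio = 1,
                          extra_totals = numeric(0),
                          tolerance = 1e-12, max_iter = 200L) {
  stopifnot(inherits(table, "thermo_table"),
            inherits(medium, "physiological_medium"))
  if (!chelator %in% table$components$name)
    stop("unknown chelator '", chelator, "'", call. = FALSE)
  if (is.unsorted(rev(grid), strictly = TRUE))
    stop("grid must be strictly decreasing", call. = FALSE)

  bf <- numeric(length(grid))
  iters <- integer(length(grid))
  resid <- numeric(length(grid))
  start <- NULL
  for (i in seq_along(grid)) {
    tot <- stats::setNames(c(grid[i], grid[i] / ratio),
                           c(metal, chelator))
    prob <- assemble_system(table, medium, c(tot, extra_totals))
    sol <- solve_equilibrium(prob, tolerance = tolerance,
                             max_iter = max_iter, start = start)
    if (!sol$converged)
      stop(sprintf("speciation failed to converge at total %s = %.3e M (residual %.2e)",
                   metal, grid[i], sol$residual), call. = FALSE)
    bf[i] <- bound_fraction(sol, metal, chelator)
    iters[i] <- sol$iterations
    resid[i] <- sol$residual
    start <- log10(sol$free[prob$components])
  }
  structure(
    list(points = data.frame(total_metal = grid, bound_fraction = bf,
                             iterations = iters, residual = resid),
         chelator = chelator, metal = metal, ratio = ratio,
         medium = medium, extra_totals = extra_totals),
    class = "dilution_scan"
  )
}

#' Default dilution grid: 1e-3 to 1e-17 M, 10 points per decade
#'
#' The grid spans from above therapeutic chelator concentrations down far
#' enough that the release crossing of even the strongest chelator under the
#' reference medium lies inside the scanned range.
#'
#' @return Strictly decreasing numeric vector of total concentrations (mol/L).
#' @export
default_dilution_grid <- function() {
  10^seq(-3, -17, by = -0.1)
}

#' Transmetallation scan: dilution in the presence of a competing metal
#'
#' Same protocol as [dilution_scan()], with a constant total of an
#' endogenous competing metal (physiological calcium at 1.1 mM, or zinc at
#' 15 uM) added to the system. Displacement of Gd(III) from the chelator by
#' the competitor shifts the release threshold to higher total concentration.
#' With a zero competitor total the result reproduces [dilution_scan()]
#' bit-identically.
#'
#' @inheritParams dilution_scan
#' @param competitor name of the competing metal component (`"Ca"`, `"Zn"`).
#' @param competitor_total constant total of the competitor (mol/L). Defaults
#'   to the physiological values 1.1e-3 for Ca and 15e-6 for Zn.
#' @return A `dilution_scan` object.
#' @export
transmetallation_scan <- function(table, medium, chelator,
                                  competitor = c("Ca", "Zn"),
                                  competitor_total = NULL,
                                  metal = "Gd",
                                  grid = default_dilution_grid(), ratio = 1,
                                  tolerance = 1e-12, max_iter = 200L) {
  competitor <- competitor[1]
  if (!competitor %in% table$components$name)
    stop("unknown competitor '", competitor, "'", call. = FALSE)
  if (is.null(competitor_total))
    competitor_total <- switch(competitor, Ca = 1.1e-3, Zn = 15e-6,
                               stop("no default total for competitor '",
                                    competitor, "'", call. = FALSE))
  if (competitor_total > 0) {
    S <- table$stoich
    both <- S[, competitor] != 0 & S[, chelator] != 0
    if (!any(both))
      stop("no ", competitor, "-", chelator,
           " species in the table; transmetallation cannot be modelled",
           call. = FALSE)
  }
  extra <- stats::setNames(competitor_total, competitor)
  dilution_scan(table, medium, chelator, metal = metal, grid = grid,
                ratio = ratio, extra_totals = extra[extra > 0],
                tolerance = tolerance, max_iter = max_iter)
}

#' Release threshold of a dilution scan
#'
#' Total-metal concentration at which the bound fraction crosses 0.5, located
#' by interpolation linear in log10(concentration) between the bracketing
#' grid points. The curve is monotonized first (non-increasing bound fraction
#' with decreasing total; numerical ripple up to 1e-9 is flattened). If the
#' curve never crosses 0.5, `crossing_found` is `FALSE` and the threshold is
#' reported as the nearer grid bound.
#'
#' @param scan a [dilution_scan()] result.
#' @return An object of class `release_threshold`: `chelator`, `threshold`
#'   (mol/L), `crossing_found`, plus the scan's `medium` and grid range.
#' @export
release_threshold <- function(scan) {
  stopifnot(inherits(scan, "dilution_scan"))
  conc <- scan$points$total_metal
  f <- scan$points$bound_fraction
  # monotonize: bound fraction must not increase as total decreases
  f <- cummin(f + 1e-9) - 1e-9
  f <- pmin(pmax(f, 0), 1)

  if (all(f >= 0.5)) {
    out <- list(threshold = min(conc), crossing_found = FALSE)
  } else if (all(f < 0.5)) {
    out <- list(threshold = max(conc), crossing_found = FALSE)
  } else {
    i <- which(f < 0.5)[1]        # first point below 0.5 (grid descends)
    lo <- log10(conc[i - 1]); hi <- log10(conc[i])
    w <- (0.5 - f[i - 1]) / (f[i] - f[i - 1])
    out <- list(threshold = 10^(lo + w * (hi - lo)), crossing_found = TRUE)
  }
  structure(c(list(chelator = scan$chelator, metal = scan$metal),
              out,
              list(medium = scan$medium,
                   grid_range = range(conc))),
            class = "release_threshold")
}

#' @export
print.release_threshold <- function(x, ...) {
  cat(sprintf("<release_threshold> %s: %.3e M%s\n", x$chelator, x$threshold,
              if (x$crossing_found) "" else " (no crossing in range)"))
  invisible(x)
}

#' Rank chelators by release threshold
#'
#' Orders chelators from weakest to strongest (descending release threshold:
#' the chelator that releases the metal at the highest concentration is the
#' weakest). Thresholds within `tie_window` log10 units are reported as tied,
#' reflecting that a factor-two difference is not resolvable by this
#' protocol. All scans must have been run on the same medium and grid.
#'
#' @param thresholds list of [release_threshold()] objects.
#' @param tie_window tie width in log10 units (default 0.3).
#' @return An object of class `chelator_ranking`: data.frame `table`
#'   (`chelator`, `threshold`, `log10_threshold`, `tier` with 1 = weakest),
#'   and a compact `ordering` string such as `"EDTA = DTPABMA < DTPA = DOTA < HOPO"`.
#' @export
chelator_ranking <- function(thresholds, tie_window = 0.3) {
  stopifnot(length(thresholds) >= 1,
            all(vapply(thresholds, inherits, logical(1), "release_threshold")))
  media <- lapply(thresholds, function(t) t$medium)
  grids <- lapply(thresholds, function(t) t$grid_range)
  if (length(thresholds) > 1) {
    same <- vapply(media[-1], identical, logical(1), media[[1]]) &
      vapply(grids[-1], identical, logical(1), grids[[1]])
    if (!all(same))
      stop("thresholds were computed on different media or grids",
           call. = FALSE)
  }
  df <- data.frame(
    chelator = vapply(thresholds, function(t) t$chelator, character(1)),
    threshold = vapply(thresholds, function(t) t$threshold, numeric(1)),
    stringsAsFactors = FALSE
  )
  df$log10_threshold <- log10(df$threshold)
  df <- df[order(-df$log10_threshold), , drop = FALSE]  # weakest first
  tier <- integer(nrow(df))
  tier[1] <- 1L
  if (nrow(df) > 1) {
    anchor <- df$log10_threshold[1]
    for (k in 2:nrow(df)) {
      if (anchor - df$log10_threshold[k] <= tie_window) {
        tier[k] <- tier[k - 1]
      } else {
        tier[k] <- tier[k - 1] + 1L
        anchor <- df$log10_threshold[k]
      }
    }
  }
  df$tier <- tier
  rownames(df) <- NULL
  ordering <- paste(
    vapply(split(df$chelator, df$tier),
           function(g) paste(g, collapse = " = "), character(1)),
    collapse = " < ")
  structure(list(table = df, ordering = ordering, tie_window = tie_window),
            class = "chelator_ranking")
}

#' @export
print.chelator_ranking <- function(x, ...) {
  cat("<chelator_ranking> weakest -> strongest:\n  ", x$ordering, "\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}
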