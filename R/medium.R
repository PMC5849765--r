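#' Physiological medium composition
#'
#' Fixed-pH background against which speciation is computed: total
#' concentrations (mol/L) of the endogenous ligand classes (and optionally
#' competing metals), plus the pH. The proton is handled separately as a
#' fixed free concentration of \eqn{10^{-pH}} and must not appear in `totals`.
#'
#' @param totals named numeric vector of total concentrations in mol/L;
#'   all values strictly positive.
#' @param pH solution pH, in (0, 14).
#' @return An object of class `physiological_medium`.
#' @export
physiological_medium <- function(totals, pH) {
  totals <- unlist(totals)
  if (is.null(names(totals)) || any(!nzchar(names(totals))))
    stop("totals must be a named vector", call. = FALSE)
  if (any(!is.finite(totals)) || any(totals <= 0))
    stop("totals must be strictly positive", call. = FALSE)
  if (!is.finite(pH) || pH <= 0 || pH >= 14)
    stop("pH must lie in (0, 14)", call. = FALSE)
  structure(list(totals = totals, pH = pH), class = "physiological_medium")
}

#' @export
print.physiological_medium <- function(x, ...) {
  cat("<physiological_medium> pH", x$pH, "\n")
  for (nm in names(x$totals))
    cat(sprintf("  %-12s %s\n", nm, format_conc(x$totals[[nm]])))
  invisible(x)
}

format_conc <- function(x) {
  if (x >= 1e-3) sprintf("%.4g mM", x * 1e3)
  else if (x >= 1e-6) sprintf("%.4g uM", x * 1e6)
  else sprintf("%.4g nM", x * 1e9)
}

#' Blood-plasma-like reference medium
#'
#' The endogenous low-molecular-weight ligand pool used throughout the
#' dilution simulations: phosphates 1.1 mM, carbonates 25 mM, oxalates
#' 9.2 uM, lactates 1.5 mM, citrates 160 uM, at pH 7.4. Hydroxide needs no
#' total: it derives from the fixed pH and the table's pKw.
#'
#' @param pH solution pH (default 7.4).
#' @return A [physiological_medium()].
#' @export
serum_medium <- function(pH = 7.4) {
  physiological_medium(
    c(phosphate = 1.1e-3, carbonate = 25e-3, oxalate = 9.2e-6,
      lactate = 1.5e-3, citrate = 160e-6),
    pH = pH
  )
}

#' Read a medium composition from a config file
#'
#' YAML mapping of component name to a concentration string with unit suffix
#' (`mM`, `uM`/`µM`, or `nM`), plus a numeric `pH` key, e.g.
#'
#' ```yaml
#' pH: 7.4
#' carbonate: 25 mM
#' oxalate: 9.2 uM
#' ```
#'
#' @param path path to the YAML file.
#' @return A [physiological_medium()].
#' @export
read_medium <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pH)) stop("medium config must contain a 'pH' key", call. = FALSE)
  pH <- as.numeric(cfg$pH)
  cfg$pH <- NULL
  totals <- vapply(cfg, parse_conc, numeric(1))
  physiological_medium(totals, pH)
}

parse_conc <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))  # bare numbers are mol/L
  m <- regmatches(x, regexec(
    "^\\s*([0-9.eE+-]+)\\s*(mM|uM|µM|nM|M)\\s*$", x))[[1]]
  if (length(m) != 3)
    stop("cannot parse concentration '", x,
         "' (expected e.g. '25 mM', '9.2 uM')", call. = FALSE)
  val <- as.numeric(m[2])
  val * switch(m[3], M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9)
}
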