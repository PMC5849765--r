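#' Thermodynamic constants table
#'
#' A `thermo_table` holds the components (metals, chelators, endogenous
#' ligands, and the proton) and the cumulative formation equilibria built from
#' them. Each species is defined by a signed stoichiometry vector \eqn{\nu}
#' over the components and a cumulative formation constant \eqn{\log_{10}\beta}
#' on the molar scale, so that at equilibrium
#' \deqn{c_i = 10^{\log\beta_i} \prod_j x_j^{\nu_{ij}}}
#' where \eqn{x_j} are the free component concentrations. Hydroxide-containing
#' species are encoded with negative proton stoichiometry; the water
#' ionization constant `pKw` is a table-level parameter (the hydroxide ion
#' itself is the species with \eqn{\nu_H = -1} and \eqn{\log\beta = -pK_w}).
#'
#' @param components data.frame with columns `name` (unique identifiers),
#'   `charge` (signed integer), and `kind` (one of `"metal"`,
#'   `"synthetic_chelator"`, `"endogenous_ligand"`, `"proton"`). Exactly one
#'   component must have `kind = "proton"`.
#' @param species data.frame with columns `label` (unique) and `log_beta`
#'   (finite), and optionally `provenance` (free text).
#' @param stoich integer matrix of stoichiometric coefficients, one row per
#'   species (rownames = species labels), one column per component
#'   (colnames = component names). Every row must have at least one nonzero
#'   entry.
#' @param pKw water ionization constant (log10 scale), default 13.78.
#'
#' @return An object of class `thermo_table`.
#' @seealso [load_constants()], [write_constants()],
#'   [conditional_stability_constant()], [assemble_system()]
#' @export
thermo_table <- function(components, species, stoich, pKw = 13.78) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  stopifnot(
    all(c("name", "charge", "kind") %in% names(components)),
    all(c("label", "log_beta") %in% names(species))
  )
  if (is.null(species$provenance))
    species$provenance <- rep("", nrow(species))
  if (anyDuplicated(components$name))
    stop("component names must be unique", call. = FALSE)
  kinds <- c("metal", "synthetic_chelator", "endogenous_ligand", "proton")
  bad <- setdiff(components$kind, kinds)
  if (length(bad))
    stop("unknown component kind: ", paste(bad, collapse = ", "), call. = FALSE)
  if (sum(components$kind == "proton") != 1L)
    stop("exactly one component must have kind = 'proton'", call. = FALSE)
  if (anyDuplicated(species$label))
    stop("duplicate species label: ",
         paste(unique(species$label[duplicated(species$label)]), collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(species$log_beta)))
    stop("log_beta must be finite for every species", call. = FALSE)

  stoich <- as.matrix(stoich)
  if (nrow(species)) {
    if (nrow(stoich) != nrow(species))
      stop("stoich must have one row per species", call. = FALSE)
    unknown <- setdiff(colnames(stoich), components$name)
    if (length(unknown))
      stop("species reference undeclared component(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    # pad with zero columns for unreferenced components, fix column order
    missing_cols <- setdiff(components$name, colnames(stoich))
    if (length(missing_cols)) {
      pad <- matrix(0L, nrow(stoich), length(missing_cols),
                    dimnames = list(NULL, missing_cols))
      stoich <- cbind(stoich, pad)
    }
    stoich <- stoich[, components$name, drop = FALSE]
    rownames(stoich) <- species$label
    if (any(rowSums(stoich != 0) == 0))
      stop("every species needs at least one nonzero stoichiometric coefficient",
           call. = FALSE)
  } else {
    stoich <- matrix(0L, 0L, nrow(components),
                     dimnames = list(NULL, components$name))
  }

  structure(
    list(components = components, species = species, stoich = stoich,
         pKw = pKw),
    class = "thermo_table"
  )
}

#' @export
print.thermo_table <- function(x, ...) {
  cat("<thermo_table>\n")
  cat("  components:", nrow(x$components),
      sprintf("(%s)", paste(x$components$name, collapse = ", ")), "\n")
  cat("  species   :", nrow(x$species), "\n")
  cat("  pKw       :", x$pKw, "\n")
  invisible(x)
}

proton_name <- function(table) {
  table$components$name[table$components$kind == "proton"]
}

#' Read a constants table from delimited text
#'
#' The file dialect is diff-friendly plain text: comment lines start with
#' `#`; directive lines start with `#!` and declare components and table-level
#' parameters; the header row names the columns. Layout:
#'
#' ```
#' #! pKw 13.78
#' #! component H  charge=1  kind=proton
#' #! component Gd charge=3  kind=metal
#' label  log_beta  Gd  H  provenance
#' GdOH   -8.30     1   -1  literature
#' ```
#'
#' Columns are `label`, `log_beta`, one signed-integer stoichiometry column
#' per component, and optionally `provenance`. Fields are tab-separated by
#' default; comma-separated files are accepted. Decimal point only.
#'
#' @param path path to the file.
#' @return A validated [thermo_table()].
#' @export
load_constants <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- seq_along(keep)[keep]

  directive <- startsWith(trimws(lines), "#!")
  comment <- startsWith(trimws(lines), "#") & !directive

  comps <- list()
  pKw <- 13.78
  for (i in which(directive)) {
    toks <- strsplit(trimws(sub("^\\s*#!\\s*", "", lines[i])), "\\s+")[[1]]
    if (toks[1] == "pKw") {
      pKw <- as.numeric(toks[2])
      if (!is.finite(pKw))
        stop("line ", lineno[i], ": malformed pKw directive", call. = FALSE)
    } else if (toks[1] == "component") {
      kv <- toks[-(1:2)]
      get <- function(key) {
        hit <- grep(paste0("^", key, "="), kv, value = TRUE)
        if (!length(hit))
          stop("line ", lineno[i], ": component directive missing '", key, "='",
               call. = FALSE)
        sub(paste0("^", key, "="), "", hit[1])
      }
      comps[[length(comps) + 1L]] <- data.frame(
        name = toks[2], charge = as.integer(get("charge")), kind = get("kind"),
        stringsAsFactors = FALSE)
    } else {
      stop("line ", lineno[i], ": unknown directive '", toks[1], "'",
           call. = FALSE)
    }
  }
  if (!length(comps)) stop("no component directives found", call. = FALSE)
  components <- do.call(rbind, comps)

  body <- lines[!directive & !comment]
  body_no <- lineno[!directive & !comment]
  if (!length(body)) stop("no header row found", call. = FALSE)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  split_row <- function(s) trimws(strsplit(s, sep, fixed = TRUE)[[1]])

  header <- split_row(body[1])
  if (header[1] != "label" || header[2] != "log_beta")
    stop("header must start with 'label' and 'log_beta'", call. = FALSE)
  nu_cols <- setdiff(header[-(1:2)], "provenance")
  unknown <- setdiff(nu_cols, components$name)
  if (length(unknown))
    stop("header references undeclared component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  has_prov <- "provenance" %in% header

  rows <- body[-1]
  rows_no <- body_no[-1]
  n <- length(rows)
  labels <- character(n); log_beta <- numeric(n); prov <- character(n)
  stoich <- matrix(0L, n, length(nu_cols), dimnames = list(NULL, nu_cols))
  for (k in seq_len(n)) {
    f <- split_row(rows[k])
    if (length(f) != length(header))
      stop("line ", rows_no[k], ": expected ", length(header), " fields, got ",
           length(f), call. = FALSE)
    names(f) <- header
    labels[k] <- f[["label"]]
    lb <- suppressWarnings(as.numeric(f[["log_beta"]]))
    if (!is.finite(lb))
      stop("line ", rows_no[k], ": malformed log_beta '", f[["log_beta"]], "'",
           call. = FALSE)
    log_beta[k] <- lb
    nu <- suppressWarnings(as.numeric(f[nu_cols]))
    if (any(!is.finite(nu)) || any(nu != round(nu)))
      stop("line ", rows_no[k], ": stoichiometry must be signed integers",
           call. = FALSE)
    stoich[k, ] <- as.integer(nu)
    prov[k] <- if (has_prov) f[["provenance"]] else ""
  }
  if (anyDuplicated(labels))
    stop("duplicate species label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)

  thermo_table(
    components = components,
    species = data.frame(label = labels, log_beta = log_beta,
                         provenance = prov, stringsAsFactors = FALSE),
    stoich = stoich, pKw = pKw
  )
}

#' Write a constants table to delimited text
#'
#' Inverse of [load_constants()]: the written file reloads to a table with
#' identical stoichiometry and `log_beta` values.
#'
#' @param table a [thermo_table()].
#' @param path output path.
#' @param sep field separator, tab by default.
#' @return `path`, invisibly.
#' @export
write_constants <- function(table, path, sep = "\t") {
  stopifnot(inherits(table, "thermo_table"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#! pKw %.10g", table$pKw), con)
  writeLines(sprintf("#! component %s charge=%d kind=%s",
                     table$components$name, table$components$charge,
                     table$components$kind), con)
  header <- c("label", "log_beta", colnames(table$stoich), "provenance")
  writeLines(paste(header, collapse = sep), con)
  for (k in seq_len(nrow(table$species))) {
    writeLines(paste(c(table$species$label[k],
                       sprintf("%.10g", table$species$log_beta[k]),
                       as.character(table$stoich[k, ]),
                       table$species$provenance[k]),
                     collapse = sep), con)
  }
  invisible(path)
}

#' Packaged physiological constants table
#'
#' Loads the constants file shipped with the package: Gd(III), Ca(II) and
#' Zn(II) formation equilibria with five synthetic chelators (HOPO = the
#' octadentate hydroxypyridinone 3,4,3-LI(1,2-HOPO), DTPA, DOTA, DTPA-BMA,
#' EDTA) and the endogenous ligand classes (hydroxide, phosphate, carbonate,
#' oxalate, lactate, citrate), plus all ligand protonation ladders. The file
#' is assembled from published stability-constant compilations (25 degC,
#' I = 0.1 M scale); the provenance column flags each entry. It is a
#' literature-assembled stand-in, not a transcription of any single source.
#'
#' @return A [thermo_table()].
#' @export
gd_constants <- function() {
  load_constants(default_constants_path())
}

#' Path to the packaged constants file
#' @return File path of the installed constants table.
#' @export
default_constants_path <- function() {
  system.file("extdata", "gd_constants_synthetic.tsv", package = "chelspec",
              mustWork = TRUE)
}
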