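#' Metabolic balance study container
#'
#' Holds the raw activity records of a radiotracer balance study: per-animal
#' organ activities, per-cage daily excreta (urine and feces collected as
#' group samples, one cage per group), and the injected activity per animal.
#' All tissues and excreta are assayed, so the administered dose can be fully
#' accounted for.
#'
#' @param animals data.frame with columns `animal_id` (unique), `group`,
#'   and optionally `cage` (defaults to the group label: one cage per group).
#' @param organs data.frame with columns `animal_id`, `compartment`,
#'   `activity_kBq` (>= 0). Conventional compartments: skeleton, liver,
#'   kidneys, brain, thymus, heart, lungs, spleen, ART (abdominal remainder
#'   tissue), carcass.
#' @param excreta data.frame with columns `cage`, `day` (1..`n_days`,
#'   complete per cage), `route` (`"urine"` or `"feces"`), `activity_kBq`.
#' @param injected_kBq injected activity per animal (kBq); scalar or vector
#'   named by `animal_id`.
#' @param n_days number of collection days (default 4).
#' @return An object of class `balance_study`.
#' @export
balance_study <- function(animals, organs, excreta, injected_kBq,
                          n_days = 4L) {
  animals <- as.data.frame(animals, stringsAsFactors = FALSE)
  organs <- as.data.frame(organs, stringsAsFactors = FALSE)
  excreta <- as.data.frame(excreta, stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "group") %in% names(animals)),
            all(c("animal_id", "compartment", "activity_kBq") %in% names(organs)),
            all(c("cage", "day", "route", "activity_kBq") %in% names(excreta)))
  if (is.null(animals$cage)) animals$cage <- animals$group
  if (anyDuplicated(animals$animal_id))
    stop("animal_id must be unique", call. = FALSE)
  if (!all(organs$animal_id %in% animals$animal_id))
    stop("organ records for unknown animal(s)", call. = FALSE)
  if (any(organs$activity_kBq < 0) || any(excreta$activity_kBq < 0))
    stop("activities must be >= 0", call. = FALSE)
  if (!all(excreta$route %in% c("urine", "feces")))
    stop("excreta route must be 'urine' or 'feces'", call. = FALSE)
  if (!all(excreta$cage %in% animals$cage))
    stop("excreta records for unknown cage(s)", call. = FALSE)
  for (cg in unique(animals$cage)) {
    have <- excreta[excreta$cage == cg, ]
    need <- expand.grid(day = seq_len(n_days), route = c("urine", "feces"),
                        stringsAsFactors = FALSE)
    key <- paste(have$day, have$route)
    if (!all(paste(need$day, need$route) %in% key))
      stop("incomplete excreta records for cage '", cg,
           "': days 1..", n_days, " x {urine, feces} required", call. = FALSE)
  }
  if (length(injected_kBq) == 1L)
    injected_kBq <- stats::setNames(rep(injected_kBq, nrow(animals)),
                                    animals$animal_id)
  if (!all(animals$animal_id %in% names(injected_kBq)))
    stop("injected_kBq must cover every animal", call. = FALSE)
  structure(list(animals = animals, organs = organs, excreta = excreta,
                 injected_kBq = injected_kBq[animals$animal_id],
                 n_days = as.integer(n_days)),
            class = "balance_study")
}

#' @export
print.balance_study <- function(x, ...) {
  cat("<balance_study>", nrow(x$animals), "animals in",
      length(unique(x$animals$group)), "groups,",
      x$n_days, "collection days\n")
  invisible(x)
}

#' Read a balance study from delimited text
#'
#' The records file is tab-separated with columns `animal_id`, `group`,
#' `compartment`, `activity_kBq`. Organ rows carry the animal's id; excreta
#' rows are cage (group) samples, carry the cage label in `animal_id`, and
#' use compartments of the form `urine_day1` ... `feces_day4`. The manifest
#' is a YAML file with at least `injected_kBq` (per-animal injected
#' activity), and optionally `n_days`.
#'
#' @param records_path path to the records file.
#' @param manifest_path path to the YAML manifest.
#' @return A [balance_study()].
#' @export
read_balance_study <- function(records_path, manifest_path) {
  rec <- utils::read.delim(records_path, stringsAsFactors = FALSE)
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$injected_kBq))
    stop("manifest must contain 'injected_kBq'", call. = FALSE)
  n_days <- if (is.null(man$n_days)) 4L else as.integer(man$n_days)
  is_exc <- grepl("^(urine|feces)_day[0-9]+$", rec$compartment)
  organs <- rec[!is_exc, c("animal_id", "group", "compartment", "activity_kBq")]
  exc <- rec[is_exc, ]
  m <- regmatches(exc$compartment,
                  regexec("^(urine|feces)_day([0-9]+)$", exc$compartment))
  excreta <- data.frame(
    cage = exc$animal_id,
    day = as.integer(vapply(m, `[`, character(1), 3)),
    route = vapply(m, `[`, character(1), 2),
    activity_kBq = exc$activity_kBq,
    stringsAsFactors = FALSE
  )
  animals <- unique(organs[, c("animal_id", "group")])
  balance_study(animals, organs[, c("animal_id", "compartment", "activity_kBq")],
                excreta, injected_kBq = man$injected_kBq, n_days = n_days)
}

#' Write a balance study to delimited text
#'
#' Inverse of [read_balance_study()]: writes the records file and the YAML
#' manifest.
#'
#' @param study a [balance_study()].
#' @param records_path,manifest_path output paths.
#' @return `records_path`, invisibly.
#' @export
write_balance_study <- function(study, records_path, manifest_path) {
  stopifnot(inherits(study, "balance_study"))
  org <- merge(study$organs, study$animals[, c("animal_id", "group")],
               by = "animal_id", sort = FALSE)
  org <- org[, c("animal_id", "group", "compartment", "activity_kBq")]
  exc <- study$excreta
  cage_group <- unique(study$animals[, c("cage", "group")])
  exc <- merge(exc, cage_group, by = "cage", sort = FALSE)
  exc_rows <- data.frame(
    animal_id = exc$cage, group = exc$group,
    compartment = sprintf("%s_day%d", exc$route, exc$day),
    activity_kBq = exc$activity_kBq, stringsAsFactors = FALSE
  )
  utils::write.table(rbind(org, exc_rows), records_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  inj <- study$injected_kBq
  man <- list(n_days = study$n_days,
              injected_kBq = if (length(unique(inj)) == 1L)
                unname(inj[1]) else as.list(inj))
  yaml::write_yaml(man, manifest_path)
  invisible(records_path)
}
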