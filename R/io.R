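#' @title CSV / YAML input-output
#' @description
#' Readers and writers for the plain-text schemas the pipeline exchanges:
#' surveys, coefficient sets, rate tables, demographic inputs, projections
#' and ground-truth presets.
#' @name io
NULL

#' Read a two-wave survey CSV
#'
#' Schema: respondent_id, sex (female/male), age_w1, weight, cog_w1, fun_w1,
#' cog_w2, fun_w2, dead_w2 (0/1); categories as codebook strings; wave-2
#' categories empty for the dead.
#'
#' @param path CSV file path.
#' @export
read_survey <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(respondent_id = "character"))
  for (col in c("cog_w2", "fun_w2")) d[[col]][d[[col]] == ""] <- NA_character_
  validate_survey(d[d$dead_w2 == 1 | (!is.na(d$cog_w2) & !is.na(d$fun_w2)), ])
  d
}

#' Write a survey as CSV
#' @param survey survey data.frame.
#' @param path CSV file path.
#' @export
write_survey <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write fitted coefficients as tidy CSV
#'
#' One row per (process, origin, destination, term); age terms on the
#' centred scale unless \code{natural = TRUE}.
#'
#' @param coeffs a \code{transition_coefficients} object.
#' @param path CSV file path.
#' @param natural report on the natural (uncentred) age scale.
#' @export
write_coefficients <- function(coeffs, path, natural = FALSE) {
  mats <- if (natural) coef_natural(coeffs)
          else lapply(coeffs$origins, `[[`, "coef")
  rows <- do.call(rbind, lapply(names(mats), function(org) {
    B <- mats[[org]]
    data.frame(process = coeffs$process, origin = org,
               dest = rep(colnames(B), each = nrow(B)),
               term = rep(rownames(B), ncol(B)),
               value = as.vector(B), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a rate table as tidy CSV
#' @param table a \code{rate_table}.
#' @param path CSV file path.
#' @export
write_rate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write demographic inputs as a set of CSVs
#'
#' Creates population.csv, fertility.csv, lifetable.csv and, if present,
#' migration.csv under \code{dir}.
#'
#' @param demog a \code{demographic_inputs} object.
#' @param dir output directory (created if missing).
#' @export
write_demographics <- function(demog, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(demog$initial_population, file.path(dir, "population.csv"),
                   row.names = FALSE)
  utils::write.csv(demog$fertility, file.path(dir, "fertility.csv"),
                   row.names = FALSE)
  utils::write.csv(demog$life_table, file.path(dir, "lifetable.csv"),
                   row.names = FALSE)
  if (!is.null(demog$migration))
    utils::write.csv(demog$migration, file.path(dir, "migration.csv"),
                     row.names = FALSE)
  utils::write.csv(data.frame(state = names(demog$state_prevalence),
                              fraction = as.numeric(demog$state_prevalence)),
                   file.path(dir, "state_prevalence.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read demographic inputs written by [write_demographics()]
#' @param dir directory holding the CSVs.
#' @param sex_ratio_at_birth male births per female birth.
#' @export
read_demographics <- function(dir, sex_ratio_at_birth = 1.05) {
  mig_path <- file.path(dir, "migration.csv")
  prev_path <- file.path(dir, "state_prevalence.csv")
  prev <- NULL
  if (file.exists(prev_path)) {
    pd <- utils::read.csv(prev_path, stringsAsFactors = FALSE)
    prev <- stats::setNames(pd$fraction, pd$state)
  }
  demographic_inputs(
    initial_population = utils::read.csv(file.path(dir, "population.csv")),
    fertility = utils::read.csv(file.path(dir, "fertility.csv")),
    life_table = utils::read.csv(file.path(dir, "lifetable.csv")),
    migration = if (file.exists(mig_path)) utils::read.csv(mig_path) else NULL,
    sex_ratio_at_birth = sex_ratio_at_birth,
    state_prevalence = prev
  )
}

#' Write a projection's stocks and flows as CSV
#'
#' projection.csv (year, age, sex, state, count) and flows.csv.
#'
#' @param projection a \code{projection_result}.
#' @param dir output directory.
#' @param include_sub65 include sub-65 rows (state "SUB65").
#' @export
write_projection <- function(projection, dir, include_sub65 = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(projection_to_df(projection, include_sub65),
                   file.path(dir, "projection.csv"), row.names = FALSE)
  utils::write.csv(projection$flows, file.path(dir, "flows.csv"),
                   row.names = FALSE)
  invisible(dir)
}

coeffs_to_list <- function(coeffs) {
  list(process = coeffs$process, center = coeffs$center,
       origins = lapply(coeffs$origins, function(o) {
         B <- o$coef
         stats::setNames(lapply(seq_len(ncol(B)), function(j)
           as.list(stats::setNames(B[, j], rownames(B)))), colnames(B))
       }))
}

coeffs_from_list <- function(x) {
  origins <- lapply(x$origins, function(o) {
    terms <- names(o[[1]])
    B <- vapply(o, function(d) unlist(d)[terms], numeric(length(terms)))
    B <- matrix(B, nrow = length(terms),
                dimnames = list(terms, names(o)))
    list(coef = B, n = NA_integer_, loglik = NA_real_, iterations = 0L)
  })
  structure(list(process = x$process, origins = origins, center = x$center),
            class = "transition_coefficients")
}

#' Write a ground-truth preset as YAML
#' @param preset a \code{truth_preset}.
#' @param path YAML file path.
#' @export
write_preset <- function(preset, path) {
  yaml::write_yaml(list(
    name = preset$name,
    cognitive = coeffs_to_list(preset$cognitive),
    functional = coeffs_to_list(preset$functional),
    initial_mixture = as.list(preset$initial_mixture)
  ), path)
  invisible(path)
}

#' Read a ground-truth preset written by [write_preset()]
#' @param path YAML file path.
#' @export
read_preset <- function(path) {
  x <- yaml::read_yaml(path)
  p <- list(name = x$name,
            cognitive = coeffs_from_list(x$cognitive),
            functional = coeffs_from_list(x$functional),
            initial_mixture = unlist(x$initial_mixture)[living_states()],
            scenario = demographic_scenario())
  class(p) <- "truth_preset"
  p
}
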