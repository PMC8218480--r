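#' @title Health-state system
#' @description
#' The model tracks older adults (65+) across a composite health-state space
#' built from two dimensions:
#' \itemize{
#'   \item cognition, from the Mini-Mental State Examination (MMSE, 0--30):
#'     \code{INTACT} (>= 24), \code{MILD} (18--23), \code{MODERATE} (10--17),
#'     \code{SEVERE} (<= 9);
#'   \item function, from the count of limitations in six activities of daily
#'     living (ADL: bathing, dressing, eating, transferring, indoor walking,
#'     toileting): \code{ACTIVE} (0), \code{ADL12} (1--2), \code{ADL3P} (3+).
#' }
#' The 12 living combinations plus the absorbing state \code{DEAD} give 13
#' composite states, serialized as \code{"INTACT_ACTIVE"}, \code{"MILD_ADL12"},
#' ..., \code{"DEAD"}.
#' @name health_states
NULL

#' Cognitive severity levels, ordered mildest to most severe
#' @export
COGNITIVE_LEVELS <- c("INTACT", "MILD", "MODERATE", "SEVERE")

#' Functional severity levels, ordered mildest to most severe
#' @export
FUNCTIONAL_LEVELS <- c("ACTIVE", "ADL12", "ADL3P")

#' The 12 living composite states (cognition-major order)
#' @export
living_states <- function() {
  as.vector(t(outer(COGNITIVE_LEVELS, FUNCTIONAL_LEVELS, paste, sep = "_")))
}

#' All 13 composite states including the absorbing death state
#' @export
all_states <- function() c(living_states(), "DEAD")

#' Compose a composite state code from its two dimensions
#'
#' @param cognition character vector of cognitive levels.
#' @param fun character vector of functional levels.
#' @return character vector of composite state codes.
#' @export
composite_state <- function(cognition, fun) {
  stopifnot(all(cognition %in% COGNITIVE_LEVELS), all(fun %in% FUNCTIONAL_LEVELS))
  paste(cognition, fun, sep = "_")
}

check_living <- function(state, what = "state") {
  bad <- setdiff(unique(state), living_states())
  if (length(bad))
    stop(sprintf("%s must be a living composite state; got: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  invisible(state)
}

#' Cognitive component of a composite state
#' @param state character vector of living composite state codes.
#' @export
state_cognition <- function(state) {
  check_living(state)
  sub("_.*$", "", state)
}

#' Functional component of a composite state
#' @param state character vector of living composite state codes.
#' @export
state_function <- function(state) {
  check_living(state)
  sub("^[A-Z]+_", "", state)
}

#' Classify an MMSE total score into a cognitive category
#'
#' Thresholds: intact >= 24, mild 18--23, moderate 10--17, severe <= 9.
#'
#' @param mmse_score integer vector of MMSE totals in 0--30.
#' @return character vector of cognitive categories.
#' @export
classify_cognition <- function(mmse_score) {
  if (any(is.na(mmse_score)))
    stop("MMSE score contains missing values", call. = FALSE)
  if (any(mmse_score != floor(mmse_score)))
    stop("MMSE score must be a whole number", call. = FALSE)
  bad <- mmse_score[mmse_score < 0 | mmse_score > 30]
  if (length(bad))
    stop(sprintf("MMSE score out of range 0-30: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  out <- rep("SEVERE", length(mmse_score))
  out[mmse_score >= 10] <- "MODERATE"
  out[mmse_score >= 18] <- "MILD"
  out[mmse_score >= 24] <- "INTACT"
  out
}

#' Classify an ADL-limitation count into a functional category
#'
#' Six ADL items; 0 limitations = active, 1--2, 3+.
#'
#' @param adl_limitation_count integer vector of limitation counts in 0--6.
#' @return character vector of functional categories.
#' @export
classify_function <- function(adl_limitation_count) {
  x <- adl_limitation_count
  if (any(is.na(x)))
    stop("ADL limitation count contains missing values", call. = FALSE)
  if (any(x != floor(x)))
    stop("ADL limitation count must be a whole number", call. = FALSE)
  bad <- x[x < 0 | x > 6]
  if (length(bad))
    stop(sprintf("ADL limitation count out of range 0-6: %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  out <- rep("ACTIVE", length(x))
  out[x >= 1] <- "ADL12"
  out[x >= 3] <- "ADL3P"
  out
}

#' Impairment class of a living composite state
#'
#' Partition used throughout reporting: \code{NONE} (intact and active),
#' \code{ADL_ONLY} (ADL limitations, cognitively intact), \code{CI_ONLY}
#' (cognitive impairment, no ADL limitations), \code{CI_AND_ADL} (both).
#' "Impaired" means any class other than \code{NONE}.
#'
#' @param state character vector of living composite state codes.
#' @return character vector of impairment classes.
#' @export
impairment_class <- function(state) {
  if (any(state == "DEAD"))
    stop("impairment_class is undefined for DEAD", call. = FALSE)
  check_living(state)
  ci <- state_cognition(state) != "INTACT"
  adl <- state_function(state) != "ACTIVE"
  out <- rep("NONE", length(state))
  out[!ci & adl] <- "ADL_ONLY"
  out[ci & !adl] <- "CI_ONLY"
  out[ci & adl] <- "CI_AND_ADL"
  out
}

#' Nursing-home-type care needs flag
#'
#' TRUE for states with three or more ADL limitations, or moderate-to-severe
#' cognitive impairment, or both.
#'
#' @param state character vector of living composite state codes.
#' @return logical vector.
#' @export
needs_nursing_home_care <- function(state) {
  if (any(state == "DEAD"))
    stop("needs_nursing_home_care is undefined for DEAD", call. = FALSE)
  check_living(state)
  state_function(state) == "ADL3P" |
    state_cognition(state) %in% c("MODERATE", "SEVERE")
}

#' Machine-readable codebook of the composite state system
#'
#' @return a data.frame with one row per living state: code, cognition,
#'   function, impairment_class, nursing_home_flag.
#' @export
state_codebook <- function() {
  st <- living_states()
  data.frame(
    code = st,
    cognition = state_cognition(st),
    `function` = state_function(st),
    impairment_class = impairment_class(st),
    nursing_home_flag = needs_nursing_home_care(st),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Write the state codebook as CSV
#' @param path file path.
#' @export
write_state_codebook <- function(path) {
  utils::write.csv(state_codebook(), path, row.names = FALSE)
  invisible(path)
}

# ---- structural transition rules ------------------------------------------
# No recovery from moderate or severe cognitive impairment; no recovery from
# 3+ ADL limitations. Death is reachable from every living state.

#' Permitted destinations per cognitive origin (structural no-recovery rules)
#' @export
cognitive_destinations <- function() {
  list(
    INTACT   = c("MILD", "MODERATE", "SEVERE", "DEAD"),
    MILD     = c("INTACT", "MODERATE", "SEVERE", "DEAD"),
    MODERATE = c("SEVERE", "DEAD"),
    SEVERE   = "DEAD"
  )
}

#' Permitted destinations per functional origin (structural no-recovery rules)
#' @export
functional_destinations <- function() {
  list(
    ACTIVE = c("ADL12", "ADL3P", "DEAD"),
    ADL12  = c("ACTIVE", "ADL3P", "DEAD"),
    ADL3P  = "DEAD"
  )
}

process_levels <- function(process) {
  switch(process,
         cognitive = COGNITIVE_LEVELS,
         functional = FUNCTIONAL_LEVELS,
         stop("unknown process: ", process, call. = FALSE))
}

process_destinations <- function(process) {
  switch(process,
         cognitive = cognitive_destinations(),
         functional = functional_destinations(),
         stop("unknown process: ", process, call. = FALSE))
}

# severity rank; DEAD treated as most severe for worsening classification
severity_rank <- function(process, state) {
  lv <- c(process_levels(process), "DEAD")
  match(state, lv)
}
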