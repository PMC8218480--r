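#' @title Transition estimation from two-wave panel data
#' @description
#' Two survey waves two years apart are converted into annual transitions by
#' midpoint imputation: a respondent observed in the same category at both
#' waves is assumed to have stayed in it at the midpoint year; a respondent
#' observed in different categories (or dead at wave 2) is assigned the
#' wave-1 or wave-2 value with equal probability, the transition being
#' equally likely to have happened in either year. Each respondent then
#' contributes up to two 1-year transition pairs per process, which enter a
#' weighted multinomial logistic regression per origin state with the choice
#' set restricted to structurally permitted destinations:
#' \itemize{
#'   \item cognitive process: ln(p_ij/p_ii) = b0 + b1 age + b2 age^2 + b3 sex
#'   \item functional process: ln(p_ij/p_ii) = b0 + b1 age + b2 sex + b3 CI
#' }
#' Age is centred at 80 internally (see [coef_natural()]); sex is coded
#' female = 1, male = 0; CI (cognitive impairment, any severity) = 1.
#' @name transition_estimation
NULL

AGE_MIN <- 65L
AGE_MAX <- 100L   # open interval 100+
AGE_CENTER <- 80

SEX_LEVELS <- c("female", "male")

#' Midpoint-state imputation for one process
#'
#' Deterministic when both waves agree; otherwise a fair draw between the
#' wave-1 and wave-2 values (DEAD being an admissible wave-2 value). Uses the
#' current RNG stream; seed with [set.seed()] for reproducibility.
#'
#' @param state_w1 character vector, living states of the process (or
#'   composite states).
#' @param state_w2 character vector, same length; states or "DEAD".
#' @return character vector of imputed midpoint states.
#' @export
impute_midpoint_state <- function(state_w1, state_w2) {
  if (any(state_w1 == "DEAD"))
    stop("wave-1 state cannot be DEAD", call. = FALSE)
  n <- length(state_w1)
  stopifnot(length(state_w2) == n)
  same <- state_w1 == state_w2
  out <- state_w1
  if (any(!same)) {
    take_w2 <- stats::runif(sum(!same)) < 0.5
    out[!same][take_w2] <- state_w2[!same][take_w2]
  }
  out
}

validate_survey <- function(survey) {
  need <- c("respondent_id", "sex", "age_w1", "weight",
            "cog_w1", "fun_w1", "cog_w2", "fun_w2", "dead_w2")
  miss <- setdiff(need, names(survey))
  if (length(miss))
    stop("survey is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!survey$sex %in% SEX_LEVELS))
    stop("sex must be 'female' or 'male'", call. = FALSE)
  if (any(survey$weight <= 0 | !is.finite(survey$weight)))
    stop("sampling weights must be positive and finite", call. = FALSE)
  if (any(survey$age_w1 < AGE_MIN))
    stop("age_w1 must be >= 65", call. = FALSE)
  if (any(!survey$dead_w2 %in% c(0, 1)))
    stop("dead_w2 must be 0/1", call. = FALSE)
  alive <- survey$dead_w2 == 0
  if (any(!survey$cog_w1 %in% COGNITIVE_LEVELS) ||
      any(!survey$fun_w1 %in% FUNCTIONAL_LEVELS))
    stop("invalid wave-1 category codes", call. = FALSE)
  if (any(!survey$cog_w2[alive] %in% COGNITIVE_LEVELS) ||
      any(!survey$fun_w2[alive] %in% FUNCTIONAL_LEVELS))
    stop("invalid wave-2 category codes for survivors", call. = FALSE)
  invisible(survey)
}

# Composite midpoint imputation shared by the two processes. Death at wave 2
# is treated as one of the "different states": the midpoint is the full
# wave-1 state or DEAD with equal probability. For survivors the cognitive
# and functional midpoints are imputed by independent fair draws.
impute_survey_midpoints <- function(survey) {
  n <- nrow(survey)
  dead2 <- survey$dead_w2 == 1
  mid_dead <- rep(FALSE, n)
  mid_cog <- survey$cog_w1
  mid_fun <- survey$fun_w1
  # fixed draw order (death, cognition, function) keeps the stream stable
  u_dead <- stats::runif(n)
  u_cog <- stats::runif(n)
  u_fun <- stats::runif(n)
  mid_dead[dead2] <- u_dead[dead2] < 0.5
  alive2 <- !dead2
  diff_cog <- alive2 & survey$cog_w1 != survey$cog_w2
  mid_cog[diff_cog & u_cog < 0.5] <- survey$cog_w2[diff_cog & u_cog < 0.5]
  diff_fun <- alive2 & survey$fun_w1 != survey$fun_w2
  mid_fun[diff_fun & u_fun < 0.5] <- survey$fun_w2[diff_fun & u_fun < 0.5]
  data.frame(mid_dead = mid_dead, mid_cog = mid_cog, mid_fun = mid_fun,
             stringsAsFactors = FALSE)
}

pairs_from_midpoints <- function(survey, mid, process) {
  n <- nrow(survey)
  age1 <- pmin(survey$age_w1, AGE_MAX)
  age2 <- pmin(survey$age_w1 + 1L, AGE_MAX)
  dead2 <- survey$dead_w2 == 1
  ci_w1 <- as.integer(survey$cog_w1 != "INTACT")
  ci_mid <- as.integer(mid$mid_cog != "INTACT")
  ci_w2 <- ifelse(dead2, ci_mid, as.integer(survey$cog_w2 != "INTACT"))

  if (process == "cognitive") {
    o1 <- survey$cog_w1
    d1 <- ifelse(mid$mid_dead, "DEAD", mid$mid_cog)
    o2 <- mid$mid_cog
    d2 <- ifelse(dead2, "DEAD", survey$cog_w2)
    ci1 <- ci2 <- rep(NA_integer_, n)
  } else {
    o1 <- survey$fun_w1
    d1 <- ifelse(mid$mid_dead, "DEAD", mid$mid_fun)
    o2 <- mid$mid_fun
    d2 <- ifelse(dead2, "DEAD", survey$fun_w2)
    # CI covariate: cognition at the end of the interval (last known
    # cognition when the interval ends in death)
    ci1 <- ifelse(mid$mid_dead, ci_w1, ci_mid)
    ci2 <- ci_w2
  }
  second <- !mid$mid_dead
  pairs <- data.frame(
    respondent_id = c(survey$respondent_id, survey$respondent_id[second]),
    origin = c(o1, o2[second]),
    dest = c(d1, d2[second]),
    age = c(age1, age2[second]),
    sex = c(survey$sex, survey$sex[second]),
    female = as.integer(c(survey$sex, survey$sex[second]) == "female"),
    ci = c(ci1, ci2[second]),
    weight = c(survey$weight, survey$weight[second]),
    stringsAsFactors = FALSE
  )
  # drop structurally impossible observed transitions (possible in noisy
  # real data; never produced by the synthetic generator)
  dests <- process_destinations(process)
  allowed <- c(paste(process_levels(process), process_levels(process)),
               unlist(lapply(names(dests), function(o) paste(o, dests[[o]]))))
  ok <- paste(pairs$origin, pairs$dest) %in% allowed
  if (any(!ok))
    warning(sprintf("dropped %d pair(s) with structurally forbidden %s transitions",
                    sum(!ok), process), call. = FALSE)
  pairs[ok, , drop = FALSE]
}

#' Build annual transition pairs from a two-wave survey
#'
#' Respondents lost to follow-up (alive-status unknown at wave 2, i.e.
#' missing wave-2 categories with dead_w2 = 0) are dropped with a message.
#' Imputation draws come from the current RNG stream; with the same seed the
#' composite midpoints, and hence the CI covariate, agree across the two
#' processes.
#'
#' @param survey a survey data.frame (see [read_survey()] for the schema).
#' @param process "cognitive" or "functional".
#' @param midpoint "impute" (the two-wave method; default) or "recorded",
#'   which uses the true midpoint columns (mid_cog, mid_fun, mid_dead) that
#'   the synthetic generator can emit under its debug flag. Real surveys do
#'   not observe the midpoint; "recorded" exists so the regression machinery
#'   can be validated in isolation from the imputation approximation.
#' @return data.frame of 1-year transition pairs with covariates.
#' @export
build_transition_pairs <- function(survey, process = c("cognitive", "functional"),
                                   midpoint = c("impute", "recorded")) {
  process <- match.arg(process)
  midpoint <- match.arg(midpoint)
  if (nrow(survey) == 0) {
    warning("empty survey: no transition pairs", call. = FALSE)
    return(data.frame())
  }
  lost <- survey$dead_w2 == 0 & (is.na(survey$cog_w2) | is.na(survey$fun_w2))
  if (any(lost)) {
    message(sprintf("dropping %d respondent(s) lost to follow-up", sum(lost)))
    survey <- survey[!lost, , drop = FALSE]
  }
  validate_survey(survey)
  mid <- survey_midpoints(survey, midpoint)
  pairs_from_midpoints(survey, mid, process)
}

survey_midpoints <- function(survey, midpoint) {
  if (midpoint == "recorded") {
    need <- c("mid_cog", "mid_fun", "mid_dead")
    if (!all(need %in% names(survey)))
      stop("midpoint = 'recorded' needs mid_cog/mid_fun/mid_dead columns ",
           "(generate the survey with keep_midpoint = TRUE)", call. = FALSE)
    data.frame(mid_dead = survey$mid_dead == 1,
               mid_cog = ifelse(survey$mid_dead == 1, survey$cog_w1, survey$mid_cog),
               mid_fun = ifelse(survey$mid_dead == 1, survey$fun_w1, survey$mid_fun),
               stringsAsFactors = FALSE)
  } else {
    impute_survey_midpoints(survey)
  }
}

#' Fit the per-origin multinomial transition models
#'
#' One weighted multinomial logit per origin state, reference category
#' "stay", choice set restricted to the structurally permitted destinations.
#' A permitted destination never observed in the data gets its intercept
#' fixed at -20 (probability ~ 0) with a warning rather than failing.
#'
#' @param pairs transition pairs from [build_transition_pairs()].
#' @param process "cognitive" or "functional".
#' @param start optional \code{transition_coefficients} used as warm start
#'   (e.g. the point estimate when refitting bootstrap replicates).
#' @return an object of class \code{transition_coefficients}: per origin a
#'   coefficient matrix (terms x destinations) on the age-centred scale.
#' @export
fit_transition_model <- function(pairs, process = c("cognitive", "functional"),
                                 start = NULL) {
  process <- match.arg(process)
  origins <- process_levels(process)
  dests <- process_destinations(process)
  terms <- if (process == "cognitive")
    c("(Intercept)", "age_c", "age_c2", "female")
  else
    c("(Intercept)", "age_c", "female", "ci")

  fits <- list()
  for (org in origins) {
    rows <- pairs[pairs$origin == org, , drop = FALSE]
    if (nrow(rows) == 0)
      stop(sprintf("no transition pairs observed for origin %s; enlarge the data",
                   org), call. = FALSE)
    permitted <- dests[[org]]
    a <- rows$age - AGE_CENTER
    X <- if (process == "cognitive") cbind(1, a, a^2, rows$female)
         else cbind(1, a, rows$female, rows$ci)
    colnames(X) <- terms
    observed <- intersect(permitted, unique(rows$dest))
    unobserved <- setdiff(permitted, observed)
    B <- matrix(0, length(terms), length(permitted),
                dimnames = list(terms, permitted))
    B["(Intercept)", unobserved] <- -20
    if (length(unobserved))
      warning(sprintf("origin %s: destination(s) %s never observed; intercept fixed at -20",
                      org, paste(unobserved, collapse = ", ")), call. = FALSE)
    fit <- NULL
    if (length(observed)) {
      y <- match(rows$dest, observed)
      y[is.na(y)] <- 0L                 # stay = reference
      s0 <- NULL
      if (!is.null(start) && org %in% names(start$origins)) {
        sB <- start$origins[[org]]$coef
        if (all(observed %in% colnames(sB)) &&
            identical(rownames(sB), terms) && all(is.finite(sB[, observed])))
          s0 <- sB[, observed, drop = FALSE]
      }
      fit <- fit_mlogit(X, y, rows$weight, start = s0)
      if (fit$separation || !fit$converged)
        stop(errorCondition(sprintf(
          "multinomial fit for origin %s (%s process) did not converge; enlarge the data",
          org, process), class = "mspop_estimation_error"))
      B[, observed] <- fit$coef
    }
    fits[[org]] <- list(coef = B, n = nrow(rows),
                        loglik = if (is.null(fit)) NA_real_ else fit$loglik,
                        iterations = if (is.null(fit)) 0L else fit$iterations)
  }
  structure(list(process = process, origins = fits, center = AGE_CENTER),
            class = "transition_coefficients")
}

#' @export
print.transition_coefficients <- function(x, ...) {
  cat(sprintf("Transition model coefficients (%s process, age centred at %d)\n",
              x$process, x$center))
  for (org in names(x$origins)) {
    cat(sprintf("\norigin %s (n = %s):\n", org, x$origins[[org]]$n))
    print(round(x$origins[[org]]$coef, 4))
  }
  invisible(x)
}

#' Coefficients on the natural (uncentred) age scale
#'
#' Internally age enters as (age - 80) for optimizer conditioning; this
#' accessor undoes the shift for reporting.
#'
#' @param coeffs a \code{transition_coefficients} object.
#' @return list of per-origin coefficient matrices with terms on the natural
#'   age scale.
#' @export
coef_natural <- function(coeffs) {
  stopifnot(inherits(coeffs, "transition_coefficients"))
  c0 <- coeffs$center
  lapply(coeffs$origins, function(o) {
    B <- o$coef
    out <- B
    if ("age_c2" %in% rownames(B)) {
      out["(Intercept)", ] <- B["(Intercept)", ] - c0 * B["age_c", ] +
        c0^2 * B["age_c2", ]
      out["age_c", ] <- B["age_c", ] - 2 * c0 * B["age_c2", ]
      rownames(out) <- sub("^age_c2$", "age2", sub("^age_c$", "age", rownames(out)))
    } else {
      out["(Intercept)", ] <- B["(Intercept)", ] - c0 * B["age_c", ]
      rownames(out) <- sub("^age_c$", "age", rownames(out))
    }
    out
  })
}

#' Annual transition probabilities implied by fitted coefficients
#'
#' Softmax over the permitted destinations with "stay" as reference:
#' p_ij = exp(eta_ij) / (1 + sum_k exp(eta_ik)). Structurally forbidden
#' destinations have probability exactly 0. Ages above 100 use the age-100
#' (open interval) value.
#'
#' @param coeffs \code{transition_coefficients}.
#' @param origin origin state of the process.
#' @param age age in years (>= 65; capped at 100).
#' @param sex "female" or "male".
#' @param ci 0/1 cognitive-impairment indicator (functional process only).
#' @return named probability vector over all process states plus DEAD.
#' @export
predict_transition_probs <- function(coeffs, origin, age, sex, ci = NULL) {
  stopifnot(inherits(coeffs, "transition_coefficients"))
  process <- coeffs$process
  if (!origin %in% process_levels(process))
    stop("unknown origin state: ", origin, call. = FALSE)
  if (age < AGE_MIN) stop("age must be >= 65", call. = FALSE)
  if (!sex %in% SEX_LEVELS) stop("sex must be 'female' or 'male'", call. = FALSE)
  a <- min(age, AGE_MAX) - coeffs$center
  female <- as.integer(sex == "female")
  x <- if (process == "cognitive") c(1, a, a^2, female)
  else {
    if (is.null(ci)) stop("ci indicator required for the functional process",
                          call. = FALSE)
    c(1, a, female, as.integer(ci))
  }
  B <- coeffs$origins[[origin]]$coef
  eta <- drop(x %*% B)
  ex <- exp(eta)
  denom <- 1 + sum(ex)
  out <- stats::setNames(numeric(length(process_levels(process)) + 1L),
                         c(process_levels(process), "DEAD"))
  out[names(ex)] <- ex / denom
  out[origin] <- 1 / denom
  out
}

# fast vectorised kernel evaluation over the age grid for one (origin, sex, ci)
predict_probs_grid <- function(coeffs, origin, sex, ci = NULL) {
  process <- coeffs$process
  ages <- AGE_MIN:AGE_MAX
  a <- ages - coeffs$center
  female <- as.integer(sex == "female")
  X <- if (process == "cognitive") cbind(1, a, a^2, female)
       else cbind(1, a, female, as.integer(ci))
  B <- coeffs$origins[[origin]]$coef
  eta <- X %*% B
  ex <- exp(eta)
  denom <- 1 + rowSums(ex)
  P <- matrix(0, length(ages), length(process_levels(process)) + 1L,
              dimnames = list(ages, c(process_levels(process), "DEAD")))
  P[, colnames(ex)] <- ex / denom
  P[, origin] <- 1 / denom
  P
}

#' Build the annual transition rate table
#'
#' Tabulates the fitted annual transition probability vectors on the full
#' grid: ages 65--100 (100 = open interval), both sexes, every origin of each
#' process, and both CI strata for the functional process. Every row sums to
#' one; structural zeros are exact zeros.
#'
#' @param cog_coeffs fitted cognitive \code{transition_coefficients}.
#' @param fun_coeffs fitted functional \code{transition_coefficients}.
#' @return an object of class \code{rate_table} holding two probability
#'   arrays: \code{cognitive[age, sex, origin, dest]} and
#'   \code{functional[age, sex, ci, origin, dest]}.
#' @export
build_rate_table <- function(cog_coeffs, fun_coeffs) {
  stopifnot(identical(cog_coeffs$process, "cognitive"),
            identical(fun_coeffs$process, "functional"))
  ages <- as.character(AGE_MIN:AGE_MAX)
  cogd <- c(COGNITIVE_LEVELS, "DEAD")
  fund <- c(FUNCTIONAL_LEVELS, "DEAD")
  cog <- array(0, dim = c(length(ages), 2, 4, 5),
               dimnames = list(age = ages, sex = SEX_LEVELS,
                               origin = COGNITIVE_LEVELS, dest = cogd))
  fun <- array(0, dim = c(length(ages), 2, 2, 3, 4),
               dimnames = list(age = ages, sex = SEX_LEVELS,
                               ci = c("0", "1"),
                               origin = FUNCTIONAL_LEVELS, dest = fund))
  for (sx in SEX_LEVELS) {
    for (org in COGNITIVE_LEVELS)
      cog[, sx, org, ] <- predict_probs_grid(cog_coeffs, org, sx)
    for (cistr in c("0", "1"))
      for (org in FUNCTIONAL_LEVELS)
        fun[, sx, cistr, org, ] <-
          predict_probs_grid(fun_coeffs, org, sx, ci = as.integer(cistr))
  }
  tab <- structure(list(cognitive = cog, functional = fun),
                   class = "rate_table")
  validate_rate_table(tab)
  tab
}

validate_rate_table <- function(tab, tol = 1e-12) {
  rs_cog <- apply(tab$cognitive, c(1, 2, 3), sum)
  rs_fun <- apply(tab$functional, c(1, 2, 3, 4), sum)
  if (max(abs(rs_cog - 1)) > tol || max(abs(rs_fun - 1)) > tol)
    stop("rate table rows do not sum to 1", call. = FALSE)
  if (min(tab$cognitive) < 0 || min(tab$functional) < 0)
    stop("negative transition probability", call. = FALSE)
  # structural zeros
  for (org in COGNITIVE_LEVELS) {
    forb <- setdiff(c(COGNITIVE_LEVELS, "DEAD"),
                    c(org, cognitive_destinations()[[org]]))
    if (length(forb) && any(tab$cognitive[, , org, forb] != 0))
      stop("structural zero violated in cognitive table", call. = FALSE)
  }
  for (org in FUNCTIONAL_LEVELS) {
    forb <- setdiff(c(FUNCTIONAL_LEVELS, "DEAD"),
                    c(org, functional_destinations()[[org]]))
    if (length(forb) && any(tab$functional[, , , org, forb] != 0))
      stop("structural zero violated in functional table", call. = FALSE)
  }
  invisible(tab)
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Annual transition rate table\n")
  cat("  cognitive : ages 65-100+ x sex x 4 origins -> 5 destinations\n")
  cat("  functional: ages 65-100+ x sex x CI stratum x 3 origins -> 4 destinations\n")
  invisible(x)
}

#' Tidy data.frame view of a rate table
#' @param x a \code{rate_table}.
#' @param ... unused.
#' @export
as.data.frame.rate_table <- function(x, ...) {
  cog <- as.data.frame.table(x$cognitive, responseName = "value",
                             stringsAsFactors = FALSE)
  cog$process <- "cognitive"; cog$ci <- NA_character_
  fun <- as.data.frame.table(x$functional, responseName = "value",
                             stringsAsFactors = FALSE)
  fun$process <- "functional"
  out <- rbind(cog[, c("process", "origin", "dest", "age", "sex", "ci", "value")],
               fun[, c("process", "origin", "dest", "age", "sex", "ci", "value")])
  out$age <- as.integer(out$age)
  rownames(out) <- NULL
  out
}

#' Estimate both transition processes from a survey
#'
#' Convenience wrapper: seeds the RNG, imputes the midpoint states once (so
#' the CI covariate of the functional process is consistent with the imputed
#' cognitive midpoints), fits both processes and tabulates the rate table.
#'
#' @param survey two-wave survey data.frame.
#' @param seed integer seed for the imputation draws.
#' @param midpoint "impute" or "recorded", see [build_transition_pairs()].
#' @return list(cognitive, functional, rate_table).
#' @export
estimate_transition_models <- function(survey, seed = 1L,
                                       midpoint = c("impute", "recorded")) {
  midpoint <- match.arg(midpoint)
  set.seed(seed)
  lost <- survey$dead_w2 == 0 & (is.na(survey$cog_w2) | is.na(survey$fun_w2))
  if (any(lost)) {
    message(sprintf("dropping %d respondent(s) lost to follow-up", sum(lost)))
    survey <- survey[!lost, , drop = FALSE]
  }
  validate_survey(survey)
  mid <- survey_midpoints(survey, midpoint)
  cogp <- pairs_from_midpoints(survey, mid, "cognitive")
  funp <- pairs_from_midpoints(survey, mid, "functional")
  cog <- fit_transition_model(cogp, "cognitive")
  fun <- fit_transition_model(funp, "functional")
  list(cognitive = cog, functional = fun,
       rate_table = build_rate_table(cog, fun))
}
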