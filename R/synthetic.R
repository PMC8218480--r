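#' @title Synthetic cohorts with known ground truth
#' @description
#' Stand-ins for the restricted survey and census inputs: a deterministic
#' demographic-input builder and a two-wave panel generator driven by known
#' transition kernels, so that estimation, bootstrap and projection can be
#' validated by parameter recovery. The generator targets structural, not
#' empirical, realism: state occupancies are severity-enriched relative to
#' community prevalence so every origin state has adequate exposure, and the
#' wave-1 age distribution is close to uniform over 65--100, mirroring the
#' oldest-old oversampling of longevity surveys.
#' @name synthetic_cohort
NULL

truth_coeffs <- function(process, mats) {
  terms <- if (process == "cognitive")
    c("(Intercept)", "age_c", "age_c2", "female")
  else c("(Intercept)", "age_c", "female", "ci")
  origins <- lapply(names(mats), function(org) {
    B <- mats[[org]]
    stopifnot(identical(rownames(B), terms))
    list(coef = B, n = NA_integer_, loglik = NA_real_, iterations = 0L)
  })
  names(origins) <- names(mats)
  structure(list(process = process, origins = origins, center = AGE_CENTER),
            class = "transition_coefficients")
}

cmat <- function(terms, dests, ...) {
  matrix(c(...), nrow = length(terms), dimnames = list(terms, dests))
}

# "paper-like" cognitive kernel: worsening and death log-odds increase with
# age; recovery decreases with age; female excess for intact -> any CI and
# for mild -> intact / mild -> death / severe -> death; male excess for
# intact -> death and for progression among the impaired.
paper_like_cognitive <- function() {
  t4 <- c("(Intercept)", "age_c", "age_c2", "female")
  truth_coeffs("cognitive", list(
    INTACT = cmat(t4, c("MILD", "MODERATE", "SEVERE", "DEAD"),
                  -1.9, 0.05, 6e-4, 0.25,
                  -3.0, 0.07, 8e-4, 0.25,
                  -4.2, 0.09, 1e-3, 0.25,
                  -3.0, 0.08, 8e-4, -0.35),
    MILD = cmat(t4, c("INTACT", "MODERATE", "SEVERE", "DEAD"),
                -1.6, -0.05, -5e-4, 0.20,
                -1.8, 0.06, 6e-4, -0.30,
                -3.2, 0.08, 8e-4, -0.30,
                -2.6, 0.08, 8e-4, 0.15),
    MODERATE = cmat(t4, c("SEVERE", "DEAD"),
                    -1.4, 0.05, 5e-4, -0.25,
                    -2.0, 0.07, 7e-4, -0.15),
    SEVERE = cmat(t4, "DEAD",
                  -0.9, 0.06, 5e-4, 0.20)
  ))
}

# "paper-like" functional kernel: onset/progression/death increase with age
# and with cognitive impairment; recovery from 1-2 ADL decreases with age,
# is higher for females and lower under CI; onset/progression/death higher
# for males.
paper_like_functional <- function() {
  t4 <- c("(Intercept)", "age_c", "female", "ci")
  truth_coeffs("functional", list(
    ACTIVE = cmat(t4, c("ADL12", "ADL3P", "DEAD"),
                  -2.0, 0.06, -0.20, 0.50,
                  -3.3, 0.08, -0.20, 0.60,
                  -3.0, 0.08, -0.25, 0.50),
    ADL12 = cmat(t4, c("ACTIVE", "ADL3P", "DEAD"),
                 -1.2, -0.05, 0.25, -0.40,
                 -1.9, 0.06, -0.30, 0.50,
                 -2.4, 0.07, -0.20, 0.50),
    ADL3P = cmat(t4, "DEAD",
                 -0.8, 0.06, -0.20, 0.40)
  ))
}

identity_cognitive <- function() {
  t4 <- c("(Intercept)", "age_c", "age_c2", "female")
  z <- function(dests) {
    B <- matrix(0, 4, length(dests), dimnames = list(t4, dests))
    B["(Intercept)", ] <- -Inf
    B
  }
  truth_coeffs("cognitive", list(
    INTACT = z(c("MILD", "MODERATE", "SEVERE", "DEAD")),
    MILD = z(c("INTACT", "MODERATE", "SEVERE", "DEAD")),
    MODERATE = z(c("SEVERE", "DEAD")),
    SEVERE = z("DEAD")
  ))
}

identity_functional <- function() {
  t4 <- c("(Intercept)", "age_c", "female", "ci")
  z <- function(dests) {
    B <- matrix(0, 4, length(dests), dimnames = list(t4, dests))
    B["(Intercept)", ] <- -Inf
    B
  }
  truth_coeffs("functional", list(
    ACTIVE = z(c("ADL12", "ADL3P", "DEAD")),
    ADL12 = z(c("ACTIVE", "ADL3P", "DEAD")),
    ADL3P = z("DEAD")
  ))
}

shift_intercepts <- function(coeffs, delta) {
  coeffs$origins <- lapply(coeffs$origins, function(o) {
    o$coef["(Intercept)", ] <- o$coef["(Intercept)", ] + delta
    o
  })
  coeffs
}

# wave-1 composite mixture: independent severity-enriched marginals
default_initial_mixture <- function() {
  cogm <- c(INTACT = 0.38, MILD = 0.26, MODERATE = 0.20, SEVERE = 0.16)
  funm <- c(ACTIVE = 0.47, ADL12 = 0.31, ADL3P = 0.22)
  # cognition-major order to match living_states()
  m <- outer(cogm, funm)
  out <- as.vector(t(m))
  names(out) <- living_states()
  out
}

#' Named collection of ground-truth presets
#'
#' \describe{
#'   \item{null}{no transitions at all (exact structural zeros everywhere);
#'     projections keep every entrant intact-active.}
#'   \item{paper_like}{qualitatively realistic kernels: worsening and death
#'     increase with age and with cognitive impairment, recovery decreases
#'     with age; female excess for intact-to-CI onset, male excess for ADL
#'     progression and most deaths.}
#'   \item{stress}{the paper_like kernels with all non-stay intercepts
#'     raised by 0.8 (high turnover).}
#'   \item{cognitive_only}{paper_like cognition, frozen function: used for
#'     parameter-recovery and bootstrap-coverage calibration experiments,
#'     where the marginal estimand must equal the kernel truth.}
#'   \item{functional_only}{frozen cognition (so CI is a fixed covariate),
#'     paper_like function.}
#' }
#'
#' @return named list of presets; each preset holds cognitive and functional
#'   \code{transition_coefficients}, an initial composite-state mixture and
#'   a demographic scenario.
#' @export
truth_presets <- function() {
  base <- list(initial_mixture = default_initial_mixture(),
               scenario = demographic_scenario())
  mk <- function(name, cog, fun) {
    p <- c(list(name = name, cognitive = cog, functional = fun), base)
    class(p) <- "truth_preset"
    p
  }
  list(
    null = mk("null", identity_cognitive(), identity_functional()),
    paper_like = mk("paper_like", paper_like_cognitive(), paper_like_functional()),
    stress = mk("stress",
                shift_intercepts(paper_like_cognitive(), 0.8),
                shift_intercepts(paper_like_functional(), 0.8)),
    cognitive_only = mk("cognitive_only", paper_like_cognitive(),
                        identity_functional()),
    functional_only = mk("functional_only", identity_cognitive(),
                         paper_like_functional())
  )
}

#' @export
print.truth_preset <- function(x, ...) {
  cat(sprintf("Ground-truth preset '%s'\n", x$name))
  invisible(x)
}

#' Survey generator configuration
#'
#' @param n number of respondents (default: the 1824 of the source survey,
#'   1010 female / 814 male).
#' @param age_decay geometric decay rate of the wave-1 age distribution over
#'   65--100 (0.02 = near-uniform, emulating oldest-old oversampling).
#' @param female_share probability of being female.
#' @param weight_sdlog log-sd of the log-normal sampling weights; 0 or
#'   \code{unit_weights = TRUE} gives unit weights.
#' @param unit_weights use weight 1 for everyone.
#' @param keep_midpoint debug flag: also record the true (normally hidden)
#'   midpoint state.
#' @export
survey_config <- function(n = 1824L, age_decay = 0.02,
                          female_share = 1010 / 1824, weight_sdlog = 0.5,
                          unit_weights = FALSE, keep_midpoint = FALSE) {
  stopifnot(n >= 1, age_decay >= 0, female_share >= 0, female_share <= 1)
  list(n = as.integer(n), age_decay = age_decay, female_share = female_share,
       weight_sdlog = weight_sdlog, unit_weights = unit_weights,
       keep_midpoint = keep_midpoint)
}

# sample one destination per row of a probability matrix (rows sum to 1)
sample_rows <- function(P, u) {
  cp <- t(apply(P, 1, cumsum))
  idx <- rowSums(u > cp) + 1L
  colnames(P)[pmin(idx, ncol(P))]
}

#' Generate a two-wave panel survey from a truth preset
#'
#' Each respondent draws a wave-1 composite state from the preset's initial
#' mixture, then undergoes two sequential annual transitions from the truth
#' kernels in the projection's combination order: cognitive kernel first,
#' then the functional kernel with the CI stratum taken from the
#' post-transition cognition; death by either kernel is absorbing. Only the
#' wave-1 and wave-2 states are recorded -- the midpoint stays hidden as in
#' real data (unless \code{keep_midpoint}).
#'
#' @param truth a preset from [truth_presets()].
#' @param config a [survey_config()].
#' @param seed integer seed.
#' @return survey data.frame in the standard schema.
#' @export
generate_survey <- function(truth, config = survey_config(), seed = 1L) {
  stopifnot(inherits(truth, "truth_preset"))
  set.seed(seed)
  n <- config$n
  ages <- AGE_MIN:AGE_MAX
  agew <- exp(-config$age_decay * (ages - AGE_MIN))
  age_w1 <- sample(ages, n, replace = TRUE, prob = agew)
  sex <- ifelse(stats::runif(n) < config$female_share, "female", "male")
  weight <- if (config$unit_weights || config$weight_sdlog == 0) rep(1, n)
            else stats::rlnorm(n, 0, config$weight_sdlog)
  state1 <- sample(names(truth$initial_mixture), n, replace = TRUE,
                   prob = truth$initial_mixture)
  cog <- state_cognition(state1)
  fun <- state_function(state1)

  tab <- build_rate_table(truth$cognitive, truth$functional)
  sexi <- ifelse(sex == "female", 1L, 2L)

  n_age <- AGE_MAX - AGE_MIN + 1L
  step_year <- function(cog, fun, alive, age) {
    agei <- pmin(age, AGE_MAX) - AGE_MIN + 1L
    u_cog <- stats::runif(length(cog))
    u_fun <- stats::runif(length(cog))
    new_cog <- cog; new_fun <- fun; new_alive <- alive
    idx <- which(alive)
    if (length(idx)) {
      # gather kernel rows by linear array index (dest is the last stride)
      orgi <- match(cog[idx], COGNITIVE_LEVELS)
      base <- agei[idx] + (sexi[idx] - 1L) * n_age + (orgi - 1L) * (2L * n_age)
      Pc <- matrix(0, length(idx), 5,
                   dimnames = list(NULL, c(COGNITIVE_LEVELS, "DEAD")))
      for (j in 1:5) Pc[, j] <- tab$cognitive[base + (j - 1L) * (8L * n_age)]
      dc <- sample_rows(Pc, u_cog[idx])
      new_cog[idx] <- ifelse(dc == "DEAD", cog[idx], dc)
      died_c <- dc == "DEAD"
      new_alive[idx][died_c] <- FALSE
      idx2 <- idx[!died_c]
      if (length(idx2)) {
        cii <- as.integer(new_cog[idx2] != "INTACT")
        forgi <- match(fun[idx2], FUNCTIONAL_LEVELS)
        baself <- agei[idx2] + (sexi[idx2] - 1L) * n_age + cii * (2L * n_age) +
          (forgi - 1L) * (4L * n_age)
        Pf <- matrix(0, length(idx2), 4,
                     dimnames = list(NULL, c(FUNCTIONAL_LEVELS, "DEAD")))
        for (j in 1:4) Pf[, j] <- tab$functional[baself + (j - 1L) * (12L * n_age)]
        df <- sample_rows(Pf, u_fun[idx2])
        new_fun[idx2] <- ifelse(df == "DEAD", fun[idx2], df)
        new_alive[idx2][df == "DEAD"] <- FALSE
      }
    }
    list(cog = new_cog, fun = new_fun, alive = new_alive)
  }

  alive <- rep(TRUE, n)
  y1 <- step_year(cog, fun, alive, age_w1)
  y2 <- step_year(y1$cog, y1$fun, y1$alive, age_w1 + 1L)

  out <- data.frame(
    respondent_id = sprintf("R%06d", seq_len(n)),
    sex = sex, age_w1 = age_w1, weight = weight,
    cog_w1 = cog, fun_w1 = fun,
    cog_w2 = ifelse(y2$alive, y2$cog, NA_character_),
    fun_w2 = ifelse(y2$alive, y2$fun, NA_character_),
    dead_w2 = as.integer(!y2$alive),
    stringsAsFactors = FALSE
  )
  if (config$keep_midpoint) {
    out$mid_cog <- ifelse(y1$alive, y1$cog, NA_character_)
    out$mid_fun <- ifelse(y1$alive, y1$fun, NA_character_)
    out$mid_dead <- as.integer(!y1$alive)
  }
  out
}

# ---- demographic inputs ----------------------------------------------------

#' Demographic scenario parameters for the synthetic input builder
#'
#' Defaults describe a large, aging, low-fertility population with a
#' China-2010-like scale and shape: ~1.34 billion people, about 10% aged
#' 65+, a total fertility rate of 1.65 declining 1% a year over 2010--2017,
#' and Gompertz-Makeham child/adult mortality with a male excess.
#'
#' @param total_population total initial population (persons).
#' @param young_decay,old_decay piecewise-exponential pyramid decay rates
#'   (per year of age) below/above \code{pivot_age}.
#' @param pivot_age age at which the pyramid decay steepens.
#' @param tfr_2010 total fertility rate in 2010 (births per woman).
#' @param fertility_trend multiplicative per-year fertility change 2010-2017.
#' @param makeham,infant,gompertz_a,gompertz_b life-table parameters:
#'   q(a) = makeham + infant e^(-a) + gompertz_a e^(gompertz_b a), ages 0-64.
#' @param male_mortality_excess multiplier on male death probabilities.
#' @param sex_ratio_at_birth male births per female birth.
#' @param state_prevalence optional named 12-vector over [living_states()]
#'   allocating the initial 65+ population (default: a mildly impaired mix).
#' @export
demographic_scenario <- function(total_population = 1.34e9,
                                 young_decay = 0.008, old_decay = 0.042,
                                 pivot_age = 44,
                                 tfr_2010 = 1.65, fertility_trend = 0.99,
                                 makeham = 0.0025, infant = 0.012,
                                 gompertz_a = 2e-5, gompertz_b = 0.088,
                                 male_mortality_excess = 1.15,
                                 sex_ratio_at_birth = 1.05,
                                 state_prevalence = NULL) {
  if (is.null(state_prevalence)) {
    state_prevalence <- c(
      INTACT_ACTIVE = 0.800, INTACT_ADL12 = 0.045, INTACT_ADL3P = 0.012,
      MILD_ACTIVE = 0.055, MILD_ADL12 = 0.020, MILD_ADL3P = 0.010,
      MODERATE_ACTIVE = 0.020, MODERATE_ADL12 = 0.012, MODERATE_ADL3P = 0.007,
      SEVERE_ACTIVE = 0.007, SEVERE_ADL12 = 0.004, SEVERE_ADL3P = 0.008
    )
  }
  stopifnot(abs(sum(state_prevalence) - 1) < 1e-9,
            identical(sort(names(state_prevalence)), sort(living_states())))
  list(total_population = total_population, young_decay = young_decay,
       old_decay = old_decay, pivot_age = pivot_age, tfr_2010 = tfr_2010,
       fertility_trend = fertility_trend, makeham = makeham, infant = infant,
       gompertz_a = gompertz_a, gompertz_b = gompertz_b,
       male_mortality_excess = male_mortality_excess,
       sex_ratio_at_birth = sex_ratio_at_birth,
       state_prevalence = state_prevalence)
}

#' Build complete demographic inputs from a scenario
#'
#' Deterministic for a given scenario; the seed is recorded for provenance
#' only. Emits initial population by single year of age 0--100+ and sex,
#' age-specific fertility for calendar years 2010--2017, a life table for
#' ages 0--64, zero net migration, and the 65+ health-state allocation.
#'
#' @param scenario a [demographic_scenario()].
#' @param seed integer, recorded on the result.
#' @return a \code{demographic_inputs} object (see [demographic_inputs()]).
#' @export
generate_demographics <- function(scenario = demographic_scenario(), seed = 1L) {
  ages <- 0:100
  w <- ifelse(ages <= scenario$pivot_age,
              exp(-scenario$young_decay * ages),
              exp(-scenario$young_decay * scenario$pivot_age -
                    scenario$old_decay * (ages - scenario$pivot_age)))
  w <- w / sum(w)
  # constant small male surplus at birth washed out at old ages
  male_frac <- 0.512 - 0.0008 * pmax(0, ages - 50)
  total <- scenario$total_population * w
  init <- data.frame(
    age = rep(ages, 2),
    sex = rep(SEX_LEVELS, each = length(ages)),
    count = c(total * (1 - male_frac), total * male_frac)
  )
  fages <- 15:49
  shape <- exp(-((fages - 27) / 6)^2)
  shape <- shape / sum(shape)
  fert <- do.call(rbind, lapply(2010:2017, function(yr) {
    data.frame(year = yr, age = fages,
               rate = scenario$tfr_2010 * scenario$fertility_trend^(yr - 2010) * shape)
  }))
  la <- 0:64
  qf <- scenario$makeham + scenario$infant * exp(-la) +
    scenario$gompertz_a * exp(scenario$gompertz_b * la)
  qm <- pmin(qf * scenario$male_mortality_excess, 1)
  if (any(qf < 0 | qf > 1 | qm < 0 | qm > 1))
    stop("scenario implies death probabilities outside [0, 1]", call. = FALSE)
  lt <- data.frame(age = rep(la, 2), sex = rep(SEX_LEVELS, each = length(la)),
                   qx = c(qf, qm))
  demographic_inputs(
    initial_population = init, fertility = fert, life_table = lt,
    migration = NULL, sex_ratio_at_birth = scenario$sex_ratio_at_birth,
    state_prevalence = scenario$state_prevalence, seed = seed
  )
}
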