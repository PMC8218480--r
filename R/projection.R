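#' @title Deterministic cohort-component multi-state projection
#' @description
#' Stock-flow dynamics with fractional persons, 2010--2060. Each simulated
#' year: (1) births from the female population aged 15--49 and the
#' fertility schedule (frozen at its 2017 values thereafter); (2) sub-65
#' survival from the life table with a 1.5%/yr future mortality decline,
#' plus net migration, with survivors of age 64 becoming entrants; (3) 65+
#' health-state transitions under the annual rate table with a 1%/yr
#' improvement applied to worsening and death probabilities; (4) one-year
#' age shift, age 100+ accumulating; (5) entrants added to the
#' intact-active state at age 65. Within a 65+ year the cognitive kernel is
#' applied first and the functional kernel second, its CI stratum taken from
#' the post-update cognition -- the mechanism by which cognitive impairment
#' drives the onset of functional disability.
#' @name population_projection
NULL

#' Assumption schedules for the projection
#'
#' @param fertility_freeze_year last calendar year with its own fertility
#'   schedule; later years reuse it.
#' @param mortality_decline_rate annual proportional decline of sub-65 death
#'   probabilities (0.015 = 1.5%/yr).
#' @param transition_improvement_rate annual proportional reduction of 65+
#'   worsening and death transition probabilities (0.01 = 1%/yr).
#' @param improvement_base_year year from which the improvement accrues
#'   (default 2014, the end of the estimation window); earlier years are
#'   unadjusted.
#' @param mortality_base_year year from which the mortality decline accrues.
#' @export
assumption_schedule <- function(fertility_freeze_year = 2017,
                                mortality_decline_rate = 0.015,
                                transition_improvement_rate = 0.01,
                                improvement_base_year = 2014,
                                mortality_base_year = 2010) {
  stopifnot(mortality_decline_rate >= 0, mortality_decline_rate < 1,
            transition_improvement_rate >= 0, transition_improvement_rate < 1)
  structure(list(fertility_freeze_year = fertility_freeze_year,
                 mortality_decline_rate = mortality_decline_rate,
                 transition_improvement_rate = transition_improvement_rate,
                 improvement_base_year = improvement_base_year,
                 mortality_base_year = mortality_base_year),
            class = "assumption_schedule")
}

#' Container for demographic model inputs
#'
#' @param initial_population data.frame(age 0--100, sex, count), age 100
#'   meaning 100+.
#' @param fertility data.frame(year, age, rate), births per woman per year,
#'   ages 15--49.
#' @param life_table data.frame(age 0--64, sex, qx), annual death probability.
#' @param migration optional data.frame(year, age, sex, net) of net migrants
#'   (sub-65 ages; default none).
#' @param sex_ratio_at_birth male births per female birth.
#' @param state_prevalence optional named vector over [living_states()]
#'   allocating the initial 65+ population across health states (default:
#'   all intact-active).
#' @param seed provenance only.
#' @export
demographic_inputs <- function(initial_population, fertility, life_table,
                               migration = NULL, sex_ratio_at_birth = 1.05,
                               state_prevalence = NULL, seed = NA_integer_) {
  stopifnot(all(c("age", "sex", "count") %in% names(initial_population)),
            all(c("year", "age", "rate") %in% names(fertility)),
            all(c("age", "sex", "qx") %in% names(life_table)))
  if (any(initial_population$count < 0))
    stop("initial population counts must be non-negative", call. = FALSE)
  if (any(fertility$rate < 0))
    stop("fertility rates must be non-negative", call. = FALSE)
  if (any(fertility$rate > 0 & (fertility$age < 15 | fertility$age > 49)))
    stop("fertility must be zero outside ages 15-49", call. = FALSE)
  if (any(life_table$qx < 0 | life_table$qx > 1))
    stop("life-table qx must lie in [0, 1]", call. = FALSE)
  if (is.null(state_prevalence)) {
    state_prevalence <- stats::setNames(rep(0, 12), living_states())
    state_prevalence["INTACT_ACTIVE"] <- 1
  }
  stopifnot(abs(sum(state_prevalence) - 1) < 1e-9)
  structure(list(initial_population = initial_population,
                 fertility = fertility, life_table = life_table,
                 migration = migration,
                 sex_ratio_at_birth = sex_ratio_at_birth,
                 state_prevalence = state_prevalence[living_states()],
                 seed = seed),
            class = "demographic_inputs")
}

#' @export
print.demographic_inputs <- function(x, ...) {
  cat(sprintf("Demographic inputs: %.3f million persons initially\n",
              sum(x$initial_population$count) / 1e6))
  invisible(x)
}

#' Births from the female population and a fertility schedule
#'
#' @param female_by_age named numeric vector of female person-counts (names
#'   are ages).
#' @param rates_by_age named numeric vector of fertility rates (names are
#'   ages 15--49).
#' @param sex_ratio male births per female birth.
#' @return list(female, male, total).
#' @export
births <- function(female_by_age, rates_by_age, sex_ratio = 1.05) {
  if (any(rates_by_age < 0)) stop("negative fertility rate", call. = FALSE)
  common <- intersect(names(female_by_age), names(rates_by_age))
  total <- sum(female_by_age[common] * rates_by_age[common])
  male <- total * sex_ratio / (1 + sex_ratio)
  list(female = total - male, male = male, total = total)
}

# sub-65 stocks are a 65 x 2 matrix, rows = ages 0..64, cols = sexes

#' Advance the sub-65 population by one year
#'
#' Each cohort survives with probability 1 - qx * (1 - decline)^(year -
#' base), receives net migration, and shifts one year of age; survivors of
#' age 64 are returned as the 65th-birthday entrants, and the year's births
#' enter at age 0.
#'
#' @param sub65 65 x 2 matrix (ages 0--64 by sex) of person counts.
#' @param life_table data.frame(age, sex, qx).
#' @param migration_year optional data.frame(age, sex, net) for this year.
#' @param year calendar year.
#' @param schedule an [assumption_schedule()].
#' @param births_by_sex list(female, male) entering age 0.
#' @return list(sub65, entrants = c(female, male), deaths).
#' @export
advance_sub65 <- function(sub65, life_table, migration_year = NULL, year,
                          schedule = assumption_schedule(),
                          births_by_sex = list(female = 0, male = 0)) {
  decline <- (1 - schedule$mortality_decline_rate)^
    max(0, year - schedule$mortality_base_year)
  q <- matrix(0, 65, 2, dimnames = list(0:64, SEX_LEVELS))
  q[cbind(life_table$age + 1L, match(life_table$sex, SEX_LEVELS))] <- life_table$qx
  qeff <- q * decline
  if (any(qeff < 0 | qeff > 1))
    stop("effective sub-65 death probability outside [0, 1]", call. = FALSE)
  deaths <- sum(sub65 * qeff)
  surv <- sub65 * (1 - qeff)
  mig <- 0
  if (!is.null(migration_year) && nrow(migration_year)) {
    m <- matrix(0, 65, 2, dimnames = list(0:64, SEX_LEVELS))
    m[cbind(migration_year$age + 1L,
            match(migration_year$sex, SEX_LEVELS))] <- migration_year$net
    surv <- surv + m
    mig <- sum(m)
  }
  entrants <- surv[65, ]
  out <- rbind(c(births_by_sex$female, births_by_sex$male),
               surv[-65, , drop = FALSE])
  dimnames(out) <- list(0:64, SEX_LEVELS)
  list(sub65 = out, entrants = entrants, deaths = deaths, migration = mig)
}

# 65+ stocks are a 4-d array [age 65..100, sex, cognition, function]

empty_pop65 <- function() {
  array(0, dim = c(36, 2, 4, 3),
        dimnames = list(age = 65:100, sex = SEX_LEVELS,
                        cognition = COGNITIVE_LEVELS,
                        fun = FUNCTIONAL_LEVELS))
}

#' Add 65th-birthday entrants to the intact-active state
#'
#' @param pop65 65+ population array.
#' @param entrants named vector c(female, male), non-negative.
#' @export
enter_at_65 <- function(pop65, entrants) {
  stopifnot(all(entrants >= 0))
  pop65["65", "female", "INTACT", "ACTIVE"] <-
    pop65["65", "female", "INTACT", "ACTIVE"] + entrants[["female"]]
  pop65["65", "male", "INTACT", "ACTIVE"] <-
    pop65["65", "male", "INTACT", "ACTIVE"] + entrants[["male"]]
  pop65
}

#' Apply the annual transition-improvement assumption to a rate table
#'
#' Worsening and death probabilities are multiplied by
#' (1 - rate)^(year - base); the freed mass is added to the stay
#' probability; recovery probabilities are unchanged, so rows still sum to
#' one and structural zeros are preserved. Years at or before the base year
#' leave the table unchanged.
#'
#' @param table a \code{rate_table}.
#' @param year calendar year.
#' @param schedule an [assumption_schedule()].
#' @export
adjust_rates_for_year <- function(table, year, schedule = assumption_schedule()) {
  f <- (1 - schedule$transition_improvement_rate)^
    max(0, year - schedule$improvement_base_year)
  if (f == 1) return(table)
  adjust <- function(arr, levels, origin_dim) {
    dests <- c(levels, "DEAD")
    orank <- seq_along(levels)
    for (oi in orank) {
      worse <- dests[c(which(seq_along(levels) > oi), length(dests))]
      # index helper: origin is dimension origin_dim, dest is the last
      idx_o <- slice.index(arr, origin_dim) == oi
      for (d in worse) {
        di <- match(d, dests)
        sel <- idx_o & slice.index(arr, length(dim(arr))) == di
        stay <- idx_o & slice.index(arr, length(dim(arr))) == oi
        freed <- arr[sel] * (1 - f)
        arr[sel] <- arr[sel] * f
        arr[stay] <- arr[stay] + freed
      }
    }
    arr
  }
  table$cognitive <- adjust(table$cognitive, COGNITIVE_LEVELS, 3)
  table$functional <- adjust(table$functional, FUNCTIONAL_LEVELS, 4)
  table
}

#' One year of 65+ health-state transitions (expected-value flows)
#'
#' @param pop65 65+ population array.
#' @param table a (possibly year-adjusted) \code{rate_table}.
#' @param cognitive_first apply the cognitive kernel first (default; the
#'   functional kernel's CI stratum then reflects post-update cognition).
#'   \code{FALSE} applies the functional kernel first, with the CI stratum
#'   from pre-update cognition (sensitivity analysis).
#' @return list(pop65, deaths = array of deaths by age/sex/state occupied
#'   when dying, total_deaths).
#' @export
transition_step <- function(pop65, table, cognitive_first = TRUE) {
  deaths <- empty_pop65()
  out <- empty_pop65()
  for (ai in 1:36) {
    for (si in 1:2) {
      P <- pop65[ai, si, , ]                       # 4 x 3
      Kc <- table$cognitive[ai, si, , ]            # 4 origins x 5 dests
      if (cognitive_first) {
        A <- t(Kc[, 1:4]) %*% P                    # post-cognitive, 4 x 3
        deaths[ai, si, , ] <- deaths[ai, si, , ] + P * Kc[, 5]
        for (ci in 1:4) {
          Kf <- table$functional[ai, si, if (ci == 1) 1 else 2, , ] # 3 x 4
          out[ai, si, ci, ] <- A[ci, ] %*% Kf[, 1:3]
          deaths[ai, si, ci, ] <- deaths[ai, si, ci, ] + A[ci, ] * Kf[, 4]
        }
      } else {
        B <- matrix(0, 4, 3)
        for (ci in 1:4) {
          Kf <- table$functional[ai, si, if (ci == 1) 1 else 2, , ]
          B[ci, ] <- P[ci, ] %*% Kf[, 1:3]
          deaths[ai, si, ci, ] <- deaths[ai, si, ci, ] + P[ci, ] * Kf[, 4]
        }
        out[ai, si, , ] <- t(Kc[, 1:4]) %*% B
        deaths[ai, si, , ] <- deaths[ai, si, , ] + B * Kc[, 5]
      }
      if (min(out[ai, si, , ]) < -1e-12)
        stop("negative population after transition: corrupted rate table",
             call. = FALSE)
    }
  }
  list(pop65 = out, deaths = deaths, total_deaths = sum(deaths))
}

#' Shift the 65+ population one year of age (100+ accumulates)
#'
#' @param pop65 65+ population array.
#' @export
age_shift_65plus <- function(pop65) {
  out <- empty_pop65()
  out[36, , , ] <- pop65[36, , , ] + pop65[35, , , ]
  out[2:35, , , ] <- pop65[1:34, , , ]
  out
}

#' Run the full 2010--2060 projection
#'
#' @param demog a [demographic_inputs()] object.
#' @param table the annual \code{rate_table}.
#' @param schedule an [assumption_schedule()].
#' @param start,end first and last calendar years of the projection.
#' @param cognitive_first kernel combination order, see [transition_step()].
#' @return a \code{projection_result}: 65+ stocks \code{pop65[year, age,
#'   sex, cognition, function]}, sub-65 stocks \code{sub65[year, age, sex]}
#'   and a yearly flow ledger (births, deaths, migration, entrants).
#' @export
project <- function(demog, table, schedule = assumption_schedule(),
                    start = 2010, end = 2060, cognitive_first = TRUE) {
  stopifnot(inherits(demog, "demographic_inputs"), inherits(table, "rate_table"),
            end > start)
  years <- start:end
  ny <- length(years)
  pop65 <- array(0, dim = c(ny, 36, 2, 4, 3),
                 dimnames = c(list(year = years), dimnames(empty_pop65())))
  sub65 <- array(0, dim = c(ny, 65, 2),
                 dimnames = list(year = years, age = 0:64, sex = SEX_LEVELS))
  flows <- data.frame(year = years[-ny], births = 0, deaths_sub65 = 0,
                      deaths_65plus = 0, migration = 0, entrants = 0)

  ip <- demog$initial_population
  s65 <- matrix(0, 65, 2, dimnames = list(0:64, SEX_LEVELS))
  sub <- ip[ip$age < 65, ]
  s65[cbind(sub$age + 1L, match(sub$sex, SEX_LEVELS))] <- sub$count
  p65 <- empty_pop65()
  old <- ip[ip$age >= 65, ]
  prev <- demog$state_prevalence
  for (i in seq_len(nrow(old))) {
    a <- min(old$age[i], 100)
    si <- match(old$sex[i], SEX_LEVELS)
    for (s in living_states()) {
      ci <- match(state_cognition(s), COGNITIVE_LEVELS)
      fi <- match(state_function(s), FUNCTIONAL_LEVELS)
      p65[a - 64, si, ci, fi] <- p65[a - 64, si, ci, fi] + old$count[i] * prev[[s]]
    }
  }
  sub65[1, , ] <- s65
  pop65[1, , , , ] <- p65

  fert_years <- sort(unique(demog$fertility$year))
  for (t in seq_len(ny - 1L)) {
    yr <- years[t]
    fy <- min(max(yr, min(fert_years)), schedule$fertility_freeze_year)
    if (!fy %in% fert_years) fy <- max(fert_years[fert_years <= fy])
    frates <- demog$fertility[demog$fertility$year == fy, ]
    rates <- stats::setNames(frates$rate, frates$age)
    fem <- stats::setNames(s65[, "female"], 0:64)
    b <- births(fem, rates, demog$sex_ratio_at_birth)

    mig_y <- NULL
    if (!is.null(demog$migration))
      mig_y <- demog$migration[demog$migration$year == yr, ]
    adv <- advance_sub65(s65, demog$life_table, mig_y, yr, schedule,
                         births_by_sex = b)

    tab_y <- adjust_rates_for_year(table, yr, schedule)
    tr <- tryCatch(transition_step(p65, tab_y, cognitive_first),
                   error = function(e)
                     stop(sprintf("year %d: %s", yr, conditionMessage(e)),
                          call. = FALSE))
    p65 <- age_shift_65plus(tr$pop65)
    p65 <- enter_at_65(p65, adv$entrants)
    s65 <- adv$sub65

    flows$births[t] <- b$total
    flows$deaths_sub65[t] <- adv$deaths
    flows$deaths_65plus[t] <- tr$total_deaths
    flows$migration[t] <- adv$migration
    flows$entrants[t] <- sum(adv$entrants)
    sub65[t + 1L, , ] <- s65
    pop65[t + 1L, , , , ] <- p65
  }
  structure(list(years = years, pop65 = pop65, sub65 = sub65, flows = flows,
                 schedule = schedule),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  ny <- length(x$years)
  cat(sprintf("Multi-state projection %d-%d\n", x$years[1], x$years[ny]))
  cat(sprintf("  total population: %.3fM (%d) -> %.3fM (%d)\n",
              (sum(x$pop65[1, , , , ]) + sum(x$sub65[1, , ])) / 1e6, x$years[1],
              (sum(x$pop65[ny, , , , ]) + sum(x$sub65[ny, , ])) / 1e6, x$years[ny]))
  cat(sprintf("  65+ population  : %.3fM -> %.3fM\n",
              sum(x$pop65[1, , , , ]) / 1e6, sum(x$pop65[ny, , , , ]) / 1e6))
  invisible(x)
}

#' Yearly conservation identity of a projection
#'
#' total(t+1) = total(t) + births - deaths + net migration, from the flow
#' ledger.
#'
#' @param projection a \code{projection_result}.
#' @return maximum absolute yearly discrepancy (persons).
#' @export
check_conservation <- function(projection) {
  ny <- length(projection$years)
  tot <- sapply(seq_len(ny), function(t)
    sum(projection$pop65[t, , , , ]) + sum(projection$sub65[t, , ]))
  fl <- projection$flows
  pred <- tot[-ny] + fl$births - fl$deaths_sub65 - fl$deaths_65plus + fl$migration
  max(abs(pred - tot[-1]))
}

#' Long-format view of the 65+ stocks of a projection
#'
#' @param projection a \code{projection_result}.
#' @param include_sub65 also emit sub-65 rows with state "SUB65".
#' @return data.frame(year, age, sex, state, count).
#' @export
projection_to_df <- function(projection, include_sub65 = FALSE) {
  d <- as.data.frame.table(projection$pop65, responseName = "count",
                           stringsAsFactors = FALSE)
  d$state <- composite_state(d$cognition, d$fun)
  out <- data.frame(year = as.integer(d$year), age = as.integer(d$age),
                    sex = d$sex, state = d$state, count = d$count,
                    stringsAsFactors = FALSE)
  if (include_sub65) {
    s <- as.data.frame.table(projection$sub65, responseName = "count",
                             stringsAsFactors = FALSE)
    out <- rbind(out, data.frame(year = as.integer(s$year),
                                 age = as.integer(s$age), sex = s$sex,
                                 state = "SUB65", count = s$count,
                                 stringsAsFactors = FALSE))
  }
  out
}
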