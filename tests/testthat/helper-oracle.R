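# Independent, deliberately naive re-implementation of the projection
# dynamics: scalar nested loops, no shared code with project() beyond the
# input objects. Used as the brute-force oracle.

oracle_adjust <- function(tab, year, schedule) {
  f <- (1 - schedule$transition_improvement_rate)^
    max(0, year - schedule$improvement_base_year)
  cog <- tab$cognitive
  fun <- tab$functional
  sev_c <- c(COGNITIVE_LEVELS, "DEAD")
  sev_f <- c(FUNCTIONAL_LEVELS, "DEAD")
  for (a in 1:36) for (s in 1:2) {
    for (o in seq_along(COGNITIVE_LEVELS)) {
      for (d in seq_along(sev_c)) {
        if (d > o) {           # worsening or death
          freed <- cog[a, s, o, d] * (1 - f)
          cog[a, s, o, d] <- cog[a, s, o, d] * f
          cog[a, s, o, o] <- cog[a, s, o, o] + freed
        }
      }
    }
    for (ci in 1:2) for (o in seq_along(FUNCTIONAL_LEVELS)) {
      for (d in seq_along(sev_f)) {
        if (d > o) {
          freed <- fun[a, s, ci, o, d] * (1 - f)
          fun[a, s, ci, o, d] <- fun[a, s, ci, o, d] * f
          fun[a, s, ci, o, o] <- fun[a, s, ci, o, o] + freed
        }
      }
    }
  }
  list(cognitive = cog, functional = fun)
}

oracle_project <- function(demog, tab, schedule, start = 2010, end = 2060) {
  years <- start:end
  ny <- length(years)
  sexes <- c("female", "male")
  pop65 <- array(0, dim = c(ny, 36, 2, 4, 3))
  sub65 <- array(0, dim = c(ny, 65, 2))

  # initial stocks
  ip <- demog$initial_population
  prev <- demog$state_prevalence
  s65 <- matrix(0, 65, 2)
  p65 <- array(0, dim = c(36, 2, 4, 3))
  for (i in seq_len(nrow(ip))) {
    a <- ip$age[i]; si <- if (ip$sex[i] == "female") 1 else 2
    if (a < 65) {
      s65[a + 1, si] <- s65[a + 1, si] + ip$count[i]
    } else {
      a <- min(a, 100)
      for (k in seq_along(living_states())) {
        st <- living_states()[k]
        ci <- match(state_cognition(st), COGNITIVE_LEVELS)
        fi <- match(state_function(st), FUNCTIONAL_LEVELS)
        p65[a - 64, si, ci, fi] <- p65[a - 64, si, ci, fi] +
          ip$count[i] * prev[[st]]
      }
    }
  }
  sub65[1, , ] <- s65
  pop65[1, , , , ] <- p65

  lt <- demog$life_table
  fert_years <- sort(unique(demog$fertility$year))
  for (t in 1:(ny - 1)) {
    yr <- years[t]
    # births
    fy <- min(max(yr, min(fert_years)), schedule$fertility_freeze_year)
    if (!fy %in% fert_years) fy <- max(fert_years[fert_years <= fy])
    fr <- demog$fertility[demog$fertility$year == fy, ]
    btot <- 0
    for (i in seq_len(nrow(fr)))
      btot <- btot + s65[fr$age[i] + 1, 1] * fr$rate[i]
    srb <- demog$sex_ratio_at_birth
    b_m <- btot * srb / (1 + srb); b_f <- btot - b_m

    # sub-65 survival and shift
    decl <- (1 - schedule$mortality_decline_rate)^
      max(0, yr - schedule$mortality_base_year)
    surv <- matrix(0, 65, 2)
    for (si in 1:2) for (a in 0:64) {
      qrow <- lt$qx[lt$age == a & lt$sex == sexes[si]]
      q <- if (length(qrow)) qrow[1] * decl else 0
      surv[a + 1, si] <- s65[a + 1, si] * (1 - q)
    }
    if (!is.null(demog$migration)) {
      mg <- demog$migration[demog$migration$year == yr, ]
      for (i in seq_len(nrow(mg)))
        surv[mg$age[i] + 1, if (mg$sex[i] == "female") 1 else 2] <-
          surv[mg$age[i] + 1, if (mg$sex[i] == "female") 1 else 2] + mg$net[i]
    }
    entrants <- surv[65, ]
    new_s65 <- matrix(0, 65, 2)
    new_s65[1, ] <- c(b_f, b_m)
    for (a in 1:64) new_s65[a + 1, ] <- surv[a, ]

    # 65+ transitions, cognitive kernel then functional kernel
    at <- oracle_adjust(tab, yr, schedule)
    post <- array(0, dim = c(36, 2, 4, 3))
    for (ai in 1:36) for (si in 1:2) {
      mid <- array(0, dim = c(4, 3))
      for (co in 1:4) for (fo in 1:3) {
        m <- p65[ai, si, co, fo]
        if (m == 0) next
        for (cd in 1:4)
          mid[cd, fo] <- mid[cd, fo] + m * at$cognitive[ai, si, co, cd]
      }
      for (cd in 1:4) for (fo in 1:3) {
        m <- mid[cd, fo]
        if (m == 0) next
        ci <- if (cd == 1) 1 else 2
        for (fd in 1:3)
          post[ai, si, cd, fd] <- post[ai, si, cd, fd] +
            m * at$functional[ai, si, ci, fo, fd]
      }
    }
    # age shift with 100+ accumulator, then entry at 65
    shifted <- array(0, dim = c(36, 2, 4, 3))
    shifted[36, , , ] <- post[36, , , ] + post[35, , , ]
    for (ai in 35:2) shifted[ai, , , ] <- post[ai - 1, , , ]
    shifted[1, 1, 1, 1] <- entrants[1]
    shifted[1, 2, 1, 1] <- entrants[2]

    p65 <- shifted
    s65 <- new_s65
    sub65[t + 1, , ] <- s65
    pop65[t + 1, , , , ] <- p65
  }
  list(years = years, pop65 = pop65, sub65 = sub65)
}
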