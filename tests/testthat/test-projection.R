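test_that("births follow the fertility hand-sum and scale linearly", {
  fem <- setNames(rep(0, 65), 0:64)
  rates <- setNames(rep(0, 35), 15:49)
  expect_equal(births(fem, rates)$total, 0)

  fem[as.character(20:24)] <- 1000
  rates[as.character(20:24)] <- 0.1
  b <- births(fem, rates, sex_ratio = 1.0)
  expect_equal(b$total, 500)
  expect_equal(b$female, 250)
  expect_equal(b$male, 250)
  b2 <- births(fem * 2, rates, sex_ratio = 1.0)
  expect_equal(b2$total, 1000)
  expect_error(births(fem, -rates), "negative")
})

test_that("sub-65 survival matches its closed form including the mortality decline", {
  lt <- data.frame(age = rep(0:64, 2),
                   sex = rep(c("female", "male"), each = 65), qx = 0)
  s <- matrix(100, 65, 2, dimnames = list(0:64, c("female", "male")))
  sched <- assumption_schedule()
  # zero mortality: a pure one-year shift, age-64 stock becomes entrants
  adv <- advance_sub65(s, lt, NULL, 2010, sched, list(female = 7, male = 9))
  expect_equal(unname(adv$entrants), c(100, 100))
  expect_equal(unname(adv$sub65[1, ]), c(7, 9))
  expect_equal(unname(adv$sub65[2, ]), c(100, 100))
  expect_equal(adv$deaths, 0)

  lt$qx <- 0.1
  adv0 <- advance_sub65(s, lt, NULL, 2010, sched)
  expect_equal(unname(adv0$sub65[2, 1]), 90)
  adv10 <- advance_sub65(s, lt, NULL, 2020, sched)
  expect_equal(unname(adv10$sub65[2, 1]), 100 * (1 - 0.1 * 0.985^10),
               tolerance = 1e-12)
  lt$qx <- 1.5  # infeasible
  expect_error(advance_sub65(s, lt, NULL, 2010, sched), "outside")
})

test_that("entrants land exclusively in intact-active at 65", {
  p <- mspop:::empty_pop65()
  p2 <- enter_at_65(p, c(female = 100, male = 40))
  expect_equal(p2["65", "female", "INTACT", "ACTIVE"], 100)
  expect_equal(p2["65", "male", "INTACT", "ACTIVE"], 40)
  expect_equal(sum(p2), 140)
  expect_identical(enter_at_65(p, c(female = 0, male = 0)), p)
})

test_that("the improvement adjustment rescales worsening and death only", {
  tab <- manual_rate_table(
    cog_rows = list(
      INTACT = c(INTACT = 0.7, MILD = 0.2, DEAD = 0.1),
      MILD = c(INTACT = 0.1, MILD = 0.6, MODERATE = 0.2, DEAD = 0.1),
      MODERATE = c(MODERATE = 0.8, SEVERE = 0.1, DEAD = 0.1),
      SEVERE = c(SEVERE = 0.9, DEAD = 0.1)),
    fun_rows = list(
      ACTIVE = c(ACTIVE = 0.8, ADL12 = 0.15, DEAD = 0.05),
      ADL12 = c(ACTIVE = 0.1, ADL12 = 0.7, ADL3P = 0.1, DEAD = 0.1),
      ADL3P = c(ADL3P = 0.85, DEAD = 0.15))
  )
  sched <- assumption_schedule(improvement_base_year = 2014)
  expect_identical(adjust_rates_for_year(tab, 2014, sched), tab)
  expect_identical(adjust_rates_for_year(tab, 2010, sched), tab)

  a1 <- adjust_rates_for_year(tab, 2015, sched)
  expect_equal(unname(a1$cognitive["70", "female", "INTACT",
                                   c("INTACT", "MILD", "DEAD")]),
               c(0.703, 0.198, 0.099))
  # recovery (MILD -> INTACT) untouched
  expect_equal(a1$cognitive["70", "male", "MILD", "INTACT"], 0.1)
  # rows still sum to one after a long horizon; structural zeros preserved
  a30 <- adjust_rates_for_year(tab, 2044, sched)
  expect_true(max(abs(apply(a30$cognitive, c(1, 2, 3), sum) - 1)) < 1e-12)
  expect_true(max(abs(apply(a30$functional, c(1, 2, 3, 4), sum) - 1)) < 1e-12)
  expect_true(all(a30$cognitive[, , "SEVERE", c("INTACT", "MILD", "MODERATE")] == 0))
})

test_that("transition flows conserve mass and match a matrix-power closed form", {
  idt <- identity_rate_table()
  p <- mspop:::empty_pop65()
  p["72", "female", "MILD", "ADL12"] <- 123
  st <- transition_step(p, idt)
  expect_equal(st$pop65, p)
  expect_equal(st$total_deaths, 0)

  # pure death kernels absorb everything
  dead_tab <- manual_rate_table(
    cog_rows = setNames(lapply(COGNITIVE_LEVELS, function(o)
      c(DEAD = 1)), COGNITIVE_LEVELS),
    fun_rows = setNames(lapply(FUNCTIONAL_LEVELS, function(o)
      setNames(1, o)), FUNCTIONAL_LEVELS))
  st2 <- transition_step(p, dead_tab)
  expect_equal(sum(st2$pop65), 0)
  expect_equal(st2$total_deaths, 123)

  # two-living-state toy iterated t years equals the t-th matrix power:
  # cognition frozen, ACTIVE <-> ADL12 with death, constant over age/sex
  K <- matrix(c(0.80, 0.15, 0.05,
                0.10, 0.80, 0.10,
                0.00, 0.00, 1.00), 3, 3, byrow = TRUE,
              dimnames = list(c("ACTIVE", "ADL12", "DEAD"),
                              c("ACTIVE", "ADL12", "DEAD")))
  toy <- manual_rate_table(
    cog_rows = setNames(lapply(COGNITIVE_LEVELS, function(o)
      setNames(1, o)), COGNITIVE_LEVELS),
    fun_rows = list(
      ACTIVE = c(ACTIVE = 0.80, ADL12 = 0.15, DEAD = 0.05),
      ADL12 = c(ACTIVE = 0.10, ADL12 = 0.80, DEAD = 0.10),
      ADL3P = c(ADL3P = 1)))
  pop <- mspop:::empty_pop65()
  pop["65", "male", "INTACT", "ACTIVE"] <- 1000
  cur <- pop; dead <- 0
  for (t in 1:10) {
    st <- transition_step(cur, toy)
    cur <- st$pop65; dead <- dead + st$total_deaths
  }
  v <- c(1000, 0, 0)
  Kt <- diag(3); for (t in 1:10) Kt <- Kt %*% K
  ref <- drop(v %*% Kt)
  expect_equal(unname(cur["65", "male", "INTACT", c("ACTIVE", "ADL12")]),
               unname(ref[1:2]), tolerance = 1e-9)
  expect_equal(dead, unname(ref[3]), tolerance = 1e-9)
})

test_that("the 65+ age shift accumulates the open 100+ interval and conserves mass", {
  p <- mspop:::empty_pop65()
  p["99", "female", "INTACT", "ACTIVE"] <- 5
  p["100", "male", "MILD", "ADL3P"] <- 7
  p["70", "male", "SEVERE", "ACTIVE"] <- 2
  s <- age_shift_65plus(p)
  expect_equal(s["100", "female", "INTACT", "ACTIVE"], 5)
  expect_equal(s["100", "male", "MILD", "ADL3P"], 7)
  expect_equal(s["71", "male", "SEVERE", "ACTIVE"], 2)
  expect_equal(sum(s), sum(p))
})

test_that("an immortal closed population is exactly conserved for 50 years", {
  dm <- manual_demographics(sub65_count = 5e5, pop65_age = 70,
                            pop65_count = 1e5)
  pj <- project(dm, identity_rate_table())
  tot <- sapply(seq_along(pj$years), function(t)
    sum(pj$pop65[t, , , , ]) + sum(pj$sub65[t, , ]))
  expect_true(max(abs(tot - tot[1])) < 1e-9)
  expect_equal(check_conservation(pj), 0, tolerance = 1e-9)
})

test_that("a single cohort with constant death probability decays geometrically", {
  dm <- manual_demographics(pop65_age = 65, pop65_count = 1000)
  tab <- manual_rate_table(
    cog_rows = list(INTACT = c(INTACT = 0.9, DEAD = 0.1),
                    MILD = c(MILD = 1), MODERATE = c(MODERATE = 1),
                    SEVERE = c(SEVERE = 1)),
    fun_rows = setNames(lapply(FUNCTIONAL_LEVELS, function(o)
      setNames(1, o)), FUNCTIONAL_LEVELS))
  sched <- assumption_schedule(transition_improvement_rate = 0)
  pj <- project(dm, tab, sched)
  for (t in c(1, 5, 20, 35)) {
    expect_equal(sum(pj$pop65[t + 1, , , , ]), 1000 * 0.9^t, tolerance = 1e-9)
  }
})

test_that("stocks stay non-negative and flows satisfy conservation on a full scenario", {
  pr <- truth_presets()
  dm <- generate_demographics(demographic_scenario(total_population = 1e6))
  tab <- build_rate_table(pr$paper_like$cognitive, pr$paper_like$functional)
  pj <- project(dm, tab)
  expect_true(min(pj$pop65) >= 0)
  expect_true(min(pj$sub65) >= 0)
  expect_lt(check_conservation(pj), 1e-9)
})

test_that("faster assumed improvement never shrinks the living 2060 population", {
  pr <- truth_presets()
  dm <- generate_demographics(demographic_scenario(total_population = 1e6))
  tab <- build_rate_table(pr$paper_like$cognitive, pr$paper_like$functional)
  p1 <- project(dm, tab, assumption_schedule(transition_improvement_rate = 0.01))
  p2 <- project(dm, tab, assumption_schedule(transition_improvement_rate = 0.02))
  ny <- length(p1$years)
  expect_gte(sum(p2$pop65[ny, , , , ]), sum(p1$pop65[ny, , , , ]))
})

test_that("with no worsening transitions the impaired population is identically zero", {
  pr <- truth_presets()
  dm <- generate_demographics(demographic_scenario(total_population = 1e6))
  # null preset: no transitions at all; entrants are intact-active, but the
  # initial mixture must also be intact-active for zero impairment
  prev <- setNames(rep(0, 12), living_states())
  prev["INTACT_ACTIVE"] <- 1
  dm2 <- demographic_inputs(dm$initial_population, dm$fertility,
                            dm$life_table, state_prevalence = prev)
  tab <- build_rate_table(pr$null$cognitive, pr$null$functional)
  pj <- project(dm2, tab)
  impaired <- sum(pj$pop65[, , , , ]) - sum(pj$pop65[, , , "INTACT", "ACTIVE"])
  expect_equal(impaired, 0)
})

test_that("the alternative kernel order is available and differs when CI matters", {
  pr <- truth_presets()
  dm <- manual_demographics(pop65_age = 65, pop65_count = 1000)
  tab <- build_rate_table(pr$paper_like$cognitive, pr$paper_like$functional)
  a <- project(dm, tab, cognitive_first = TRUE, start = 2010, end = 2020)
  b <- project(dm, tab, cognitive_first = FALSE, start = 2010, end = 2020)
  expect_false(isTRUE(all.equal(a$pop65, b$pop65)))
})
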