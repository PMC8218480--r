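test_that("midpoint imputation is deterministic on agreement and fair on disagreement", {
  set.seed(1)
  expect_equal(impute_midpoint_state(rep("MILD", 5), rep("MILD", 5)),
               rep("MILD", 5))
  expect_equal(impute_midpoint_state("ACTIVE", "ACTIVE"), "ACTIVE")
  # 50/50 rule over 10,000 draws, DEAD admissible as the wave-2 value
  set.seed(99)
  out <- impute_midpoint_state(rep("INTACT", 10000), rep("MILD", 10000))
  expect_true(all(out %in% c("INTACT", "MILD")))
  expect_equal(mean(out == "MILD"), 0.5, tolerance = 0.02)
  set.seed(99)
  out2 <- impute_midpoint_state(rep("ACTIVE", 10000), rep("DEAD", 10000))
  expect_equal(mean(out2 == "DEAD"), 0.5, tolerance = 0.02)
  expect_error(impute_midpoint_state("DEAD", "DEAD"), "wave-1")
})

test_that("pair construction yields two pairs per survivor, one past a dead midpoint", {
  sv <- stayer_survey(n = 500)
  set.seed(3)
  p <- build_transition_pairs(sv, "cognitive")
  expect_equal(nrow(p), 1000)                     # 2n, rule 1 forces identity
  expect_true(all(p$origin == "INTACT" & p$dest == "INTACT"))
  expect_equal(sort(unique(p$age)), c(70, 71))

  # all dead at wave 2: midpoint DEAD (1 pair) or alive (2 pairs)
  svd <- stayer_survey(n = 400)
  svd$dead_w2 <- 1L; svd$cog_w2 <- NA; svd$fun_w2 <- NA
  set.seed(11)
  pd <- build_transition_pairs(svd, "cognitive")
  mid_dead <- 800 - nrow(pd)                      # respondents with 1 pair
  expect_equal(mid_dead / 400, 0.5, tolerance = 0.1)
  expect_true(all(pd$dest[pd$age == 71] == "DEAD"))  # survivors die in year 2
})

test_that("pair construction is deterministic under a fixed seed", {
  pr <- truth_presets()
  sv <- generate_survey(pr$paper_like, survey_config(n = 300), seed = 5)
  set.seed(17); a <- build_transition_pairs(sv, "functional")
  set.seed(17); b <- build_transition_pairs(sv, "functional")
  expect_identical(a, b)
})

test_that("lost-to-follow-up respondents are dropped with a message", {
  sv <- stayer_survey(n = 20)
  sv$cog_w2[1:3] <- NA
  set.seed(1)
  expect_message(p <- build_transition_pairs(sv, "cognitive"), "3 respondent")
  expect_equal(nrow(p), 34)
})

test_that("a fit with no real covariate effects recovers the symmetric softmax", {
  # INTACT origin with all five outcomes (stay + 4 destinations) equally
  # likely and no age/sex effect: every fitted probability ~ 1/5
  set.seed(123)
  n <- 20000
  pairs <- data.frame(
    origin = "INTACT",
    dest = sample(c("INTACT", "MILD", "MODERATE", "SEVERE", "DEAD"), n, TRUE),
    age = sample(65:100, n, TRUE),
    female = rbinom(n, 1, 0.5),
    ci = NA_integer_,
    weight = 1
  )
  fit <- suppressWarnings(fit_transition_model(
    rbind(pairs, data.frame(origin = c("MILD", "MODERATE", "SEVERE"),
                            dest = c("MILD", "MODERATE", "SEVERE"),
                            age = 80, female = 1, ci = NA, weight = 1e-6)),
    "cognitive"))
  p <- predict_transition_probs(fit, "INTACT", 80, "female")
  expect_true(all(abs(p - 0.2) < 0.02))
})

test_that("predicted probabilities equal an independently computed softmax", {
  B_int <- matrix(c(-1.9, 0.05, 6e-4, 0.25,
                    -3.0, 0.07, 8e-4, 0.25,
                    -4.2, 0.09, 1e-3, 0.25,
                    -3.0, 0.08, 8e-4, -0.35), nrow = 4,
                  dimnames = list(c("(Intercept)", "age_c", "age_c2", "female"),
                                  c("MILD", "MODERATE", "SEVERE", "DEAD")))
  co <- manual_coeffs("cognitive", list(
    INTACT = B_int,
    MILD = B_int[, c(1, 2, 3, 4)] * 0.5,
    MODERATE = B_int[, c("SEVERE", "DEAD")],
    SEVERE = B_int[, "DEAD", drop = FALSE]
  ))
  colnames(co$origins$MILD$coef) <- c("INTACT", "MODERATE", "SEVERE", "DEAD")
  p <- predict_transition_probs(co, "INTACT", 80, "female")
  # brute-force re-evaluation with scalar arithmetic
  a <- 80 - 80
  eta <- sapply(c("MILD", "MODERATE", "SEVERE", "DEAD"), function(d)
    B_int[1, d] + B_int[2, d] * a + B_int[3, d] * a^2 + B_int[4, d] * 1)
  ref <- exp(eta) / (1 + sum(exp(eta)))
  expect_equal(p[c("MILD", "MODERATE", "SEVERE", "DEAD")], ref,
               tolerance = 1e-12)
  expect_equal(unname(p["INTACT"]), 1 / (1 + sum(exp(eta))), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # single permitted destination with eta = 0 gives (0.5, 0.5)
  z <- co
  z$origins$SEVERE$coef[] <- 0
  ps <- predict_transition_probs(z, "SEVERE", 80, "male")
  expect_equal(unname(ps[c("SEVERE", "DEAD")]), c(0.5, 0.5))
})

test_that("the rate table is definitionally consistent with prediction and capped at 100", {
  pr <- truth_presets()
  tab <- build_rate_table(pr$paper_like$cognitive, pr$paper_like$functional)
  p <- predict_transition_probs(pr$paper_like$cognitive, "INTACT", 65, "female")
  expect_equal(tab$cognitive["65", "female", "INTACT", ], p)
  pf <- predict_transition_probs(pr$paper_like$functional, "ADL12", 83, "male",
                                 ci = 1)
  expect_equal(tab$functional["83", "male", "1", "ADL12", ], pf)
  # open age interval: 100+ rows equal the age-100 evaluation
  p100 <- predict_transition_probs(pr$paper_like$cognitive, "MILD", 100, "male")
  p120 <- predict_transition_probs(pr$paper_like$cognitive, "MILD", 120, "male")
  expect_identical(p100, p120)
  expect_equal(tab$cognitive["100", "male", "MILD", ], p100)
})

test_that("every rate-table row sums to one and structural zeros are exact", {
  pr <- truth_presets()
  sv <- generate_survey(pr$paper_like, survey_config(n = 1500), seed = 2)
  est <- suppressWarnings(estimate_transition_models(sv, seed = 2))
  tab <- est$rate_table
  expect_true(max(abs(apply(tab$cognitive, c(1, 2, 3), sum) - 1)) < 1e-12)
  expect_true(max(abs(apply(tab$functional, c(1, 2, 3, 4), sum) - 1)) < 1e-12)
  expect_true(all(tab$cognitive >= 0 & tab$cognitive <= 1))
  # no recovery from moderate/severe cognition or from 3+ ADL, ever
  expect_true(all(tab$cognitive[, , "MODERATE", c("INTACT", "MILD")] == 0))
  expect_true(all(tab$cognitive[, , "SEVERE", c("INTACT", "MILD", "MODERATE")] == 0))
  expect_true(all(tab$functional[, , , "ADL3P", c("ACTIVE", "ADL12")] == 0))
})

test_that("estimation is deterministic and errors are informative", {
  pr <- truth_presets()
  sv <- generate_survey(pr$paper_like, survey_config(n = 800), seed = 9)
  e1 <- suppressWarnings(estimate_transition_models(sv, seed = 4))
  e2 <- suppressWarnings(estimate_transition_models(sv, seed = 4))
  expect_identical(e1$cognitive$origins$INTACT$coef,
                   e2$cognitive$origins$INTACT$coef)
  # an origin that never occurs is a hard, named error
  svi <- sv[sv$cog_w1 != "SEVERE", ]
  svi <- svi[!is.na(svi$cog_w2) & svi$cog_w2 != "SEVERE" | svi$dead_w2 == 1, ]
  set.seed(1)
  pcg <- suppressWarnings(build_transition_pairs(svi, "cognitive"))
  pcg <- pcg[pcg$origin != "SEVERE", ]
  suppressWarnings(expect_error(fit_transition_model(pcg, "cognitive"), "SEVERE"))
})

test_that("natural-scale coefficients undo the age centring", {
  pr <- truth_presets()
  co <- pr$paper_like$cognitive
  nat <- coef_natural(co)
  # eta computed on either scale agrees
  age <- 91
  a <- age - 80
  B <- co$origins$INTACT$coef
  N <- nat$INTACT
  eta_c <- B[1, ] + B[2, ] * a + B[3, ] * a^2 + B[4, ] * 1
  eta_n <- N[1, ] + N[2, ] * age + N[3, ] * age^2 + N[4, ] * 1
  expect_equal(eta_c, eta_n, tolerance = 1e-9)
  fn <- coef_natural(pr$paper_like$functional)
  Bf <- pr$paper_like$functional$origins$ACTIVE$coef
  Nf <- fn$ACTIVE
  expect_equal(Bf[1, ] + Bf[2, ] * a + Bf[3, ] + Bf[4, ],
               Nf[1, ] + Nf[2, ] * age + Nf[3, ] + Nf[4, ], tolerance = 1e-9)
})
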