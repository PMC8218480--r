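# Small deterministic fixtures built in code.

# a survey of identical "stayer" respondents (no randomness anywhere)
stayer_survey <- function(n = 10, state = "INTACT_ACTIVE", age = 70,
                          sex = "female", weight = 1) {
  data.frame(
    respondent_id = sprintf("S%03d", seq_len(n)),
    sex = sex, age_w1 = age, weight = weight,
    cog_w1 = state_cognition(state), fun_w1 = state_function(state),
    cog_w2 = state_cognition(state), fun_w2 = state_function(state),
    dead_w2 = 0L, stringsAsFactors = FALSE
  )
}

# hand-build a transition_coefficients object from per-origin matrices
manual_coeffs <- function(process, mats) {
  terms <- if (process == "cognitive")
    c("(Intercept)", "age_c", "age_c2", "female")
  else c("(Intercept)", "age_c", "female", "ci")
  origins <- lapply(mats, function(B) {
    stopifnot(identical(rownames(B), terms))
    list(coef = B, n = NA_integer_, loglik = NA_real_, iterations = 0L)
  })
  structure(list(process = process, origins = origins, center = 80),
            class = "transition_coefficients")
}

# a rate table with age/sex/ci-constant kernels, given per-origin
# probability rows (named vectors over destinations incl. stay and DEAD)
manual_rate_table <- function(cog_rows, fun_rows) {
  ages <- as.character(65:100)
  sexes <- c("female", "male")
  cog <- array(0, dim = c(36, 2, 4, 5),
               dimnames = list(age = ages, sex = sexes,
                               origin = COGNITIVE_LEVELS,
                               dest = c(COGNITIVE_LEVELS, "DEAD")))
  fun <- array(0, dim = c(36, 2, 2, 3, 4),
               dimnames = list(age = ages, sex = sexes, ci = c("0", "1"),
                               origin = FUNCTIONAL_LEVELS,
                               dest = c(FUNCTIONAL_LEVELS, "DEAD")))
  for (org in COGNITIVE_LEVELS) {
    row <- cog_rows[[org]]
    for (d in names(row)) cog[, , org, d] <- row[[d]]
  }
  for (org in FUNCTIONAL_LEVELS) {
    row <- fun_rows[[org]]
    for (d in names(row)) fun[, , , org, d] <- row[[d]]
  }
  structure(list(cognitive = cog, functional = fun), class = "rate_table")
}

identity_rate_table <- function() {
  manual_rate_table(
    cog_rows = setNames(lapply(COGNITIVE_LEVELS, function(o)
      setNames(1, o)), COGNITIVE_LEVELS),
    fun_rows = setNames(lapply(FUNCTIONAL_LEVELS, function(o)
      setNames(1, o)), FUNCTIONAL_LEVELS)
  )
}

# minimal demographic inputs: a closed population with chosen stocks
manual_demographics <- function(sub65_count = 0, pop65_age = 65,
                                pop65_count = 0, qx = 0, fertility_rate = 0,
                                state_prevalence = NULL) {
  init <- data.frame(
    age = rep(0:100, 2), sex = rep(c("female", "male"), each = 101),
    count = 0
  )
  if (sub65_count > 0)
    init$count[init$age < 65] <- sub65_count / (65 * 2)
  if (pop65_count > 0)
    init$count[init$age == pop65_age] <- pop65_count / 2
  fert <- data.frame(year = rep(2010:2017, each = 35),
                     age = rep(15:49, 8), rate = fertility_rate)
  lt <- data.frame(age = rep(0:64, 2), sex = rep(c("female", "male"), each = 65),
                   qx = qx)
  demographic_inputs(init, fert, lt, state_prevalence = state_prevalence)
}
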