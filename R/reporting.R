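#' @title Summary metrics and published-style tables
#' @description
#' Aggregations of a projection into the reported quantities: counts (in
#' millions) of older adults by impairment class, age group (65--74, 75--84,
#' 85+), sex and nursing-home-care-needs flag; relative change over a
#' horizon; arithmetic annual relative change (total change divided by the
#' horizon, the convention the published tables follow); and composition
#' fractions.
#' @name reporting
NULL

AGE_GROUPS <- c("65-74", "75-84", "85+")

age_group_of <- function(age) {
  cut(age, breaks = c(64, 74, 84, Inf), labels = AGE_GROUPS)
}

pop65_long <- function(projection, year) {
  yi <- match(year, projection$years)
  if (is.na(yi)) stop("year outside projection span", call. = FALSE)
  d <- as.data.frame.table(projection$pop65[yi, , , , , drop = TRUE],
                           responseName = "count", stringsAsFactors = FALSE)
  d$age <- as.integer(d$age)
  d$state <- composite_state(d$cognition, d$fun)
  d$age_group <- as.character(age_group_of(d$age))
  d$impairment_class <- impairment_class(d$state)
  d$care_needs <- needs_nursing_home_care(d$state)
  d
}

#' Aggregate a projection year into counts in millions
#'
#' @param projection a \code{projection_result}.
#' @param year calendar year within the projection span.
#' @param by character vector of grouping keys among "sex", "age_group",
#'   "impairment_class", "care_needs", "state"; empty for the 65+ total.
#' @return data.frame of group keys plus \code{millions}.
#' @export
aggregate_projection <- function(projection, year, by = character()) {
  d <- pop65_long(projection, year)
  allowed <- c("sex", "age_group", "impairment_class", "care_needs", "state")
  bad <- setdiff(by, allowed)
  if (length(bad))
    stop("unknown grouping key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!length(by))
    return(data.frame(millions = sum(d$count) / 1e6))
  out <- stats::aggregate(d["count"], d[by], sum)
  out$millions <- out$count / 1e6
  out$count <- NULL
  out[do.call(order, out[by]), , drop = FALSE]
}

millions_of <- function(projection, year, impaired_only = FALSE,
                        sex = NULL, age_group = NULL, classes = NULL,
                        care_needs = NULL) {
  d <- pop65_long(projection, year)
  if (impaired_only) d <- d[d$impairment_class != "NONE", ]
  if (!is.null(sex)) d <- d[d$sex %in% sex, ]
  if (!is.null(age_group)) d <- d[d$age_group %in% age_group, ]
  if (!is.null(classes)) d <- d[d$impairment_class %in% classes, ]
  if (!is.null(care_needs)) d <- d[d$care_needs == care_needs, ]
  sum(d$count) / 1e6
}

#' Total relative change in percent
#'
#' ((v1 / v0) - 1) * 100.
#'
#' @param v0,v1 counts at the start and end of the horizon; v0 > 0.
#' @export
relative_change <- function(v0, v1) {
  if (any(v0 <= 0)) stop("baseline count must be positive", call. = FALSE)
  (v1 / v0 - 1) * 100
}

#' Arithmetic annual relative change in percent
#'
#' Total relative change divided by the horizon length (the published
#' tables' annual columns equal total change / 45), so
#' annual_relative_change(v0, v1, h) * h == relative_change(v0, v1) exactly.
#'
#' @param v0,v1 counts at the horizon endpoints; v0 > 0.
#' @param horizon_years horizon length in years (default 45, i.e.
#'   2015--2060).
#' @export
annual_relative_change <- function(v0, v1, horizon_years = 45) {
  if (any(horizon_years <= 0)) stop("horizon must be positive", call. = FALSE)
  relative_change(v0, v1) / horizon_years
}

#' Composition fraction in percent
#'
#' @param numerator_count,denominator_count counts; denominator > 0.
#' @export
fraction_of <- function(numerator_count, denominator_count) {
  if (any(denominator_count <= 0))
    stop("denominator must be positive", call. = FALSE)
  numerator_count / denominator_count * 100
}

fmt_cell <- function(point, lo = NULL, hi = NULL, digits = 3) {
  p <- formatC(round(point, digits), format = "f", digits = digits)
  if (is.null(lo)) return(p)
  sprintf("%s (%s-%s)", p,
          formatC(round(lo, digits), format = "f", digits = digits),
          formatC(round(hi, digits), format = "f", digits = digits))
}

# one summary row: counts at both years, annual and total change
summary_row <- function(label, f, point, reps, year0, year1, horizon) {
  v0 <- f(point, year0); v1 <- f(point, year1)
  if (is.null(reps)) {
    data.frame(row = label,
               y0 = fmt_cell(v0), y1 = fmt_cell(v1),
               annual_change = fmt_cell(annual_relative_change(v0, v1, horizon),
                                        digits = 2),
               total_change = fmt_cell(relative_change(v0, v1), digits = 1),
               stringsAsFactors = FALSE)
  } else {
    r0 <- vapply(reps, f, numeric(1), year = year0)
    r1 <- vapply(reps, f, numeric(1), year = year1)
    ra <- annual_relative_change(r0, r1, horizon)
    rt <- relative_change(r0, r1)
    q <- function(x) stats::quantile(x, c(0.025, 0.975), type = 1, names = FALSE)
    q0 <- q(r0); q1 <- q(r1); qa <- q(ra); qt <- q(rt)
    data.frame(row = label,
               y0 = fmt_cell(v0, q0[1], q0[2]),
               y1 = fmt_cell(v1, q1[1], q1[2]),
               annual_change = fmt_cell(annual_relative_change(v0, v1, horizon),
                                        qa[1], qa[2], digits = 2),
               total_change = fmt_cell(relative_change(v0, v1),
                                       qt[1], qt[2], digits = 1),
               stringsAsFactors = FALSE)
  }
}

#' Published-style summary tables and the care-needs series
#'
#' Builds the four summary tables -- impairment by sex; impairment by sex and
#' age group; impairment type by sex; impairment type by age group -- plus
#' the yearly nursing-home-type-care-needs series. With replicate
#' projections supplied, every cell is rendered "point (lo-hi)" from the
#' 95% percentile interval across replicates.
#'
#' @param point_projection the point \code{projection_result}.
#' @param replicate_projections optional list of replicate projections.
#' @param year0,year1 horizon endpoints (defaults 2015 and 2060).
#' @return list of data.frames: table1, table2, table3, table4, care_needs.
#' @export
make_tables <- function(point_projection, replicate_projections = NULL,
                        year0 = 2015, year1 = 2060) {
  horizon <- year1 - year0
  reps <- replicate_projections
  if (!is.null(reps) && !length(reps)) reps <- NULL

  sexes <- list(all = NULL, female = "female", male = "male")
  t1 <- do.call(rbind, lapply(names(sexes), function(sx) {
    rbind(
      summary_row(paste(sx, "total"), function(p, year)
        millions_of(p, year, sex = sexes[[sx]]), point_projection, reps,
        year0, year1, horizon),
      summary_row(paste(sx, "without impairment"), function(p, year)
        millions_of(p, year, sex = sexes[[sx]], classes = "NONE"),
        point_projection, reps, year0, year1, horizon),
      summary_row(paste(sx, "with impairment"), function(p, year)
        millions_of(p, year, sex = sexes[[sx]], impaired_only = TRUE),
        point_projection, reps, year0, year1, horizon)
    )
  }))

  t2 <- do.call(rbind, lapply(names(sexes), function(sx) {
    do.call(rbind, lapply(AGE_GROUPS, function(ag)
      summary_row(paste(sx, "impaired", ag), function(p, year)
        millions_of(p, year, sex = sexes[[sx]], age_group = ag,
                    impaired_only = TRUE),
        point_projection, reps, year0, year1, horizon)))
  }))

  classes <- c("ADL_ONLY", "CI_ONLY", "CI_AND_ADL")
  t3 <- do.call(rbind, lapply(names(sexes), function(sx) {
    do.call(rbind, lapply(classes, function(cl)
      summary_row(paste(sx, cl), function(p, year)
        millions_of(p, year, sex = sexes[[sx]], classes = cl),
        point_projection, reps, year0, year1, horizon)))
  }))

  t4 <- do.call(rbind, lapply(AGE_GROUPS, function(ag) {
    do.call(rbind, lapply(classes, function(cl)
      summary_row(paste(ag, cl), function(p, year)
        millions_of(p, year, age_group = ag, classes = cl),
        point_projection, reps, year0, year1, horizon)))
  }))

  cn_point <- vapply(point_projection$years, function(yr)
    millions_of(point_projection, yr, care_needs = TRUE), numeric(1))
  care <- data.frame(year = point_projection$years, millions = cn_point)
  if (!is.null(reps)) {
    cn_rep <- sapply(reps, function(p)
      vapply(p$years, function(yr) millions_of(p, yr, care_needs = TRUE),
             numeric(1)))
    care$lo <- apply(cn_rep, 1, stats::quantile, 0.025, type = 1, names = FALSE)
    care$hi <- apply(cn_rep, 1, stats::quantile, 0.975, type = 1, names = FALSE)
  }

  list(table1 = t1, table2 = t2, table3 = t3, table4 = t4, care_needs = care)
}

#' Point estimates reported by the original published projection
#'
#' Transcription of the point estimates (millions of persons) printed in the
#' original study's summary tables, shipped as plain CSV. These are inputs
#' for reproducing the study's derived metrics (relative changes, annual
#' changes, composition fractions); the package does not re-derive them,
#' since that would require the restricted survey and census microdata.
#'
#' @return data.frame(table, subset, group, year, millions).
#' @export
published_estimates <- function() {
  path <- system.file("extdata", "published_projection_estimates.csv",
                      package = "mspop")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Look up one published point estimate in millions
#'
#' @param subset population subset ("all", "female", "male" or an age group).
#' @param group row group (e.g. "impaired", "total", "ADL_ONLY").
#' @param year 2015 or 2060.
#' @export
published_value <- function(subset, group, year) {
  d <- published_estimates()
  v <- d$millions[d$subset == subset & d$group == group & d$year == year]
  if (length(v) != 1)
    stop(sprintf("no unique published value for (%s, %s, %d)",
                 subset, group, year), call. = FALSE)
  v
}
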