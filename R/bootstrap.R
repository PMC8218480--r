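#' @title Weighted-resampling bootstrap
#' @description
#' Uncertainty in the estimated transition rates (and anything downstream)
#' is quantified by resampling respondents with replacement, with the
#' rescaled sampling weights as draw probabilities. Each replicate dataset
#' has the original size, carries unit weights (the design weights having
#' been consumed by the sampling probabilities), and is pushed through the
#' full estimation -- midpoint imputation included -- and optionally the
#' projection. Percentile intervals are order statistics of the replicate
#' distribution.
#' @name bootstrap_uncertainty
NULL

#' Rescale sampling weights to probabilities
#'
#' @param weights positive numeric vector; may carry names identifying
#'   respondents.
#' @return weights divided by their sum.
#' @export
rescale_weights <- function(weights) {
  if (!length(weights)) stop("empty weight vector", call. = FALSE)
  bad <- which(!is.finite(weights) | weights <= 0)
  if (length(bad)) {
    who <- if (!is.null(names(weights))) names(weights)[bad[1]] else bad[1]
    stop(sprintf("non-positive sampling weight for respondent %s", who),
         call. = FALSE)
  }
  weights / sum(weights)
}

#' Draw one bootstrap replicate of a survey
#'
#' n respondents drawn with replacement using the supplied probabilities;
#' each respondent may appear once, more than once or not at all. Replicate
#' records carry weight 1.
#'
#' @param survey survey data.frame.
#' @param probabilities draw probabilities aligned with rows of
#'   \code{survey} (default: rescaled survey weights).
#' @param seed optional; if given, seeds the RNG first.
#' @return a survey data.frame of the same size.
#' @export
resample_survey <- function(survey, probabilities = NULL, seed = NULL) {
  n <- nrow(survey)
  if (is.null(probabilities)) probabilities <- rescale_weights(survey$weight)
  if (length(probabilities) != n)
    stop("probabilities not aligned with survey rows", call. = FALSE)
  if (abs(sum(probabilities) - 1) > 1e-8)
    stop("probabilities must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n, replace = TRUE, prob = probabilities)
  out <- survey[idx, , drop = FALSE]
  out$weight <- 1
  rownames(out) <- NULL
  out
}

#' Bootstrap configuration
#'
#' @param replicates number of bootstrap datasets (1000 in the source
#'   analysis).
#' @param base_seed replicate r uses seed base_seed + r.
#' @param ci_level interval coverage level.
#' @export
bootstrap_config <- function(replicates = 1000L, base_seed = 1L,
                             ci_level = 0.95) {
  stopifnot(replicates >= 1, ci_level > 0, ci_level < 1)
  list(replicates = as.integer(replicates), base_seed = as.integer(base_seed),
       ci_level = ci_level)
}

rate_table_values <- function(tab) c(tab$cognitive, tab$functional)

rate_table_from_values <- function(v, template) {
  nc <- length(template$cognitive)
  template$cognitive[] <- v[seq_len(nc)]
  template$functional[] <- v[-seq_len(nc)]
  template
}

#' Run the weighted bootstrap
#'
#' Replicate r seeds the RNG with base_seed + r, draws the resample and the
#' imputation from that stream, and re-estimates both transition processes
#' (and re-runs the projection if requested). A replicate whose estimation
#' fails (non-convergence / separation) is re-drawn with a shifted seed; if
#' more than 5% of replicates fail the bootstrap aborts.
#'
#' @param survey survey data.frame (with design weights).
#' @param config a [bootstrap_config()].
#' @param downstream "estimation" or "projection".
#' @param demog,schedule projection inputs, required when
#'   \code{downstream = "projection"}.
#' @param point_seed seed for the point-estimate imputation.
#' @param midpoint "impute" or "recorded", passed through to estimation
#'   (see [build_transition_pairs()]).
#' @return a \code{bootstrap_result}: the point rate table, per-cell
#'   percentile intervals (arrays \code{lo}/\code{hi} shaped like the rate
#'   table), the replicate value matrix, and (optionally) per-replicate
#'   projections.
#' @export
run_bootstrap <- function(survey, config = bootstrap_config(),
                          downstream = c("estimation", "projection"),
                          demog = NULL, schedule = assumption_schedule(),
                          point_seed = NULL,
                          midpoint = c("impute", "recorded")) {
  downstream <- match.arg(downstream)
  midpoint <- match.arg(midpoint)
  if (downstream == "projection" && is.null(demog))
    stop("projection downstream requires demographic inputs", call. = FALSE)
  probs <- rescale_weights(survey$weight)
  if (is.null(point_seed)) point_seed <- config$base_seed
  point <- estimate_transition_models(survey, seed = point_seed,
                                      midpoint = midpoint)

  R <- config$replicates
  values <- NULL
  projections <- if (downstream == "projection") vector("list", R) else NULL
  failures <- 0L
  for (r in seq_len(R)) {
    est <- NULL
    for (attempt in 0:9) {
      seed_r <- (config$base_seed + r + attempt * 1000003L) %% 2147483647L
      set.seed(seed_r)
      rep_survey <- resample_survey(survey, probs)
      est <- tryCatch({
        mid <- survey_midpoints(rep_survey, midpoint)
        cog <- fit_transition_model(
          pairs_from_midpoints(rep_survey, mid, "cognitive"), "cognitive",
          start = point$cognitive)
        fun <- fit_transition_model(
          pairs_from_midpoints(rep_survey, mid, "functional"), "functional",
          start = point$functional)
        list(rate_table = build_rate_table(cog, fun))
      }, error = function(e) NULL)
      if (!is.null(est)) {
        if (attempt > 0) failures <- failures + 1L
        break
      }
    }
    if (is.null(est))
      stop("bootstrap replicate failed repeatedly; estimation unstable",
           call. = FALSE)
    v <- rate_table_values(est$rate_table)
    if (is.null(values)) values <- matrix(0, R, length(v))
    values[r, ] <- v
    if (downstream == "projection")
      projections[[r]] <- project(demog, est$rate_table, schedule)
  }
  if (failures > 0.05 * R)
    stop(sprintf("%d of %d bootstrap replicates required re-draws (> 5%%): estimation unstable",
                 failures, R), call. = FALSE)

  # percentile interval as order statistics, indices floor((B+1)a) and
  # ceiling((B+1)(1-a)) (the standard bootstrap-percentile convention)
  alpha <- (1 - config$ci_level) / 2
  ilo <- max(1L, floor((R + 1) * alpha))
  ihi <- min(R, ceiling((R + 1) * (1 - alpha)))
  qs <- apply(values, 2, function(x) sort(x)[c(ilo, ihi)])
  lo <- rate_table_from_values(qs[1, ], point$rate_table)
  hi <- rate_table_from_values(qs[2, ], point$rate_table)
  structure(list(config = config, point = point$rate_table,
                 coefficients = list(cognitive = point$cognitive,
                                     functional = point$functional),
                 replicate_values = values, lo = lo, hi = hi,
                 projections = projections, redraws = failures),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %.0f%% percentile intervals (%d re-draws)\n",
              x$config$replicates, 100 * x$config$ci_level, x$redraws))
  invisible(x)
}

#' Tidy interval summary of a bootstrap result
#'
#' @param object a \code{bootstrap_result}.
#' @param ... unused.
#' @return data.frame of rate-table cells with point, lo and hi columns.
#' @export
summary.bootstrap_result <- function(object, ...) {
  pt <- as.data.frame(object$point)
  pt$lo <- as.data.frame(object$lo)$value
  pt$hi <- as.data.frame(object$hi)$value
  names(pt)[names(pt) == "value"] <- "point"
  pt
}

#' Stream bootstrap replicate rate tables to one tidy CSV
#'
#' One row per (replicate, process, origin, dest, age, sex, ci) cell.
#'
#' @param x a \code{bootstrap_result}.
#' @param path CSV file path.
#' @export
write_bootstrap_replicates <- function(x, path) {
  cells <- as.data.frame(x$point)
  cells$value <- NULL
  R <- nrow(x$replicate_values)
  out <- cells[rep(seq_len(nrow(cells)), times = R), ]
  out$replicate <- rep(seq_len(R), each = nrow(cells))
  out$value <- as.vector(t(x$replicate_values))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
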