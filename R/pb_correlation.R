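#' Parameters for the percentage bend correlation and its bootstrap CI
#'
#' @param beta Bend fraction in `[0, 0.5)`: the proportion of marginal
#'   observations that may deviate grossly without biasing the estimator.
#'   Default 0.2.
#' @param conf_level Confidence level of the bootstrap interval.
#' @param n_boot Number of bootstrap resamples (default 2999).
#' @param seed Integer root seed; per-area-year seeds are derived from it so
#'   results do not depend on evaluation order.
#' @param bend_rank_rule How the rank of the bend scale order statistic is
#'   computed: `"round"` uses `m = floor((1 - beta) n + 0.5)` (the canonical
#'   description), `"floor"` uses `m = floor((1 - beta) n)` (found in some
#'   published implementations).
#' @return A list of class `pb_params`.
#' @export
pb_params <- function(beta = 0.2, conf_level = 0.95, n_boot = 2999L,
                      seed = 1L, bend_rank_rule = c("round", "floor")) {
  bend_rank_rule <- match.arg(bend_rank_rule)
  if (beta < 0 || beta >= 0.5) stop("beta must be in [0, 0.5)", call. = FALSE)
  if (conf_level <= 0 || conf_level >= 1) stop("conf_level must be in (0, 1)",
                                               call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  structure(list(beta = beta, conf_level = conf_level,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 bend_rank_rule = bend_rank_rule),
            class = "pb_params")
}

# Bend scale omega-hat: the m-th smallest |x - median(x)|.
pb_omega <- function(x, beta = 0.2, bend_rank_rule = "round") {
  n <- length(x)
  w <- sort(abs(x - median(x)))
  m <- if (bend_rank_rule == "floor") floor((1 - beta) * n) else floor((1 - beta) * n + 0.5)
  m <- max(1L, min(n, as.integer(m)))
  omega <- w[m]
  if (omega <= 0) {
    stop("degenerate scale: more than half the data sit at the median", call. = FALSE)
  }
  omega
}

#' Percentage bend measure of location
#'
#' Robust location estimate underlying the percentage bend correlation:
#' observations more than one bend-scale unit from the median are trimmed
#' and compensated by the scale times the count imbalance.
#'
#' @param x Numeric vector, length >= 2, not all values identical.
#' @param beta Bend fraction in `[0, 0.5)`.
#' @param bend_rank_rule See [pb_params()].
#' @return The percentage bend location (a real number).
#' @export
pb_location <- function(x, beta = 0.2, bend_rank_rule = "round") {
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  omega <- pb_omega(x, beta, bend_rank_rule)
  psi <- (x - median(x)) / omega
  i1 <- sum(psi < -1)
  i2 <- sum(psi > 1)
  (sum(x[psi >= -1 & psi <= 1]) + omega * (i2 - i1)) / (length(x) - i1 - i2)
}

# Standardized, clipped deviations from the pb location: the "a" scores.
pb_scores <- function(x, beta, bend_rank_rule = "round") {
  omega <- pb_omega(x, beta, bend_rank_rule)
  loc <- pb_location(x, beta, bend_rank_rule)
  pmin(pmax((x - loc) / omega, -1), 1)
}

#' Percentage bend correlation
#'
#' The Pearson correlation of deviations standardized by the bend scale and
#' clipped to `[-1, 1]`, resistant to a fraction `beta` of marginal outliers.
#' The test statistic follows a Student t distribution with `n - 2` degrees
#' of freedom under independence.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither degenerate.
#' @inheritParams pb_location
#' @return A list with `rho_pb`, `t_stat`, `p_value` and `n`.
#' @export
pb_correlation <- function(x, y, beta = 0.2, bend_rank_rule = "round") {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  a <- pb_scores(x, beta, bend_rank_rule)
  b <- pb_scores(y, beta, bend_rank_rule)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) stop("degenerate scores: all clipped deviations are zero", call. = FALSE)
  rho <- sum(a * b) / den
  rho <- min(1, max(-1, rho))
  if (abs(rho) == 1) {
    t_stat <- sign(rho) * Inf
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(rho_pb = rho, t_stat = t_stat, p_value = p, n = n)
}

#' Bootstrap confidence interval for the percentage bend correlation
#'
#' Resamples pairs of observations with replacement, recomputes the
#' correlation on each resample, and returns the percentile interval of the
#' replicate distribution. Resamples on which the bend scale degenerates
#' (over half the resampled values tie at the median) are skipped; more than
#' 10% skipped is an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @param params A [pb_params] object (its `seed` fixes the resampling).
#' @return A list with `ci_low`, `ci_high`, `n_boot_kept`, `n_boot_skipped`
#'   and the replicate vector `replicates`.
#' @export
pb_bootstrap_ci <- function(x, y, params = pb_params()) {
  stopifnot(inherits(params, "pb_params"))
  n <- length(x)
  reps <- numeric(params$n_boot)
  keep <- logical(params$n_boot)
  with_seed(params$seed, {
    for (b in seq_len(params$n_boot)) {
      i <- sample.int(n, n, replace = TRUE)
      r <- tryCatch(
        pb_correlation(x[i], y[i], params$beta, params$bend_rank_rule)$rho_pb,
        error = function(e) NA_real_
      )
      reps[b] <- r
      keep[b] <- !is.na(r)
    }
  })
  skipped <- sum(!keep)
  if (skipped > 0.1 * params$n_boot) {
    stop("unstable bootstrap: ", skipped, " of ", params$n_boot,
         " resamples degenerate", call. = FALSE)
  }
  ci <- percentile_interval(reps[keep], params$conf_level)
  list(ci_low = ci[1], ci_high = ci[2], n_boot_kept = sum(keep),
       n_boot_skipped = skipped, replicates = reps[keep])
}

# Percentile interval whose endpoints are exact order statistics of the
# replicate set, at ranks floor((B + 1) * alpha) and B + 1 - that rank.
percentile_interval <- function(t, conf_level) {
  t <- sort(t)
  B <- length(t)
  alpha <- (1 - conf_level) / 2
  k <- max(1L, min(B, as.integer(floor((B + 1) * alpha))))
  c(t[k], t[B + 1L - k])
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Deterministic per-(area, year) seed so results are independent of the
# order in which area-years are evaluated. Kept below 2^31.
derive_seed <- function(seed, area_id, recruit_year) {
  h <- sum(utf8ToInt(as.character(area_id)) * seq_along(utf8ToInt(as.character(area_id))))
  as.integer((as.numeric(seed) * 7919 + as.numeric(recruit_year) * 131 + h * 10007) %% 2147483647)
}

#' Synchronicity Index for one area and recruitment year
#'
#' Correlates monthly CHL and MLD over the observation window (spawning
#' onset of the preceding year to the month before the survey) with the
#' percentage bend correlation, and attaches a pairs bootstrap confidence
#' interval. The index is significant when the bootstrap interval excludes
#' zero (the t-test p-value is reported alongside).
#'
#' @param chl,mld [env_series] objects covering the window.
#' @param area An [area_spec].
#' @param recruit_year Recruitment year.
#' @param params A [pb_params]; its seed is combined with the area and year.
#' @param ci Compute the bootstrap interval? Set `FALSE` to skip (e.g. in
#'   large simulation studies where only the point estimate is needed).
#' @return A one-row tibble: `area_id`, `recruit_year`, `n_months`,
#'   `rho_pb`, `t_stat`, `p_value`, `ci_low`, `ci_high`, `significant`,
#'   `significant_t`.
#' @export
compute_si <- function(chl, mld, area, recruit_year, params = pb_params(),
                       ci = TRUE) {
  window <- build_window(area, recruit_year)
  pw <- extract_paired_window(chl, mld, window)
  est <- pb_correlation(pw$chl, pw$mld, params$beta, params$bend_rank_rule)
  if (ci) {
    p2 <- params
    p2$seed <- derive_seed(params$seed, area$area_id, recruit_year)
    bci <- pb_bootstrap_ci(pw$chl, pw$mld, p2)
    ci_low <- bci$ci_low; ci_high <- bci$ci_high
    significant <- ci_low > 0 || ci_high < 0
  } else {
    ci_low <- NA_real_; ci_high <- NA_real_
    significant <- NA
  }
  tibble::tibble(
    area_id = area$area_id,
    recruit_year = as.integer(recruit_year),
    n_months = nrow(window),
    rho_pb = est$rho_pb,
    t_stat = est$t_stat,
    p_value = est$p_value,
    ci_low = ci_low,
    ci_high = ci_high,
    significant = significant,
    significant_t = est$p_value < 1 - params$conf_level
  )
}

#' Synchronicity Index table over areas and years
#'
#' @param env Named list: for each area id, a list with `chl`, `mld`
#'   [env_series] elements.
#' @param areas Named list of [area_spec] objects (default [default_areas()]).
#' @param years Named list mapping area id to the recruitment years to
#'   evaluate.
#' @inheritParams compute_si
#' @return A tibble with one row per area-year (the machine-readable twin of
#'   the per-year SI figure).
#' @export
compute_si_table <- function(env, areas = default_areas(), years,
                             params = pb_params(), ci = TRUE) {
  rows <- list()
  for (aid in names(areas)) {
    if (is.null(env[[aid]])) stop("no environmental series for area ", aid,
                                  call. = FALSE)
    for (yr in years[[aid]]) {
      rows[[length(rows) + 1L]] <-
        compute_si(env[[aid]]$chl, env[[aid]]$mld, areas[[aid]], yr, params, ci)
    }
  }
  dplyr::bind_rows(rows)
}
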