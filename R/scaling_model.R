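#' Min-max scale a variable to [0, 1]
#'
#' @param values Numeric vector, length >= 2 with max > min.
#' @param name Label for the variable being scaled.
#' @param area_id Area the values belong to.
#' @return A list of class `scaled_variable` with `values` in `[0, 1]` and
#'   the original bounds, so the scaling is invertible.
#' @export
min_max_scale <- function(values, name = "x", area_id = NA_character_) {
  if (length(values) < 2L) stop("need at least 2 values to scale", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi <= lo) stop("degenerate range: all values equal for ", name,
                     " in area ", area_id, call. = FALSE)
  structure(list(source_name = name, area_id = area_id,
                 values = (values - lo) / (hi - lo),
                 original_min = lo, original_max = hi),
            class = "scaled_variable")
}

#' Invert a min-max scaling
#' @param scaled A `scaled_variable`.
#' @param values Scaled values to map back (defaults to the stored ones).
#' @return Values on the original scale.
#' @export
min_max_invert <- function(scaled, values = scaled$values) {
  scaled$original_min + values * (scaled$original_max - scaled$original_min)
}

#' Assemble the pooled standardized regression table
#'
#' Joins recruitment, SI and window-mean SST on (area, year); within each
#' area, min-max scales all three; the response is `log(1 + scaled
#' recruitment)` (so it lives in `[0, log 2]`); rows are then pooled across
#' areas. Years missing any component are dropped with a message.
#'
#' @param recruits List of per-area recruitment tibbles
#'   (`area_id,year,abundance`), as from [load_recruitment()].
#' @param si_table SI tibble from [compute_si_table()] (needs `area_id`,
#'   `recruit_year`, `rho_pb`).
#' @param sst_means Tibble `area_id,recruit_year,sst_mean`.
#' @return A tibble `area_id,recruit_year,y,si_scaled,sst_scaled`.
#' @export
build_regression_table <- function(recruits, si_table, sst_means) {
  rec <- dplyr::bind_rows(recruits)
  merged <- dplyr::inner_join(
    dplyr::inner_join(rec,
                      si_table[, c("area_id", "recruit_year", "rho_pb")],
                      by = c("area_id", "year" = "recruit_year")),
    sst_means, by = c("area_id", "year" = "recruit_year"))
  n_dropped <- nrow(rec) - nrow(merged)
  if (n_dropped > 0) {
    message(n_dropped, " area-year(s) dropped: missing SI or SST")
  }
  out <- lapply(split(merged, merged$area_id), function(d) {
    if (nrow(d) < 2L) stop("area ", d$area_id[1],
                           " has fewer than 2 complete years; scaling undefined",
                           call. = FALSE)
    tibble::tibble(
      area_id = d$area_id,
      recruit_year = d$year,
      y = log1p(min_max_scale(d$abundance, "recruitment", d$area_id[1])$values),
      si_scaled = min_max_scale(d$rho_pb, "SI", d$area_id[1])$values,
      sst_scaled = min_max_scale(d$sst_mean, "SST", d$area_id[1])$values
    )
  })
  dplyr::bind_rows(out)
}

#' Robust linear regression by Huber M-estimation
#'
#' Fits `y ~ si_scaled + sst_scaled` by iteratively reweighted least squares
#' with the Huber weight function: rows whose standardized residual exceeds
#' the tuning constant are down-weighted proportionally. The residual scale
#' is the rescaled median absolute deviation (about zero), recomputed each
#' iteration. A zero residual scale (exact fit) terminates with the current
#' (least squares) solution and unit weights.
#'
#' @param table A regression table from [build_regression_table()].
#' @param tuning_k Huber tuning constant (default 1.345, 95% efficiency at
#'   the Gaussian).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Iteration cap; non-convergence is reported, not hidden.
#' @return An object of class `robust_fit`: `coefficients` (intercept, SI
#'   slope, SST slope), `scale`, `weights`, `fitted`, `residuals`,
#'   `converged`, `iterations`, plus the model frame.
#' @export
fit_robust <- function(table, tuning_k = 1.345, tol = 1e-8, max_iter = 50L) {
  if (nrow(table) < 4L) stop("need at least 4 rows to fit", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, si_scaled = table$si_scaled,
             sst_scaled = table$sst_scaled)
  y <- table$y
  fit_robust_xy(X, y, tuning_k, tol, max_iter, model = table)
}

# IRLS core on an explicit design matrix; shared with the bootstrap loop.
fit_robust_xy <- function(X, y, tuning_k = 1.345, tol = 1e-8, max_iter = 50L,
                          model = NULL, warn = TRUE) {
  q0 <- qr(X)
  if (q0$rank < ncol(X)) {
    stop("design matrix is rank deficient (collinear predictors)", call. = FALSE)
  }
  beta <- qr.coef(q0, y)
  w <- rep(1, length(y))
  converged <- FALSE
  iter <- 0L
  s <- 0
  repeat {
    r <- y - drop(X %*% beta)
    s <- mad(r, center = 0)
    if (s < .Machine$double.eps^0.75) {
      # exact (or near-exact) fit: the LS solution is the M-estimate
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    w <- pmin(1, tuning_k * s / abs(r))
    w[abs(r) < .Machine$double.eps] <- 1
    sw <- sqrt(w)
    wf <- stats::.lm.fit(X * sw, y * sw)
    beta_new <- wf$coefficients
    if (wf$pivoted) beta_new[wf$pivot] <- wf$coefficients
    iter <- iter + 1L
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  names(beta) <- colnames(X)
  if (!converged && warn) {
    warning("IRLS did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  structure(list(coefficients = beta, scale = s, weights = w,
                 fitted = drop(X %*% beta), residuals = y - drop(X %*% beta),
                 converged = converged, iterations = iter,
                 tuning_k = tuning_k, tol = tol, max_iter = max_iter,
                 model = model),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat("Huber M-estimation fit (k =", x$tuning_k, ")\n")
  print(round(x$coefficients, 4))
  cat("residual scale:", signif(x$scale, 4),
      "| converged:", x$converged, "in", x$iterations, "iterations\n")
  invisible(x)
}

#' Bootstrap confidence intervals for the robust fit
#'
#' Random-X (case) resampling: rows of the regression table are resampled
#' with replacement, the robust model refit, and the coefficient replicates
#' summarized as three interval families — first-order Normal approximation
#' (`estimate +- z * sd(replicates)`), bootstrap Percentile (order
#' statistics of the replicate set), and the adjusted bootstrap percentile
#' BCa (bias-correction from the fraction of replicates below the estimate,
#' acceleration from the jackknife). A coefficient is flagged significant
#' under a family when that interval excludes zero.
#'
#' @param table Regression table.
#' @param n_boot Number of case resamples (default 2999).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Integer seed; the replicate set is reproducible.
#' @param tuning_k,tol,max_iter Passed to the robust fit.
#' @param stratify_by_area Resample within area instead of pooled.
#' @return A list of class `coef_cis`: tibble `intervals` with columns
#'   `coefficient,estimate,family,ci_low,ci_high,significant`; the replicate
#'   matrix; `n_boot`, `seed`, `n_failed`.
#' @export
bootstrap_cis <- function(table, n_boot = 2999L, conf_level = 0.95,
                          seed = 1L, tuning_k = 1.345, tol = 1e-8,
                          max_iter = 50L, stratify_by_area = FALSE) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  fit0 <- fit_robust(table, tuning_k, tol, max_iter)
  t0 <- fit0$coefficients
  X <- cbind(1, table$si_scaled, table$sst_scaled)
  y <- table$y
  n <- nrow(table)
  strata <- if (stratify_by_area) split(seq_len(n), table$area_id) else list(seq_len(n))

  refit <- function(idx) {
    tryCatch(fit_robust_xy(X[idx, , drop = FALSE], y[idx], tuning_k, tol,
                           max_iter, warn = FALSE)$coefficients,
             error = function(e) rep(NA_real_, ncol(X)))
  }

  reps <- matrix(NA_real_, n_boot, length(t0),
                 dimnames = list(NULL, names(t0)))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(strata, function(s) s[sample.int(length(s), length(s), replace = TRUE)]),
                    use.names = FALSE)
      reps[b, ] <- refit(idx)
    }
  })
  ok <- stats::complete.cases(reps)
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * n_boot) {
    stop("unstable bootstrap: ", n_failed, " of ", n_boot, " refits failed",
         call. = FALSE)
  }
  reps <- reps[ok, , drop = FALSE]

  # jackknife for the BCa acceleration
  jack <- t(vapply(seq_len(n), function(i) refit(setdiff(seq_len(n), i)),
                   numeric(length(t0))))

  rows <- list()
  for (j in seq_along(t0)) {
    t_j <- reps[, j]
    fam <- interval_families(t_j, unname(t0[j]), jack[, j], conf_level)
    for (f in names(fam)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        coefficient = names(t0)[j], estimate = unname(t0[j]), family = f,
        ci_low = fam[[f]][1], ci_high = fam[[f]][2],
        significant = fam[[f]][1] > 0 || fam[[f]][2] < 0)
    }
  }
  structure(list(intervals = dplyr::bind_rows(rows), replicates = reps,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_failed = n_failed, fit = fit0, conf_level = conf_level),
            class = "coef_cis")
}

# The three interval families from one replicate vector. A degenerate
# replicate set (zero spread) collapses every family onto the estimate.
interval_families <- function(t, t0, jack, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (length(unique(t)) == 1L && t[1] == t0) {
    pt_int <- c(t0, t0)
    return(list(normal = pt_int, percentile = pt_int, bca = pt_int))
  }
  normal <- c(t0 - z * sd(t), t0 + z * sd(t))
  percentile <- percentile_interval(t, conf_level)
  bca <- bca_interval(t, t0, jack, conf_level)
  list(normal = normal, percentile = percentile, bca = bca)
}

# BCa: bias-correction z0 from the fraction of replicates below the point
# estimate; acceleration a from the jackknife skewness. Falls back to the
# percentile interval when z0 is undefined (all replicates on one side).
bca_interval <- function(t, t0, jack, conf_level) {
  alpha <- (1 - conf_level) / 2
  prop <- mean(t < t0)
  if (prop <= 0 || prop >= 1) return(percentile_interval(t, conf_level))
  z0 <- qnorm(prop)
  jm <- mean(jack, na.rm = TRUE)
  d <- jm - jack
  denom <- 6 * sum(d^2, na.rm = TRUE)^1.5
  a <- if (denom > 0) sum(d^3, na.rm = TRUE) / denom else 0
  adj <- function(zalpha) pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  a1 <- adj(qnorm(alpha)); a2 <- adj(qnorm(1 - alpha))
  ts <- sort(t); B <- length(ts)
  # same order-statistic convention as the percentile interval, so BCa
  # reduces to it exactly when z0 = 0 and a = 0
  lo <- ts[max(1L, min(B, as.integer(floor((B + 1) * a1))))]
  hi <- ts[max(1L, min(B, B + 1L - as.integer(floor((B + 1) * (1 - a2)))))]
  c(lo, hi)
}

#' Preliminary Pearson screen between annual SI and SST
#'
#' Classical Pearson correlation with its two-sided t-test, used to check
#' for association between the two predictors before the pooled fit.
#'
#' @param si_by_year,sst_by_year Numeric vectors of equal length >= 3.
#' @return A list with `rho` and `p_value`.
#' @export
pearson_screen <- function(si_by_year, sst_by_year) {
  if (length(si_by_year) != length(sst_by_year) || length(si_by_year) < 3L) {
    stop("need equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (sd(si_by_year) == 0 || sd(sst_by_year) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(si_by_year, sst_by_year, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Residual diagnostics for the robust fit
#'
#' Checks the three classical assumptions: normality of residuals
#' (Shapiro-Wilk), homogeneity of variance (correlation of absolute
#' residuals with fitted values), and independence (lag-1 autocorrelation of
#' residuals within each area, in year order).
#'
#' @param fit A `robust_fit` with at least 5 residuals and its model frame.
#' @param table The regression table the fit was computed on (defaults to
#'   the model frame stored in the fit).
#' @return A list of class `residual_diagnostics`: `normality` (W statistic
#'   and p-value), `homoscedasticity` (correlation and p-value),
#'   `autocorrelation` (per-area lag-1 tibble), `residual_table`, and a
#'   `degenerate` flag set when the residual variance is zero.
#' @export
residual_diagnostics <- function(fit, table = fit$model) {
  r <- fit$residuals
  if (length(r) < 5L) stop("need at least 5 residuals", call. = FALSE)
  if (sd(r) < 1e-12 * max(1, max(abs(fit$fitted)))) {
    return(structure(list(degenerate = TRUE,
                          message = "degenerate: zero residual variance",
                          residual_table = NULL),
                     class = "residual_diagnostics"))
  }
  sw <- stats::shapiro.test(r)
  het <- stats::cor.test(abs(r), fit$fitted, method = "pearson")
  rt <- tibble::tibble(area_id = table$area_id,
                       recruit_year = table$recruit_year,
                       fitted = fit$fitted, residual = r,
                       weight = fit$weights)
  lag1 <- lapply(split(rt, rt$area_id), function(d) {
    d <- d[order(d$recruit_year), ]
    x <- d$residual
    rho <- if (length(x) >= 3 && sd(x[-1]) > 0 && sd(x[-length(x)]) > 0)
      cor(x[-1], x[-length(x)]) else NA_real_
    tibble::tibble(area_id = d$area_id[1], lag1_autocorrelation = rho,
                   n = length(x))
  })
  structure(list(
    degenerate = FALSE,
    normality = list(statistic = unname(sw$statistic), p_value = sw$p.value),
    homoscedasticity = list(correlation = unname(het$estimate),
                            p_value = het$p.value,
                            flagged = unname(het$estimate) > 0 && het$p.value < 0.05),
    autocorrelation = dplyr::bind_rows(lag1),
    residual_table = rt
  ), class = "residual_diagnostics")
}
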