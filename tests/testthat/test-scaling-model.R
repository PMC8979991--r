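test_that("min-max scaling is exact, affine-invariant and invertible", {
  s <- min_max_scale(c(2, 4, 6))
  expect_equal(s$values, c(0, 0.5, 1))
  expect_error(min_max_scale(c(7, 7, 7)), "degenerate range")

  set.seed(31)
  x <- rnorm(25)
  expect_equal(min_max_scale(3 + 2 * x)$values, min_max_scale(x)$values)
  expect_equal(min_max_invert(min_max_scale(x)), x, tolerance = 1e-12)
})

test_that("regression table pools per-area standardized rows", {
  gen <- generate_study(study_scenario(seed = 3))
  tab <- build_regression_table(gen$recruitment, gen$si_values, gen$sst_means)
  expect_equal(nrow(tab), 18 + 18 + 15)
  expect_true(all(tab$y >= 0 & tab$y <= log(2) + 1e-12))
  expect_true(all(tab$si_scaled >= 0 & tab$si_scaled <= 1))
  # the max-recruitment year of each area scales to log(2)
  for (aid in c("SoS", "GoL", "AS")) {
    expect_equal(max(tab$y[tab$area_id == aid]), log(2))
    expect_equal(min(tab$y[tab$area_id == aid]), 0)
  }

  # a year missing its SI is dropped, with a message
  si_partial <- gen$si_values[-1, ]
  expect_message(
    tab2 <- build_regression_table(gen$recruitment, si_partial, gen$sst_means),
    "dropped")
  expect_equal(nrow(tab2), 50)

  # an area reduced to one complete year cannot be scaled
  si_one <- gen$si_values[gen$si_values$area_id != "AS" |
                            gen$si_values$recruit_year == 2004, ]
  expect_error(
    suppressMessages(build_regression_table(gen$recruitment, si_one, gen$sst_means)),
    "fewer than 2")
})

test_that("Huber IRLS recovers a noiseless linear system exactly", {
  tab <- exact_table()
  fit <- fit_robust(tab)
  expect_equal(unname(fit$coefficients), c(0.21, 0.21, -0.07), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(unname(fit$weights), rep(1, nrow(tab)))
})

test_that("Huber fit resists a gross response outlier better than OLS", {
  tab <- exact_table(n = 40, seed = 12)
  set.seed(13)
  noisy <- tab
  noisy$y <- noisy$y + rnorm(40, 0, 0.03)
  clean_slope <- fit_robust(noisy)$coefficients[["si_scaled"]]

  contaminated <- noisy
  contaminated$y[7] <- contaminated$y[7] + 5
  huber_slope <- fit_robust(contaminated)$coefficients[["si_scaled"]]
  ols_slope <- coef(lm(y ~ si_scaled + sst_scaled, contaminated))[["si_scaled"]]

  expect_lt(abs(huber_slope - clean_slope), 0.02)
  expect_lt(abs(huber_slope - clean_slope), abs(ols_slope - clean_slope))
})

test_that("Huber with an infinite tuning constant is ordinary least squares", {
  set.seed(14)
  tab <- exact_table(n = 35, seed = 14)
  tab$y <- tab$y + rnorm(35, 0, 0.1)
  fit <- fit_robust(tab, tuning_k = 1e10)
  ols <- coef(lm(y ~ si_scaled + sst_scaled, tab))
  expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
})

test_that("Huber IRLS agrees with the reference M-estimator on noisy data", {
  skip_if_not_installed("MASS")
  set.seed(15)
  tab <- exact_table(n = 60, seed = 15)
  tab$y <- tab$y + rnorm(60, 0, 0.08)
  tab$y[c(3, 44)] <- tab$y[c(3, 44)] + c(2, -3)
  fit <- fit_robust(tab, tol = 1e-10, max_iter = 200)
  ref <- MASS::rlm(y ~ si_scaled + sst_scaled, tab, psi = MASS::psi.huber,
                   k = 1.345, scale.est = "MAD", acc = 1e-10, maxit = 200)
  # both solve the same estimating equations; small discrepancy comes from
  # the reference implementation's internal scale-update order
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-5)
})

test_that("fit is equivariant and rejects collinear designs", {
  set.seed(16)
  tab <- exact_table(n = 30, seed = 16)
  tab$y <- tab$y + rnorm(30, 0, 0.05)
  f1 <- fit_robust(tab)
  tab2 <- tab; tab2$y <- tab2$y + 0.37
  f2 <- fit_robust(tab2)
  expect_equal(f2$coefficients[["(Intercept)"]],
               f1$coefficients[["(Intercept)"]] + 0.37, tolerance = 1e-7)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-7)

  tab3 <- tab; tab3$sst_scaled <- tab3$si_scaled
  expect_error(fit_robust(tab3), "rank deficient")
  expect_error(fit_robust(tab[1:3, ]), "at least 4")
})

test_that("interval families collapse to the estimate on zero-residual data", {
  tab <- exact_table(n = 20, seed = 17)
  cis <- bootstrap_cis(tab, n_boot = 199, seed = 18)
  iv <- cis$intervals
  expect_equal(nrow(iv), 9)
  expect_true(all(abs(iv$ci_high - iv$ci_low) < 1e-10))
  expect_true(all(abs(iv$ci_low - iv$estimate) < 1e-10))
})

test_that("percentile endpoints are order statistics of the replicate set", {
  set.seed(19)
  tab <- exact_table(n = 51, seed = 19)
  tab$y <- pmin(pmax(tab$y + rnorm(51, 0, 0.15), 0), log(2))
  cis <- bootstrap_cis(tab, n_boot = 399, seed = 20)
  B <- nrow(cis$replicates)
  k <- floor((B + 1) * 0.025)
  for (j in seq_len(ncol(cis$replicates))) {
    t_sorted <- sort(cis$replicates[, j])
    iv <- cis$intervals
    row <- iv[iv$coefficient == colnames(cis$replicates)[j] &
                iv$family == "percentile", ]
    expect_identical(row$ci_low, t_sorted[k])
    expect_identical(row$ci_high, t_sorted[B + 1 - k])
  }
})

test_that("BCa reduces to the percentile interval when z0 = 0 and a = 0", {
  # symmetric replicate set around the estimate => z0 = 0; symmetric
  # jackknife values => acceleration 0
  t0 <- 0.5
  reps <- t0 + c(-seq(0.001, 0.3, length.out = 500), seq(0.001, 0.3, length.out = 500))
  jack <- t0 + seq(-0.1, 0.1, length.out = 20)
  bca <- synchrec:::bca_interval(reps, t0, jack, 0.95)
  pct <- synchrec:::percentile_interval(reps, 0.95)
  expect_identical(bca, pct)
})

test_that("BCa and percentile agree closely under symmetric noise", {
  set.seed(21)
  tab <- exact_table(n = 51, seed = 21)
  tab$y <- tab$y + rnorm(51, 0, 0.1)
  cis <- bootstrap_cis(tab, n_boot = 2999, seed = 22)
  iv <- cis$intervals
  for (coefficient in unique(iv$coefficient)) {
    p <- iv[iv$coefficient == coefficient & iv$family == "percentile", ]
    b <- iv[iv$coefficient == coefficient & iv$family == "bca", ]
    expect_lt(abs(p$ci_low - b$ci_low), 0.02)
    expect_lt(abs(p$ci_high - b$ci_high), 0.02)
  }
})

test_that("bootstrap replicate sets are seed-reproducible", {
  set.seed(23)
  tab <- exact_table(n = 30, seed = 23)
  tab$y <- tab$y + rnorm(30, 0, 0.1)
  c1 <- bootstrap_cis(tab, n_boot = 99, seed = 7)
  runif(5)
  c2 <- bootstrap_cis(tab, n_boot = 99, seed = 7)
  expect_identical(c1$replicates, c2$replicates)
  expect_identical(c1$intervals, c2$intervals)
  expect_equal(formals(bootstrap_cis)$n_boot, 2999L)
})

test_that("Pearson screen matches the closed-form covariance ratio", {
  s <- pearson_screen(1:10, 2 * (1:10))
  expect_equal(s$rho, 1)
  expect_lt(s$p_value, 1e-12)

  x <- c(1, 2, 3); y <- c(1, 3, 2)
  expected <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_screen(x, y)$rho, expected, tolerance = 1e-12)

  expect_error(pearson_screen(1:5, rep(3, 5)), "degenerate")
})

test_that("residual diagnostics flag degeneracy and heteroscedasticity", {
  tab <- exact_table(n = 20, seed = 24)
  d0 <- residual_diagnostics(fit_robust(tab))
  expect_true(d0$degenerate)
  expect_match(d0$message, "zero residual variance")

  # variance growing with the fitted values must be flagged
  set.seed(25)
  n <- 150
  si <- runif(n); sst <- runif(n)
  mu <- 0.1 + 0.5 * si
  tab2 <- tibble::tibble(area_id = rep(c("A", "B", "C"), length.out = n),
                         recruit_year = 2000 + seq_len(n),
                         y = mu + rnorm(n, 0, 0.25 * mu),
                         si_scaled = si, sst_scaled = sst)
  d2 <- residual_diagnostics(fit_robust(tab2))
  expect_false(d2$degenerate)
  expect_gt(d2$homoscedasticity$correlation, 0)
  expect_true(d2$homoscedasticity$flagged)
  expect_true(all(c("area_id", "fitted", "residual", "weight") %in%
                    names(d2$residual_table)))
  expect_equal(nrow(d2$autocorrelation), 3)
})

test_that("normality check keeps its nominal type-I error on Gaussian residuals", {
  set.seed(26)
  n <- 200
  rejections <- vapply(1:500, function(i) {
    si <- runif(n); sst <- runif(n)
    tab <- tibble::tibble(area_id = "A", recruit_year = 2000 + seq_len(n),
                          y = 0.2 + 0.2 * si - 0.1 * sst + rnorm(n),
                          si_scaled = si, sst_scaled = sst)
    residual_diagnostics(fit_robust(tab))$normality$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.09)
})
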