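# Independent, deliberately naive transcription of the percentage bend
# recipe: scalar loops and explicit sorting only. This is the oracle the
# package implementation is checked against; keep it free of any shared code.

naive_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

naive_pb_omega <- function(x, beta) {
  med <- naive_median(x)
  w <- numeric(length(x))
  for (i in seq_along(x)) w[i] <- abs(x[i] - med)
  w <- sort(w)
  m <- floor((1 - beta) * length(x) + 0.5)
  w[m]
}

naive_pb_location <- function(x, beta) {
  med <- naive_median(x)
  omega <- naive_pb_omega(x, beta)
  i1 <- 0; i2 <- 0; acc <- 0
  for (i in seq_along(x)) {
    psi <- (x[i] - med) / omega
    if (psi < -1) i1 <- i1 + 1
    else if (psi > 1) i2 <- i2 + 1
    else acc <- acc + x[i]
  }
  (acc + omega * (i2 - i1)) / (length(x) - i1 - i2)
}

naive_pb_scores <- function(x, beta) {
  omega <- naive_pb_omega(x, beta)
  loc <- naive_pb_location(x, beta)
  a <- numeric(length(x))
  for (i in seq_along(x)) {
    u <- (x[i] - loc) / omega
    if (u > 1) u <- 1
    if (u < -1) u <- -1
    a[i] <- u
  }
  a
}

naive_pb_correlation <- function(x, y, beta) {
  a <- naive_pb_scores(x, beta)
  b <- naive_pb_scores(y, beta)
  sab <- 0; saa <- 0; sbb <- 0
  for (i in seq_along(a)) {
    sab <- sab + a[i] * b[i]
    saa <- saa + a[i] * a[i]
    sbb <- sbb + b[i] * b[i]
  }
  sab / sqrt(saa * sbb)
}

# Random dataset with a controllable fraction of gross outliers, for the
# oracle-equivalence sweeps.
random_outlier_pair <- function(n, outlier_frac = 0.1) {
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  k <- max(0L, floor(outlier_frac * n))
  if (k > 0) {
    i <- sample.int(n, k)
    y[i] <- y[i] + sample(c(-1, 1), k, replace = TRUE) * runif(k, 5, 50)
  }
  list(x = x, y = y)
}

# Build a tiny env_series covering given months with given values.
toy_series <- function(area_id, variable, start_year, start_month, values) {
  idx <- seq(12L * start_year + start_month - 1L, length.out = length(values))
  env_series(area_id, variable, idx %/% 12L, idx %% 12L + 1L, values)
}

# Noiseless regression table with known coefficients, for fit contracts.
exact_table <- function(n = 40, b = c(0.21, 0.21, -0.07), seed = 99) {
  set.seed(seed)
  si <- runif(n); sst <- runif(n)
  tibble::tibble(area_id = rep(c("A", "B"), length.out = n),
                 recruit_year = 2000 + seq_len(n),
                 y = b[1] + b[2] * si + b[3] * sst,
                 si_scaled = si, sst_scaled = sst)
}

# Noise-free single-area scenario whose CHL/MLD synchrony is set purely by
# the phase lag, for the SI phase-response checks.
noise_free <- function(phase_lag, n_years = 3L, area_id = "NF") {
  area_scenario(area_id, n_years = n_years, start_year = 2010L,
                mld_mean = 40, mld_amplitude = 25,
                chl_mean = 0.5, chl_amplitude = 0.4,
                phase_lag = phase_lag,
                env_noise_sd = c(mld = 0, chl = 0, sst = 0),
                abundance_min = 1e5, abundance_max = 1e6)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
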