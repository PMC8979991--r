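#' Scenario for one simulated area
#'
#' Monthly MLD, CHL and SST are a single annual cosine harmonic plus
#' independent Gaussian noise. CHL shares MLD's seasonal cycle shifted by
#' `phase_lag` months: lag 0 is perfect synchrony, lag 6 anti-phase, so the
#' lag is the dial that sets the true strength of the CHL-MLD synchronicity
#' the index is built to detect.
#'
#' @param area_id Area identifier.
#' @param n_years Number of recruitment years.
#' @param start_year First recruitment year (environment is generated from
#'   the preceding year so every observation window is covered).
#' @param mld_mean,mld_amplitude Mixed layer depth cycle (m).
#' @param chl_mean,chl_amplitude Chlorophyll-a cycle (mg/m3).
#' @param seasonal_phase Month offset of the shared cycle peak.
#' @param phase_lag Months by which the CHL cycle lags MLD's.
#' @param env_noise_sd Named vector of noise standard deviations for
#'   `mld`, `chl`, `sst`.
#' @param sst_mean,sst_amplitude,sst_trend SST cycle (degC) and linear warming
#'   trend (degC/year).
#' @param abundance_min,abundance_max Bounds of Age-1 abundance (thousands of
#'   individuals) used to invert the recruitment model.
#' @param spawning_start_month,survey_month Survey calendar (see [area_spec]).
#' @return A list of class `area_scenario`.
#' @export
area_scenario <- function(area_id, n_years, start_year = 2002L,
                          mld_mean, mld_amplitude, chl_mean, chl_amplitude,
                          seasonal_phase = 1, phase_lag = 0,
                          env_noise_sd = c(mld = 2, chl = 0.04, sst = 0.4),
                          sst_mean = 19, sst_amplitude = 4.5, sst_trend = 0.02,
                          abundance_min, abundance_max,
                          spawning_start_month = 4L, survey_month = 7L) {
  stopifnot(mld_amplitude >= 0, chl_amplitude >= 0, sst_amplitude >= 0)
  if (mld_mean - mld_amplitude <= 0) stop("MLD cycle dips below zero", call. = FALSE)
  if (chl_mean - chl_amplitude <= 0) stop("CHL cycle dips below zero", call. = FALSE)
  if (abundance_min >= abundance_max) stop("abundance_min must be < abundance_max",
                                           call. = FALSE)
  structure(list(area_id = area_id, n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 mld_mean = mld_mean, mld_amplitude = mld_amplitude,
                 chl_mean = chl_mean, chl_amplitude = chl_amplitude,
                 seasonal_phase = seasonal_phase, phase_lag = phase_lag,
                 env_noise_sd = env_noise_sd,
                 sst_mean = sst_mean, sst_amplitude = sst_amplitude,
                 sst_trend = sst_trend,
                 abundance_min = abundance_min, abundance_max = abundance_max,
                 spawning_start_month = as.integer(spawning_start_month),
                 survey_month = as.integer(survey_month)),
            class = "area_scenario")
}

#' Default three-area study scenario
#'
#' Mimics the three Mediterranean ecosystems: MLD/CHL seasonal ranges per
#' area match the observed envelopes (e.g. SoS MLD ~12-50 m, CHL 0.05-0.49
#' mg/m3; AS CHL up to 1.28 mg/m3), series spans are 18/18/15 recruitment
#' years, and the per-area phase lags are set so the noise-free window
#' correlation reproduces the observed per-area SI levels (strong in SoS,
#' intermediate in GoL, weak in AS). True regression coefficients default to
#' (0.21, 0.21, -0.07) for (intercept, SI, SST).
#'
#' @param true_coefficients Numeric length-3 vector (intercept, SI slope,
#'   SST slope) of the generative recruitment model.
#' @param response_noise_sd Standard deviation of the noise added to the
#'   modeled response on the log(1 + scaled) scale.
#' @param seed Root seed of the study.
#' @return A list of class `study_scenario`.
#' @export
study_scenario <- function(true_coefficients = c(0.21, 0.21, -0.07),
                           response_noise_sd = 0.18, seed = 1L) {
  stopifnot(length(true_coefficients) == 3, response_noise_sd >= 0)
  areas <- list(
    SoS = area_scenario("SoS", n_years = 18L, start_year = 2002L,
                        mld_mean = 31, mld_amplitude = 19,
                        chl_mean = 0.27, chl_amplitude = 0.21,
                        phase_lag = 1.2, env_noise_sd = c(mld = 1.5, chl = 0.02, sst = 0.4),
                        sst_mean = 19.5, abundance_min = 6e4, abundance_max = 8e5,
                        survey_month = 7L),
    GoL = area_scenario("GoL", n_years = 18L, start_year = 2002L,
                        mld_mean = 44, mld_amplitude = 31,
                        chl_mean = 0.51, chl_amplitude = 0.41,
                        phase_lag = 1.75, env_noise_sd = c(mld = 3, chl = 0.04, sst = 0.4),
                        sst_mean = 17, abundance_min = 2e5, abundance_max = 5e6,
                        survey_month = 7L),
    AS  = area_scenario("AS", n_years = 15L, start_year = 2004L,
                        mld_mean = 42, mld_amplitude = 29,
                        chl_mean = 0.72, chl_amplitude = 0.55,
                        phase_lag = 2.35, env_noise_sd = c(mld = 3, chl = 0.06, sst = 0.4),
                        sst_mean = 17.5, abundance_min = 4e6, abundance_max = 4e7,
                        survey_month = 6L)
  )
  structure(list(areas = areas,
                 true_coefficients = as.numeric(true_coefficients),
                 response_noise_sd = response_noise_sd,
                 seed = as.integer(seed)),
            class = "study_scenario")
}

#' Simulate monthly CHL, MLD and SST series for one area
#'
#' For absolute month index `t`:
#' `MLD = mld_mean + mld_amplitude * cos(2*pi*(t - phase)/12) + eps`,
#' `CHL` the same cycle shifted by `phase_lag` months, and
#' `SST = sst_mean + sst_amplitude * cos(2*pi*(t - phase)/12) +
#' sst_trend * t/12 + eps`, each `eps` i.i.d. Gaussian with the scenario's
#' standard deviation. CHL and MLD are floored at 0.01 in their units.
#' Bit-identical for a fixed seed.
#'
#' @param scenario An [area_scenario].
#' @param seed Integer seed.
#' @return A list of [env_series]: `chl`, `mld`, `sst`.
#' @export
simulate_env <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "area_scenario"))
  y0 <- scenario$start_year - 1L
  y1 <- scenario$start_year + scenario$n_years - 1L
  idx <- seq(month_index(y0, 1L), month_index(y1, 12L))
  t_rel <- seq_along(idx) - 1L
  cyc <- function(lag) cos(2 * pi * (idx - scenario$seasonal_phase - lag) / 12)
  nsd <- scenario$env_noise_sd
  with_seed(seed, {
    mld <- scenario$mld_mean + scenario$mld_amplitude * cyc(0) +
      stats::rnorm(length(idx), 0, nsd[["mld"]])
    chl <- scenario$chl_mean + scenario$chl_amplitude * cyc(scenario$phase_lag) +
      stats::rnorm(length(idx), 0, nsd[["chl"]])
    sst <- scenario$sst_mean + scenario$sst_amplitude * cyc(0) +
      scenario$sst_trend * t_rel / 12 +
      stats::rnorm(length(idx), 0, nsd[["sst"]])
  })
  yr <- index_to_year(idx); mo <- index_to_month(idx)
  list(
    chl = env_series(scenario$area_id, "CHL", yr, mo, pmax(chl, 0.01)),
    mld = env_series(scenario$area_id, "MLD", yr, mo, pmax(mld, 0.01)),
    sst = env_series(scenario$area_id, "SST", yr, mo, sst)
  )
}

#' Simulate annual recruitment from the regression model
#'
#' The generative inverse of the analysis model: per area, SI and SST are
#' min-max scaled, the response `y = b0 + b_SI * si + b_SST * sst + eps` is
#' drawn and clipped to `[0, log 2]`, and abundance is reconstructed as
#' `abundance_min + (exp(y) - 1) * (abundance_max - abundance_min)`.
#'
#' @param study A [study_scenario].
#' @param si_values Tibble `area_id,recruit_year,rho_pb` computed from the
#'   simulated environment with the real SI pipeline.
#' @param sst_means Tibble `area_id,recruit_year,sst_mean`.
#' @param seed Integer seed for the response noise.
#' @return A named list of per-area recruitment tibbles
#'   (`area_id,year,abundance`), plus the latent responses as attribute
#'   `"latent_y"`.
#' @export
simulate_recruitment <- function(study, si_values, sst_means,
                                 seed = study$seed) {
  stopifnot(inherits(study, "study_scenario"))
  b <- study$true_coefficients
  out <- list()
  latent <- list()
  for (aid in names(study$areas)) {
    sc <- study$areas[[aid]]
    si <- si_values[si_values$area_id == aid, ]
    si <- si[order(si$recruit_year), ]
    ss <- sst_means[sst_means$area_id == aid, ]
    ss <- ss[order(ss$recruit_year), ]
    if (nrow(si) < 2L) stop("fewer than 2 years for area ", aid, call. = FALSE)
    if (!identical(si$recruit_year, ss$recruit_year)) {
      stop("SI and SST years misaligned for area ", aid, call. = FALSE)
    }
    si_s <- min_max_scale(si$rho_pb, "SI", aid)$values
    # a constant SST contributes nothing beyond the intercept; map it to 0
    # rather than failing, so degenerate covariates can be simulated
    sst_s <- if (max(ss$sst_mean) > min(ss$sst_mean))
      min_max_scale(ss$sst_mean, "SST", aid)$values else rep(0, nrow(ss))
    eps <- with_seed(derive_seed(seed, paste0("recruit-", aid), 0L),
                     stats::rnorm(nrow(si), 0, study$response_noise_sd))
    y <- b[1] + b[2] * si_s + b[3] * sst_s + eps
    y <- pmin(pmax(y, 0), log(2))
    ab <- sc$abundance_min + expm1(y) * (sc$abundance_max - sc$abundance_min)
    out[[aid]] <- tibble::tibble(area_id = aid, year = si$recruit_year,
                                 abundance = ab)
    latent[[aid]] <- tibble::tibble(area_id = aid, year = si$recruit_year, y = y)
  }
  attr(out, "latent_y") <- dplyr::bind_rows(latent)
  out
}

#' Generate a complete synthetic study
#'
#' Simulates the environment for every area, runs the real SI/SST window
#' computations on it, simulates recruitment from the regression model, and
#' (optionally) writes the pipeline-ingestible CSV files plus a
#' `truth.json` record of every generative parameter.
#'
#' @param study A [study_scenario].
#' @param dir Output directory; `NULL` keeps everything in memory.
#' @param params [pb_params] used for the SI point estimates fed into the
#'   recruitment model (no bootstrap is run here).
#' @return A list: `env` (per-area series), `areas` ([area_spec]s), `years`,
#'   `si_values`, `sst_means`, `recruitment`, `truth`, and file `paths` when
#'   `dir` was given.
#' @export
generate_study <- function(study, dir = NULL, params = pb_params(seed = study$seed)) {
  stopifnot(inherits(study, "study_scenario"))
  env <- list(); areas <- list(); years <- list()
  for (aid in names(study$areas)) {
    sc <- study$areas[[aid]]
    env[[aid]] <- simulate_env(sc, derive_seed(study$seed, paste0("env-", aid), 0L))
    areas[[aid]] <- area_spec(aid, aid, sc$spawning_start_month, sc$survey_month)
    years[[aid]] <- seq(sc$start_year, sc$start_year + sc$n_years - 1L)
  }
  si_values <- compute_si_table(env, areas, years, params, ci = FALSE)
  sst_means <- window_sst_table(env, areas, years)
  recruitment <- simulate_recruitment(study, si_values, sst_means)

  truth <- list(
    seed = study$seed,
    true_coefficients = study$true_coefficients,
    response_noise_sd = study$response_noise_sd,
    areas = lapply(study$areas, function(sc) sc[setdiff(names(sc), "env_noise_sd")]),
    env_noise_sd = lapply(study$areas, function(sc) as.list(sc$env_noise_sd))
  )
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(env = file.path(dir, "env.csv"),
                  recruitment = file.path(dir, "recruitment.csv"),
                  truth = file.path(dir, "truth.json"))
    env_long <- dplyr::bind_rows(lapply(env, dplyr::bind_rows))
    env_long <- tibble::tibble(
      area_id = env_long$area_id,
      date = format_ym(env_long$year, env_long$month),
      variable = env_long$variable, value = env_long$value,
      units = env_long$units)
    readr::write_csv(env_long, paths$env)
    rec_long <- dplyr::bind_rows(recruitment)
    readr::write_csv(tibble::tibble(area_id = rec_long$area_id,
                                    year = rec_long$year,
                                    abundance_thousands = rec_long$abundance),
                     paths$recruitment)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  list(env = env, areas = areas, years = years, si_values = si_values,
       sst_means = sst_means, recruitment = recruitment, truth = truth,
       paths = paths)
}

#' Window-mean SST for every area-year
#'
#' @param env Named list of per-area series lists (needs `sst`).
#' @param areas Named list of [area_spec]s.
#' @param years Named list of recruitment years per area.
#' @return A tibble `area_id,recruit_year,sst_mean`.
#' @export
window_sst_table <- function(env, areas, years) {
  rows <- list()
  for (aid in names(areas)) {
    for (yr in years[[aid]]) {
      w <- build_window(areas[[aid]], yr)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        area_id = aid, recruit_year = as.integer(yr),
        sst_mean = window_mean_sst(env[[aid]]$sst, w))
    }
  }
  dplyr::bind_rows(rows)
}
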