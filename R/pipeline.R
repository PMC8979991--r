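#' Pipeline configuration
#'
#' Collects everything a full run needs: input paths (or `simulate = TRUE`
#' to generate a synthetic study first), area calendars, percentage bend
#' parameters, regression settings, output directory and the root seed.
#'
#' @param env_path,recruitment_path Input CSVs (ignored when `simulate`).
#' @param simulate Generate the default synthetic study instead of reading
#'   files.
#' @param areas Named list of [area_spec]s.
#' @param beta,conf_level,n_boot Percentage bend / bootstrap settings
#'   (defaults 0.2 / 0.95 / 2999).
#' @param tuning_k,tol,max_iter,stratify_by_area Robust-fit settings.
#' @param out_dir Output directory.
#' @param seed Root seed recorded in every output.
#' @param verbose Narrate stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(env_path = NULL, recruitment_path = NULL,
                            simulate = is.null(env_path),
                            areas = default_areas(),
                            beta = 0.2, conf_level = 0.95, n_boot = 2999L,
                            tuning_k = 1.345, tol = 1e-8, max_iter = 50L,
                            stratify_by_area = FALSE,
                            out_dir = "synchrec-out", seed = 1L,
                            verbose = TRUE) {
  structure(list(env_path = env_path, recruitment_path = recruitment_path,
                 simulate = simulate, areas = areas, beta = beta,
                 conf_level = conf_level, n_boot = as.integer(n_boot),
                 tuning_k = tuning_k, tol = tol, max_iter = as.integer(max_iter),
                 stratify_by_area = stratify_by_area, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; an `areas`
#' mapping gives per-area `name`, `spawning_start_month`, `survey_month`.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$areas)) {
    raw$areas <- lapply(names(raw$areas), function(aid) {
      a <- raw$areas[[aid]]
      area_spec(aid, a$name %||% aid,
                a$spawning_start_month %||% 4L, a$survey_month)
    })
    names(raw$areas) <- vapply(raw$areas, `[[`, "", "area_id")
  }
  over <- list(...)
  raw[names(over)] <- over
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

say <- function(config, ...) if (isTRUE(config$verbose)) message("[synchrec] ", ...)

#' Run the Synchronicity Index stage
#'
#' Computes one SI estimate (with bootstrap CI) per area-year and writes
#' `si_table.csv`. Years are those present in the recruitment series whose
#' observation window is fully covered by the environmental series; an
#' uncovered window aborts with the offending area-years named.
#'
#' @param config A `pipeline_config`.
#' @param env Named list of per-area series lists (`chl`, `mld`, `sst`); by
#'   default loaded from `config$env_path`.
#' @param years Named list of recruitment years per area.
#' @return The SI tibble (invisibly written to `out_dir/si_table.csv`).
#' @export
run_si_stage <- function(config, env, years) {
  params <- pb_params(beta = config$beta, conf_level = config$conf_level,
                      n_boot = config$n_boot, seed = config$seed)
  say(config, "SI stage: ", sum(lengths(years)), " area-years, n_boot = ",
      params$n_boot)
  si <- compute_si_table(env, config$areas[names(years)], years, params, ci = TRUE)
  if (!is.null(config$out_dir)) {
    write_output_csv(si, file.path(config$out_dir, "si_table.csv"), config$seed)
  }
  si
}

#' Run the regression stage
#'
#' Builds the pooled standardized table, fits the Huber robust regression,
#' runs the random-X bootstrap for the three interval families, the
#' SI-vs-SST Pearson screen per area, and the residual diagnostics. Writes
#' `fit_table.csv` and `diagnostics.csv`.
#'
#' @param config A `pipeline_config`.
#' @param si_table SI tibble from [run_si_stage()].
#' @param recruitment Per-area recruitment list.
#' @param sst_means Tibble `area_id,recruit_year,sst_mean`.
#' @return A list: `table`, `fit`, `cis`, `screen`, `diagnostics`.
#' @export
run_fit_stage <- function(config, si_table, recruitment, sst_means) {
  table <- build_regression_table(recruitment, si_table, sst_means)
  say(config, "fit stage: ", nrow(table), " pooled rows")
  fit <- fit_robust(table, config$tuning_k, config$tol, config$max_iter)
  cis <- bootstrap_cis(table, n_boot = config$n_boot,
                       conf_level = config$conf_level, seed = config$seed,
                       tuning_k = config$tuning_k, tol = config$tol,
                       max_iter = config$max_iter,
                       stratify_by_area = config$stratify_by_area)
  screen <- lapply(split(si_table, si_table$area_id), function(d) {
    ss <- sst_means[match(paste(d$area_id, d$recruit_year),
                          paste(sst_means$area_id, sst_means$recruit_year)), ]
    s <- pearson_screen(d$rho_pb, ss$sst_mean)
    tibble::tibble(area_id = d$area_id[1], rho = s$rho, p_value = s$p_value)
  })
  screen <- dplyr::bind_rows(screen)
  diag <- residual_diagnostics(fit, table)
  if (!is.null(config$out_dir)) {
    write_output_csv(cis$intervals, file.path(config$out_dir, "fit_table.csv"),
                     config$seed)
    if (!diag$degenerate) {
      write_output_csv(diag$residual_table,
                       file.path(config$out_dir, "diagnostics.csv"), config$seed)
    }
  }
  list(table = table, fit = fit, cis = cis, screen = screen,
       diagnostics = diag)
}

#' Run the full pipeline
#'
#' Optional simulation, then SI stage, fit stage, and a plain-text run
#' manifest (`manifest.txt`) recording the seed, settings and any warnings.
#' Every emitted number is fully determined by (inputs, config, seed).
#'
#' @param config A `pipeline_config`.
#' @return A list with `si_table`, `fit` (the stage result list), `study`
#'   (when simulated), and the output `paths`.
#' @export
run_full <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings_log <- character()
  if (config$simulate) {
    say(config, "simulating default synthetic study (seed ", config$seed, ")")
    study <- study_scenario(seed = config$seed)
    gen <- generate_study(study, dir = NULL,
                          params = pb_params(beta = config$beta, seed = config$seed))
    env <- gen$env; years <- gen$years
    recruitment <- gen$recruitment
    config$areas <- gen$areas
  } else {
    study <- NULL
    recruitment <- load_recruitment(config$recruitment_path)
    env <- list(); years <- list()
    for (aid in names(config$areas)) {
      if (!aid %in% names(recruitment)) {
        stop("recruitment input has no rows for area ", aid, call. = FALSE)
      }
      env[[aid]] <- list(
        chl = load_env_series(config$env_path, aid, "CHL"),
        mld = load_env_series(config$env_path, aid, "MLD"),
        sst = load_env_series(config$env_path, aid, "SST"))
      years[[aid]] <- recruitment[[aid]]$year
    }
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  si_table <- withCallingHandlers(
    run_si_stage(config, env, years),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  sst_means <- window_sst_table(env, config$areas, years)
  fit <- run_fit_stage(config, si_table, recruitment, sst_means)

  paths <- NULL
  if (!is.null(config$out_dir)) {
    paths <- list(si_table = file.path(config$out_dir, "si_table.csv"),
                  fit_table = file.path(config$out_dir, "fit_table.csv"),
                  diagnostics = file.path(config$out_dir, "diagnostics.csv"),
                  manifest = file.path(config$out_dir, "manifest.txt"))
    write_manifest(config, warnings_log, paths$manifest)
  }
  list(si_table = si_table, fit = fit, study = study, sst_means = sst_means,
       paths = paths)
}

write_output_csv <- function(df, path, seed) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("# synchrec output; seed=%d", seed), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

write_manifest <- function(config, warnings_log, path) {
  fields <- c(
    sprintf("package: synchrec %s",
            as.character(utils::packageVersion("synchrec"))),
    sprintf("seed: %d", config$seed),
    sprintf("n_boot: %d", config$n_boot),
    sprintf("beta: %g", config$beta),
    sprintf("conf_level: %g", config$conf_level),
    sprintf("tuning_k: %g", config$tuning_k),
    sprintf("simulate: %s", config$simulate),
    sprintf("areas: %s", paste(names(config$areas), collapse = ", ")),
    if (length(warnings_log)) paste("warning:", warnings_log) else "warnings: none"
  )
  writeLines(fields, path)
  invisible(path)
}

#' Parameter-recovery experiment
#'
#' Repeats the full generate-and-refit cycle: each replicate simulates a
#' study (3 areas, 18/18/15 years by default), pushes it through the real SI
#' and regression stages, and records the coefficient estimates, whether the
#' BCa interval covers the generative truth, and whether each interval
#' family excludes zero.
#'
#' @param n_studies Number of seeded replicates.
#' @param true_coefficients Generative coefficients.
#' @param response_noise_sd Response noise (see [study_scenario()]).
#' @param n_boot Bootstrap resamples per replicate.
#' @param seed Root seed; replicate seeds are derived from it.
#' @return A tibble with one row per replicate: estimates, BCa bounds and
#'   coverage flags for the SI and SST slopes.
#' @export
recovery_experiment <- function(n_studies = 200L,
                                true_coefficients = c(0.21, 0.21, -0.07),
                                response_noise_sd = 0.18,
                                n_boot = 999L, seed = 1L) {
  rows <- vector("list", n_studies)
  for (k in seq_len(n_studies)) {
    study <- study_scenario(true_coefficients = true_coefficients,
                            response_noise_sd = response_noise_sd,
                            seed = derive_seed(seed, "recovery", k))
    gen <- generate_study(study, dir = NULL, params = pb_params(seed = study$seed))
    table <- build_regression_table(gen$recruitment, gen$si_values, gen$sst_means)
    cis <- bootstrap_cis(table, n_boot = n_boot, seed = study$seed)
    iv <- cis$intervals
    pick <- function(coefficient, family) {
      iv[iv$coefficient == coefficient & iv$family == family, ]
    }
    si_bca <- pick("si_scaled", "bca")
    sst_bca <- pick("sst_scaled", "bca")
    rows[[k]] <- tibble::tibble(
      replicate = k, seed = study$seed,
      beta_si_hat = si_bca$estimate, beta_sst_hat = sst_bca$estimate,
      si_bca_low = si_bca$ci_low, si_bca_high = si_bca$ci_high,
      si_bca_covers = si_bca$ci_low <= true_coefficients[2] &
        true_coefficients[2] <= si_bca$ci_high,
      sst_bca_low = sst_bca$ci_low, sst_bca_high = sst_bca$ci_high,
      sst_straddles_zero = sst_bca$ci_low <= 0 & sst_bca$ci_high >= 0)
  }
  dplyr::bind_rows(rows)
}
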