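#' @importFrom stats median sd quantile pnorm qnorm pt coef lm mad cor
#' @importFrom utils head tail
NULL

# Months are handled on a single integer axis: idx = 12*year + (month-1).
# All window arithmetic reduces to closed integer intervals on this axis.
month_index <- function(year, month) 12L * as.integer(year) + (as.integer(month) - 1L)

index_to_year <- function(idx) idx %/% 12L
index_to_month <- function(idx) idx %% 12L + 1L

format_ym <- function(year, month) sprintf("%04d-%02d", year, month)

env_units <- c(CHL = "mg/m3", MLD = "m", SST = "degC")

#' Construct a monthly environmental series
#'
#' An `env_series` is a tibble holding one environmental variable (CHL, MLD
#' or SST) for one area at monthly resolution: columns `area_id`, `variable`,
#' `year`, `month`, `value`, `units`. Months must be consecutive (no gaps),
#' values finite, and CHL/MLD strictly positive.
#'
#' @param area_id Area identifier (e.g. `"SoS"`).
#' @param variable One of `"CHL"`, `"MLD"`, `"SST"`.
#' @param year,month Integer vectors of calendar year and month (1-12).
#' @param value Numeric values (mg/m3 for CHL, m for MLD, degC for SST).
#' @param units Unit string; defaults to the canonical unit for `variable`.
#' @return A tibble of class `env_series`, sorted by month.
#' @export
env_series <- function(area_id, variable, year, month, value,
                       units = env_units[[variable]]) {
  variable <- match.arg(variable, c("CHL", "MLD", "SST"))
  if (!identical(units, env_units[[variable]])) {
    stop("unknown units '", units, "' for ", variable,
         " (expected '", env_units[[variable]], "')", call. = FALSE)
  }
  out <- tibble::tibble(
    area_id = as.character(area_id),
    variable = variable,
    year = as.integer(year),
    month = as.integer(month),
    value = as.numeric(value),
    units = units
  )
  out <- out[order(month_index(out$year, out$month)), , drop = FALSE]
  validate_env_series(out)
  class(out) <- c("env_series", class(tibble::tibble()))
  out
}

validate_env_series <- function(x) {
  if (any(x$month < 1L | x$month > 12L)) {
    stop("month must be in 1..12", call. = FALSE)
  }
  idx <- month_index(x$year, x$month)
  if (anyDuplicated(idx)) {
    dup <- idx[duplicated(idx)]
    stop("duplicate months: ",
         paste(format_ym(index_to_year(dup), index_to_month(dup)), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) > 1L) {
    gaps <- setdiff(seq(min(idx), max(idx)), idx)
    if (length(gaps)) {
      stop("gap in monthly series, missing: ",
           paste(format_ym(index_to_year(gaps), index_to_month(gaps)), collapse = ", "),
           call. = FALSE)
    }
  }
  if (any(!is.finite(x$value))) {
    stop("non-finite values at rows ", paste(which(!is.finite(x$value)), collapse = ", "),
         call. = FALSE)
  }
  v <- x$variable[1]
  if (v %in% c("CHL", "MLD") && any(x$value <= 0)) {
    stop(v, " values must be strictly positive", call. = FALSE)
  }
  invisible(x)
}

#' Load a monthly environmental series from CSV
#'
#' Accepts either a per-variable file with columns `area_id,date,value`
#' (optionally `units`) or a combined long-format file with columns
#' `area_id,date,variable,value,units`, where `date` is an ISO `"YYYY-MM"`
#' month stamp. Rows may be in any order; the returned series is sorted.
#' Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @param area_id Area to extract.
#' @param variable Variable to extract (`"CHL"`, `"MLD"` or `"SST"`);
#'   required when the file is per-variable (has no `variable` column).
#' @return An [env_series].
#' @export
load_env_series <- function(path, area_id, variable = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("area_id", "date", "value")
  if (!all(need %in% names(raw))) {
    stop("missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "),
         call. = FALSE)
  }
  if ("variable" %in% names(raw)) {
    if (is.null(variable)) stop("'variable' must be given for long-format files",
                                call. = FALSE)
    raw <- raw[raw$variable == variable, , drop = FALSE]
  } else if (is.null(variable)) {
    stop("'variable' must be given for per-variable files", call. = FALSE)
  }
  raw <- raw[raw$area_id == area_id, , drop = FALSE]
  if (!nrow(raw)) stop("no rows for area '", area_id, "' / variable '",
                       variable, "' in ", path, call. = FALSE)
  ym <- parse_ym(raw$date)
  val <- suppressWarnings(as.numeric(raw$value))
  if (any(is.na(val))) {
    stop("non-numeric value at row(s) ", paste(which(is.na(val)), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  units <- if ("units" %in% names(raw)) unique(raw$units) else env_units[[variable]]
  if (length(units) != 1L) stop("inconsistent units in ", path, call. = FALSE)
  env_series(area_id, variable, ym$year, ym$month, val, units = units)
}

parse_ym <- function(x) {
  ok <- grepl("^[0-9]{4}-[0-9]{2}$", x)
  if (any(!ok)) {
    stop("malformed month stamp(s): ", paste(unique(x[!ok]), collapse = ", "),
         " (expected YYYY-MM)", call. = FALSE)
  }
  list(year = as.integer(substr(x, 1, 4)), month = as.integer(substr(x, 6, 7)))
}

#' Load annual recruitment series from CSV
#'
#' Reads a table with columns `area_id,year,abundance_thousands` (Age-1
#' abundance in thousands of individuals) and returns one tibble per area.
#'
#' @param path Path to the CSV file.
#' @return A named list of tibbles (`area_id,year,abundance`), one per area,
#'   each sorted by year. An empty file yields an empty list with a warning.
#' @export
load_recruitment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = "cid")
  need <- c("area_id", "year", "abundance_thousands")
  if (!all(need %in% names(raw))) {
    stop("missing columns: ", paste(setdiff(need, names(raw)), collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(raw)) {
    warning("empty recruitment file: ", path, call. = FALSE)
    return(list())
  }
  if (any(raw$abundance_thousands < 0)) {
    stop("negative abundance at row(s) ",
         paste(which(raw$abundance_thousands < 0), collapse = ", "), call. = FALSE)
  }
  key <- paste(raw$area_id, raw$year)
  if (anyDuplicated(key)) {
    stop("duplicate (area, year): ", paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  }
  out <- split(tibble::tibble(area_id = raw$area_id, year = raw$year,
                              abundance = raw$abundance_thousands),
               raw$area_id)
  lapply(out, function(d) d[order(d$year), , drop = FALSE])
}

#' Define an area's survey calendar
#'
#' @param area_id Short identifier.
#' @param name Display name.
#' @param spawning_start_month Month anchovy begin spawning (default April).
#' @param survey_month Month of the acoustic survey (MEDIAS/PELMED).
#' @return A list of class `area_spec`.
#' @export
area_spec <- function(area_id, name = area_id, spawning_start_month = 4L,
                      survey_month) {
  stopifnot(spawning_start_month %in% 1:12, survey_month %in% 1:12)
  structure(list(area_id = as.character(area_id), name = name,
                 spawning_start_month = as.integer(spawning_start_month),
                 survey_month = as.integer(survey_month)),
            class = "area_spec")
}

#' The three default Mediterranean areas
#'
#' Strait of Sicily (SoS) and Gulf of Lions (GoL) are surveyed in July,
#' the Adriatic Sea (AS) in June; spawning starts in April everywhere.
#'
#' @return A named list of [area_spec] objects.
#' @export
default_areas <- function() {
  list(
    SoS = area_spec("SoS", "Strait of Sicily", 4L, 7L),
    GoL = area_spec("GoL", "Gulf of Lions", 4L, 7L),
    AS  = area_spec("AS", "Adriatic Sea", 4L, 6L)
  )
}

#' Build the observation window for one recruitment year
#'
#' The window runs from the spawning onset month of the year before the
#' recruitment year to the month preceding the survey in the recruitment
#' year, inclusive. With the default April start, SoS/GoL (July survey)
#' windows span 15 months and AS (June survey) 14.
#'
#' @param area An [area_spec].
#' @param recruit_year Calendar year the Age-1 abundance refers to.
#' @return A tibble (`year`, `month`) of class `obs_window`, with
#'   attributes `area_id` and `recruit_year`.
#' @export
build_window <- function(area, recruit_year) {
  stopifnot(inherits(area, "area_spec"))
  recruit_year <- as.integer(recruit_year)
  if (area$survey_month < area$spawning_start_month) {
    warning("window for ", area$area_id, " is shorter than 12 months ",
            "(survey precedes spawning onset in the calendar)", call. = FALSE)
  }
  from <- month_index(recruit_year - 1L, area$spawning_start_month)
  to <- month_index(recruit_year, area$survey_month) - 1L
  idx <- seq(from, to)
  out <- tibble::tibble(year = index_to_year(idx), month = index_to_month(idx))
  attr(out, "area_id") <- area$area_id
  attr(out, "recruit_year") <- recruit_year
  class(out) <- c("obs_window", class(out))
  out
}

# Pull the window months out of a series; errors name any missing stamp.
window_values <- function(series, window) {
  sidx <- month_index(series$year, series$month)
  widx <- month_index(window$year, window$month)
  pos <- match(widx, sidx)
  if (anyNA(pos)) {
    miss <- widx[is.na(pos)]
    stop(series$variable[1], " series for ", series$area_id[1],
         " does not cover window months: ",
         paste(format_ym(index_to_year(miss), index_to_month(miss)), collapse = ", "),
         call. = FALSE)
  }
  series$value[pos]
}

#' Extract the paired CHL/MLD vectors for a window
#'
#' @param chl,mld [env_series] objects for the same area.
#' @param window An `obs_window` from [build_window()].
#' @return A list with numeric vectors `chl` and `mld`, aligned month by
#'   month in window order.
#' @export
extract_paired_window <- function(chl, mld, window) {
  if (!identical(chl$area_id[1], mld$area_id[1])) {
    stop("area mismatch: ", chl$area_id[1], " vs ", mld$area_id[1], call. = FALSE)
  }
  wa <- attr(window, "area_id")
  if (!is.null(wa) && !identical(wa, chl$area_id[1])) {
    stop("window belongs to area ", wa, ", series to ", chl$area_id[1], call. = FALSE)
  }
  list(chl = window_values(chl, window), mld = window_values(mld, window))
}

#' Mean SST over an observation window
#'
#' @param sst An SST [env_series].
#' @param window An `obs_window`.
#' @return The arithmetic mean of the window's monthly SST values (degC).
#' @export
window_mean_sst <- function(sst, window) {
  mean(window_values(sst, window))
}
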