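#' Engine configuration
#'
#' Collects every numeric rule of the coaching engine in one place. The
#' defaults are the intervention's published operating parameters: a 300 m
#' geofence polled every 2 minutes, hourly step-count synchronisation, at
#' most 3 geolocation prompts per day and never two within 4 hours, all
#' between 08:00 and 20:00; one step-feedback message at a random minute in
#' 11:30-12:30; one preference-tailored (BCT) message in each of 08:00-09:00
#' and 16:00-18:00; a 4-message weighted subset on the BCT channel; step
#' strata split at 2000/2001 and 6000/6001; survey responses -1/0/+1 scored
#' 1/5/10; and a daily goal of 7000-8000 steps.
#'
#' All times are minutes since local midnight and all windows are half-open
#' `[start, end)`.
#'
#' @param radius_m Geofence radius in meters.
#' @param geo_poll_interval_min Minutes between geofence evaluations.
#' @param step_sync_interval_min Minutes between step-count syncs.
#' @param geo_window Two minutes-of-day, the geolocation delivery window.
#' @param geo_daily_cap Maximum geolocation messages per user per day.
#' @param geo_min_gap_min Minimum minutes between geolocation deliveries.
#' @param morning_window,midday_window,evening_window Two minutes-of-day
#'   each: the scheduled windows for the morning BCT, midday step-feedback
#'   and evening BCT messages.
#' @param bct_subset_k Size of the preference-weighted subset from which the
#'   BCT message is drawn uniformly.
#' @param strata_bounds Upper bounds (inclusive) of the LOW and MID step
#'   strata.
#' @param score_map Named integer vector mapping survey responses
#'   `-1`, `0`, `+1` to preference scores.
#' @param step_goal Length-2 integer vector, the guideline daily step goal
#'   range; only the minimum is evaluated, the maximum is metadata.
#'
#' @return A list of class `engine_config`.
#' @export
#' @examples
#' cfg <- engine_config()
#' cfg$radius_m
engine_config <- function(radius_m = 300,
                          geo_poll_interval_min = 2L,
                          step_sync_interval_min = 60L,
                          geo_window = c(8L * 60L, 20L * 60L),
                          geo_daily_cap = 3L,
                          geo_min_gap_min = 240L,
                          morning_window = c(8L * 60L, 9L * 60L),
                          midday_window = c(11L * 60L + 30L, 12L * 60L + 30L),
                          evening_window = c(16L * 60L, 18L * 60L),
                          bct_subset_k = 4L,
                          strata_bounds = c(2000L, 6000L),
                          score_map = c(`-1` = 1L, `0` = 5L, `1` = 10L),
                          step_goal = c(7000L, 8000L)) {
  cfg <- list(
    radius_m = as.numeric(radius_m),
    geo_poll_interval_min = as.integer(geo_poll_interval_min),
    step_sync_interval_min = as.integer(step_sync_interval_min),
    geo_window = as.integer(geo_window),
    geo_daily_cap = as.integer(geo_daily_cap),
    geo_min_gap_min = as.integer(geo_min_gap_min),
    morning_window = as.integer(morning_window),
    midday_window = as.integer(midday_window),
    evening_window = as.integer(evening_window),
    bct_subset_k = as.integer(bct_subset_k),
    strata_bounds = as.integer(strata_bounds),
    score_map = stats::setNames(as.integer(score_map), names(score_map)),
    step_goal = as.integer(step_goal)
  )
  validate_engine_config(cfg)
  structure(cfg, class = "engine_config")
}

validate_engine_config <- function(cfg) {
  stopifnot(
    cfg$radius_m > 0,
    cfg$geo_poll_interval_min >= 1L,
    cfg$step_sync_interval_min >= 1L,
    cfg$geo_daily_cap >= 1L,
    cfg$geo_min_gap_min > 0L,
    cfg$bct_subset_k >= 1L,
    length(cfg$strata_bounds) == 2L,
    cfg$strata_bounds[1] < cfg$strata_bounds[2],
    length(cfg$step_goal) == 2L,
    cfg$step_goal[1] <= cfg$step_goal[2]
  )
  for (w in list(cfg$geo_window, cfg$morning_window, cfg$midday_window,
                 cfg$evening_window)) {
    if (length(w) != 2L || w[1] >= w[2] || w[1] < 0L || w[2] > 1440L) {
      abort("engine_config: each window must be two minutes-of-day with start < end")
    }
  }
  if (!identical(sort(names(cfg$score_map)), sort(c("-1", "0", "1")))) {
    abort("engine_config: score_map must be named '-1', '0', '1'")
  }
  invisible(cfg)
}

#' @export
print.engine_config <- function(x, ...) {
  fmt <- function(w) sprintf("[%02d:%02d, %02d:%02d)",
                             w[1] %/% 60, w[1] %% 60, w[2] %/% 60, w[2] %% 60)
  cat("<engine_config>\n")
  cat("  geofence: radius", x$radius_m, "m, poll every",
      x$geo_poll_interval_min, "min, window", fmt(x$geo_window), "\n")
  cat("  geo limits: cap", x$geo_daily_cap, "/day, min gap",
      x$geo_min_gap_min, "min\n")
  cat("  scheduled: morning", fmt(x$morning_window), "midday",
      fmt(x$midday_window), "evening", fmt(x$evening_window), "\n")
  cat("  BCT subset k =", x$bct_subset_k,
      "; strata bounds", paste(x$strata_bounds, collapse = "/"),
      "; goal", paste(x$step_goal, collapse = "-"), "steps\n")
  invisible(x)
}

#' Read or write an engine configuration file
#'
#' Configurations round-trip through YAML (or JSON, by file extension).
#' Fields absent from the file keep their defaults.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg An [engine_config()] object.
#' @return `read_engine_config()` returns an `engine_config`;
#'   `write_engine_config()` returns `path` invisibly.
#' @export
read_engine_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$score_map)) {
    raw$score_map <- unlist(raw$score_map)
  }
  known <- names(formals(engine_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(engine_config, raw)
}

#' @rdname read_engine_config
#' @export
write_engine_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "engine_config"))
  x <- unclass(cfg)
  x$score_map <- as.list(x$score_map)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
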