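#' Score BCT preference survey responses
#'
#' At baseline, users rate each of ten types of coaching message (one per
#' preference-tailored BCT) on a three-point scale: -1 = negative,
#' 0 = neutral, +1 = positive. Scoring maps these responses elementwise to
#' the sampling weights used by the BCT message channel: -1 -> 1, 0 -> 5,
#' +1 -> 10.
#'
#' @param responses A data frame with one row per user and one `bct_<tag>`
#'   column per tag in [bct_preference_tags()], each value in
#'   \{-1, 0, +1\}. Extra columns (e.g. `user_id`, `first_name`) pass
#'   through unchanged.
#' @param score_map Named vector mapping `-1`, `0`, `1` to scores; the
#'   default is the engine's 1/5/10.
#' @return A tibble of the same shape with the `bct_` columns replaced by
#'   integer scores in \{1, 5, 10\}.
#' @export
#' @examples
#' resp <- tibble::tibble(user_id = "u1", first_name = "Anna",
#'   !!!stats::setNames(as.list(c(-1, 0, 1, 0, 0, 1, -1, 1, 0, 0)),
#'                      paste0("bct_", bct_preference_tags())))
#' score_preferences(resp)
score_preferences <- function(responses,
                              score_map = c(`-1` = 1L, `0` = 5L, `1` = 10L)) {
  responses <- as_tibble(responses)
  cols <- paste0("bct_", bct_preference_tags())
  missing_cols <- setdiff(cols, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("responses are missing BCT column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in cols) {
    v <- responses[[col]]
    bad <- !(v %in% c(-1L, 0L, 1L))
    if (any(bad)) {
      abort(sprintf(
        "invalid response for %s: %s (must be -1, 0 or +1)",
        sub("^bct_", "", col), paste(unique(v[bad]), collapse = ", ")
      ))
    }
    responses[[col]] <- unname(score_map[as.character(v)])
  }
  responses
}

#' Build a user roster from survey responses
#'
#' Scores the preference responses and attaches the default daily step-goal
#' range. The roster is the engine's user table: one row per user with
#' identity, first name (inserted into messages), per-BCT scores, and goal.
#'
#' @param responses As in [score_preferences()]; must carry `user_id` and
#'   `first_name`.
#' @param config An [engine_config()]; supplies the score map and goal.
#' @return A tibble with columns `user_id`, `first_name`, the ten
#'   `bct_` score columns, `step_goal_min` and `step_goal_max`.
#' @export
build_roster <- function(responses, config = engine_config()) {
  responses <- as_tibble(responses)
  if (!all(c("user_id", "first_name") %in% names(responses))) {
    abort("responses must have user_id and first_name columns")
  }
  if (anyDuplicated(responses$user_id) > 0) {
    abort("user_id values must be unique within a roster")
  }
  if (any(!nzchar(responses$first_name) | is.na(responses$first_name))) {
    abort("every user needs a nonempty first_name")
  }
  scored <- score_preferences(responses, score_map = config$score_map)
  scored$step_goal_min <- config$step_goal[1]
  scored$step_goal_max <- config$step_goal[2]
  scored
}

#' Read a preference survey CSV
#'
#' Columns: `user_id, first_name`, then `bct_<tag>` for each of the ten
#' preference-tailored BCTs, values in \{-1, 0, 1\}.
#'
#' @param path CSV path, UTF-8, header required.
#' @return A tibble of raw responses (not yet scored).
#' @export
read_preferences <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          user_id = readr::col_character(),
                          first_name = readr::col_character(),
                          .default = readr::col_integer()
                        ))
  cols <- c("user_id", "first_name", paste0("bct_", bct_preference_tags()))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("preferences file missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df[cols]
}

#' @rdname read_preferences
#' @param responses A responses (or scored roster) tibble.
#' @export
write_preferences <- function(responses, path) {
  readr::write_csv(as_tibble(responses), path)
  invisible(path)
}

#' Classify a daily step count into a performance stratum
#'
#' Step-feedback messages are tailored to one of three performance bands:
#' `LOW` for counts up to 2000, `MID` for 2001-6000, `HIGH` from 6001 up.
#' The three bands partition the nonnegative integers.
#'
#' @param steps Nonnegative integer vector of cumulative daily step counts.
#' @param strata_bounds Inclusive upper bounds of LOW and MID.
#' @return A factor with levels `LOW`, `MID`, `HIGH`.
#' @export
#' @examples
#' classify_step_stratum(c(0, 2000, 2001, 6000, 6001))
classify_step_stratum <- function(steps, strata_bounds = c(2000L, 6000L)) {
  if (any(is.na(steps)) || any(steps < 0)) {
    abort("steps must be nonnegative and non-missing")
  }
  out <- ifelse(steps <= strata_bounds[1], "LOW",
                ifelse(steps <= strata_bounds[2], "MID", "HIGH"))
  factor(out, levels = .strata)
}

#' Evaluate the daily step goal
#'
#' The guideline goal is a range (default 7000-8000 steps/day); a day counts
#' as meeting the goal once the minimum is reached. The upper bound defines
#' no behaviour and is kept as metadata only.
#'
#' @param steps Nonnegative numeric vector of daily step counts.
#' @param goal_min Minimum daily steps (default 7000).
#' @return Logical vector, `TRUE` where `steps >= goal_min`.
#' @export
#' @examples
#' goal_met(c(6999, 7000))
goal_met <- function(steps, goal_min = 7000L) {
  if (any(is.na(steps)) || any(steps < 0)) {
    abort("steps must be nonnegative and non-missing")
  }
  steps >= goal_min
}

#' Step-count store
#'
#' The engine keeps the hourly step-count synchronisations from the phone in
#' a per-user, per-day append-only store. Counts are cumulative within a
#' day, so on one `(user_id, date)` successive records must have
#' nondecreasing `steps` and strictly increasing `time`; a new date starts a
#' fresh series at any value. Violating records are rejected (the store is
#' returned unchanged for them) and collected in the `rejected` attribute
#' with reason `MONOTONICITY`, mirroring a fault observed in piloting where
#' a device stopped advancing its date.
#'
#' @param store A step-store tibble as returned by `step_store()`.
#' @param records Tibble with columns `user_id`, `date` (Date), `time`
#'   (minutes since midnight, 0-1439), `steps` (cumulative, >= 0), `sensor`
#'   (`"pedometer"` or `"accelerometer"`). Processed in row order.
#' @return `step_store()`: an empty store. `record_step_update()`: the
#'   updated store; rejected rows (with a `reason` column) are attached as
#'   `attr(, "rejected")` and reported via a warning.
#' @export
#' @examples
#' st <- step_store()
#' st <- record_step_update(st, tibble::tibble(
#'   user_id = "u1", date = as.Date("2026-01-05"), time = c(600, 660),
#'   steps = c(1200, 1500), sensor = "pedometer"))
step_store <- function() {
  tibble(
    user_id = character(), date = as.Date(character()),
    time = integer(), steps = integer(), sensor = character()
  )
}

#' @rdname step_store
#' @export
record_step_update <- function(store, records) {
  records <- as_tibble(records)
  need <- c("user_id", "date", "time", "steps", "sensor")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("step records missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(records$steps < 0 | is.na(records$steps))) {
    abort("steps must be nonnegative")
  }
  if (any(!records$sensor %in% c("pedometer", "accelerometer"))) {
    abort("sensor must be 'pedometer' or 'accelerometer'")
  }
  records$date <- as.Date(records$date)
  records$time <- as.integer(records$time)
  records$steps <- as.integer(records$steps)

  # latest (steps, time) per user-day already in the store
  key <- function(u, d) paste(u, as.integer(d))
  last_steps <- new.env(parent = emptyenv())
  if (nrow(store) > 0) {
    st_key <- key(store$user_id, store$date)
    for (k in unique(st_key)) {
      idx <- which(st_key == k)
      i <- idx[which.max(store$time[idx])]
      assign(k, c(store$steps[i], store$time[i]), envir = last_steps)
    }
  }
  ok <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    k <- key(records$user_id[i], records$date[i])
    prev <- if (exists(k, envir = last_steps)) get(k, envir = last_steps) else NULL
    ok[i] <- is.null(prev) ||
      (records$steps[i] >= prev[1] && records$time[i] > prev[2])
    if (ok[i]) {
      assign(k, c(records$steps[i], records$time[i]), envir = last_steps)
    }
  }
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- "MONOTONICITY"
    warn(sprintf("rejected %d step record(s) violating cumulative monotonicity",
                 nrow(rejected)))
  }
  out <- bind_rows(store, records[ok, , drop = FALSE])
  attr(out, "rejected") <- rejected
  out
}

#' Latest step count for a day
#'
#' Returns the most recent synchronised count for `(user_id, date)`. When no
#' record exists for that date — including the pilot fault where the device
#' keeps reporting under a stale date — the engine falls back to
#' `(steps = 0, stale = TRUE)` so a scheduled contact is never skipped; the
#' delivery is flagged instead.
#'
#' @param store A step store.
#' @param user_id Single user id (must exist in the roster the caller
#'   validated; unknown ids in a nonempty store error).
#' @param date The calendar day.
#' @param known_users Optional character vector of valid ids for lookup
#'   validation.
#' @return A one-row tibble with `steps` and `stale`.
#' @export
steps_for_day <- function(store, user_id, date, known_users = NULL) {
  if (!is.null(known_users) && !user_id %in% known_users) {
    abort(paste0("unknown user: ", user_id))
  }
  date <- as.Date(date)
  idx <- which(store$user_id == user_id & store$date == date)
  if (length(idx) == 0) {
    return(tibble(steps = 0L, stale = TRUE))
  }
  i <- idx[which.max(store$time[idx])]
  tibble(steps = store$steps[i], stale = FALSE)
}
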