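# Simulated-clock scheduler. Clock resolution is one minute; all windows are
# half-open [start, end) in minutes since local midnight; the day boundary is
# local midnight of the abstract simulation clock (no time zones, no DST).

.fmt_ts <- function(date, minute) {
  sprintf("%s %02d:%02d", format(date, "%Y-%m-%d"), minute %/% 60, minute %% 60)
}

#' Plan one day's scheduled contacts
#'
#' Draws the three guaranteed daily contact times independently and
#' uniformly over whole minutes within their windows: a preference-tailored
#' (BCT) message in the morning (default 08:00-09:00) and evening (default
#' 16:00-18:00), and a step-feedback message at midday (default
#' 11:30-12:30). Times are re-drawn every day.
#'
#' @param date The simulated day.
#' @param config An [engine_config()].
#' @return A one-row tibble `date, morning_min, midday_min, evening_min`
#'   (minutes since midnight).
#' @export
#' @examples
#' set.seed(1)
#' plan_day(as.Date("2026-01-05"))
plan_day <- function(date, config = engine_config()) {
  draw <- function(w) w[1] + sample.int(w[2] - w[1], 1L) - 1L
  tibble(
    date = as.Date(date),
    morning_min = draw(config$morning_window),
    midday_min = draw(config$midday_window),
    evening_min = draw(config$evening_window)
  )
}

#' Geolocation delivery gate
#'
#' A green-space prompt is allowed only when all three rate rules hold: the
#' current time is inside the geolocation window (default 08:00-20:00),
#' fewer than the daily cap (default 3) have been sent today, and at least
#' the minimum gap (default 4 h) has passed since the previous geolocation
#' delivery. The gap is measured delivery-to-delivery, not
#' attempt-to-attempt, and the daily counter resets at local midnight.
#'
#' @param state A list with `geo_sent_today` (count) and `last_geo_time`
#'   (absolute simulation minute of the last geolocation delivery, or
#'   `NULL`). See [geo_gate_state()].
#' @param now Absolute simulation minute (minute-of-day is `now %% 1440`).
#' @param config An [engine_config()].
#' @return A list `allow` (logical) and `reason` (`NULL` when allowed, else
#'   `"WINDOW"`, `"MAX_DAILY"` or `"MIN_GAP"`).
#' @export
#' @examples
#' geo_gate(geo_gate_state(), now = 9 * 60)
geo_gate <- function(state, now, config = engine_config()) {
  m <- now %% 1440L
  if (m < config$geo_window[1] || m >= config$geo_window[2]) {
    return(list(allow = FALSE, reason = "WINDOW"))
  }
  if (state$geo_sent_today >= config$geo_daily_cap) {
    return(list(allow = FALSE, reason = "MAX_DAILY"))
  }
  if (!is.null(state$last_geo_time) &&
      now - state$last_geo_time < config$geo_min_gap_min) {
    return(list(allow = FALSE, reason = "MIN_GAP"))
  }
  list(allow = TRUE, reason = NULL)
}

#' @rdname geo_gate
#' @export
geo_gate_state <- function() {
  list(geo_sent_today = 0L, last_geo_time = NULL)
}

#' Run the coaching-engine simulation
#'
#' The end-to-end event loop, per user per simulated day:
#'
#' * the geofence is evaluated against the user's GPS track every
#'   `geo_poll_interval_min` (default 2) minutes from midnight;
#' * the step store is refreshed from the day's step-record series (hourly
#'   syncs by default);
#' * the three scheduled contacts fire at the times drawn by [plan_day()];
#' * a geolocation prompt fires on a geofence hit whenever [geo_gate()]
#'   allows and an eligible message exists;
#' * every delivery, every empty-pool outcome (`NO_ELIGIBLE_MESSAGE`) and
#'   every gate denial on a geofence hit is logged.
#'
#' When a scheduled tick and a geofence tick share a minute, the scheduled
#' message is processed first. If the step store holds no record for the
#' current day at step-feedback time (e.g. the device's date stopped
#' advancing), the engine sends the LOW-stratum message for 0 steps and
#' flags the log entry `stale_steps = TRUE` rather than skipping the
#' contact.
#'
#' All randomness (daily plans, message selection, synthetic inputs)
#' descends from `seed`, so the same call is replayed byte-identically.
#'
#' @param roster Scored user roster ([build_roster()]).
#' @param lib A [message_library()].
#' @param green_spaces Green-space tibble, or a file path — a path is
#'   re-read at each simulated midnight, mirroring the app's daily refresh
#'   of the green-space list.
#' @param days Number of simulated days.
#' @param start_date First simulated day.
#' @param scenario A [scenario_params()]; used to generate step records and
#'   GPS tracks for any user-day not covered by `step_records` / `tracks`.
#' @param step_records Optional step-record tibble (`user_id, date, time,
#'   steps, sensor`) overriding generation.
#' @param tracks Optional GPS-track tibble (`user_id, date, minute, lat,
#'   lon`, minute resolution) overriding generation.
#' @param config An [engine_config()].
#' @param seed Integer seed for the whole run.
#' @param log_evaluations If `TRUE`, also record the timestamp of every
#'   geofence evaluation (large: 720/user/day at default cadence).
#' @return A `coach_sim` object: `$log` (the delivery log tibble), `$plans`,
#'   `$evaluations` (or `NULL`), plus the inputs needed for replay.
#'   `tidy()` returns the log, `glance()` a one-row summary.
#' @export
#' @examples
#' roster <- build_roster(gen_preference_responses(1, seed = 7))
#' lib <- gen_message_library(per_pool = 2)
#' db <- gen_green_spaces(3, seed = 7)
#' sim <- run_simulation(roster, lib, db, days = 1, seed = 42)
#' glance(sim)
run_simulation <- function(roster, lib, green_spaces,
                           days = 1L,
                           start_date = as.Date("2026-01-05"),
                           scenario = scenario_params(n_users = nrow(roster)),
                           step_records = NULL,
                           tracks = NULL,
                           config = engine_config(),
                           seed = 1L,
                           log_evaluations = FALSE) {
  stopifnot(inherits(lib, "message_library"), inherits(config, "engine_config"))
  roster <- as_tibble(roster)
  if (nrow(roster) == 0) abort("roster is empty")
  start_date <- as.Date(start_date)
  from_path <- is.character(green_spaces) && length(green_spaces) == 1
  db0 <- if (from_path) read_green_spaces(green_spaces) else green_space_db(green_spaces)

  if (!is.null(step_records)) {
    step_records <- as_tibble(step_records)
    step_records$date <- as.Date(step_records$date)
  }
  if (!is.null(tracks)) {
    tracks <- as_tibble(tracks)
    tracks$date <- as.Date(tracks$date)
  }

  # deterministic GEO pool emptiness per type (selection succeeds iff nonempty)
  geo_pool_empty <- vapply(.green_space_types, function(g) {
    !any(lib$category == "GEO" & lib$green_space_type %in% c(g, "ANY"))
  }, logical(1))
  step_pool_empty <- vapply(.strata, function(s) {
    !any(lib$category == "STEP" & lib$stratum %in% c(s, "ANY"))
  }, logical(1))

  set.seed(seed)
  eval_minutes <- seq(0L, 1439L, by = config$geo_poll_interval_min)
  win <- config$geo_window
  cap <- config$geo_daily_cap
  gap <- config$geo_min_gap_min

  day_logs <- list()
  plan_rows <- list()
  eval_rows <- if (log_evaluations) list() else NULL
  last_geo <- stats::setNames(rep(-Inf, nrow(roster)), roster$user_id)

  for (d in seq_len(days)) {
    date <- start_date + (d - 1L)
    day0 <- (d - 1L) * 1440L
    weekday <- .weekday_of(date)
    db <- if (from_path) read_green_spaces(green_spaces) else db0

    for (ui in seq_len(nrow(roster))) {
      profile <- as.list(roster[ui, ])
      uid <- profile$user_id

      recs <- if (!is.null(step_records)) {
        step_records[step_records$user_id == uid, , drop = FALSE]
      } else {
        gen_step_trajectory(scenario, date, seed = NULL, user_id = uid)
      }
      trk <- if (!is.null(tracks)) {
        tracks[tracks$user_id == uid & tracks$date == date, , drop = FALSE]
      } else {
        gen_gps_track(scenario, date, db, seed = NULL, user_id = uid)
      }
      if (nrow(trk) != 1440L) {
        abort(sprintf("track for user %s on %s must have 1440 minute fixes",
                      uid, format(date)))
      }
      trk <- trk[order(trk$minute), , drop = FALSE]

      plan <- plan_day(date, config)
      plan$user_id <- uid
      plan_rows[[length(plan_rows) + 1L]] <- plan

      # --- geofence hits and gate decisions (RNG-free) ---
      hit_space <- .proximity_index(trk$lat[eval_minutes + 1L],
                                    trk$lon[eval_minutes + 1L],
                                    db, config$radius_m)
      hit_i <- which(!is.na(hit_space))
      n_hit <- length(hit_i)
      geo_minute <- eval_minutes[hit_i]
      geo_space <- hit_space[hit_i]
      geo_code <- character(n_hit)
      sent <- 0L
      lg <- last_geo[[uid]]
      for (h in seq_len(n_hit)) {
        m <- geo_minute[h]
        if (m < win[1] || m >= win[2]) {
          geo_code[h] <- "WINDOW"
        } else if (sent >= cap) {
          geo_code[h] <- "MAX_DAILY"
        } else if (day0 + m - lg < gap) {
          geo_code[h] <- "MIN_GAP"
        } else if (geo_pool_empty[[db$type[geo_space[h]]]]) {
          geo_code[h] <- "NO_ELIGIBLE_MESSAGE"
        } else {
          geo_code[h] <- "DELIVER"
          sent <- sent + 1L
          lg <- day0 + m
        }
      }
      last_geo[[uid]] <- lg

      if (log_evaluations) {
        eval_rows[[length(eval_rows) + 1L]] <- tibble(
          user_id = uid, date = date, minute = eval_minutes
        )
      }

      # --- assemble events; scheduled before geo at a shared minute ---
      sched <- tibble(
        minute = c(plan$morning_min, plan$midday_min, plan$evening_min),
        prio = 0L,
        channel = c("BCT-morning", "STEP", "BCT-evening"),
        space = NA_integer_, code = "SCHED"
      )
      geo_ev <- tibble(
        minute = geo_minute, prio = 1L, channel = "GEO",
        space = geo_space, code = geo_code
      )
      ev <- bind_rows(sched, geo_ev)
      ev <- ev[order(ev$minute, ev$prio), , drop = FALSE]

      n_ev <- nrow(ev)
      kind <- character(n_ev); message_id <- rep(NA_character_, n_ev)
      text <- rep(NA_character_, n_ev); reason <- rep(NA_character_, n_ev)
      context <- rep(NA_character_, n_ev); stale_flag <- rep(FALSE, n_ev)

      for (e in seq_len(n_ev)) {
        ch <- ev$channel[e]
        if (ch == "GEO") {
          code <- ev$code[e]
          sp <- ev$space[e]
          if (code == "DELIVER") {
            out <- select_geo_message(lib, profile, db$type[sp])
            kind[e] <- "DELIVERY"
            message_id[e] <- out$message_id
            text[e] <- out$rendered_text
            context[e] <- sprintf("type=%s;space=%s;pool=%d",
                                  db$type[sp], db$space_id[sp],
                                  out$trace$pool_size)
          } else {
            kind[e] <- "SKIP"
            reason[e] <- code
            context[e] <- sprintf("type=%s;space=%s",
                                  db$type[sp], db$space_id[sp])
          }
        } else if (ch == "STEP") {
          sd <- .steps_at(recs, date, ev$minute[e])
          out <- select_step_message(lib, profile, sd$steps, sd$stale, config)
          stale_flag[e] <- sd$stale
          if (out$reason == "SELECTED") {
            kind[e] <- "DELIVERY"
            message_id[e] <- out$message_id
            text[e] <- out$rendered_text
          } else {
            kind[e] <- "SKIP"
            reason[e] <- out$reason
          }
          context[e] <- sprintf("stratum=%s;pool=%d",
                                out$trace$stratum, out$trace$pool_size)
        } else { # BCT morning/evening
          slot <- if (ch == "BCT-morning") "morning" else "evening"
          out <- select_bct_message(lib, profile, slot, weekday, config)
          if (out$reason == "SELECTED") {
            kind[e] <- "DELIVERY"
            message_id[e] <- out$message_id
            text[e] <- out$rendered_text
            context[e] <- sprintf("slot=%s;pool=%d;subset=%s",
                                  slot, out$trace$pool_size,
                                  paste(out$trace$subset_ids, collapse = "|"))
          } else {
            kind[e] <- "SKIP"
            reason[e] <- out$reason
            context[e] <- sprintf("slot=%s;pool=%d", slot, out$trace$pool_size)
          }
        }
      }

      day_logs[[length(day_logs) + 1L]] <- tibble(
        ts = .fmt_ts(date, ev$minute),
        date = date, minute = ev$minute,
        user_id = uid, kind = kind, channel = ev$channel,
        message_id = message_id, text = text, reason = reason,
        context = context, stale_steps = stale_flag
      )
    }
  }

  structure(
    list(
      log = bind_rows(day_logs),
      plans = bind_rows(plan_rows),
      evaluations = if (log_evaluations) bind_rows(eval_rows) else NULL,
      config = config, seed = seed,
      start_date = start_date, days = as.integer(days),
      user_ids = roster$user_id
    ),
    class = "coach_sim"
  )
}

# latest visible step count for `date` at minute m (records sorted by time)
.steps_at <- function(recs, date, m) {
  idx <- which(recs$date == date & recs$time <= m)
  if (length(idx) == 0) return(list(steps = 0L, stale = TRUE))
  i <- idx[which.max(recs$time[idx])]
  list(steps = recs$steps[i], stale = FALSE)
}

#' @export
print.coach_sim <- function(x, ...) {
  nd <- sum(x$log$kind == "DELIVERY")
  cat(sprintf("<coach_sim> %d user(s) x %d day(s), seed %d: %d deliveries, %d skips\n",
              length(x$user_ids), x$days, x$seed, nd, sum(x$log$kind == "SKIP")))
  invisible(x)
}

#' @method tidy coach_sim
#' @export
tidy.coach_sim <- function(x, ...) x$log

#' @method glance coach_sim
#' @export
glance.coach_sim <- function(x, ...) {
  log <- x$log
  del <- log[log$kind == "DELIVERY", ]
  geo <- del[del$channel == "GEO", ]
  geo_per_day <- if (nrow(geo) > 0) {
    tapply(rep(1L, nrow(geo)), paste(geo$user_id, geo$date), sum)
  } else 0L
  min_gap <- Inf
  if (nrow(geo) > 1) {
    for (u in unique(geo$user_id)) {
      g <- geo[geo$user_id == u, ]
      absm <- as.integer(g$date - x$start_date) * 1440L + g$minute
      if (length(absm) > 1) min_gap <- min(min_gap, diff(sort(absm)))
    }
  }
  tibble(
    n_users = length(x$user_ids), days = x$days,
    n_delivered = nrow(del), n_skipped = sum(log$kind == "SKIP"),
    n_step = sum(del$channel == "STEP"),
    n_bct = sum(grepl("^BCT", del$channel)),
    n_geo = nrow(geo),
    max_geo_per_day = max(geo_per_day),
    min_geo_gap_min = min_gap,
    n_stale = sum(del$stale_steps)
  )
}

#' Per-user-day delivery counts
#'
#' @param x A `coach_sim` or a delivery-log tibble.
#' @return A tibble with one row per user-day and per-channel delivery
#'   counts (`step`, `bct`, `geo`, `total`).
#' @export
summarize_deliveries <- function(x) {
  log <- if (inherits(x, "coach_sim")) x$log else as_tibble(x)
  del <- log[log$kind == "DELIVERY", ]
  del$chan <- ifelse(grepl("^BCT", del$channel), "bct", tolower(del$channel))
  del |>
    group_by(.data$user_id, .data$date, .data$chan) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "chan", values_from = "n",
                       values_fill = 0L) |>
    mutate(total = rowSums(across(-c(1, 2))))
}

#' Write the delivery log as JSON lines
#'
#' One JSON object per event with fields `ts, user_id, kind, channel,
#' message_id, text, reason, context, stale_steps`. Replaying the same
#' simulation seed writes a byte-identical file.
#'
#' @param x A `coach_sim` or delivery-log tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_delivery_log <- function(x, path) {
  log <- if (inherits(x, "coach_sim")) x$log else as_tibble(x)
  out <- log[c("ts", "user_id", "kind", "channel", "message_id",
               "text", "reason", "context", "stale_steps")]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(out, con, verbose = FALSE, na = "null")
  invisible(path)
}
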