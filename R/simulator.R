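# Synthetic-data generators standing in for the mobile apps and real users.
# All generators are pure functions of (parameters, seed): the seed is applied
# to a local RNG scope so replays are bitwise identical and the caller's RNG
# state is untouched.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.first_names <- c(
  "Anna", "Bram", "Carla", "Daan", "Els", "Frank", "Greta", "Hugo",
  "Iris", "Joris", "Kim", "Lars", "Mara", "Nico", "Olga", "Paul",
  "Rosa", "Sven", "Tess", "Wim"
)

#' Scenario parameters for the synthetic cohort
#'
#' Describes the simulated world the generators emulate: adults walking in
#' discrete bouts on top of background ambulation, living around a home
#' location and sometimes passing a green space. Defaults target the
#' insufficiently active population of the intervention: about 6 walking
#' bouts a day of lognormal size (median 700 steps) plus 50 background
#' steps per hour gives a right-skewed daily total around 6000 steps —
#' below the 7000-step guideline most days.
#'
#' @param n_users Number of users to simulate.
#' @param bouts_per_day_mean Poisson mean of walking bouts per day.
#' @param bout_steps_meanlog,bout_steps_sdlog Lognormal parameters of steps
#'   per bout.
#' @param background_steps_per_hour Deterministic background step drift.
#' @param home Length-2 numeric `c(lat, lon)` of the cohort's home.
#' @param waypoint_count Waypoints per daily GPS excursion.
#' @param waypoint_spread_m Maximum distance of waypoints from home.
#' @param dwell_near_green Probability that one waypoint is placed within
#'   100 m of a random green space.
#' @param stale_fault If `TRUE`, step records carry the previous day's date
#'   (reproducing a pilot device fault where the app's date stopped
#'   advancing), so the engine sees no data for "today".
#' @return A list of class `scenario_params`.
#' @export
scenario_params <- function(n_users = 5L,
                            bouts_per_day_mean = 6,
                            bout_steps_meanlog = log(700),
                            bout_steps_sdlog = 0.5,
                            background_steps_per_hour = 50,
                            home = c(52.36, 4.90),
                            waypoint_count = 8L,
                            waypoint_spread_m = 800,
                            dwell_near_green = 0.3,
                            stale_fault = FALSE) {
  stopifnot(
    n_users >= 1, bouts_per_day_mean >= 0, background_steps_per_hour >= 0,
    waypoint_count >= 1, waypoint_spread_m >= 0,
    dwell_near_green >= 0, dwell_near_green <= 1,
    length(home) == 2
  )
  structure(
    list(
      n_users = as.integer(n_users),
      bouts_per_day_mean = bouts_per_day_mean,
      bout_steps_meanlog = bout_steps_meanlog,
      bout_steps_sdlog = bout_steps_sdlog,
      background_steps_per_hour = background_steps_per_hour,
      home = as.numeric(home),
      waypoint_count = as.integer(waypoint_count),
      waypoint_spread_m = waypoint_spread_m,
      dwell_near_green = dwell_near_green,
      stale_fault = isTRUE(stale_fault)
    ),
    class = "scenario_params"
  )
}

#' Generate a synthetic preference-survey roster
#'
#' Draws each of the ten BCT preference items i.i.d. from a distribution
#' over \{-1, 0, +1\} (uniform by default) and assigns ids and first names.
#'
#' @param n_users Number of users.
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @param prob Length-3 probabilities for responses -1, 0, +1.
#' @return A tibble of raw responses suitable for [score_preferences()] /
#'   [build_roster()].
#' @export
#' @examples
#' gen_preference_responses(3, seed = 1)
gen_preference_responses <- function(n_users, seed = NULL,
                                     prob = c(1, 1, 1) / 3) {
  stopifnot(n_users >= 1, length(prob) == 3, all(prob >= 0), sum(prob) > 0)
  .with_seed(seed, {
    out <- tibble(
      user_id = sprintf("u%03d", seq_len(n_users)),
      first_name = .first_names[(seq_len(n_users) - 1L) %% length(.first_names) + 1L]
    )
    for (tag in bct_preference_tags()) {
      out[[paste0("bct_", tag)]] <-
        sample(c(-1L, 0L, 1L), n_users, replace = TRUE, prob = prob)
    }
    out
  })
}

#' Generate one user-day of hourly step records
#'
#' Step accrual is modelled as a compound process: a Poisson number of
#' walking bouts at uniform times of day, each of lognormal size, on top of
#' a deterministic background drift per hour. Hourly cumulative counts are
#' emitted the way the phone syncs them (one record per hour, cumulative
#' and nondecreasing), so the expected daily total is
#' `bouts_per_day_mean * exp(meanlog + sdlog^2 / 2) + 24 * background`.
#'
#' @param params A [scenario_params()].
#' @param date The simulated calendar day.
#' @param seed RNG seed.
#' @param user_id Id stamped on the records.
#' @return A tibble of `StepRecord`s: `user_id, date, time, steps, sensor`,
#'   one row per hour (times 60, 120, ..., 1439). Under `stale_fault` the
#'   `date` column carries the previous day.
#' @export
gen_step_trajectory <- function(params, date, seed = NULL, user_id = "u001") {
  stopifnot(inherits(params, "scenario_params"))
  date <- as.Date(date)
  .with_seed(seed, {
    n_bouts <- stats::rpois(1, params$bouts_per_day_mean)
    bout_min <- sort(floor(stats::runif(n_bouts, 0, 1440)))
    bout_sz <- stats::rlnorm(n_bouts, params$bout_steps_meanlog,
                             params$bout_steps_sdlog)
    sensor <- sample(c("pedometer", "accelerometer"), 1)
    sync_min <- c(seq(60L, 1380L, by = 60L), 1439L)
    cum <- vapply(sync_min, function(m) {
      bg <- params$background_steps_per_hour * m / 60
      floor(bg + sum(bout_sz[bout_min <= m]))
    }, numeric(1))
    tibble(
      user_id = user_id,
      date = if (params$stale_fault) date - 1L else date,
      time = as.integer(sync_min),
      steps = as.integer(cum),
      sensor = sensor
    )
  })
}

#' Generate one user-day GPS track
#'
#' A minute-resolution track: the user leaves home, visits random waypoints
#' within `waypoint_spread_m` of home and returns, positions linearly
#' interpolated between waypoints. With probability `dwell_near_green` one
#' waypoint is placed within 100 m of a randomly chosen green space, so the
#' track passes through the 300 m geofence.
#'
#' @param params A [scenario_params()].
#' @param date Simulated day (stamped on the track).
#' @param green_spaces Green-space tibble (may have zero rows).
#' @param seed RNG seed.
#' @param user_id Id stamped on the track.
#' @return A tibble `user_id, date, minute (0..1439), lat, lon`.
#' @export
gen_gps_track <- function(params, date, green_spaces, seed = NULL,
                          user_id = "u001") {
  stopifnot(inherits(params, "scenario_params"))
  date <- as.Date(date)
  .with_seed(seed, {
    k <- params$waypoint_count
    wp <- destination_point(
      params$home[1], params$home[2],
      bearing_deg = stats::runif(k, 0, 360),
      distance_m = stats::runif(k, 0, params$waypoint_spread_m)
    )
    if (nrow(green_spaces) > 0 &&
        stats::runif(1) < params$dwell_near_green) {
      g <- green_spaces[sample.int(nrow(green_spaces), 1), ]
      near <- destination_point(g$lat, g$lon,
                                bearing_deg = stats::runif(1, 0, 360),
                                distance_m = stats::runif(1, 0, 100))
      slot_i <- sample.int(k, 1)
      wp$lat[slot_i] <- near$lat
      wp$lon[slot_i] <- near$lon
    }
    path_lat <- c(params$home[1], wp$lat, params$home[1])
    path_lon <- c(params$home[2], wp$lon, params$home[2])
    t_nodes <- seq(0, 1439, length.out = length(path_lat))
    minute <- 0:1439
    tibble(
      user_id = user_id, date = date, minute = minute,
      lat = stats::approx(t_nodes, path_lat, xout = minute)$y,
      lon = stats::approx(t_nodes, path_lon, xout = minute)$y
    )
  })
}

#' Generate a synthetic green-space database
#'
#' `n` points uniform in a bounding box, with types cycling through park,
#' forest, walking trail.
#'
#' @param n Number of spaces.
#' @param bbox Named or positional numeric: `lat_min, lat_max, lon_min,
#'   lon_max`.
#' @param seed RNG seed.
#' @return A green-space tibble ([green_space_db()]).
#' @export
#' @examples
#' gen_green_spaces(3, seed = 1)
gen_green_spaces <- function(n, bbox = c(52.30, 52.42, 4.80, 5.00),
                             seed = NULL) {
  stopifnot(n >= 1, length(bbox) == 4, bbox[1] < bbox[2], bbox[3] < bbox[4])
  .with_seed(seed, {
    types <- rep_len(.green_space_types, n)
    green_space_db(tibble(
      space_id = sprintf("gs%03d", seq_len(n)),
      name = paste(gsub("_", " ", types), seq_len(n)),
      type = types,
      lat = stats::runif(n, bbox[1], bbox[2]),
      lon = stats::runif(n, bbox[3], bbox[4])
    ))
  })
}

# phrase bank used to pad generated variants into the 20-30 word house style
.fillers <- c(
  "Every little walk counts, so keep moving at your own pace today.",
  "A short stroll outside can clear your head and lift your mood.",
  "Small steps add up quickly when you keep at it every single day.",
  "Fresh air and a steady pace make the day feel a lot lighter."
)

.base_texts <- function() {
  list(
    STEP = c(
      LOW = "So far you have taken <number> steps today, <name>. There is still plenty of day left, so how about a short walk to get going?",
      MID = "So far you have taken <number> steps today, <name>. Well done! You can be proud of yourself.",
      HIGH = "Fantastic, <name>! You have already taken <number> steps today. Keep this up and your daily goal is well within reach."
    ),
    GEO = c(
      "Do you want to get some extra steps in today? You are close to a <green_space_type> where you can enjoy a nice walk."
    ),
    BCT = c(
      action_planning = "Good preparation is half the battle won! Plan and write down when and where you will go for a walk in the coming days.",
      reward = "Hey <name>, keep up the good work! Try to keep walking every day. You can do it.",
      social_comparison = "Hi <name>, here's a little fact: last week, 73% of walkers in the programme took enough steps every day!",
      consequences = "Did you know that walking can help relieve stress? Walking makes your brain release chemicals that stimulate relaxation and improve your mood.",
      barrier_identification = "No time to go for a walk? Get your steps in throughout the day by taking the stairs, getting off the bus a stop earlier, or parking further away.",
      social_support = "Hey <name>, have you told your friends or family about your walking goals? That way, they can support or join you for a walk!",
      social_approval = "Good morning <name>. If you manage to keep walking regularly, your friends and family will surely be proud of you.",
      goal_setting = "What's your new goal, <name>? Set yourself an achievable walking goal for this week.",
      self_monitoring = "Curious to know how many steps you've already taken today? Try to keep track by checking the step counter every day.",
      review_goals = "Did you achieve this week's walking goal, <name>? If so, good job! If not, try to think of a new goal for next week."
    )
  )
}

#' Generate a message-library fixture
#'
#' Builds a library covering every selectable pool: `per_pool` templates
#' for each STEP stratum, each green-space type, and each of the ten
#' preference-tailored BCT tags (`3 + 3 + 10 = 16` templates at
#' `per_pool = 1`). The first template of each pool is a curated example
#' text; additional templates are numbered variants padded from a phrase
#' bank. The result always passes [validate_library()] with zero coverage
#' errors.
#'
#' @param per_pool Templates per pool (>= 1).
#' @param seed RNG seed used to pick variant filler phrases.
#' @return A [message_library()].
#' @export
#' @examples
#' lib <- gen_message_library(per_pool = 2, seed = 1)
#' glance(validate_library(lib))
gen_message_library <- function(per_pool = 1L, seed = 1L) {
  stopifnot(per_pool >= 1)
  base <- .base_texts()
  .with_seed(seed, {
    rows <- list()
    add <- function(id, category, bct_tag, stratum, gst, text) {
      rows[[length(rows) + 1L]] <<- tibble(
        message_id = id, category = category, bct_tag = bct_tag,
        stratum = stratum, green_space_type = gst,
        allowed_weekdays = "", allowed_slots = "", text = text
      )
    }
    variant <- function(text, j) {
      if (j == 1L) return(text)
      filler <- sample(.fillers, 1)
      paste0(text, " ", filler)
    }
    for (s in .strata) {
      for (j in seq_len(per_pool)) {
        add(sprintf("step_%s_%02d", tolower(s), j), "STEP",
            "feedback_on_performance", s, "",
            variant(base$STEP[[s]], j))
      }
    }
    for (g in .green_space_types) {
      for (j in seq_len(per_pool)) {
        add(sprintf("geo_%s_%02d", g, j), "GEO", "provide_instruction",
            "", g, variant(base$GEO[[1]], j))
      }
    }
    for (b in bct_preference_tags()) {
      for (j in seq_len(per_pool)) {
        add(sprintf("bct_%s_%02d", b, j), "BCT", b, "", "",
            variant(base$BCT[[b]], j))
      }
    }
    message_library(bind_rows(rows))
  })
}
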