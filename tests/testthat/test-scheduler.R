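test_that("daily plans land inside their windows and replay under a seed", {
  cfg <- engine_config()
  set.seed(31)
  for (i in 1:50) {
    p <- plan_day(as.Date("2026-01-05") + i, cfg)
    expect_true(p$morning_min >= 480 && p$morning_min < 540)
    expect_true(p$midday_min >= 690 && p$midday_min < 750)
    expect_true(p$evening_min >= 960 && p$evening_min < 1080)
  }
  set.seed(8); p1 <- plan_day(as.Date("2026-01-05"))
  set.seed(8); p2 <- plan_day(as.Date("2026-01-05"))
  expect_identical(p1, p2)
})

test_that("the geolocation gate applies window, cap and gap rules", {
  cfg <- engine_config()
  st <- geo_gate_state()
  expect_true(geo_gate(st, now = 9 * 60, cfg)$allow)
  # 10:00 after a 09:00 send -> too soon
  st <- list(geo_sent_today = 1L, last_geo_time = 9L * 60L)
  d <- geo_gate(st, now = 10 * 60, cfg)
  expect_false(d$allow); expect_equal(d$reason, "MIN_GAP")
  # 13:00 is exactly 4 h later -> allowed
  expect_true(geo_gate(st, now = 13 * 60, cfg)$allow)
  # outside the window
  d <- geo_gate(geo_gate_state(), now = 21 * 60, cfg)
  expect_equal(d$reason, "WINDOW")
  expect_equal(geo_gate(geo_gate_state(), now = 7 * 60 + 59, cfg)$reason, "WINDOW")
  expect_true(geo_gate(geo_gate_state(), now = 8 * 60, cfg)$allow)
  # daily cap reached
  st <- list(geo_sent_today = 3L, last_geo_time = 8L * 60L)
  expect_equal(geo_gate(st, now = 15 * 60, cfg)$reason, "MAX_DAILY")
})

test_that("a day away from green spaces delivers exactly 1 STEP + 2 BCT", {
  roster <- build_roster(gen_preference_responses(1, seed = 2))
  lib <- gen_message_library(per_pool = 2)
  park <- one_space()
  trk <- dwell_track("u001", "2026-01-05", 53.0, 5.5) # ~70 km from the park
  sim <- run_simulation(roster, lib, park, days = 1, tracks = trk, seed = 10)
  del <- sim$log[sim$log$kind == "DELIVERY", ]
  expect_equal(nrow(del), 3)
  expect_equal(sum(del$channel == "STEP"), 1)
  expect_equal(sum(grepl("^BCT", del$channel)), 2)
  # each inside its scheduled window
  expect_true(del$minute[del$channel == "BCT-morning"] %in% 480:539)
  expect_true(del$minute[del$channel == "STEP"] %in% 690:749)
  expect_true(del$minute[del$channel == "BCT-evening"] %in% 960:1079)
})

test_that("continuous geofence dwell is capped at 3 prompts >= 4 h apart", {
  roster <- build_roster(gen_preference_responses(1, seed = 2))
  lib <- gen_message_library(per_pool = 2)
  park <- one_space()
  trk <- dwell_track("u001", "2026-01-05", park$lat, park$lon)
  sim <- run_simulation(roster, lib, park, days = 1, tracks = trk, seed = 10)
  del <- sim$log[sim$log$kind == "DELIVERY", ]
  geo <- del[del$channel == "GEO", ]
  expect_equal(nrow(del), 6) # 3 scheduled + 3 geolocation
  expect_equal(nrow(geo), 3)
  expect_true(all(diff(sort(geo$minute)) >= 240))
  expect_true(all(geo$minute >= 480 & geo$minute < 1200))
  # denials are logged with their reasons
  skips <- sim$log[sim$log$kind == "SKIP", ]
  expect_setequal(unique(skips$reason), c("WINDOW", "MIN_GAP", "MAX_DAILY"))
  # rendered prompt names the green-space type
  expect_true(all(grepl("park", geo$text)))
})

test_that("an empty GEO pool yields logged NO_ELIGIBLE events, not deliveries", {
  roster <- build_roster(gen_preference_responses(1, seed = 2))
  lib_no_geo <- message_library(
    dplyr::filter(tibble::as_tibble(gen_message_library(2)), category != "GEO"))
  park <- one_space()
  trk <- dwell_track("u001", "2026-01-05", park$lat, park$lon)
  sim <- run_simulation(roster, lib_no_geo, park, days = 1, tracks = trk, seed = 10)
  expect_equal(sum(sim$log$kind == "DELIVERY" & sim$log$channel == "GEO"), 0)
  geo_skips <- sim$log[sim$log$channel == "GEO", ]
  expect_true(any(geo_skips$reason == "NO_ELIGIBLE_MESSAGE"))
  # in-window skips never deplete the cap: every in-window hit is logged
  expect_equal(sum(geo_skips$reason == "NO_ELIGIBLE_MESSAGE"), 360)
})

test_that("stale step data sends the LOW message, flagged, never skipped", {
  roster <- build_roster(gen_preference_responses(1, seed = 2))
  lib <- gen_message_library(per_pool = 2)
  park <- one_space()
  trk <- dwell_track("u001", "2026-01-05", 53.0, 5.5)
  sim <- run_simulation(roster, lib, park, days = 1, tracks = trk,
                        scenario = scenario_params(n_users = 1, stale_fault = TRUE),
                        seed = 10)
  step <- sim$log[sim$log$channel == "STEP", ]
  expect_equal(step$kind, "DELIVERY")
  expect_true(step$stale_steps)
  expect_true(grepl("stratum=LOW", step$context))
})

test_that("scheduled and geofence ticks sharing a minute process scheduled first", {
  roster <- build_roster(gen_preference_responses(1, seed = 2))
  lib <- gen_message_library(per_pool = 2)
  park <- one_space()
  trk <- dwell_track("u001", "2026-01-05", park$lat, park$lon)
  sim <- run_simulation(roster, lib, park, days = 1, tracks = trk, seed = 10)
  log <- sim$log
  shared <- intersect(log$minute[log$channel %in% c("STEP", "BCT-morning", "BCT-evening")],
                      log$minute[log$channel == "GEO"])
  for (m in shared) {
    rows <- which(log$minute == m)
    expect_true(log$channel[rows[1]] != "GEO")
  }
})

test_that("safety properties hold across seeds and days", {
  # scaled to 12 seeds x 7 days here; the acceptance suite runs the full sweep
  roster <- build_roster(gen_preference_responses(1, seed = 2))
  lib <- gen_message_library(per_pool = 2)
  park <- one_space()
  dates <- as.Date("2026-01-05") + 0:6
  trk <- dwell_tracks("u001", dates, park$lat, park$lon)
  for (s in 1:12) {
    sim <- run_simulation(roster, lib, park, days = 7, tracks = trk, seed = s)
    del <- sim$log[sim$log$kind == "DELIVERY", ]
    geo <- del[del$channel == "GEO", ]
    per_day <- table(geo$date)
    expect_true(all(per_day <= 3))
    expect_true(all(geo$minute >= 480 & geo$minute < 1200))
    absm <- sort(as.integer(geo$date - as.Date("2026-01-05")) * 1440L + geo$minute)
    if (length(absm) > 1) expect_true(all(diff(absm) >= 240))
    per_day_sched <- summarize_deliveries(sim)
    expect_true(all(per_day_sched$step == 1))
    expect_true(all(per_day_sched$bct == 2))
  }
})

test_that("identical seeds replay to a byte-identical delivery log", {
  roster <- build_roster(gen_preference_responses(3, seed = 5))
  lib <- gen_message_library(per_pool = 2)
  db <- gen_green_spaces(4, seed = 5)
  sim1 <- run_simulation(roster, lib, db, days = 3, seed = 77)
  sim2 <- run_simulation(roster, lib, db, days = 3, seed = 77)
  expect_identical(sim1$log, sim2$log)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_delivery_log(sim1, f1); write_delivery_log(sim2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed differs
  sim3 <- run_simulation(roster, lib, db, days = 3, seed = 78)
  expect_false(identical(sim1$log, sim3$log))
})

test_that("geofence evaluations run at the configured 2-minute cadence", {
  roster <- build_roster(gen_preference_responses(1, seed = 2))
  lib <- gen_message_library(per_pool = 1)
  park <- one_space()
  trk <- dwell_track("u001", "2026-01-05", park$lat, park$lon)
  sim <- run_simulation(roster, lib, park, days = 1, tracks = trk, seed = 1,
                        log_evaluations = TRUE)
  gaps <- diff(sort(sim$evaluations$minute))
  modal <- as.integer(names(which.max(table(gaps))))
  expect_equal(modal, 2L)
  expect_equal(nrow(sim$evaluations), 720)
})

test_that("the delivery log serialises to JSONL and summarises per user-day", {
  roster <- build_roster(gen_preference_responses(2, seed = 5))
  lib <- gen_message_library(per_pool = 2)
  db <- gen_green_spaces(3, seed = 5)
  sim <- run_simulation(roster, lib, db, days = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_delivery_log(sim, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(sim$log))
  first <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("ts", "user_id", "kind", "channel") %in% names(first)))
  summ <- summarize_deliveries(sim)
  expect_equal(nrow(summ), 4) # 2 users x 2 days
  expect_true(all(summ$total >= 3))
})
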