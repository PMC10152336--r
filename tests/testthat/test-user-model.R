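test_that("preference scoring maps -1/0/+1 to 1/5/10 elementwise", {
  resp <- make_profile()[1:2]
  for (tag in bct_preference_tags()) resp[[paste0("bct_", tag)]] <- 0L
  resp$bct_action_planning <- -1L
  resp$bct_reward <- 1L
  scored <- score_preferences(resp)
  expect_equal(scored$bct_action_planning, 1L)
  expect_equal(scored$bct_reward, 10L)
  expect_true(all(unlist(scored[paste0("bct_", bct_preference_tags()[3:10])]) == 5L))

  # bijection on each coordinate
  for (v in c(-1L, 0L, 1L)) {
    r <- resp
    r$bct_goal_setting <- v
    expect_equal(score_preferences(r)$bct_goal_setting,
                 c(`-1` = 1L, `0` = 5L, `1` = 10L)[[as.character(v)]])
  }
})

test_that("invalid survey responses error naming the BCT", {
  resp <- make_profile()[1:2]
  for (tag in bct_preference_tags()) resp[[paste0("bct_", tag)]] <- 0L
  resp$bct_social_support <- 2L
  expect_error(score_preferences(resp), "social_support")
})

test_that("step strata partition the counts with bounds 2000/2001 and 6000/6001", {
  expect_equal(as.character(classify_step_stratum(c(0, 2000, 2001, 6000, 6001))),
               c("LOW", "LOW", "MID", "MID", "HIGH"))
  # brute force: exactly one stratum per count, boundaries as stated
  x <- 0:20000
  s <- classify_step_stratum(x)
  expect_false(any(is.na(s)))
  expect_equal(max(x[s == "LOW"]), 2000)
  expect_equal(min(x[s == "MID"]), 2001)
  expect_equal(max(x[s == "MID"]), 6000)
  expect_equal(min(x[s == "HIGH"]), 6001)
  expect_error(classify_step_stratum(-1))
})

test_that("goal evaluation flips at the 7000-step minimum and is monotone", {
  expect_false(goal_met(6999))
  expect_true(goal_met(7000))
  expect_false(goal_met(0))
  g <- goal_met(0:10000)
  expect_true(all(diff(g) >= 0)) # monotone nondecreasing
})

test_that("step store enforces per-day cumulative monotonicity", {
  d <- as.Date("2026-01-05")
  st <- step_store()
  st <- record_step_update(st, tibble::tibble(
    user_id = "u1", date = d, time = c(600L, 660L), steps = c(1200L, 1500L),
    sensor = "pedometer"))
  expect_equal(nrow(st), 2)

  # decreasing count on the same day is rejected, store unchanged for it
  expect_warning(
    st2 <- record_step_update(st, tibble::tibble(
      user_id = "u1", date = d, time = 720L, steps = 900L,
      sensor = "pedometer")),
    "monotonicity"
  )
  expect_equal(nrow(st2), 2)
  rej <- attr(st2, "rejected")
  expect_equal(rej$reason, "MONOTONICITY")
  expect_equal(rej$steps, 900L)

  # a new day restarts the cumulative series at any value
  st3 <- record_step_update(st, tibble::tibble(
    user_id = "u1", date = c(d, d + 1), time = c(1380L, 30L),
    steps = c(9000L, 100L), sensor = "pedometer"))
  expect_equal(nrow(st3), 4)
  # oracle: per-day grouping of the series
  by_day <- split(st3$steps, st3$date)
  expect_true(all(vapply(by_day, function(s) all(diff(s) >= 0), logical(1))))
})

test_that("steps_for_day returns latest count, or the (0, stale) fallback", {
  d <- as.Date("2026-01-05")
  st <- record_step_update(step_store(), tibble::tibble(
    user_id = "u1", date = d, time = c(600L, 660L), steps = c(1200L, 1500L),
    sensor = "accelerometer"))
  expect_equal(steps_for_day(st, "u1", d),
               tibble::tibble(steps = 1500L, stale = FALSE))
  expect_equal(steps_for_day(st, "u1", d + 1),
               tibble::tibble(steps = 0L, stale = TRUE))
  expect_equal(steps_for_day(step_store(), "u1", d)$stale, TRUE)
  expect_error(steps_for_day(st, "nobody", d, known_users = "u1"), "unknown user")
})

test_that("step store replay is idempotent per timestamp", {
  recs <- gen_step_trajectory(scenario_params(), as.Date("2026-01-05"), seed = 3)
  st1 <- record_step_update(step_store(), recs)
  st2 <- record_step_update(step_store(), recs)
  latest <- function(st) steps_for_day(st, "u001", as.Date("2026-01-05"))
  expect_identical(latest(st1), latest(st2))
})

test_that("preferences round-trip through CSV and build a roster", {
  resp <- gen_preference_responses(4, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_preferences(resp, path)
  back <- read_preferences(path)
  expect_equal(as.data.frame(back), as.data.frame(resp))
  roster <- build_roster(back)
  expect_equal(roster$step_goal_min, rep(7000L, 4))
  expect_true(all(unlist(roster[paste0("bct_", bct_preference_tags())]) %in%
                    c(1L, 5L, 10L)))
  # duplicate ids refuse to build
  expect_error(build_roster(dplyr::bind_rows(resp, resp[1, ])), "unique")
})
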