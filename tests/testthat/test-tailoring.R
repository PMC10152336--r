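test_that("weighted subsets validate input and exhaust small pools", {
  expect_error(weighted_subset(c("a", "b"), c(1, 0), 1), "positive")
  expect_error(weighted_subset(c("a", "b"), c(1, -2), 1), "positive")
  expect_error(weighted_subset("a", c(1, 2), 1), "equal length")
  set.seed(1)
  expect_setequal(weighted_subset(c("a", "b"), c(10, 1), k = 2), c("a", "b"))
  expect_setequal(weighted_subset(c("a", "b"), c(10, 1), k = 5), c("a", "b"))
})

test_that("first-draw selection probability is proportional to weight", {
  # analytic: P(first item) = 10/11 with weights 10:1
  set.seed(2024)
  n <- 1e5
  first <- character(n)
  for (i in seq_len(n)) first[i] <- weighted_subset(c("hi", "lo"), c(10, 1), 1)
  expect_equal(mean(first == "hi"), 10 / 11, tolerance = 0.01 / (10 / 11))
})

test_that("equal weights give uniform selection (chi-square)", {
  set.seed(7)
  ids <- sprintf("m%02d", 1:8)
  draws <- replicate(2e4, weighted_subset(ids, rep(1, 8), 1))
  tab <- table(factor(draws, levels = ids))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("step-feedback selection filters by stratum and renders the count", {
  lib <- gen_message_library(per_pool = 2)
  prof <- make_profile()
  set.seed(3)
  out <- select_step_message(lib, prof, steps = 4321)
  expect_equal(out$reason, "SELECTED")
  expect_equal(out$trace$stratum, "MID")
  expect_true(grepl("4321", out$rendered_text))
  expect_true(grepl("Anna", out$rendered_text))
  expect_true(startsWith(out$message_id, "step_mid"))

  out <- select_step_message(lib, prof, steps = 1500)
  expect_true(startsWith(out$message_id, "step_low"))
  # stale data falls back to the LOW pool at zero steps
  out <- select_step_message(lib, prof, steps = 9999, stale = TRUE)
  expect_equal(out$trace$stratum, "LOW")
  expect_true(grepl("\\b0\\b", out$rendered_text))
  # no STEP templates at all -> logged non-event
  bct_only <- message_library(dplyr::filter(tibble::as_tibble(lib),
                                            category == "BCT"))
  out <- select_step_message(bct_only, prof, steps = 4321)
  expect_equal(out$reason, "NO_ELIGIBLE_MESSAGE")
  expect_null(out$message_id)
})

test_that("green-space prompts honour the type filter and ANY wildcard", {
  lib <- gen_message_library(per_pool = 1)
  prof <- make_profile(first_name = "Joris")
  set.seed(4)
  out <- select_geo_message(lib, prof, "park")
  expect_equal(out$reason, "SELECTED")
  expect_true(grepl("park", out$rendered_text))

  # forest request with park-only templates and no ANY -> no eligible message
  park_only <- message_library(dplyr::filter(
    tibble::as_tibble(lib), !(category == "GEO" & green_space_type != "park")))
  expect_equal(select_geo_message(park_only, prof, "forest")$reason,
               "NO_ELIGIBLE_MESSAGE")

  # an ANY-typed template is eligible for all three types
  any_geo <- tibble::as_tibble(lib)
  any_geo$green_space_type[any_geo$category == "GEO"] <- ""
  any_geo <- message_library(dplyr::filter(any_geo, category == "GEO") |> head(1))
  for (g in green_space_types()) {
    expect_equal(select_geo_message(any_geo, prof, g)$reason, "SELECTED")
  }
  expect_error(select_geo_message(lib, prof, "meadow"), "unknown green_space_type")
})

test_that("BCT selection respects slot/weekday restrictions and the 4-subset", {
  lib0 <- tibble::as_tibble(gen_message_library(per_pool = 1))
  lib0$allowed_weekdays[lib0$message_id == "bct_reward_01"] <- "Mon"
  lib0$allowed_slots[lib0$message_id == "bct_goal_setting_01"] <- "morning"
  lib <- message_library(lib0)
  prof <- make_profile()

  set.seed(5)
  ids_tue <- unique(replicate(200, {
    select_bct_message(lib, prof, "evening", "Tue")$message_id
  }))
  expect_false("bct_reward_01" %in% ids_tue)   # Mon-only excluded on Tuesday
  expect_false("bct_goal_setting_01" %in% ids_tue) # morning-only in the evening
  ids_mon <- unique(replicate(200, {
    select_bct_message(lib, prof, "morning", "Mon")$message_id
  }))
  expect_true("bct_reward_01" %in% ids_mon)

  # one eligible message: the subset is the pool and it is selected
  single <- message_library(lib0[lib0$message_id == "bct_reward_01", ])
  out <- select_bct_message(single, prof, "morning", "Mon")
  expect_equal(out$message_id, "bct_reward_01")
  expect_equal(out$trace$subset_ids, "bct_reward_01")
  # empty pool
  expect_equal(select_bct_message(single, prof, "morning", "Tue")$reason,
               "NO_ELIGIBLE_MESSAGE")

  # the subset has at most 4 members and feeds the final uniform choice
  out <- select_bct_message(lib, prof, "evening", "Wed")
  expect_lte(length(out$trace$subset_ids), 4)
  expect_true(out$message_id %in% out$trace$subset_ids)
})

test_that("selected messages always satisfy every active filter", {
  lib <- gen_message_library(per_pool = 2)
  prof <- make_profile(scores = c(10L, rep(1L, 9)))
  set.seed(6)
  for (i in 1:50) {
    steps <- sample(0:10000, 1)
    out <- select_step_message(lib, prof, steps)
    row <- lib[lib$message_id == out$message_id, ]
    expect_equal(row$category, "STEP")
    expect_true(row$stratum %in%
                  c(as.character(classify_step_stratum(steps)), "ANY"))
    g <- sample(green_space_types(), 1)
    out <- select_geo_message(lib, prof, g)
    row <- lib[lib$message_id == out$message_id, ]
    expect_equal(row$category, "GEO")
    expect_true(row$green_space_type %in% c(g, "ANY"))
    wd <- sample(c("Mon", "Tue", "Sun"), 1)
    out <- select_bct_message(lib, prof, "morning", wd)
    row <- lib[lib$message_id == out$message_id, ]
    expect_equal(row$category, "BCT")
    expect_true(grepl(wd, row$allowed_weekdays))
  }
})

test_that("same seed and inputs give an identical outcome sequence", {
  lib <- gen_message_library(per_pool = 3)
  prof <- make_profile(scores = rep(c(1L, 5L, 10L), length.out = 10))
  run <- function() {
    set.seed(123)
    lapply(1:20, function(i) {
      list(
        s = select_step_message(lib, prof, i * 400)$message_id,
        g = select_geo_message(lib, prof, "forest")$message_id,
        b = select_bct_message(lib, prof, "evening", "Fri")$message_id
      )
    })
  }
  expect_identical(run(), run())
})
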