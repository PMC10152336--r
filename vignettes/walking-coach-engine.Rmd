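---
title: "The tailored walking-coach engine: model, rules and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The tailored walking-coach engine: model, rules and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkcoach)
library(dplyr)
```

## What the engine does

walkcoach implements the server side of an individually tailored
text-message intervention that coaches adults toward a guideline walking
goal of 7000–8000 steps per day. Three tailoring parameters drive message
choice:

1. **Step count.** The phone syncs a cumulative daily step count every
   hour. At a random midday minute the engine sends feedback matched to the
   user's current performance stratum: LOW (≤ 2000 steps), MID (2001–6000)
   or HIGH (≥ 6001).
2. **Geolocation.** Every 2 minutes the device compares its position with a
   database of green spaces (parks, forests, walking trails). Inside a
   300 m geofence the engine may send a contextual walking prompt naming
   the green-space type — at most 3 per day, never two within 4 hours, and
   only between 08:00 and 20:00. Only the matched space and a timestamp are
   recorded, never the user's coordinates.
3. **BCT preferences.** At baseline users rate ten types of coaching
   message — one per behaviour change technique (BCT), e.g. goal setting,
   social comparison, barrier identification — on a −1/0/+1 scale, scored
   1/5/10. Each morning (08:00–09:00) and evening (16:00–18:00) the engine
   selects a BCT message.

Selection is **elimination-based**: the library is filtered by channel,
then by context (stratum, green-space type, weekday/time restrictions),
and a random choice is made from the surviving pool. On the BCT channel
the choice is taken in two stages: a subset of 4 messages is drawn by
successive sampling *without replacement with probability proportional to
the user's preference score* for each message's BCT, then one of the 4 is
chosen uniformly. Proportionality is exact for the first draw and very
nearly exact for the whole procedure when the pool is large relative to 4:
with 100 messages tagged at score 10 and 100 at score 1, the measured
per-message frequency ratio is ≈ 10, matching the design intent that a
score-10 message be ten times likelier than a score-1 message. Whether the
original two-stage scheme (subset then uniform pick) was meant to preserve
that proportionality exactly is unknowable from the design documents; we
implement the literal procedure and verify the ratio empirically.

## The scheduler and its rules

The simulated clock runs at 1-minute resolution; all windows are half-open
`[start, end)` because the design states wall-clock bounds only. The day
boundary is local midnight of an abstract local clock — no time zones or
DST, which the simulation does not need. When a scheduled tick and a
geofence tick fall on the same minute, the scheduled message is processed
first.

Rate limiting for geolocation prompts is measured
**delivery-to-delivery**: a denied attempt does not reset the 4-hour gap,
and an attempt that finds no eligible message does not consume the daily
cap. The cap counter resets at midnight; the gap is carried across
midnight (two deliveries 3 hours apart around midnight would violate it,
and the engine prevents that). Denials (`WINDOW`, `MAX_DAILY`, `MIN_GAP`)
and empty-pool outcomes (`NO_ELIGIBLE_MESSAGE`) are logged even though a
production system would be silent — the delivery log is the engine's test
surface. The transport layer (a messaging app in production) is abstracted
to a JSON-lines sink.

If the step store has no record for the current day at feedback time — a
fault observed in piloting, where a device's date stopped advancing — the
engine does not skip the contact: it sends the LOW-stratum message for 0
steps and flags the log entry `stale_steps = TRUE`, making the fault
observable downstream.

One deliberate asymmetry is preserved from the design: the daily goal is
7000–8000 steps but the top feedback stratum already starts at 6001 steps.
Both are implemented exactly as stated; [goal_met()] evaluates only the
7000 minimum (the upper bound has no defined behaviour and is kept as
metadata).

## Geometry

Distances are haversine great-circle distances on a sphere of mean radius
6 371 008.8 m; at the 300 m geofence scale the spherical error is far
below a meter, so no ellipsoidal geodesy is warranted. The geofence
boundary is **inclusive** (`distance ≤ radius` is a hit) — the design does
not say, so we chose inclusivity and document it; ties between equidistant
spaces break to the lexicographically smallest `space_id` for determinism.
Synthetic positions at exact distances are built with the spherical
destination-point construction ([destination_point()]), which is how the
tests bisect the hit/miss threshold to 300 ± 1 m.

## The synthetic world

The generators stand in for the mobile apps and the human cohort; their
defaults are one stated world, chosen once:

* **Step accrual** (`gen_step_trajectory()`): a Poisson number of walking
  bouts per day (mean 6) at uniform times, each of lognormal size
  (median 700 steps, `sdlog` 0.5), over a deterministic background drift
  of 50 steps/hour. The design documents no generative model; this one was
  chosen because it produces realistic right-skewed daily totals (mean
  ≈ 6000, most days short of the 7000 goal, as expected for the target
  population) and has closed-form moments
  (`bouts * exp(meanlog + sdlog²/2) + 24 * background`) that the tests
  check. Counts are emitted as hourly cumulative syncs, the way the phone
  reports them.
* **GPS tracks** (`gen_gps_track()`): piecewise-linear minute-resolution
  walks through random waypoints within 800 m of home; with probability
  `dwell_near_green` (default 0.3) one waypoint is placed within 100 m of
  a green space so the track crosses the geofence. This is not a
  human-mobility model — no roads, no dwell-time realism — so green tests
  establish rule correctness (caps, gaps, windows, filters), not
  behavioural realism.
* **Preferences** (`gen_preference_responses()`): i.i.d. uniform over
  {−1, 0, +1} per item by default.
* **Message library** (`gen_message_library()`): English fixture texts
  seeded from the intervention's published example messages, one pool per
  STEP stratum, green-space type and BCT tag. Real libraries are larger
  (hundreds of messages) and curated for a ~20–30-word house style and a
  B1 reading level; the package replaces readability testing with
  word-count linting only, and the lint is a warning because the length
  bound is approximate by design.

All generators are pure functions of (parameters, seed) and replay
bitwise-identically; `run_simulation()` derives every random draw from its
single `seed`, so a whole simulation replays to a byte-identical delivery
log.

## Numerical and design choices

* Scheduled times are drawn uniformly over whole minutes, start inclusive,
  end exclusive; they are re-drawn each day (the design is ambiguous
  between per-day and fixed times; per-day drawing was chosen as the
  literal reading of "every day at a random time").
* Empty candidate pools are logged non-events, never exceptions.
* Survey loading replaces a survey UI: responses arrive "entered manually"
  as CSV.
* The daily refresh of the green-space list is modelled by re-reading the
  file at simulated midnight when `run_simulation()` is given a path.
* No cross-day repeat suppression: message diversity comes only from the
  random choice among the 4-subset, as designed.
* No dynamic re-weighting of preferences (a named future direction), no
  polygon geofences, no real transport or push notifications.

## A small end-to-end run

```{r example}
roster <- build_roster(gen_preference_responses(2, seed = 7))
lib <- gen_message_library(per_pool = 2)
spaces <- gen_green_spaces(4, seed = 7)

sim <- run_simulation(roster, lib, spaces, days = 3, seed = 42)
glance(sim)
summarize_deliveries(sim)
tidy(sim) |>
  filter(kind == "DELIVERY") |>
  select(ts, user_id, channel, text) |>
  head(4)
```

Every user-day shows exactly one STEP and two BCT deliveries; GEO prompts
appear only on days a track crosses a geofence, never more than 3 and
never closer than 4 hours. `autoplot(sim)` draws the delivery timeline.

## Known limitations

The simulator's mobility and step models are deliberately simple; the
engine's statistical guarantees (the ×10 preference ratio, uniformity
under equal weights) are asymptotic Monte-Carlo statements checked at
10^4–10^5 draws; and the word-count lint is a crude stand-in for a proper
readability assessment. None of these affect the rule logic, which is
exercised exhaustively by the property suites.
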