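# Shared fixtures, built in code at test time.

# a one-row profile with chosen scores for all ten preference BCTs
make_profile <- function(first_name = "Anna", scores = 5L, user_id = "u001") {
  cols <- paste0("bct_", bct_preference_tags())
  if (length(scores) == 1L) scores <- rep(scores, length(cols))
  out <- tibble::tibble(user_id = user_id, first_name = first_name)
  for (i in seq_along(cols)) out[[cols[i]]] <- as.integer(scores[i])
  out$step_goal_min <- 7000L
  out$step_goal_max <- 8000L
  out
}

# a single green space at a fixed reference point
one_space <- function(lat = 52.36, lon = 4.90, type = "park", id = "gs001") {
  tibble::tibble(space_id = id, name = "test space", type = type,
                 lat = lat, lon = lon)
}

# a full-day minute track pinned to one position
dwell_track <- function(user_id, date, lat, lon) {
  tibble::tibble(user_id = user_id, date = as.Date(date), minute = 0:1439,
                 lat = lat, lon = lon)
}

# minute tracks for several users/days at one position
dwell_tracks <- function(user_ids, dates, lat, lon) {
  grid <- expand.grid(user_id = user_ids, date = as.Date(dates),
                      stringsAsFactors = FALSE)
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    dwell_track(grid$user_id[i], grid$date[i], lat, lon)
  }))
}

# independent distance oracle: spherical law of cosines, same mean radius
slc_distance_m <- function(lat1, lon1, lat2, lon2, R = 6371008.8) {
  to_rad <- pi / 180
  d <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  R * acos(pmin(1, pmax(-1, d)))
}

# brute-force linear-scan proximity oracle
brute_nearest <- function(lat, lon, spaces, radius_m) {
  d <- slc_distance_m(lat, lon, spaces$lat, spaces$lon)
  ok <- which(d <= radius_m)
  if (length(ok) == 0) return(NULL)
  ok[order(d[ok], spaces$space_id[ok])][1]
}
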