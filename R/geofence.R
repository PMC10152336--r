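# Green-space geofence: haversine distances on the mean Earth radius and a
# nearest-within-radius proximity check. At the 300 m scale of the geofence,
# spherical error versus an ellipsoid is far below a meter.

EARTH_RADIUS_M <- 6371008.8

.check_coords <- function(lat, lon) {
  if (any(is.na(lat)) || any(is.na(lon)) ||
      any(lat < -90 | lat > 90) || any(lon < -180 | lon > 180)) {
    abort("coordinates must satisfy lat in [-90, 90], lon in [-180, 180]")
  }
}

#' Great-circle distance in meters
#'
#' Haversine distance on a sphere of mean radius 6 371 008.8 m. Vectorised
#' and recycled over its arguments.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees.
#' @return Numeric vector of distances in meters.
#' @export
#' @examples
#' haversine_m(0, 0, 0, 1) # one degree of longitude at the equator
haversine_m <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Destination point along a bearing
#'
#' Spherical direct geodesic: the point `distance_m` meters from
#' `(lat, lon)` along an initial bearing. Used to construct synthetic
#' positions at known distances (e.g. geofence threshold bisection, GPS
#' track waypoints).
#'
#' @param lat,lon Start point, WGS84 decimal degrees.
#' @param bearing_deg Initial bearing, degrees clockwise from north.
#' @param distance_m Distance in meters.
#' @return A tibble with columns `lat`, `lon`.
#' @export
#' @examples
#' destination_point(52.36, 4.90, 0, 300) # 300 m due north
destination_point <- function(lat, lon, bearing_deg, distance_m) {
  .check_coords(lat, lon)
  to_rad <- pi / 180
  phi1 <- lat * to_rad
  lam1 <- lon * to_rad
  theta <- bearing_deg * to_rad
  delta <- distance_m / EARTH_RADIUS_M
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(sin(theta) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  tibble(lat = phi2 / to_rad,
         lon = ((lam2 / to_rad + 540) %% 360) - 180)
}

#' Read a green-space database
#'
#' Accepts either a CSV (`space_id, name, type, lat, lon`) or a GeoJSON
#' FeatureCollection of Point features with properties `space_id, name,
#' type`; both yield the identical in-memory table. `type` is a closed
#' enum: `park`, `forest` or `walking_trail`.
#'
#' @param path File path (`.csv`, `.json` or `.geojson`).
#' @return A tibble with columns `space_id, name, type, lat, lon`.
#' @export
read_green_spaces <- function(path) {
  if (!file.exists(path)) abort(paste0("green-space file not found: ", path))
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::read_json(path)
    if (is.null(gj$features)) abort("GeoJSON must be a FeatureCollection")
    df <- purrr::map_dfr(gj$features, function(f) {
      if (is.null(f$geometry) || !identical(f$geometry$type, "Point")) {
        abort("green-space GeoJSON features must be Points")
      }
      tibble(
        space_id = as.character(f$properties$space_id %||% NA_character_),
        name = as.character(f$properties$name %||% NA_character_),
        type = as.character(f$properties$type %||% NA_character_),
        lon = as.numeric(f$geometry$coordinates[[1]]),
        lat = as.numeric(f$geometry$coordinates[[2]])
      )
    })
    df <- df[c("space_id", "name", "type", "lat", "lon")]
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            space_id = readr::col_character(),
                            name = readr::col_character(),
                            type = readr::col_character(),
                            lat = readr::col_double(),
                            lon = readr::col_double()
                          ))
  }
  green_space_db(df)
}

#' @rdname read_green_spaces
#' @param spaces A green-space data frame to validate or write.
#' @export
green_space_db <- function(spaces) {
  df <- as_tibble(spaces)
  need <- c("space_id", "name", "type", "lat", "lon")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("green spaces missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df <- df[need]
  bad_type <- which(!df$type %in% .green_space_types)
  if (length(bad_type) > 0) {
    abort(sprintf("green space '%s': unknown type '%s'",
                  df$space_id[bad_type[1]], df$type[bad_type[1]]))
  }
  if (anyDuplicated(df$space_id) > 0) abort("space_id values must be unique")
  bad <- which(is.na(df$lat) | is.na(df$lon) |
                 df$lat < -90 | df$lat > 90 | df$lon < -180 | df$lon > 180)
  if (length(bad) > 0) {
    abort(sprintf("green space '%s': malformed coordinates", df$space_id[bad[1]]))
  }
  df
}

#' @rdname read_green_spaces
#' @export
write_green_spaces <- function(spaces, path) {
  spaces <- green_space_db(spaces)
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    features <- purrr::pmap(spaces, function(space_id, name, type, lat, lon) {
      list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(lon, lat)),
        properties = list(space_id = space_id, name = name, type = type)
      )
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = features),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    readr::write_csv(spaces, path)
  }
  invisible(path)
}

#' Proximity check against the green-space database
#'
#' Determines whether a position lies within `radius_m` (boundary
#' inclusive) of any green space, and if so returns the nearest one; ties
#' on distance break to the lexicographically smallest `space_id`. This is
#' the geofence the engine evaluates every 2 minutes. No user coordinates
#' are retained: the result carries only the matched space and its type
#' (the privacy contract of the intervention).
#'
#' @param lat,lon A single position, WGS84 decimal degrees.
#' @param spaces A green-space tibble ([green_space_db()]).
#' @param radius_m Geofence radius in meters (default 300).
#' @return A tibble with columns `space_id, name, type, distance_m`: one
#'   row on a hit, zero rows when no space is within radius (an empty
#'   database is a miss, not an error).
#' @export
#' @examples
#' db <- gen_green_spaces(3, seed = 1)
#' check_proximity(db$lat[1], db$lon[1], db)
check_proximity <- function(lat, lon, spaces, radius_m = 300) {
  stopifnot(length(lat) == 1, length(lon) == 1)
  if (radius_m <= 0) abort("radius_m must be positive")
  .check_coords(lat, lon)
  if (nrow(spaces) == 0) {
    return(tibble(space_id = character(), name = character(),
                  type = character(), distance_m = numeric()))
  }
  d <- haversine_m(lat, lon, spaces$lat, spaces$lon)
  within <- which(d <= radius_m)
  if (length(within) == 0) {
    return(tibble(space_id = character(), name = character(),
                  type = character(), distance_m = numeric()))
  }
  ord <- within[order(d[within], spaces$space_id[within])]
  i <- ord[1]
  tibble(space_id = spaces$space_id[i], name = spaces$name[i],
         type = spaces$type[i], distance_m = d[i])
}

# Vectorised geofence over a track: for positions (lat[i], lon[i]) return
# the index of the nearest in-radius space (ties by space_id) or NA.
# Hot path of the scheduler; returns an integer vector.
.proximity_index <- function(lat, lon, spaces, radius_m) {
  n <- length(lat)
  if (nrow(spaces) == 0) return(rep(NA_integer_, n))
  ord <- order(spaces$space_id)
  to_rad <- pi / 180
  phi <- lat * to_rad
  sphi <- spaces$lat[ord] * to_rad
  slam <- spaces$lon[ord] * to_rad
  best <- rep(NA_integer_, n)
  best_d <- rep(Inf, n)
  for (j in seq_along(ord)) {
    a <- sin((sphi[j] - phi) / 2)^2 +
      cos(phi) * cos(sphi[j]) * sin((slam[j] - lon * to_rad) / 2)^2
    d <- 2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
    upd <- d <= radius_m & d < best_d   # strict: earlier (smaller id) wins ties
    best[upd] <- ord[j]
    best_d[upd] <- d[upd]
  }
  best
}
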