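# Shared fixtures, all generated in code.

# Minimal track table.
toy_track <- function(time, lon, lat, id = "a") {
  tibble::tibble(animal_id = id, time = time, lon = lon, lat = lat)
}

# Write a telemetry CSV in the Movebank dialect; `rows` is a data frame with
# timestamp / lon / lat / id columns as character.
write_toy_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  names(rows) <- c("timestamp", "location-long", "location-lat",
                   "individual-local-identifier")
  readr::write_csv(rows, path, progress = FALSE)
  path
}

# Knot vector placing an interior knot at every interior observation time
# (the interpolation limit).
interp_knots <- function(times) {
  times <- sort(unique(times))
  structure(list(interior = times[-c(1, length(times))],
                 boundary = range(times), order = 4L),
            class = "knot_vector")
}

# Smooth two-coordinate sinusoid track sampled hourly, with optional noise.
sine_track <- function(duration = 10, noise = 0, seed = 1, id = "s",
                       amp = 0.1, period_lon = 2.5, period_lat = 2) {
  set.seed(seed)
  t <- seq(0, duration, by = 1 / 24)
  toy_track(t,
            lon = amp * cos(2 * pi * t / period_lon) + rnorm(length(t), 0, noise),
            lat = amp * sin(2 * pi * t / period_lat) + rnorm(length(t), 0, noise),
            id = id)
}

# Constant-position track observed hourly.
constant_track <- function(lon, lat, duration = 20, id = "c", start = 0) {
  t <- seq(start, start + duration, by = 1 / 24)
  toy_track(t, lon = rep(lon, length(t)), lat = rep(lat, length(t)), id = id)
}

# Default-workflow fit: density-guided knots + GCV-tuned penalties.
fit_default <- function(tr) {
  kn <- select_knots(tr$time)
  tu <- tune_smoothing(tr, knots = kn)
  fit_track_spline(tr, knots = kn,
                   lambda_lon = tu$lambda_lon, lambda_lat = tu$lambda_lat)
}
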