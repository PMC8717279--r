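#' Local meters-per-degree scale factors on the WGS84 ellipsoid
#'
#' Converts degree rates to metric rates at a given latitude. The default
#' measures the geodesic length of a short (0.001 degree) meridian or
#' parallel arc centered at the point and scales up, so the factors inherit
#' the accuracy of the WGS84 geodesic. `method = "spherical"` uses the
#' familiar constants (111,132 m per degree latitude; 111,320 cos(lat) per
#' degree longitude) for cheap approximate work.
#'
#' @param lat Latitude(s) in degrees.
#' @param lon Longitude(s) in degrees (only the meridian/parallel location
#'   matters; default 0).
#' @param method `"geodesic"` (default) or `"spherical"`.
#' @return Tibble with `m_per_deg_lat`, `m_per_deg_lon`.
#' @export
meters_per_degree <- function(lat, lon = 0, method = c("geodesic", "spherical")) {
  method <- match.arg(method)
  if (any(abs(lat) > 90)) stop_domain("Latitude outside [-90, 90].")
  n <- max(length(lat), length(lon))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n)
  if (method == "spherical") {
    return(tibble(m_per_deg_lat = rep(111132, n),
                  m_per_deg_lon = 111320 * cos(lat * pi / 180)))
  }
  d <- 0.001
  lat_lo <- pmax(lat - d / 2, -90); lat_hi <- pmin(lat + d / 2, 90)
  mlat <- geosphere::distGeo(cbind(lon, lat_lo), cbind(lon, lat_hi)) / (lat_hi - lat_lo)
  mlon <- geosphere::distGeo(cbind(lon - d / 2, lat), cbind(lon + d / 2, lat)) / d
  tibble(m_per_deg_lat = mlat, m_per_deg_lon = mlon)
}

#' Estimated speed along a smoothed movement curve
#'
#' Differentiates the fitted spline path, converts the degree rates to metric
#' rates with per-point WGS84 scale factors at the fitted latitude, and
#' combines them as the Euclidean norm
#' \eqn{\hat x'(t) = \sqrt{\hat x_{lat}'(t)^2 + \hat x_{lon}'(t)^2}} (in
#' meters), rescaled from per-day to meters per second.
#'
#' @param model A `track_spline`.
#' @param times Optional explicit times (days); default the refined grid.
#' @param resolution Grid resolution in minutes when `times` is `NULL`.
#' @param method Degree-to-meter conversion, see [meters_per_degree()].
#' @return Tibble with `time`, `speed` (m/s).
#' @export
path_speed <- function(model, times = NULL, resolution = 60,
                       method = c("geodesic", "spherical")) {
  method <- match.arg(method)
  pos <- evaluate_path(model, times = times, resolution = resolution)
  der <- path_derivative(model, times = pos$time)
  sc <- meters_per_degree(pos$lat, pos$lon, method = method)
  vlat <- der$dlat * sc$m_per_deg_lat / 86400
  vlon <- der$dlon * sc$m_per_deg_lon / 86400
  tibble(time = pos$time, speed = sqrt(vlat^2 + vlon^2))
}

#' Classify rest times by a speed cutoff
#'
#' Binary rest/transit classification: a grid time is a rest time when the
#' estimated speed falls strictly below the cutoff (default 0.25 m/s, a
#' working definition of "resting or near-stationary" rather than literal
#' zero speed).
#'
#' @param speed Tibble from [path_speed()] (`time`, `speed`).
#' @param cutoff Speed cutoff in m/s (default 0.25).
#' @return The input with a logical `is_rest` column. An empty rest set is
#'   allowed (a message is emitted).
#' @export
classify_rest <- function(speed, cutoff = 0.25) {
  if (!is.data.frame(speed) || !all(c("time", "speed") %in% names(speed))) {
    stop_input("`speed` must have columns time, speed.")
  }
  if (!is.numeric(cutoff) || cutoff <= 0) stop_parameter("`cutoff` must be > 0.")
  out <- mutate(as_tibble(speed), is_rest = .data$speed < cutoff)
  if (!any(out$is_rest)) inform("No grid times classified as rest at this cutoff.")
  out
}

#' Kernel density of rest times
#'
#' Gaussian KDE over the rest-classified grid times. Bandwidths of a few days
#' to ~2 weeks resolve multi-day shifts in resting behavior; `"auto"` applies
#' Silverman's rule. An empty rest set yields an absent density
#' (see [time_density()]), not a zero density.
#'
#' @param rest Output of [classify_rest()], or a numeric vector of rest
#'   times.
#' @param bandwidth Days or `"auto"`.
#' @return A [time_density()] object (absent when no rest times).
#' @export
rest_density <- function(rest, bandwidth = "auto") {
  times <- if (is.data.frame(rest)) {
    if (!all(c("time", "is_rest") %in% names(rest))) {
      stop_input("`rest` must be classify_rest() output or a numeric vector.")
    }
    rest$time[rest$is_rest]
  } else {
    as.numeric(rest)
  }
  time_density(times, bandwidth = bandwidth)
}
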