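#' WGS84 geodesic distance between points
#'
#' Shortest ellipsoidal distance (Karney's algorithm via
#' [geosphere::distGeo()]) in meters. Vectorized over rows.
#'
#' @param p,q Matrices/data frames with columns (lon, lat) in decimal
#'   degrees, or length-2 vectors.
#' @return Distances in meters.
#' @examples
#' geodesic_distance(c(0, 0), c(0, 1))  # one degree of latitude, ~110574 m
#' @export
geodesic_distance <- function(p, q) {
  p <- coerce_lonlat(p); q <- coerce_lonlat(q)
  geosphere::distGeo(p, q)
}

coerce_lonlat <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = FALSE)
  if (ncol(x) != 2) stop_input("Coordinates must have two columns (lon, lat).")
  if (any(!is.finite(x)) || any(abs(x[, 2]) > 90) || any(abs(x[, 1]) > 180)) {
    stop_domain("Invalid coordinates: need finite lon in [-180, 180], lat in [-90, 90].")
  }
  x
}

#' Pairwise geodesic distance series on the shared refined grid
#'
#' Evaluates both fitted movement curves on the intersection of their domains
#' using the global anchored grid (so both animals are estimated at exactly
#' the same clock times) and returns the per-time WGS84 geodesic distance.
#'
#' @param model_a,model_b `track_spline` fits for the two animals.
#' @param resolution Grid resolution in minutes (default 60).
#' @return Tibble with `time`, `dist_m`, carrying attributes `pair` (the two
#'   animal ids) and `overlap` (the overlap window in days).
#' @export
distance_series <- function(model_a, model_b, resolution = 60) {
  stopifnot(inherits(model_a, "track_spline"), inherits(model_b, "track_spline"))
  lo <- max(model_a$domain[1], model_b$domain[1])
  hi <- min(model_a$domain[2], model_b$domain[2])
  if (!(lo < hi)) {
    stop_overlap(sprintf(
      "No overlap between monitoring domains [%.2f, %.2f] ('%s') and [%.2f, %.2f] ('%s').",
      model_a$domain[1], model_a$domain[2], model_a$animal_id,
      model_b$domain[1], model_b$domain[2], model_b$animal_id))
  }
  grid <- refined_grid(c(lo, hi), resolution = resolution, anchor = 0)
  if (length(grid) < 2) {
    stop_overlap("Fewer than 2 shared grid points in the overlap window.")
  }
  pa <- evaluate_path(model_a, times = grid)
  pb <- evaluate_path(model_b, times = grid)
  out <- tibble(time = grid,
                dist_m = geosphere::distGeo(cbind(pa$lon, pa$lat),
                                            cbind(pb$lon, pb$lat)))
  attr(out, "pair") <- c(model_a$animal_id, model_b$animal_id)
  attr(out, "overlap") <- c(lo, hi)
  attr(out, "resolution") <- resolution
  out
}

#' Cooccurrence potential of a pair
#'
#' Restricts the shared grid to times where the pair's geodesic distance is
#' strictly below the threshold `delta` and estimates a Gaussian KDE over
#' those times: the cooccurrence potential, a density over study time that is
#' high in windows offering many opportunities for interaction. With no
#' qualifying times the potential is absent (zero cooccurrence), flagged
#' rather than reported as a zero function.
#'
#' @param dist Distance series from [distance_series()].
#' @param delta Distance threshold in meters (default 1800).
#' @param bandwidth KDE bandwidth in days or `"auto"` (Silverman on the
#'   cooccurring times).
#' @return Object of class `cooccurrence`: list with `pair`, `delta`,
#'   `co_times` (tibble `time`, `dist_m`), `n_co`, `fraction` (share of grid
#'   time within `delta`), `potential` (a [time_density()], absent when
#'   `n_co == 0`), `window`.
#' @export
cooccurrence_potential <- function(dist, delta = 1800, bandwidth = "auto") {
  if (!is.data.frame(dist) || !all(c("time", "dist_m") %in% names(dist))) {
    stop_input("`dist` must be a distance series with columns time, dist_m.")
  }
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0) {
    stop_parameter("`delta` must be a positive distance in meters.")
  }
  co <- filter(as_tibble(dist), .data$dist_m < delta)
  pot <- if (nrow(co) == 0) {
    time_density(numeric(0))
  } else if (identical(bandwidth, "auto") && length(unique(co$time)) < 2) {
    time_density(co$time, bandwidth = 1)  # single time: 1-day fallback bandwidth
  } else {
    time_density(co$time, bandwidth = bandwidth)
  }
  structure(list(
    pair = attr(dist, "pair"),
    delta = delta,
    co_times = co,
    n_co = nrow(co),
    n_grid = nrow(dist),
    fraction = nrow(co) / nrow(dist),
    potential = pot,
    window = attr(dist, "overlap") %||% range(dist$time)
  ), class = "cooccurrence")
}

#' @export
#' @method print cooccurrence
print.cooccurrence <- function(x, ...) {
  pair <- paste(x$pair %||% c("?", "?"), collapse = " vs ")
  cat(sprintf("<cooccurrence %s: delta = %.0f m, %d/%d grid times within (%.1f%%)>\n",
              pair, x$delta, x$n_co, x$n_grid, 100 * x$fraction))
  if (is_empty_density(x$potential)) cat("  potential: absent (zero cooccurrence)\n")
  invisible(x)
}

#' Test whether a pair had zero cooccurrence
#' @param x A `cooccurrence` object.
#' @return Logical scalar.
#' @export
is_zero_cooccurrence <- function(x) {
  stopifnot(inherits(x, "cooccurrence"))
  x$n_co == 0
}

#' @export
autoplot.cooccurrence <- function(object, resolution = 360, ...) {
  if (is_zero_cooccurrence(object)) {
    stop_input("No cooccurring times; nothing to plot.")
  }
  autoplot(object$potential, resolution = resolution) +
    ggplot2::labs(title = sprintf("Cooccurrence potential (delta = %.0f m)", object$delta),
                  y = "cooccurrence potential (1/day)")
}

#' Plot a pairwise distance series with the cooccurrence threshold
#'
#' @param dist Distance series from [distance_series()].
#' @param delta Threshold line in meters (default 1800).
#' @return A ggplot object.
#' @export
plot_distance_series <- function(dist, delta = 1800) {
  pair <- paste(attr(dist, "pair") %||% c("A", "B"), collapse = " vs ")
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$time, y = .data$dist_m)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = delta, color = "darkorange") +
    ggplot2::labs(x = "study time (days)", y = "distance (m)", title = pair)
}
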