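#' Density-guided knot selection
#'
#' Interior knots are placed at observation times whose sampled-time density
#' exceeds a threshold, expressed as a quantile of the density values at the
#' observation times, then thinned to a minimum spacing. This concentrates
#' basis flexibility where the monitoring record is dense and keeps the fit
#' stiff across multi-day gaps, where a flexible spline would oscillate.
#'
#' @param times Observation times (study days) for one animal, or a track
#'   table (in which case `animal` may select an individual).
#' @param density Optional precomputed [time_density()] of the times; default
#'   recomputes with `bandwidth`.
#' @param quantile Density-quantile threshold `q` in `[0, 1)`: times with
#'   density above the `q`-th quantile of the density values at the
#'   observation times are kept (at `q = 0` all times are kept). Default 0.05.
#' @param min_spacing Minimum spacing between interior knots in days
#'   (default 2 hours).
#' @param bandwidth Bandwidth for the density when not supplied.
#' @param animal Optional animal id for a multi-animal track table.
#' @return Object of class `knot_vector`: list with `interior`, `boundary`,
#'   `order` (fixed 4 = cubic).
#' @export
select_knots <- function(times, density = NULL, quantile = 0.05,
                         min_spacing = 2 / 24, bandwidth = "auto",
                         animal = NULL) {
  if (is.data.frame(times)) times <- one_track(times, animal)$time
  times <- sort(unique(as.numeric(times)))
  if (length(times) < 2) stop_input("Need at least 2 distinct times to place knots.")
  if (!is.numeric(quantile) || quantile < 0 || quantile >= 1) {
    stop_parameter("`quantile` must lie in [0, 1).")
  }
  if (is.null(density)) density <- time_density(times, bandwidth = bandwidth)
  f <- eval_density(density, times)
  if (quantile <= 0) {
    keep <- rep(TRUE, length(times))
  } else {
    k <- stats::quantile(f, probs = quantile, type = 7, names = FALSE)
    keep <- f > k
  }
  if (!any(keep)) {
    stop_parameter(paste0("All observation times fall at or below the density ",
                          "threshold; lower `quantile`."),
                   class = "trackfda_degenerate_knots_error")
  }
  boundary <- range(times)
  cand <- times[keep]
  cand <- cand[cand > boundary[1] & cand < boundary[2]]
  interior <- thin_knots(cand, min_spacing, boundary)
  structure(list(interior = interior, boundary = boundary, order = 4L),
            class = "knot_vector")
}

# Greedy left-to-right thinning to a minimum spacing, also enforcing the
# spacing against both boundary knots.
thin_knots <- function(x, min_spacing, boundary) {
  if (length(x) == 0) return(numeric(0))
  x <- sort(x)
  out <- numeric(0)
  last <- boundary[1]
  for (xi in x) {
    if (xi - last >= min_spacing && boundary[2] - xi >= min_spacing) {
      out <- c(out, xi)
      last <- xi
    }
  }
  out
}

#' @export
#' @method print knot_vector
print.knot_vector <- function(x, ...) {
  cat(sprintf("<knot_vector: %d interior knots on [%.3f, %.3f], order %d>\n",
              length(x$interior), x$boundary[1], x$boundary[2], x$order))
  invisible(x)
}

# Full knot sequence for splines::splineDesign (boundary knots repeated
# `order` times).
full_knots <- function(knots) {
  c(rep(knots$boundary[1], knots$order), knots$interior,
    rep(knots$boundary[2], knots$order))
}

n_basis <- function(knots) length(knots$interior) + knots$order

# Basis (or derivative) design matrix at given times. Sparse by default:
# B-spline designs have only `order` nonzeros per row, and sparse normal
# equations keep long tracks (thousands of knots) fast.
basis_matrix <- function(knots, t, deriv = 0L, sparse = TRUE) {
  splines::splineDesign(full_knots(knots), t, ord = knots$order,
                        derivs = rep(deriv, length(t)), sparse = sparse)
}

#' Second-derivative roughness penalty matrix by Riemann quadrature
#'
#' \eqn{R_{jk} = \sum_l \phi_j''(\tilde t_l)\, \phi_k''(\tilde t_l)\, h} on a
#' fine uniform grid \eqn{\tilde t} over the knot domain, with
#' `max(1000, 20 K)` quadrature points (K = number of basis functions).
#'
#' @param knots A `knot_vector`.
#' @param n_quad Number of quadrature points; default `max(1000, 20 * K)`.
#' @return Symmetric positive semi-definite K x K matrix (sparse
#'   [Matrix::Matrix()]).
#' @export
penalty_matrix <- function(knots, n_quad = NULL) {
  K <- n_basis(knots)
  n_quad <- n_quad %||% max(1000L, 20L * K)
  tg <- seq(knots$boundary[1], knots$boundary[2], length.out = n_quad)
  h <- tg[2] - tg[1]
  B2 <- basis_matrix(knots, tg, deriv = 2L)
  R <- Matrix::crossprod(B2) * h
  Matrix::forceSymmetric(R)
}

#' Fit a penalized B-spline movement model to one animal's track
#'
#' Latitude and longitude are smoothed separately on a shared cubic B-spline
#' basis: each coordinate solves the penalized least squares problem
#' \eqn{\min_c \|y - \Phi c\|^2 + \lambda c^\top R c} with the
#' second-derivative roughness penalty `R` from [penalty_matrix()], giving
#' \eqn{\hat c = (\Phi^\top\Phi + \lambda R)^{-1}\Phi^\top y}. The effective
#' degrees of freedom per coordinate is the trace of the smoother matrix.
#' A single tiny ridge jitter (`1e-10` times the mean diagonal) is applied if
#' the normal equations are numerically singular (e.g. the unpenalized
#' interpolation limit with more basis functions than observations); the fit
#' records whether this happened.
#'
#' @param tracks Track table; filtered to `animal` if given.
#' @param knots A `knot_vector` from [select_knots()]; default selects knots
#'   with the default density threshold.
#' @param lambda_lon,lambda_lat Nonnegative roughness penalties. Defaults 0
#'   (no penalty); use [tune_smoothing()] for GCV-guided values.
#' @param animal Optional animal id.
#' @param n_quad Quadrature points for the penalty matrix.
#' @return Object of class `track_spline`: fitted basis coefficients for both
#'   coordinates, knots, penalties, penalty matrix, per-coordinate effective
#'   degrees of freedom and residual summaries, the data domain and epoch.
#' @examples
#' tr <- simulate_track(seed = 1, duration = 20)
#' fit <- fit_track_spline(tr, lambda_lon = 1, lambda_lat = 1)
#' glance(fit)
#' @export
fit_track_spline <- function(tracks, knots = NULL, lambda_lon = 0,
                             lambda_lat = 0, animal = NULL, n_quad = NULL) {
  tr <- one_track(tracks, animal)
  if (!is.numeric(lambda_lon) || !is.numeric(lambda_lat) ||
      lambda_lon < 0 || lambda_lat < 0) {
    stop_parameter("Penalties must be nonnegative numbers.")
  }
  if (is.null(knots)) knots <- select_knots(tr$time)
  if (!inherits(knots, "knot_vector")) stop_input("`knots` must be a knot_vector.")
  if (min(tr$time) < knots$boundary[1] - 1e-12 ||
      max(tr$time) > knots$boundary[2] + 1e-12) {
    stop_domain("Observations fall outside the knot domain.")
  }
  t <- tr$time
  Phi <- basis_matrix(knots, t)
  R <- penalty_matrix(knots, n_quad = n_quad)
  flon <- solve_penalized(Phi, R, tr$lon, lambda_lon)
  flat <- solve_penalized(Phi, R, tr$lat, lambda_lat)

  structure(list(
    animal_id = tr$animal_id[1],
    knots = knots,
    coef = cbind(lon = flon$coef, lat = flat$coef),
    lambda = c(lon = lambda_lon, lat = lambda_lat),
    df = c(lon = flon$df, lat = flat$df),
    rss = c(lon = flon$rss, lat = flat$rss),
    penalty = R,
    n_obs = nrow(tr),
    domain = range(t),
    epoch = attr(tracks, "epoch"),
    jittered = flon$jittered || flat$jittered
  ), class = "track_spline")
}

# Penalized least squares for one coordinate: coefficients, effective df
# (trace of the smoother matrix) and RSS. A single ridge jitter of
# 1e-10 * mean(diag) rescues numerically singular normal equations (the
# unpenalized K >= n interpolation limit).
solve_penalized <- function(Phi, R, y, lambda, PtP = NULL, Pty = NULL) {
  PtP <- PtP %||% Matrix::crossprod(Phi)
  Pty <- Pty %||% Matrix::crossprod(Phi, y)
  A <- PtP + lambda * R
  jittered <- FALSE
  sol <- tryCatch(Matrix::solve(A, cbind(Pty, PtP)), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(sol)) {
    jittered <- TRUE
    A <- A + Matrix::Diagonal(nrow(A), 1e-10 * mean(Matrix::diag(A)))
    sol <- Matrix::solve(A, cbind(Pty, PtP))
  }
  sol <- as.matrix(sol)
  coef <- sol[, 1]
  df <- sum(diag(sol[, -1, drop = FALSE]))
  fitted <- as.numeric(Phi %*% coef)
  list(coef = coef, df = df, rss = sum((y - fitted)^2), jittered = jittered)
}

#' @export
#' @method print track_spline
print.track_spline <- function(x, ...) {
  cat(sprintf("<track_spline '%s': %d obs, %d basis fns on [%.2f, %.2f] days>\n",
              x$animal_id, x$n_obs, nrow(x$coef), x$domain[1], x$domain[2]))
  cat(sprintf("  lambda (lon, lat): %.3g, %.3g; df: %.1f, %.1f\n",
              x$lambda["lon"], x$lambda["lat"], x$df["lon"], x$df["lat"]))
  invisible(x)
}

#' @rdname fit_track_spline
#' @param x,object A `track_spline`.
#' @param ... Unused.
#' @export
tidy.track_spline <- function(x, ...) {
  tibble(term = rep(seq_len(nrow(x$coef)), 2),
         coordinate = rep(c("lon", "lat"), each = nrow(x$coef)),
         estimate = c(x$coef[, "lon"], x$coef[, "lat"]))
}

#' @rdname fit_track_spline
#' @export
glance.track_spline <- function(x, ...) {
  tibble(animal_id = x$animal_id, n_obs = x$n_obs, n_basis = nrow(x$coef),
         n_interior_knots = length(x$knots$interior),
         lambda_lon = unname(x$lambda["lon"]), lambda_lat = unname(x$lambda["lat"]),
         df_lon = unname(x$df["lon"]), df_lat = unname(x$df["lat"]),
         rmse_lon = sqrt(x$rss["lon"] / x$n_obs),
         rmse_lat = sqrt(x$rss["lat"] / x$n_obs),
         domain_start = x$domain[1], domain_end = x$domain[2])
}

#' Evaluate a fitted movement curve on a time grid
#'
#' Positions are the basis expansion at the requested times. The default grid
#' is the refined uniform grid at `resolution` minutes over the model domain,
#' anchored at study time 0 so all animals share one global grid.
#' Extrapolation outside the fitted domain is refused.
#'
#' @param model A `track_spline`.
#' @param times Optional explicit times (days); default the anchored refined
#'   grid.
#' @param resolution Grid resolution in minutes when `times` is `NULL`.
#' @return Tibble with `time`, `lon`, `lat`.
#' @export
evaluate_path <- function(model, times = NULL, resolution = 60) {
  stopifnot(inherits(model, "track_spline"))
  if (is.null(times)) {
    times <- model_grid(model, resolution)
  }
  times <- check_in_domain(model, times)
  B <- basis_matrix(model$knots, times)
  tibble(time = times,
         lon = as.numeric(B %*% model$coef[, "lon"]),
         lat = as.numeric(B %*% model$coef[, "lat"]))
}

# Refined grid over a model's own domain. For a domain starting at the grid
# anchor this spans endpoint-to-endpoint; otherwise grid points are the
# global-grid times falling inside the domain.
model_grid <- function(model, resolution = 60) {
  g <- refined_grid(model$domain, resolution = resolution, anchor = 0)
  if (length(g) < 2) {
    stop_domain("Model domain too short for the requested grid resolution.")
  }
  g
}

check_in_domain <- function(model, times) {
  eps <- 1e-9 * max(1, abs(model$domain))
  if (any(times < model$domain[1] - eps | times > model$domain[2] + eps)) {
    stop_domain(sprintf("Requested times outside the fitted domain [%.6f, %.6f]; no extrapolation.",
                        model$domain[1], model$domain[2]))
  }
  pmin(pmax(times, model$domain[1]), model$domain[2])
}

#' First derivative of the fitted movement curve
#'
#' Exact derivative of the basis expansion (same coefficients, differentiated
#' basis), in degrees per day for each coordinate.
#'
#' @inheritParams evaluate_path
#' @return Tibble with `time`, `dlon`, `dlat` (degrees/day).
#' @export
path_derivative <- function(model, times = NULL, resolution = 60) {
  stopifnot(inherits(model, "track_spline"))
  if (is.null(times)) times <- model_grid(model, resolution)
  times <- check_in_domain(model, times)
  B1 <- basis_matrix(model$knots, times, deriv = 1L)
  tibble(time = times,
         dlon = as.numeric(B1 %*% model$coef[, "lon"]),
         dlat = as.numeric(B1 %*% model$coef[, "lat"]))
}

#' @export
autoplot.track_spline <- function(object, tracks = NULL, resolution = 60, ...) {
  path <- evaluate_path(object, resolution = resolution)
  p <- ggplot2::ggplot(path, ggplot2::aes(x = .data$lon, y = .data$lat)) +
    ggplot2::geom_path(color = "steelblue") +
    ggplot2::labs(x = "longitude", y = "latitude",
                  title = sprintf("Smoothed path: %s", object$animal_id))
  if (!is.null(tracks)) {
    tr <- one_track(tracks, object$animal_id)
    p <- p + ggplot2::geom_point(data = tr, alpha = 0.3, size = 0.6)
  }
  p
}
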