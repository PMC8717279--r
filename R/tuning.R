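#' Generalized cross-validation score for one coordinate
#'
#' \eqn{\mathrm{GCV}(\lambda) = \mathrm{MSE}(\lambda) / (1 -
#' \mathrm{df}(\lambda)/M)^2} where `M` is the number of observations and
#' `df` the trace of the smoother matrix. The squared denominator is the
#' Craven-Wahba convention; `squared = FALSE` gives the linear-denominator
#' variant.
#'
#' @param tracks Track table for one animal (or use `animal`).
#' @param knots A `knot_vector`.
#' @param lambda Penalty (nonnegative scalar).
#' @param coordinate `"lon"` or `"lat"`.
#' @param squared Use the squared denominator (default `TRUE`).
#' @param animal Optional animal id.
#' @return GCV score (scalar).
#' @export
gcv_score <- function(tracks, knots, lambda, coordinate = c("lon", "lat"),
                      squared = TRUE, animal = NULL) {
  coordinate <- match.arg(coordinate)
  tr <- one_track(tracks, animal)
  fit <- fit_track_spline(tr, knots = knots,
                          lambda_lon = if (coordinate == "lon") lambda else 0,
                          lambda_lat = if (coordinate == "lat") lambda else 0)
  gcv_from_fit(fit, coordinate, squared = squared)
}

gcv_from_fit <- function(fit, coordinate, squared = TRUE) {
  M <- fit$n_obs
  df <- unname(fit$df[coordinate])
  if (df >= M) {
    abort(sprintf("Effective df (%.2f) >= number of observations (%d): GCV undefined.",
                  df, M),
          class = "trackfda_gcv_undefined_error")
  }
  mse <- unname(fit$rss[coordinate]) / M
  denom <- 1 - df / M
  mse / if (squared) denom^2 else denom
}

# The GCV formula itself, exposed for direct checks.
gcv_formula <- function(mse, df, m, squared = TRUE) {
  if (df >= m) abort("df >= M: GCV undefined.", class = "trackfda_gcv_undefined_error")
  mse / if (squared) (1 - df / m)^2 else (1 - df / m)
}

#' Select roughness penalties by generalized cross-validation
#'
#' Evaluates the GCV criterion for latitude and longitude on a grid of
#' candidate penalties (default log-spaced \eqn{10^{-8}}..\eqn{10^{4}}, 25
#' points) and returns the per-coordinate argmin (ties resolved toward the
#' smaller penalty, i.e. the less smoothed fit). The full GCV trace is
#' returned so the selection can be overridden after visual inspection of the
#' fitted paths, which is standard practice when a criterion-optimal fit
#' misses ecologically meaningful shifts. With `equal = TRUE` a single shared
#' penalty minimizing the summed GCV is returned for both coordinates
#' (roughness penalized equally in both dimensions).
#'
#' @param tracks Track table for one animal (or use `animal`).
#' @param knots A `knot_vector`; default [select_knots()] on the data.
#' @param grid Candidate penalties (nonnegative, nonempty).
#' @param equal Force a common penalty for both coordinates.
#' @param squared GCV denominator convention (see [gcv_score()]).
#' @param animal Optional animal id.
#' @return List with `lambda_lon`, `lambda_lat`, and `trace` (tibble with
#'   `lambda`, `gcv_lon`, `gcv_lat`, `df_lon`, `df_lat`).
#' @export
tune_smoothing <- function(tracks, knots = NULL,
                           grid = 10^seq(-8, 4, length.out = 25),
                           equal = FALSE, squared = TRUE, animal = NULL) {
  tr <- one_track(tracks, animal)
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid < 0)) {
    stop_parameter("`grid` must be a nonempty vector of nonnegative penalties.")
  }
  if (is.null(knots)) knots <- select_knots(tr$time)
  grid <- sort(grid)
  # Design and penalty are fixed across the grid; only lambda changes.
  Phi <- basis_matrix(knots, tr$time)
  R <- penalty_matrix(knots)
  PtP <- Matrix::crossprod(Phi)
  M <- nrow(tr)
  rows <- purrr::map(grid, function(lam) {
    flon <- solve_penalized(Phi, R, tr$lon, lam, PtP = PtP)
    flat <- solve_penalized(Phi, R, tr$lat, lam, PtP = PtP)
    score <- function(f) {
      if (f$df >= M) return(NA_real_)
      denom <- 1 - f$df / M
      (f$rss / M) / if (squared) denom^2 else denom
    }
    tibble(lambda = lam, gcv_lon = score(flon), gcv_lat = score(flat),
           df_lon = flon$df, df_lat = flat$df)
  })
  trace <- bind_rows(rows)
  pick <- function(scores) {
    if (all(is.na(scores))) {
      abort("GCV undefined for every candidate penalty.",
            class = "trackfda_tuning_error")
    }
    grid[which.min(replace(scores, is.na(scores), Inf))]  # ties: smaller lambda
  }
  if (equal) {
    lam <- pick(trace$gcv_lon + trace$gcv_lat)
    list(lambda_lon = lam, lambda_lat = lam, trace = trace)
  } else {
    list(lambda_lon = pick(trace$gcv_lon),
         lambda_lat = pick(trace$gcv_lat),
         trace = trace)
  }
}

#' Serialize a fitted spline model to JSON
#'
#' Writes knots, order, coefficients, penalties, domain and epoch so a fitted
#' movement model can be re-created exactly without refitting.
#'
#' @param model A `track_spline`.
#' @param path Output JSON file path.
#' @return `path`, invisibly.
#' @export
write_spline_json <- function(model, path) {
  stopifnot(inherits(model, "track_spline"))
  doc <- list(
    animal_id = model$animal_id,
    order = model$knots$order,
    boundary = model$knots$boundary,
    interior_knots = model$knots$interior,
    coef_lon = unname(model$coef[, "lon"]),
    coef_lat = unname(model$coef[, "lat"]),
    lambda = as.list(model$lambda),
    df = as.list(model$df),
    n_obs = model$n_obs,
    domain = model$domain,
    epoch = if (!is.null(model$epoch)) format(model$epoch, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    jittered = model$jittered
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a spline model serialized by [write_spline_json()]
#'
#' @param path JSON file path.
#' @return A `track_spline` (penalty matrix recomputed from the knots).
#' @export
read_spline_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  knots <- structure(list(interior = as.numeric(doc$interior_knots %||% numeric(0)),
                          boundary = as.numeric(doc$boundary),
                          order = as.integer(doc$order)),
                     class = "knot_vector")
  structure(list(
    animal_id = doc$animal_id,
    knots = knots,
    coef = cbind(lon = as.numeric(doc$coef_lon), lat = as.numeric(doc$coef_lat)),
    lambda = c(lon = doc$lambda$lon, lat = doc$lambda$lat),
    df = c(lon = doc$df$lon, lat = doc$df$lat),
    rss = c(lon = NA_real_, lat = NA_real_),
    penalty = penalty_matrix(knots),
    n_obs = as.integer(doc$n_obs),
    domain = as.numeric(doc$domain),
    epoch = if (is.character(doc$epoch) && length(doc$epoch) == 1)
      as.POSIXct(doc$epoch, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    jittered = isTRUE(doc$jittered)
  ), class = "track_spline")
}
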