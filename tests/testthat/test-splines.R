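test_that("knot selection keeps all times at q = 0 and thresholds above it", {
  t <- seq(0, 10, by = 0.1)
  kn <- select_knots(t, quantile = 0, min_spacing = 0)
  expect_equal(kn$interior, t[-c(1, length(t))])
  expect_equal(kn$boundary, c(0, 10))
  # near-uniform times at a very high quantile: almost nothing survives
  res <- tryCatch(select_knots(t, quantile = 0.99, min_spacing = 0),
                  trackfda_degenerate_knots_error = function(e) e)
  if (inherits(res, "knot_vector")) {
    expect_lte(length(res$interior), ceiling(0.01 * length(t)))
  } else {
    expect_s3_class(res, "trackfda_degenerate_knots_error")
  }
})

test_that("no interior knots fall inside a long sampling gap", {
  set.seed(4)
  t <- sort(c(runif(120, 0, 10), runif(120, 50, 60)))
  kn <- select_knots(t, quantile = 0.3)
  expect_true(all(kn$interior <= 10 | kn$interior >= 50))
  expect_true(any(kn$interior < 10) && any(kn$interior > 50))
  # oracle: KDE evaluated in the gap is below the threshold quantile
  d <- time_density(t)
  thresh <- quantile(eval_density(d, t), 0.3, names = FALSE)
  expect_lt(eval_density(d, 30), thresh)
})

test_that("knot thinning enforces the minimum spacing", {
  t <- seq(0, 1, by = 0.001)
  kn <- select_knots(t, quantile = 0, min_spacing = 0.05)
  expect_true(all(diff(kn$interior) >= 0.05 - 1e-12))
})

test_that("unpenalized fit with knots at every time interpolates the data", {
  tr <- sine_track(duration = 10, noise = 0.01, seed = 5)
  tr <- tr[seq(1, nrow(tr), by = 6), ]   # 4-hourly to keep K = n + 2 modest
  fit <- fit_track_spline(tr, knots = interp_knots(tr$time))
  p <- evaluate_path(fit, times = tr$time)
  expect_lt(max(abs(p$lon - tr$lon)), 1e-6)
  expect_lt(max(abs(p$lat - tr$lat)), 1e-6)
})

test_that("huge penalty collapses the fit to the least-squares line", {
  set.seed(5)
  t <- seq(0, 10, length.out = 80)
  tr <- toy_track(t, lon = 0.2 + 0.05 * t + rnorm(80, 0, 0.005),
                  lat = 1 - 0.02 * t + rnorm(80, 0, 0.005))
  kn <- select_knots(t, min_spacing = 2)
  fit <- fit_track_spline(tr, knots = kn, lambda_lon = 1e12, lambda_lat = 1e12)
  p <- evaluate_path(fit, times = t)
  expect_lt(max(abs(p$lon - fitted(lm(lon ~ time, tr)))), 1e-3)
  expect_lt(max(abs(p$lat - fitted(lm(lat ~ time, tr)))), 1e-3)
  # derivative is the OLS slope in the penalty null space
  d <- path_derivative(fit, times = c(2, 5, 8))
  expect_lt(max(abs(d$dlon - coef(lm(lon ~ time, tr))[2])), 1e-3)
  expect_equal(unname(fit$df["lon"]), 2, tolerance = 1e-3)
})

test_that("effective df decreases and RSS increases with the penalty", {
  tr <- sine_track(duration = 8, noise = 0.01, seed = 6)
  kn <- select_knots(tr$time)
  lambdas <- c(1e-6, 1e-3, 1, 1e3)
  fits <- lapply(lambdas, function(l)
    fit_track_spline(tr, knots = kn, lambda_lon = l, lambda_lat = l))
  dfs <- vapply(fits, function(f) unname(f$df["lon"]), numeric(1))
  rsss <- vapply(fits, function(f) unname(f$rss["lon"]), numeric(1))
  expect_true(all(diff(dfs) < 0))
  expect_true(all(diff(rsss) > 0))
})

test_that("fitted values are linear in the observations", {
  t <- seq(0, 6, by = 1 / 12)
  set.seed(7)
  y1 <- toy_track(t, lon = rnorm(length(t)), lat = rnorm(length(t)))
  y2 <- toy_track(t, lon = rnorm(length(t)), lat = rnorm(length(t)))
  ysum <- toy_track(t, lon = y1$lon + y2$lon, lat = y1$lat + y2$lat)
  kn <- select_knots(t)
  f1 <- evaluate_path(fit_track_spline(y1, kn, 0.01, 0.01), times = t)
  f2 <- evaluate_path(fit_track_spline(y2, kn, 0.01, 0.01), times = t)
  fs <- evaluate_path(fit_track_spline(ysum, kn, 0.01, 0.01), times = t)
  expect_equal(fs$lon, f1$lon + f2$lon, tolerance = 1e-9)
  expect_equal(fs$lat, f1$lat + f2$lat, tolerance = 1e-9)
})

test_that("GCV follows the squared-denominator formula", {
  expect_equal(trackfda:::gcv_formula(mse = 1, df = 0, m = 100), 1)
  expect_equal(trackfda:::gcv_formula(mse = 0.5, df = 50, m = 100), 2)
  # diverges as df approaches M
  scores <- sapply(c(0.5, 0.9, 0.99, 0.999), function(frac)
    trackfda:::gcv_formula(mse = 1, df = frac * 100, m = 100))
  expect_true(all(diff(scores) > 0))
  expect_gt(scores[4], 1e5)
  expect_error(trackfda:::gcv_formula(1, 100, 100),
               class = "trackfda_gcv_undefined_error")
  # linear-denominator variant
  expect_equal(trackfda:::gcv_formula(0.5, 50, 100, squared = FALSE), 1)
})

test_that("GCV selection picks an interior penalty for smooth signal plus noise", {
  tr <- sine_track(duration = 10, noise = 0.002, seed = 6)
  tuned <- tune_smoothing(tr)
  grid <- sort(tuned$trace$lambda)
  expect_gt(tuned$lambda_lon, min(grid))
  expect_lt(tuned$lambda_lon, max(grid))
  expect_gt(tuned$lambda_lat, min(grid))
  expect_lt(tuned$lambda_lat, max(grid))
})

test_that("GCV selection smooths white noise maximally and honors tiny grids", {
  set.seed(7)
  t <- seq(0, 10, by = 1 / 24)
  tr <- toy_track(t, lon = 0.5 + rnorm(length(t), 0, 0.01),
                  lat = -0.5 + rnorm(length(t), 0, 0.01))
  tuned <- tune_smoothing(tr)
  grid <- sort(tuned$trace$lambda)
  expect_gte(tuned$lambda_lon, grid[length(grid) - 1])
  one <- tune_smoothing(tr, grid = 0.123)
  expect_equal(one$lambda_lon, 0.123)
  expect_equal(one$lambda_lat, 0.123)
  # equal-penalty mode returns a shared value
  eq <- tune_smoothing(tr, equal = TRUE)
  expect_equal(eq$lambda_lon, eq$lambda_lat)
})

test_that("path evaluation uses the hourly refined grid and refuses extrapolation", {
  t <- seq(0, 10, by = 0.25)
  tr <- toy_track(t, lon = 0.01 * t, lat = -0.01 * t)
  fit <- fit_track_spline(tr, knots = select_knots(t), lambda_lon = 1, lambda_lat = 1)
  p <- evaluate_path(fit)
  expect_equal(nrow(p), 241)   # 60-min grid, 10-day domain, inclusive ends
  expect_equal(range(p$time), c(0, 10))
  expect_error(evaluate_path(fit, times = 10.5), class = "trackfda_domain_error")
  expect_error(path_derivative(fit, times = -0.1), class = "trackfda_domain_error")
})

test_that("a refined one-minute grid stays on the same smooth path", {
  tr <- sine_track(duration = 4, noise = 0, seed = 8)
  fit <- fit_track_spline(tr, knots = select_knots(tr$time),
                          lambda_lon = 1e-6, lambda_lat = 1e-6)
  hourly <- evaluate_path(fit, resolution = 60)
  fine <- evaluate_path(fit, resolution = 1)
  # chord deviation bound: max |x''| * dt^2 / 8 between hourly anchors
  interp <- approx(hourly$time, hourly$lat, xout = fine$time)$y
  dd <- diff(path_derivative(fit, times = fine$time)$dlat) * 1440  # ~x'' per day^2
  bound <- max(abs(dd)) * (1 / 24)^2 / 8
  expect_lt(max(abs(fine$lat - interp)), bound * 1.05 + 1e-12)
})

test_that("spline derivative agrees with central finite differences", {
  tr <- sine_track(duration = 6, noise = 0.005, seed = 9)
  fit <- fit_default(tr)
  t0 <- seq(0.5, 5.5, by = 0.25)
  h <- 1e-4
  d <- path_derivative(fit, times = t0)
  fd_lon <- (evaluate_path(fit, times = t0 + h)$lon -
               evaluate_path(fit, times = t0 - h)$lon) / (2 * h)
  fd_lat <- (evaluate_path(fit, times = t0 + h)$lat -
               evaluate_path(fit, times = t0 - h)$lat) / (2 * h)
  expect_lt(max(abs(d$dlon - fd_lon)), 1e-5)
  expect_lt(max(abs(d$dlat - fd_lat)), 1e-5)
})

test_that("constant tracks have zero derivative everywhere", {
  tr <- constant_track(-57, -16, duration = 5)
  fit <- fit_track_spline(tr, knots = select_knots(tr$time),
                          lambda_lon = 1, lambda_lat = 1)
  d <- path_derivative(fit)
  expect_lt(max(abs(d$dlon)), 1e-8)
  expect_lt(max(abs(d$dlat)), 1e-8)
})

test_that("penalty matrix is symmetric positive semi-definite", {
  kn <- select_knots(seq(0, 5, by = 0.25))
  R <- as.matrix(penalty_matrix(kn))
  expect_equal(R, t(R), tolerance = 1e-12)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
  # second-derivative penalty has a 2-dimensional (linear) null space
  expect_equal(sum(ev < 1e-8 * max(ev)), 2)
})

test_that("spline models serialize to JSON and back", {
  tr <- sine_track(duration = 5, noise = 0.005, seed = 10)
  fit <- fit_track_spline(tr, knots = select_knots(tr$time),
                          lambda_lon = 0.01, lambda_lat = 0.02)
  p <- tempfile(fileext = ".json")
  write_spline_json(fit, p)
  back <- read_spline_json(p)
  g <- seq(0.2, 4.8, by = 0.1)
  expect_equal(evaluate_path(back, times = g), evaluate_path(fit, times = g),
               tolerance = 1e-12)
  expect_equal(back$lambda, fit$lambda)
  expect_equal(back$domain, fit$domain)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  tr <- sine_track(duration = 4, noise = 0.01, seed = 11)
  fit <- fit_track_spline(tr, knots = select_knots(tr$time),
                          lambda_lon = 0.1, lambda_lat = 0.1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * nrow(fit$coef))
  expect_setequal(unique(td$coordinate), c("lon", "lat"))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(tr))
  expect_gt(gl$df_lon, 0)
  expect_lte(gl$df_lon, min(gl$n_basis, gl$n_obs))
})
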