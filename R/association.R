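# Default bins-per-axis rule for the equal-frequency histogram estimator.
# Cells grow as (n/5)^(2/3), so the expected count per cell grows like
# 5 (n/5)^(1/3) and the plug-in independence bias (~(B-1)^2 / 2n nats)
# vanishes with n; a constant-count rule (cells ~ n) would leave an O(1)
# bias of roughly 0.1 nats on independent data.
mi_default_bins <- function(n) max(2L, floor((n / 5)^(1 / 3)))

# Fast equal-frequency histogram plug-in MI (nats). Ranks break ties by
# order, giving exactly n/B-balanced marginals (up to remainders).
mi_hist <- function(x, y, bins) {
  n <- length(x)
  bx <- ceiling(rank(x, ties.method = "first") * bins / n)
  by <- ceiling(rank(y, ties.method = "first") * bins / n)
  joint <- tabulate(bx + (by - 1L) * bins, nbins = bins * bins) / n
  px <- tabulate(bx, bins) / n
  py <- tabulate(by, bins) / n
  keep <- joint > 0
  prod_xy <- as.vector(outer(px, py))
  sum(joint[keep] * log(joint[keep] / prod_xy[keep]))
}

# Kraskov-Stoegbauer-Grassberger (KSG-1) k-NN MI estimator, O(n^2); used as a
# cross-check on moderate sample sizes.
mi_ksg <- function(x, y, k = 5L) {
  n <- length(x)
  if (k >= n) stop_parameter("KSG `k` must be smaller than the sample size.")
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dj <- pmax(dx, dy)
  diag(dj) <- Inf
  eps <- apply(dj, 1, function(r) sort(r, partial = k)[k])
  diag(dx) <- Inf; diag(dy) <- Inf
  nx <- rowSums(dx < eps)
  ny <- rowSums(dy < eps)
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' Mutual information between two sample sequences
#'
#' Plug-in estimate of the mutual information \eqn{I(X;Y) = \int\!\!\int
#' p(x,y)\log\{p(x,y)/(p_x(x)p_y(y))\}\,dx\,dy} in nats. The default
#' estimator bins both variables into `bins` equal-frequency classes and sums
#' \eqn{\hat p \log(\hat p / \hat p_x \hat p_y)} over occupied cells of the
#' two-dimensional histogram; `bins` defaults to
#' `max(2, floor((n/5)^(1/3)))` per axis, under which the estimate converges
#' to 0 for independent inputs as n grows. A Kraskov k-nearest-neighbor
#' estimator (`estimator = "ksg"`) is available for validation. Small
#' negative estimates (possible for KSG) are clamped to 0 and flagged.
#'
#' @param x,y Numeric sample sequences of equal length.
#' @param bins Bins per axis for the histogram estimator; default the rule
#'   above.
#' @param estimator `"histogram"` (default) or `"ksg"`.
#' @param k Neighbor count for the KSG estimator.
#' @param min_n Minimum sample size (default 10).
#' @return One-row tibble: `value` (nats, >= 0), `estimator`, `n`,
#'   `bins_or_k`, `clamped`.
#' @examples
#' x <- runif(1000)
#' mutual_information(x, x, bins = 8)$value  # = log(8)
#' @export
mutual_information <- function(x, y, bins = NULL,
                               estimator = c("histogram", "ksg"),
                               k = 5L, min_n = 10L) {
  estimator <- match.arg(estimator)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_input("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < min_n) {
    stop_input(sprintf("Need at least %d samples; got %d.", min_n, n))
  }
  if (estimator == "histogram") {
    bins <- as.integer(bins %||% mi_default_bins(n))
    if (bins < 2) stop_parameter("`bins` must be at least 2.")
    raw <- mi_hist(x, y, bins)
    par <- bins
  } else {
    raw <- mi_ksg(x, y, k = as.integer(k))
    par <- as.integer(k)
  }
  clamped <- raw < 0
  tibble(value = max(raw, 0), estimator = estimator, n = n,
         bins_or_k = par, clamped = clamped)
}

#' Localized mutual information series for a pair of animals
#'
#' For each time on the shared refined grid, both fitted movement curves are
#' evaluated inside the window `[t - lambda, t + lambda]` (truncated at the
#' overlap boundaries), mutual information is estimated separately for the
#' latitude pair and the longitude pair, and the two are combined as the
#' Euclidean norm \eqn{\sqrt{I_{lat}^2 + I_{lon}^2}}. The result is a
#' time-varying association curve: windows where one animal's movement is
#' informative about the other's score high regardless of their distance.
#' Times whose window holds fewer than `min_n` grid samples are marked
#' undefined (`NA`), not zero.
#'
#' @param model_a,model_b `track_spline` fits with overlapping domains.
#' @param lambda Window radius in hours (default 48, i.e. a 4-day window).
#' @param resolution Shared grid resolution in minutes (default 60).
#' @param bins Bins per axis passed to the estimator; default the per-window
#'   rule of [mutual_information()].
#' @param min_n Minimum window sample count (default 10).
#' @return Tibble with `time`, `mi_lat`, `mi_lon`, `raw` (the combined LMI),
#'   `defined`; attributes `pair`, `lambda_hours`, `resolution`.
#' @export
lmi_series <- function(model_a, model_b, lambda = 48, resolution = 60,
                       bins = NULL, min_n = 10L) {
  stopifnot(inherits(model_a, "track_spline"), inherits(model_b, "track_spline"))
  if (!is.numeric(lambda) || lambda <= 0) {
    stop_parameter("`lambda` must be a positive window radius in hours.")
  }
  lam_days <- lambda / 24
  if (lam_days <= resolution / 1440) {
    stop_parameter("Window radius must exceed the grid spacing.")
  }
  lo <- max(model_a$domain[1], model_b$domain[1])
  hi <- min(model_a$domain[2], model_b$domain[2])
  if (!(lo < hi)) {
    stop_overlap("No overlap between the two monitoring domains.")
  }
  grid <- refined_grid(c(lo, hi), resolution = resolution, anchor = 0)
  pa <- evaluate_path(model_a, times = grid)
  pb <- evaluate_path(model_b, times = grid)
  ng <- length(grid)
  tol <- 1e-9  # grid times are float multiples of the step; keep borderline points
  lo_idx <- findInterval(grid - lam_days - tol, grid, left.open = TRUE) + 1L
  hi_idx <- findInterval(grid + lam_days + tol, grid)
  mi_lat <- mi_lon <- rep(NA_real_, ng)
  for (i in seq_len(ng)) {
    idx <- lo_idx[i]:hi_idx[i]
    nw <- length(idx)
    if (nw < min_n) next
    b <- as.integer(bins %||% mi_default_bins(nw))
    mi_lat[i] <- max(0, mi_hist(pa$lat[idx], pb$lat[idx], b))
    mi_lon[i] <- max(0, mi_hist(pa$lon[idx], pb$lon[idx], b))
  }
  out <- tibble(time = grid, mi_lat = mi_lat, mi_lon = mi_lon,
                raw = sqrt(mi_lat^2 + mi_lon^2),
                defined = !is.na(mi_lat))
  attr(out, "pair") <- c(model_a$animal_id, model_b$animal_id)
  attr(out, "lambda_hours") <- lambda
  attr(out, "resolution") <- resolution
  out
}

#' Scale localized mutual information series to [0, 1]
#'
#' The default `"pointwise_max"` policy divides each series' raw LMI at each
#' grid time by the maximum raw LMI across the supplied series at that time,
#' so at every time the most associated pair scores 1 and the others are
#' relative to it (a correlation-like scale across pairs). `"global_max"`
#' instead divides each series by its own maximum over time. `0/0` is mapped
#' to 0; undefined times stay `NA`.
#'
#' @param series A single LMI tibble from [lmi_series()] or a list of them on
#'   a common grid.
#' @param policy `"pointwise_max"` (default) or `"global_max"`.
#' @return The input series (single tibble or list, matching the input) with
#'   a `scaled` column added.
#' @export
scale_lmi <- function(series, policy = c("pointwise_max", "global_max")) {
  policy <- match.arg(policy)
  single <- is.data.frame(series)
  lst <- if (single) list(series) else series
  if (!length(lst) || !all(vapply(lst, is.data.frame, logical(1)))) {
    stop_input("`series` must be an LMI tibble or a nonempty list of them.")
  }
  times <- lst[[1]]$time
  same <- vapply(lst, function(s) length(s$time) == length(times) &&
                   max(abs(s$time - times)) < 1e-9, logical(1))
  if (!all(same)) stop_input("All LMI series must share the same time grid.")
  if (policy == "pointwise_max") {
    raws <- do.call(cbind, lapply(lst, function(s) s$raw))
    mx <- apply(raws, 1, function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    lst <- purrr::map(lst, function(s) {
      sc <- s$raw / mx
      sc[!is.na(s$raw) & !is.na(mx) & mx == 0] <- 0  # 0/0 -> 0
      mutate(s, scaled = sc)
    })
  } else {
    lst <- purrr::map(lst, function(s) {
      mx <- suppressWarnings(max(s$raw, na.rm = TRUE))
      sc <- if (!is.finite(mx) || mx == 0) ifelse(is.na(s$raw), NA_real_, 0) else s$raw / mx
      mutate(s, scaled = sc)
    })
  }
  if (single) lst[[1]] else lst
}

#' Five-number window summary of distance and association
#'
#' Restricts a pair's distance series and scaled LMI series to a closed time
#' window and reports linear-interpolation quantiles (min, Q1, median, Q3,
#' max) of each, the shape used to tabulate peak-association episodes.
#'
#' @param dist Distance series from [distance_series()].
#' @param lmi LMI series carrying a `scaled` column (see [scale_lmi()]).
#' @param window Length-2 numeric, closed window `[start, end]` in study
#'   days.
#' @return Tibble with one row per metric (`"distance"`, `"lmi"`): `pair`,
#'   `window_start`, `window_end`, `metric`, `min`, `q1`, `median`, `q3`,
#'   `max`, `n`.
#' @export
summarize_window <- function(dist, lmi, window) {
  if (length(window) != 2 || window[1] > window[2]) {
    stop_parameter("`window` must be an increasing length-2 vector of days.")
  }
  if (!"scaled" %in% names(lmi)) {
    stop_input("`lmi` lacks a `scaled` column; run scale_lmi() first.")
  }
  d <- filter(as_tibble(dist), .data$time >= window[1], .data$time <= window[2])
  l <- filter(as_tibble(lmi), .data$time >= window[1], .data$time <= window[2],
              .data$defined, !is.na(.data$scaled))
  if (nrow(d) == 0 || nrow(l) == 0) {
    abort("Window does not intersect the series' grids.",
          class = "trackfda_window_error")
  }
  pair <- paste(attr(dist, "pair") %||% attr(lmi, "pair") %||% c("A", "B"),
                collapse = " vs ")
  bind_rows(
    mutate(five_num(d$dist_m), metric = "distance", n = nrow(d)),
    mutate(five_num(l$scaled), metric = "lmi", n = nrow(l))
  ) |>
    mutate(pair = pair, window_start = window[1], window_end = window[2]) |>
    select("pair", "window_start", "window_end", "metric",
           "min", "q1", "median", "q3", "max", "n")
}

#' Plot localized mutual information over time
#'
#' @param series An LMI tibble or list of them (scaled if available).
#' @return A ggplot object.
#' @export
plot_lmi <- function(series) {
  lst <- if (is.data.frame(series)) list(series) else series
  df <- bind_rows(purrr::map(lst, function(s) {
    mutate(as_tibble(s),
           pair = paste(attr(s, "pair") %||% c("A", "B"), collapse = " vs "))
  }))
  ycol <- if ("scaled" %in% names(df)) "scaled" else "raw"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data[[ycol]],
                                   color = .data$pair)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "study time (days)",
                  y = if (ycol == "scaled") "scaled LMI" else "LMI (nats)")
}
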