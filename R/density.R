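#' Gaussian kernel density over study time
#'
#' Builds a one-dimensional Gaussian-kernel density estimate over a set of
#' study times, evaluable at arbitrary times. This is the common machinery
#' behind the sampled-time density that guides knot placement, the
#' rest-period density, and the cooccurrence potential: all three are KDEs of
#' time values restricted to some condition.
#'
#' The estimate is the standard \eqn{\hat f_h(t) = (nh)^{-1} \sum_i K((t -
#' t_i)/h)} with Gaussian \eqn{K}. `bandwidth = "auto"` applies Silverman's
#' rule-of-thumb ([stats::bw.nrd0()]), which requires at least two distinct
#' times.
#'
#' An empty `times` vector yields an *absent* density (`is_empty_density()`
#' is `TRUE`, evaluation returns `NA`): a condition that never holds has no
#' density, which is distinct from a density that is zero somewhere.
#'
#' @param times Numeric study times (days) the density is estimated from.
#' @param bandwidth Kernel bandwidth in days, or `"auto"` for Silverman's
#'   rule.
#' @return An object of class `time_density` with fields `times`, `bw`,
#'   `support` (range of the sample), `n`.
#' @examples
#' d <- time_density(c(0, 1, 2, 10), bandwidth = 1)
#' eval_density(d, c(0, 5, 10))
#' @export
time_density <- function(times, bandwidth = "auto") {
  times <- as.numeric(times)
  times <- times[is.finite(times)]
  if (length(times) == 0) {
    return(structure(list(times = numeric(0), bw = NA_real_,
                          support = c(NA_real_, NA_real_), n = 0L),
                     class = "time_density"))
  }
  if (identical(bandwidth, "auto") || identical(bandwidth, "silverman")) {
    if (length(unique(times)) < 2) {
      stop_parameter("Automatic bandwidth needs at least 2 distinct times.")
    }
    bw <- stats::bw.nrd0(times)
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) {
      stop_parameter("`bandwidth` must be a positive number of days.")
    }
  }
  structure(list(times = sort(times), bw = bw,
                 support = range(times), n = length(times)),
            class = "time_density")
}

#' Evaluate a time density at arbitrary times
#'
#' @param density A [time_density()] object.
#' @param t Numeric times (days) to evaluate at.
#' @return Density values (per day); `NA` for an absent (empty) density.
#' @export
eval_density <- function(density, t) {
  stopifnot(inherits(density, "time_density"))
  t <- as.numeric(t)
  if (is_empty_density(density)) return(rep(NA_real_, length(t)))
  ti <- density$times
  h <- density$bw
  # Chunked evaluation keeps the outer() workspace bounded for long grids.
  out <- numeric(length(t))
  chunk <- max(1L, floor(5e6 / max(1L, length(ti))))
  idx <- seq_along(t)
  for (start in seq(1L, length(t), by = chunk)) {
    j <- idx[start:min(start + chunk - 1L, length(t))]
    out[j] <- colMeans(dnorm(outer(ti, t[j], "-"), sd = h))
  }
  out
}

#' Test whether a density is absent (estimated from zero times)
#' @param density A [time_density()] object.
#' @return Logical scalar.
#' @export
is_empty_density <- function(density) {
  inherits(density, "time_density") && density$n == 0L
}

#' Integrated density mass over an interval
#'
#' Exact under the Gaussian kernel: the mass in `[lower, upper]` is the mean
#' of per-kernel normal CDF differences. With infinite limits this is the
#' total mass (1 for any non-empty density).
#'
#' @param density A [time_density()] object.
#' @param lower,upper Interval bounds (days); default the whole line.
#' @return Probability mass in the interval.
#' @export
density_mass <- function(density, lower = -Inf, upper = Inf) {
  stopifnot(inherits(density, "time_density"))
  if (is_empty_density(density)) return(NA_real_)
  mean(stats::pnorm(upper, density$times, density$bw) -
         stats::pnorm(lower, density$times, density$bw))
}

#' @export
#' @method print time_density
print.time_density <- function(x, ...) {
  if (is_empty_density(x)) {
    cat("<time_density: absent (no qualifying times)>\n")
  } else {
    cat(sprintf("<time_density: n = %d, bandwidth = %.4g days, support [%.3f, %.3f]>\n",
                x$n, x$bw, x$support[1], x$support[2]))
  }
  invisible(x)
}

#' Sample a time density onto a uniform grid as a tibble
#'
#' @param density A [time_density()] object.
#' @param resolution Sampling step in minutes (default 360 = 6 h).
#' @param pad Extra support padding in bandwidths on each side (default 3).
#' @return Tibble with `time`, `density`; zero rows for an absent density.
#' @export
density_profile <- function(density, resolution = 360, pad = 3) {
  stopifnot(inherits(density, "time_density"))
  if (is_empty_density(density)) return(tibble(time = numeric(0), density = numeric(0)))
  lo <- density$support[1] - pad * density$bw
  hi <- density$support[2] + pad * density$bw
  t <- seq(lo, hi, by = resolution / 1440)
  tibble(time = t, density = eval_density(density, t))
}

#' @export
autoplot.time_density <- function(object, resolution = 360, ...) {
  df <- density_profile(object, resolution = resolution)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "study time (days)", y = "density (1/day)")
}

#' Density of sampled times for a track
#'
#' Convenience wrapper estimating the sampling-time density of one animal's
#' fixes, used to place spline knots where the monitoring record is dense.
#'
#' @param tracks Track table; filtered to `animal` if given.
#' @param animal Optional animal id when `tracks` holds several.
#' @param bandwidth Days or `"auto"` (Silverman).
#' @return A [time_density()] object.
#' @export
estimate_time_density <- function(tracks, animal = NULL, bandwidth = "auto") {
  tr <- one_track(tracks, animal)
  time_density(tr$time, bandwidth = bandwidth)
}
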