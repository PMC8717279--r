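#' Simulate a home-ranging telemetry track
#'
#' Positions follow a discretized Ornstein-Uhlenbeck process per coordinate
#' around a home center: \eqn{x_{t+\Delta} = x_t + \theta(\mu - x_t)\Delta +
#' \sigma\sqrt{\Delta}\,\varepsilon}, the simplest kinematic with
#' home-range-bounded movement and closed-form stationary variance
#' \eqn{\sigma^2/(2\theta)}. The nominal fix schedule (every
#' `sample_interval` minutes) is thinned by a gap model that emulates
#' collar outages: after each retained fix a gap starts with probability
#' `gap_prob`, with exponential length (mean `gap_mean_hours`) floored at
#' `gap_min_hours`, producing multi-hour-to-multi-day holes in otherwise
#' hourly sampling. Optional i.i.d. Gaussian observation noise can be added
#' to the retained fixes. Coordinates are simulated directly in degrees with
#' centers near the equator by default, so degree-to-meter conversion is
#' nearly isotropic.
#'
#' @param seed Integer seed; the track is fully reproducible from it.
#' @param duration Monitoring span in days.
#' @param start_day Study time of the first nominal fix (days); staggers
#'   monitoring windows across animals.
#' @param sample_interval Nominal fix interval in minutes (default 60).
#' @param home_center Length-2 (lon, lat) home-range center in degrees.
#' @param theta Mean-reversion rate per day (>= 0).
#' @param sigma Diffusion in degrees per sqrt(day) (>= 0).
#' @param noise_sd Observation noise SD in degrees (default 0).
#' @param gap_prob Probability a gap starts after a retained fix.
#' @param gap_mean_hours,gap_min_hours Gap length distribution (exponential
#'   mean, floor).
#' @param start_at_center Start at the home center (default) rather than a
#'   draw from the stationary distribution.
#' @param animal_id Identifier for the output track.
#' @return Track tibble (`animal_id`, `time`, `lon`, `lat`).
#' @examples
#' tr <- simulate_track(seed = 1, duration = 30)
#' summarize_monitoring(tr)
#' @export
simulate_track <- function(seed = NULL, duration = 120, start_day = 0,
                           sample_interval = 60, home_center = c(0, 0),
                           theta = 1, sigma = 0.05, noise_sd = 0,
                           gap_prob = 0.05, gap_mean_hours = 8,
                           gap_min_hours = 2, start_at_center = TRUE,
                           animal_id = "sim1") {
  check_sim_config(duration, sample_interval, theta, sigma, noise_sd,
                   gap_prob, gap_mean_hours)
  with_seed(seed, {
    n_steps <- floor(duration * 1440 / sample_interval) + 1L
    eps <- matrix(rnorm(2L * n_steps), ncol = 2)
    path <- ou_path(eps, sample_interval / 1440, home_center, theta, sigma,
                    start_at_center)
    keep <- gap_keep_index(n_steps, sample_interval, gap_prob,
                           gap_mean_hours, gap_min_hours)
    out <- tibble(
      animal_id = animal_id,
      time = start_day + (keep - 1L) * sample_interval / 1440,
      lon = path[keep, 1] + if (noise_sd > 0) rnorm(length(keep), 0, noise_sd) else 0,
      lat = path[keep, 2] + if (noise_sd > 0) rnorm(length(keep), 0, noise_sd) else 0
    )
    out
  })
}

check_sim_config <- function(duration, sample_interval, theta, sigma,
                             noise_sd, gap_prob, gap_mean_hours) {
  if (!is.numeric(duration) || duration <= 0) stop_parameter("`duration` must be > 0 days.")
  if (!is.numeric(sample_interval) || sample_interval <= 0) {
    stop_parameter("`sample_interval` must be > 0 minutes.")
  }
  if (theta < 0 || sigma < 0 || noise_sd < 0) {
    stop_parameter("`theta`, `sigma`, `noise_sd` must be nonnegative.")
  }
  if (gap_prob < 0 || gap_prob >= 1) stop_parameter("`gap_prob` must be in [0, 1).")
  if (gap_mean_hours <= 0) stop_parameter("`gap_mean_hours` must be > 0.")
  invisible(TRUE)
}

# Euler-discretized OU path driven by a given innovation matrix (n x 2).
ou_path <- function(eps, dt, center, theta, sigma, start_at_center) {
  n <- nrow(eps)
  path <- matrix(0, n, 2)
  sd_step <- sigma * sqrt(dt)
  sd_stat <- if (theta > 0) sigma / sqrt(2 * theta) else 0
  for (j in 1:2) {
    x <- if (start_at_center) center[j] else center[j] + sd_stat * eps[1, j]
    path[1, j] <- x
    for (i in seq_len(n - 1L)) {
      x <- x + theta * (center[j] - x) * dt + sd_step * eps[i + 1L, j]
      path[i + 1L, j] <- x
    }
  }
  path
}

# Indices of nominal fixes retained by the gap model.
gap_keep_index <- function(n_steps, sample_interval, gap_prob,
                           gap_mean_hours, gap_min_hours) {
  keep <- integer(0)
  i <- 1L
  while (i <= n_steps) {
    keep <- c(keep, i)
    if (gap_prob > 0 && runif(1) < gap_prob) {
      gap_h <- gap_min_hours + stats::rexp(1, rate = 1 / max(gap_mean_hours - gap_min_hours, 1e-9))
      i <- i + max(1L, as.integer(round(gap_h * 60 / sample_interval)))
    }
    i <- i + 1L
  }
  keep
}

#' Simulate a pair of tracks with scheduled association windows
#'
#' Two Ornstein-Uhlenbeck tracks whose per-step innovations are correlated
#' inside scheduled windows and independent outside:
#' \eqn{\varepsilon_B = \rho\,\varepsilon_A + \sqrt{1-\rho^2}\,\eta} when the
#' step time falls in an active window. Because the coupling acts on the
#' innovations (not the positions), association can be injected between
#' animals with distant home centers - associated movement without spatial
#' proximity - which is exactly what a movement-association measure must
#' detect independently of a distance threshold.
#'
#' @param seed Integer seed.
#' @param duration Days simulated for both animals.
#' @param windows Association schedule: 2-column matrix or list of
#'   `c(start, end)` day pairs (disjoint, within the duration). `NULL` for no
#'   association.
#' @param rho Innovation correlation inside the windows, in `[0, 1]`.
#' @param center_a,center_b Home centers (lon, lat) in degrees.
#' @param start_day_a,start_day_b First nominal fix times; stagger to control
#'   the overlap of the two monitoring windows.
#' @param ids Length-2 character vector of animal ids.
#' @inheritParams simulate_track
#' @return List with `tracks` (both animals bound into one track table),
#'   `schedule` (tibble `start`, `end`, `rho`), and the per-animal tibbles
#'   `track_a`, `track_b`.
#' @export
simulate_associated_pair <- function(seed = NULL, duration = 120,
                                     windows = NULL, rho = 0.9,
                                     center_a = c(0, 0), center_b = c(0, 0),
                                     start_day_a = 0, start_day_b = 0,
                                     sample_interval = 60, theta = 1,
                                     sigma = 0.05, noise_sd = 0,
                                     gap_prob = 0.05, gap_mean_hours = 8,
                                     gap_min_hours = 2,
                                     ids = c("A", "B")) {
  check_sim_config(duration, sample_interval, theta, sigma, noise_sd,
                   gap_prob, gap_mean_hours)
  if (!is.numeric(rho) || rho < 0 || rho > 1) stop_parameter("`rho` must be in [0, 1].")
  sched <- normalize_schedule(windows, duration, rho)
  with_seed(seed, {
    dt <- sample_interval / 1440
    n_steps <- floor(duration * 1440 / sample_interval) + 1L
    step_time <- (seq_len(n_steps) - 1L) * dt
    eps_a <- matrix(rnorm(2L * n_steps), ncol = 2)
    eta <- matrix(rnorm(2L * n_steps), ncol = 2)
    in_window <- rep(FALSE, n_steps)
    for (w in seq_len(nrow(sched))) {
      in_window <- in_window |
        (step_time >= sched$start[w] & step_time <= sched$end[w])
    }
    mix <- ifelse(in_window, rho, 0)
    eps_b <- mix * eps_a + sqrt(1 - mix^2) * eta
    path_a <- ou_path(eps_a, dt, center_a, theta, sigma, TRUE)
    path_b <- ou_path(eps_b, dt, center_b, theta, sigma, TRUE)
    keep_a <- gap_keep_index(n_steps, sample_interval, gap_prob,
                             gap_mean_hours, gap_min_hours)
    keep_b <- gap_keep_index(n_steps, sample_interval, gap_prob,
                             gap_mean_hours, gap_min_hours)
    noisy <- function(v, n) if (noise_sd > 0) v + rnorm(n, 0, noise_sd) else v
    track_a <- tibble(animal_id = ids[1],
                      time = start_day_a + (keep_a - 1L) * dt,
                      lon = noisy(path_a[keep_a, 1], length(keep_a)),
                      lat = noisy(path_a[keep_a, 2], length(keep_a)))
    track_b <- tibble(animal_id = ids[2],
                      time = start_day_b + (keep_b - 1L) * dt,
                      lon = noisy(path_b[keep_b, 1], length(keep_b)),
                      lat = noisy(path_b[keep_b, 2], length(keep_b)))
    list(tracks = bind_rows(track_a, track_b),
         schedule = sched,
         track_a = track_a,
         track_b = track_b,
         innovations = list(a = eps_a, b = eps_b, in_window = in_window,
                            step_time = step_time))
  })
}

normalize_schedule <- function(windows, duration, rho) {
  if (is.null(windows) || (is.list(windows) && length(windows) == 0)) {
    return(tibble(start = numeric(0), end = numeric(0), rho = numeric(0)))
  }
  m <- if (is.matrix(windows)) windows else do.call(rbind, windows)
  if (ncol(m) != 2 || any(m[, 1] >= m[, 2])) {
    stop_parameter("Each association window must be c(start, end) with start < end.")
  }
  if (any(m < 0) || any(m > duration)) {
    stop_parameter("Association windows must lie within [0, duration].")
  }
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2])) {
    stop_parameter("Association windows must be disjoint.")
  }
  tibble(start = m[, 1], end = m[, 2], rho = rho)
}
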