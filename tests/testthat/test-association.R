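test_that("perfect dependence with equal-frequency binning gives exactly log B", {
  set.seed(18)
  x <- runif(1000)
  for (B in c(2, 4, 8, 10)) {   # bins divide n: marginals exactly uniform
    mi <- mutual_information(x, x, bins = B)
    expect_equal(mi$value, log(B), tolerance = 1e-9)
    expect_false(mi$clamped)
  }
  # monotone transform of x leaves ranks (hence the estimate) unchanged
  expect_equal(mutual_information(x, exp(3 * x), bins = 8)$value, log(8),
               tolerance = 1e-9)
})

test_that("independent samples give near-zero mutual information", {
  set.seed(19)
  mi <- mutual_information(runif(1e5), runif(1e5))
  expect_lte(mi$value, 0.01)
  expect_gte(mi$value, 0)
})

test_that("the default estimator recovers the Gaussian closed form at rho = 0.9", {
  set.seed(42)
  n <- 2e5
  z1 <- rnorm(n)
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)
  truth <- -0.5 * log(1 - 0.81)   # 0.8304 nats
  expect_equal(mutual_information(z1, z2)$value, truth, tolerance = 0.05 / truth)
  # k-NN (KSG) cross-check on a smaller sample
  set.seed(44)
  z1 <- rnorm(2000); z2 <- 0.9 * z1 + sqrt(0.19) * rnorm(2000)
  expect_equal(mutual_information(z1, z2, estimator = "ksg")$value, truth,
               tolerance = 0.1 / truth)
})

test_that("shuffling one margin destroys dependence", {
  set.seed(43)
  wins <- 0
  for (s in 1:100) {
    x <- runif(1e4)
    y <- x + rnorm(1e4, 0, 0.1)
    aligned <- mutual_information(x, y)$value
    shuffled <- mutual_information(x, sample(y))$value
    if (shuffled <= aligned) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("estimator guards: length mismatch, minimum n, bins", {
  expect_error(mutual_information(1:10, 1:9), class = "trackfda_input_error")
  expect_error(mutual_information(1:5, 1:5), class = "trackfda_input_error")
  expect_error(mutual_information(1:20, 1:20, bins = 1),
               class = "trackfda_parameter_error")
})

test_that("identical movement models yield the per-window perfect-dependence LMI", {
  fit <- fit_default(sine_track(duration = 10, noise = 0.003, seed = 20))
  twin <- fit
  twin$animal_id <- "twin"
  l <- lmi_series(fit, twin)
  # every window is y = x per coordinate, so each coordinate's MI equals the
  # entropy of its equal-frequency bin occupancies (log B exactly only when
  # B divides the window count); the combined value is sqrt(2) times that
  bin_entropy <- function(n, B) {
    p <- tabulate(ceiling(seq_len(n) * B / n), B) / n
    -sum(p * log(p))
  }
  nw <- vapply(l$time, function(ti) sum(abs(l$time - ti) <= 2 + 1e-9), numeric(1))
  expected <- sqrt(2) * vapply(nw, bin_entropy, numeric(1), B = 2)
  expect_true(any(l$defined))
  expect_equal(l$raw[l$defined], expected[l$defined], tolerance = 1e-9)
})

test_that("an independent stationary pair has low median LMI", {
  sim <- simulate_associated_pair(seed = 7, duration = 40, gap_prob = 0)
  fa <- fit_track_spline(sim$track_a, lambda_lon = 1e-4, lambda_lat = 1e-4)
  fb <- fit_track_spline(sim$track_b, lambda_lon = 1e-4, lambda_lat = 1e-4)
  l <- lmi_series(fa, fb)
  expect_lte(median(l$raw, na.rm = TRUE), 0.05)
})

test_that("windows near the boundary are truncated and short windows masked", {
  fit <- fit_default(sine_track(duration = 6, noise = 0.003, seed = 21))
  twin <- fit; twin$animal_id <- "t"
  l <- lmi_series(fit, twin, lambda = 48, min_n = 10)
  expect_true(all(l$defined))              # hourly grid: >= 49 samples everywhere
  l2 <- lmi_series(fit, twin, lambda = 48, min_n = 1000)
  expect_false(any(l2$defined))            # mask, not zero
  expect_true(all(is.na(l2$raw)))
  expect_error(lmi_series(fit, twin, lambda = 0.5),
               class = "trackfda_parameter_error")
})

test_that("LMI localizes association to the scheduled coupling window", {
  sim <- simulate_associated_pair(seed = 1, duration = 60,
                                  windows = list(c(25, 40)), rho = 0.9)
  l <- lmi_series(fit_default(sim$track_a), fit_default(sim$track_b))
  inw <- l$time >= 25 & l$time <= 40
  expect_gte(median(l$raw[inw], na.rm = TRUE),
             3 * median(l$raw[!inw], na.rm = TRUE))
  argmax <- l$time[which.max(l$raw)]
  expect_true(argmax >= 23 && argmax <= 42)   # window +/- 48 h
})

test_that("pointwise-max scaling is 1 for the leading series and ordered in [0, 1]", {
  t <- (0:9) / 24
  mk <- function(raw) tibble::tibble(time = t, raw = raw, defined = !is.na(raw))
  a <- mk(c(2, 2, 2, 2, 0, 2, 2, 2, 2, 2))
  b <- mk(c(1, 1, 1, 1, 0, 1, 1, 1, 1, NA))
  sc <- scale_lmi(list(a, b))
  expect_equal(sc[[1]]$scaled[-5], rep(1, 9))
  expect_equal(sc[[1]]$scaled[5], 0)          # 0/0 -> 0
  expect_equal(sc[[2]]$scaled[1:4], rep(0.5, 4))
  expect_true(is.na(sc[[2]]$scaled[10]))
  expect_true(all(sc[[2]]$scaled <= 1, na.rm = TRUE))
  # single series: identically 1 where defined and positive
  one <- scale_lmi(a)
  expect_equal(one$scaled[-5], rep(1, 9))
  # global-max: each series scaled by its own maximum
  gm <- scale_lmi(list(a, b), policy = "global_max")
  expect_equal(gm[[2]]$scaled[1], 1)
  # mismatched grids are rejected
  c_bad <- mk(rep(1, 10)); c_bad$time <- c_bad$time + 1
  expect_error(scale_lmi(list(a, c_bad)), class = "trackfda_input_error")
})

test_that("window summaries report five-number quantiles of both metrics", {
  t <- (0:4) / 24
  dist <- tibble::tibble(time = t, dist_m = rep(100, 5))
  lmi <- tibble::tibble(time = t, raw = 1:5, defined = TRUE, scaled = 1:5)
  s <- summarize_window(dist, lmi, window = c(0, 1))
  d <- s[s$metric == "distance", ]
  expect_equal(unlist(d[, c("min", "q1", "median", "q3", "max")]),
               c(min = 100, q1 = 100, median = 100, q3 = 100, max = 100))
  m <- s[s$metric == "lmi", ]
  expect_equal(unlist(m[, c("min", "q1", "median", "q3", "max")]),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  expect_error(summarize_window(dist, lmi, window = c(5, 6)),
               class = "trackfda_window_error")
  expect_error(summarize_window(dist, dplyr::select(lmi, -scaled), c(0, 1)),
               class = "trackfda_input_error")
})
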