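# trackfda

Functional data analysis of animal GPS telemetry: smoothed movement curves,
speed and rest behavior, pairwise proximity, and a time-varying measure of
movement association.

## The problem

GPS collars record an animal's position as irregular hourly fixes with gaps
from hours to days, and different animals are monitored over staggered
calendar windows. Most questions about behavior and interaction — how fast an
animal is moving, when it rests, when two animals are close, when their
movements are *associated* — are questions about a continuous, differentiable
path, not about the raw fixes. `trackfda` treats each track as a smooth curve:

- **Smoothing.** Latitude and longitude are fit separately as penalized
  B-spline expansions `x̂(t) = Σ c_k φ_k(t)` minimizing
  `‖y − Φc‖² + λ cᵀRc`, where `R` is the second-derivative roughness penalty
  computed by Riemann quadrature on a fine grid. Knots are placed only at
  observation times whose sampled-time kernel density exceeds a quantile
  threshold, so sparse stretches stay stiff while dense stretches are fit
  closely. `λ` is chosen per coordinate by generalized cross-validation,
  `GCV(λ) = MSE(λ)/(1 − df(λ)/M)²`, with the full trace returned for manual
  override.
- **Kinematics.** The fitted curve is differentiated exactly through the
  basis; degree rates are converted to metric rates with per-point WGS84
  scale factors and combined as speed `x̂′(t) = √(x̂′_lat² + x̂′_lon²)` (m/s).
  Grid times below a cutoff (default 0.25 m/s) are classified as rest, and a
  kernel density over rest times profiles resting behavior through time.
- **Proximity.** All curves are evaluated on one unified refined time grid
  (default 60 min, anchored at the study epoch). For a pair, the WGS84
  geodesic distance series on the shared grid yields the *cooccurrence
  potential*: a kernel density over the times when distance < δ (default
  1800 m).
- **Association.** The *localized mutual information* (LMI) function
  estimates, in a sliding window `[t−λ, t+λ]` (default radius 48 h), the
  mutual information between the two animals' latitude series and longitude
  series, combined as `√(I_lat² + I_lon²)`. Unlike distance, LMI detects
  coordinated movement even between animals that are far apart. MI is
  estimated with an equal-frequency 2-D histogram plug-in (a k-NN estimator
  is available for validation).

A seeded Ornstein–Uhlenbeck telemetry simulator with scheduled association
windows (shared innovations, `ε_B = ρ ε_A + √(1−ρ²) η`) provides ground truth
for end-to-end validation of the whole pipeline.

The package is aimed at movement ecologists with tidy workflows: track tables
in, tibbles out, `autoplot()`/`plot_*()` for each result type, and
`tidy()`/`glance()` on fitted spline models.

## Worked example

```r
library(trackfda)

# A pair with association scheduled in days 25-40 (innovation coupling 0.9)
sim <- simulate_associated_pair(seed = 1, duration = 60,
                                windows = list(c(25, 40)), rho = 0.9,
                                center_b = c(0.01, 0), ids = c("F12", "M81"))
summarize_monitoring(sim$tracks)
#>   animal_id n_fixes first_time last_time span_days
#> 1 F12          1038          0      59.9      59.9
#> 2 M81           989          0      59.8      59.8

fit <- function(tr) {
  kn <- select_knots(tr$time)
  tu <- tune_smoothing(tr, knots = kn)
  fit_track_spline(tr, knots = kn,
                   lambda_lon = tu$lambda_lon, lambda_lat = tu$lambda_lat)
}
fit_a <- fit(sim$track_a); fit_b <- fit(sim$track_b)
fit_a
#> <track_spline 'F12': 1038 obs, 360 basis fns on [0.00, 59.88] days>
#>   lambda (lon, lat): 0.0001, 0.0001; df: 295.1, 295.1

spd <- classify_rest(path_speed(fit_a))       # hourly speed + rest flags
mean(spd$is_rest)
#> [1] 0.803

d <- distance_series(fit_a, fit_b)            # shared hourly grid
cooccurrence_potential(d)
#> <cooccurrence F12 vs M81: delta = 1800 m, 170/1436 grid times within (11.8%)>

l <- scale_lmi(lmi_series(fit_a, fit_b), policy = "global_max")
l$time[which.max(l$raw)]                      # peak association lands in 25-40
#> [1] 34.5
summarize_window(d, l, window = c(25, 40))
#>   pair       window_start window_end metric      min     q1 median     q3   max
#> 1 F12 vs M81           25         40 distance 201.   1776.  2636.  3441.  8154.
#> 2 F12 vs M81           25         40 lmi        0.00222 0.199  0.324  0.475    1
```

The monitoring summary mirrors a tracking study's Table-1-style coverage
report. The rest fraction says the animal spends ~80% of grid hours below
0.25 m/s (a home-ranging OU track is slow most of the time). The
cooccurrence line says the pair is within 1800 m for ~12% of their shared
grid; the window summary gives five-number quantiles of distance (meters) and
scaled LMI inside the association window — the LMI peak at day 34.5 falls
inside the scheduled coupling window, which is the parameter-recovery check
the test suite runs across 20 seeds.

`run_full_analysis()` chains all stages for a whole telemetry file and writes
per-animal and per-pair CSV/JSON products plus a run manifest;
`inst/cli/trackfda.R` is a thin command-line wrapper over it.

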