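---
title: "Movement curves, cooccurrence potential, and localized mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement curves, cooccurrence potential, and localized mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackfda)
```

This vignette is the package's account of its methods: the models, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## Smoothed movement curves

A track is a set of irregular fixes $(t_i, y_{lon,i}, y_{lat,i})$ on the
study day-scale (fractional days since a calendar epoch, all timestamps
UTC). Each coordinate is modeled as a cubic B-spline expansion
$\hat x(t) = \sum_{k=1}^K c_k \phi_k(t)$ minimizing

$$\lVert y - \Phi c\rVert^2 + \lambda\, c^\top R c, \qquad
R_{jk} = \sum_l \phi_j''(\tilde t_l)\, \phi_k''(\tilde t_l)\, h,$$

with $R$ evaluated by Riemann quadrature on a uniform grid $\tilde t$ of
$\max(1000, 20K)$ points. The quadrature form is used deliberately instead of
exact Gram integrals; at this grid resolution the difference is far below
the measurement scale of GPS data, and the quadrature matrix is what the
trace/df bookkeeping is defined against. The solution
$\hat c = (\Phi^\top\Phi + \lambda R)^{-1}\Phi^\top y$ defines a linear
smoother whose trace is the effective degrees of freedom. Spline order is 4
(cubic): the penalty is on the second derivative, so anything below cubic
cannot carry it, and movement paths need continuous velocity.

Sparse matrices are used throughout (the B-spline design has `order`
nonzeros per row), which keeps multi-month tracks with thousands of knots
fast on one core.

**Knot placement.** Knots are observation times whose sampled-time kernel
density $\hat f_h(t)$ exceeds a threshold, parameterized as the $q$-th
quantile of $\{\hat f_h(t_i)\}$ (default $q = 0.05$), then thinned to a
minimum spacing (default 2 h) with boundary knots at the domain endpoints.
The threshold-as-quantile is this package's construction: thresholding the
density at a fixed value requires choosing a reference time, and a quantile
of the observed density values is scale-free and transfers across animals
with different monitoring intensities. At $q = 0$ every time is kept.
Degenerate thresholds (nothing retained) raise an error suggesting a lower
$q$ rather than silently fitting an unconstrained polynomial.

**Penalty selection.** $\lambda$ is chosen per coordinate on a log-spaced
grid ($10^{-8}$ to $10^4$, 25 points) by generalized cross-validation with
the squared-denominator (Craven–Wahba) convention
$\mathrm{GCV} = \mathrm{MSE}/(1 - \mathrm{df}/M)^2$; the linear-denominator
variant sits behind `squared = FALSE`. Ties go to the smaller $\lambda$ (the
less smoothed fit, consistent with prioritizing positional fidelity). The
full GCV trace is returned: visual fine-tuning of smoothing is standard
practice for movement data, so the selection is a starting point with a
manual override, not an oracle. An `equal = TRUE` mode picks one shared
$\lambda$ for both coordinates, appropriate when there is no reason to
expect anisotropic roughness.

**Numerical edge cases.** If the normal equations are numerically singular —
the unpenalized interpolation limit with more basis functions than
observations — one ridge jitter of $10^{-10}\times$ the mean diagonal is
applied and recorded. Evaluation outside the fitted domain is refused; the
models interpolate within a monitoring window and never extrapolate beyond
it. Penalties around $10^{12}$ reproduce the least-squares line to about
$10^{-3}$ degrees; pushing $\lambda$ several orders beyond that degrades the
conditioning of $\Phi^\top\Phi + \lambda R$ faster than it sharpens the
limit, so tests and workflows treat $10^{12}$ as the practical linear limit.

## Speed, rest, and time densities

Differentiating the basis gives degree rates exactly. Metric conversion uses
per-point scale factors: the geodesic length of a 0.001° meridian (or
parallel) arc centered at the fitted latitude, scaled to meters per degree —
so the conversion inherits WGS84 accuracy at any latitude. Spherical
constants (111,132 and 111,320·cos φ m/deg) are available behind
`method = "spherical"`. Speed is the Euclidean norm of the two metric rates,
reported in m/s.

Rest is a binary working definition: grid times with speed strictly below a
cutoff, default 0.25 m/s — not literal zero speed, but stationary-to-
negligible movement. The rest-period density is a Gaussian KDE over rest
times. Bandwidths of roughly 4–12 days resolve multi-day shifts in resting
behavior; `"auto"` applies Silverman's rule. An empty rest set yields an
*absent* density object, deliberately distinct from a zero density: "this
animal never rests at this cutoff" is different information from "resting
probability is low here".

All three density products (sampled-time density, rest density, cooccurrence
potential) share one `time_density` type: a Gaussian-kernel KDE evaluable at
arbitrary times, with exact interval masses via the normal CDF. KDE
normalization is checked to $10^{-3}$ by independent quadrature in the test
suite.

## The unified grid and pairwise proximity

Every curve is evaluated on subsets of one global uniform grid: multiples of
the resolution (default 60 min) counted from study time 0. Anchoring the
grid globally — rather than starting each animal's grid at its own first fix
— makes any two animals' grids align exactly, so pairwise series are simple
joins. The hourly default matches the finest resolution of collar schedules
like the jaguar deposit; finer grids are permitted everywhere and stay on
the same smooth path.

The pairwise distance series applies the WGS84 geodesic (Karney's algorithm,
via `geosphere::distGeo`, cross-checked in tests against an independent
Vincenty implementation to 1 mm) at each shared grid time. The
cooccurrence potential is a KDE over the times with distance strictly below
δ, default 1800 m. That threshold is far beyond direct-contact distance by
design: with hourly effective resolution an animal walking 4 km/h covers
4000 m between fixes, so a wider radius captures times when interaction was
*possible* between estimated positions. Pairs that never come within δ get
the absent-potential flag (zero cooccurrence), and the KDE, when present, is
a standard density over the whole line normalized to 1.

## Localized mutual information

Mutual information $I(X;Y) = \iint p \log\{p/(p_X p_Y)\}$ is estimated by an
equal-frequency histogram plug-in: both samples are rank-binned into $B$
classes and $\hat p \log(\hat p/\hat p_x \hat p_y)$ is summed over occupied
cells, in nats. The bin rule is $B = \max(2, \lfloor (n/5)^{1/3} \rfloor)$:
with $B^2 \sim (n/5)^{2/3}$ cells the expected count per cell grows like
$n^{1/3}$, so the independence bias of the plug-in (approximately
$(B-1)^2/2n$ nats) vanishes as $n$ grows — at $n = 10^5$ it is ~0.003 nats.
A rule that keeps the count per cell constant (cells proportional to $n$)
leaves an $O(1)$ bias near 0.1 nats on independent data and would make the
estimator inconsistent for the null, which is the property the whole
association analysis rests on. A Kraskov k-NN estimator is available as an
independent cross-check; on correlated Gaussians both land within a few
percent of the closed form $-\tfrac12\log(1-\rho^2)$. Negative estimates
(possible for k-NN) are clamped to zero and flagged.

With exactly equal-frequency bins and $y = x$, the estimate is exactly the
entropy of the bin occupancies — $\log B$ when $B$ divides $n$, and the
slightly smaller exact value for uneven splits (at $B = 2$, $n = 97$:
$\ln 2 - 5\times10^{-5}$). The test suite asserts these closed forms.

The localized MI function evaluates both curves on the shared grid and, for
each grid time $t_i$, estimates MI within the window
$[t_i - \lambda, t_i + \lambda]$ separately for the latitude pair and the
longitude pair, combining them as the unweighted Euclidean norm
$\sqrt{I_{lat}^2 + I_{lon}^2}$. Defaults: window radius 48 h (a 4-day window
centered on $t_i$), window samples are the hourly grid evaluations, minimum
10 samples per window (below that the value is masked as undefined, not
zero). Windows truncate at the overlap boundaries; truncated boundary
windows have fewer samples and noisier MI, which can produce spurious edge
peaks — a known artifact to keep in mind when reading LMI curves near the
ends of a shared monitoring window. Weighting samples toward the window
center and per-coordinate weighting of the norm are deliberately not
implemented.

**Scaling.** Two policies map raw LMI to $[0,1]$. The default
`pointwise_max` divides each series' value at $t_i$ by the maximum across
the supplied series at $t_i$ — a relative-association scale across pairs,
degenerate (identically 1) for a single series. `global_max` divides each
series by its own maximum over time and is the right choice for a single
pair. $0/0$ maps to 0. Both preserve the within-time ordering of series.

## The synthetic generator

`simulate_track()` draws a discretized Ornstein–Uhlenbeck process per
coordinate around a home center:
$x_{t+\Delta} = x_t + \theta(\mu - x_t)\Delta + \sigma\sqrt{\Delta}\,\varepsilon$,
the simplest home-ranging kinematic with closed-form stationary variance
$\sigma^2/(2\theta)$ (a property the tests verify at long horizons).
Defaults: $\theta = 1$/day, $\sigma = 0.05°/\sqrt{\text{day}}$ — stationary
SD ≈ 0.035° ≈ 3.9 km near the equator, a realistic home-range scale for a
large territorial carnivore; hourly nominal fixes. Simulation is in degrees
with centers near the equator so the degree-to-meter conversion is nearly
isotropic in tests.

The gap model starts an outage after each retained fix with probability
0.05, with exponential length of mean 8 h floored at 2 h. These values
reproduce the coverage seen in public large-carnivore deposits — roughly
70–85% of nominal hourly fixes retained, gaps from two hours to multiple
days — rather than a heavier corruption that no real collar schedule shows.
The implied missing fraction is $qL/(1+qL)$ for gap rate $q$ and mean gap
length $L$ fixes (≈ 29% at the defaults), which the tests check empirically.

`simulate_associated_pair()` couples the two tracks' innovations inside
scheduled windows ($\varepsilon_B = \rho\varepsilon_A +
\sqrt{1-\rho^2}\,\eta$) and leaves them independent outside. Coupling at the
innovation level, not the position level, means association can be injected
between animals with distant home centers — associated movement without
proximity, the phenomenon that motivates measuring association separately
from distance. The generator returns the innovation matrices and window
membership as ground truth.

What the generator does *not* emulate: measurement error with heavy tails,
terrain or barrier effects, state-switching behavior (foraging/migration
regimes), diurnal activity cycles, and attraction *in space* between
animals. Passing the recovery tests therefore shows the pipeline detects
innovation-level coupling under realistic sampling; it does not certify
behavior under measurement error (not modeled here, and absent from the
public data the defaults are matched to) or under spatially mediated
interaction.

## Validation design and problem sizes

The end-to-end association check runs 20 seeded 80-day pairs with one 20-day
coupling window at $\rho = 0.9$, analyzed with the full default workflow
(density-guided knots, GCV-tuned penalties, hourly grid, 48-h LMI radius),
and requires the LMI argmax to fall inside the window ±48 h in at least
18 of 20 runs with a median inside/outside ratio of at least 3. The 80-day /
20-day proportions keep one replicate around a second of compute so the
whole design runs comfortably on a single core; the qualitative behavior is
unchanged at longer durations.

Two practical observations from this design are worth recording. First,
smoothing interacts with window length: within a 4-day window an OU path
with a 1-day reversion time has only a handful of effectively independent
excursions, so *any* two smooth curves show nonzero spurious windowed MI
(median ≈ 0.05 nats under independence at these settings, versus ≈ 0.25–0.5
inside coupling windows). Second, heavy gap corruption raises that spurious
floor, because spline interpolation across long gaps manufactures smooth
trends; with gap levels matched to real deposits the inside/outside contrast
is a factor of 3–8.

## Known limitations

- No measurement-error model: fixes are taken at face value, as in the
  public data the package is designed around. Smoothing absorbs some noise
  but confounds it with genuine small-scale movement.
- Binary rest classification at a single cutoff; no multi-state behavioral
  model.
- LMI carries no significance test; peaks should be read comparatively
  (against the same pair's baseline and other pairs), not as hypothesis
  tests.
- Pairwise only: three-way cooccurrence and partial/conditional MI are out
  of scope.
- GCV can under-smooth tracks whose sampling density varies sharply;
  the returned trace is there so the choice can be inspected and overridden.
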