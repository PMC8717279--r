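# Internal helpers shared across modules.

# Structured error constructors so callers can distinguish failure modes.
stop_config <- function(msg, ...) abort(msg, class = "trackfda_config_error", ...)
stop_input <- function(msg, ...) abort(msg, class = "trackfda_input_error", ...)
stop_domain <- function(msg, ...) abort(msg, class = "trackfda_domain_error", ...)
stop_parameter <- function(msg, ...) abort(msg, class = "trackfda_parameter_error", ...)
stop_overlap <- function(msg, ...) abort(msg, class = "trackfda_overlap_error", ...)

#' Refined uniform time grid anchored at the study epoch
#'
#' All animals' smoothed paths are evaluated on subsets of one global uniform
#' grid (multiples of the resolution counted from study time 0), so grids for
#' different animals align exactly and pairwise series can be joined by time.
#'
#' @param domain Numeric length-2, start and end of the window in study days.
#' @param resolution Grid spacing in minutes (default 60).
#' @param anchor Time (study days) the grid is anchored at; default 0, the
#'   study epoch.
#' @return Numeric vector of grid times in study days (possibly empty).
#' @examples
#' length(refined_grid(c(0, 10)))  # 241 hourly points
#' @export
refined_grid <- function(domain, resolution = 60, anchor = 0) {
  if (length(domain) != 2 || !all(is.finite(domain)) || domain[1] > domain[2]) {
    stop_parameter("`domain` must be a finite increasing length-2 vector.")
  }
  if (!is.numeric(resolution) || resolution <= 0) {
    stop_parameter("`resolution` must be a positive number of minutes.")
  }
  step <- resolution / 1440
  eps <- step * 1e-9
  k <- seq(ceiling((domain[1] - anchor) / step - eps),
           floor((domain[2] - anchor) / step + eps))
  anchor + k * step
}

# Quantile-based five-number summary (linear interpolation, stats type 7).
five_num <- function(x) {
  q <- unname(quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE))
  tibble(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

# Evaluate `code` under a given seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
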