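#' Least-squares arrival rate from a cumulative series
#'
#' Fits the homogeneous-rate model `M(t) = lambda * t` to an observed
#' cumulative arrival series by minimising the sum of squared daily errors
#' `sum_{t=0}^{n} (M(t) - lambda t)^2`. The minimiser has the closed form
#'
#' \deqn{\lambda^* = \frac{6 \sum_{t=0}^{n} t\,M(t)}{n(n+1)(2n+1)},}
#'
#' using the identity `sum t^2 = n(n+1)(2n+1)/6`. A perfectly linear series
#' returns its slope exactly.
#'
#' @param series an [arrival_series()] with at least one observed day.
#' @return The estimated rate `lambda*` in persons per day.
#' @examples
#' estimate_lambda(arrival_series(c(0, 2, 4, 6)))  # exactly 2
#' @export
estimate_lambda <- function(series) {
  stopifnot(inherits(series, "arrival_series"))
  n <- series$n
  if (n < 1L) stop("need at least one observed day to identify a rate", call. = FALSE)
  t <- 0:n
  6 * sum(t * series$M) / (n * (n + 1) * (2 * n + 1))
}

#' Least-squares pull rate across origins
#'
#' Estimates the single pull rate `rho` linking diaspora size to arrival
#' intensity, by minimising `g(rho) = sum_i (M_i - rho R_i t)^2` over origins,
#' where `M_i` is the observed total arrivals from origin `i` during `t` days
#' and `R_i` its diaspora size. The minimiser is
#'
#' \deqn{\rho^* = \frac{\sum_i M_i R_i}{t \sum_i R_i^2}.}
#'
#' @param M per-origin total arrivals over the window (persons).
#' @param R per-origin diaspora totals (persons); at least one must be > 0.
#' @param t window length in days (> 0).
#' @return The estimated pull rate `rho*` in persons^-1 day^-1.
#' @examples
#' estimate_pull_rate(M = c(1, 4), R = c(100, 200), t = 10)  # 1.8e-3
#' @export
estimate_pull_rate <- function(M, R, t) {
  if (length(M) != length(R)) stop("M and R must have the same length", call. = FALSE)
  if (anyNA(M) || anyNA(R) || any(M < 0) || any(R < 0))
    stop("M and R must be nonnegative and non-NA", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0)
    stop("t must be a single positive number of days", call. = FALSE)
  if (all(R == 0))
    stop("all diaspora totals are zero: pull rate unidentifiable", call. = FALSE)
  sum(M * R) / (t * sum(R^2))
}

#' Normal-approximation band for a Poisson expectation
#'
#' For a Poisson count with expectation `lambda * t`, the normal approximation
#' gives the envelope `lambda t -/+ theta * sqrt(lambda t)`. With `theta = 1.96`
#' this is the usual 95% interval; wider multipliers give heuristic envelopes
#' for path-wise checks.
#'
#' @param rate arrival rate `lambda` (persons/day).
#' @param t window length in days.
#' @param theta band multiplier (>= 0).
#' @param integer_bounds if `TRUE` (default), both bounds are floored to
#'   integers when reported as counts.
#' @param warn_below warn when the expectation `lambda * t` is below this value
#'   and positive (the normal approximation degrades for small counts);
#'   default 30.
#' @return A list of class `interval_band` with `center`, `lower`, `upper`,
#'   `theta` and `method = "normal"`. The lower bound is clipped at 0.
#' @examples
#' normal_band(rate = 131478, t = 1, theta = 1.96)  # (130767, 132188)
#' @export
normal_band <- function(rate, t, theta, integer_bounds = TRUE, warn_below = 30) {
  check_rate(rate, "rate")
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0)
    stop("theta must be a single nonnegative multiplier", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single nonnegative number of days", call. = FALSE)
  center <- rate * t
  if (center > 0 && center < warn_below)
    warning(sprintf("expected count %.2f is below %g: normal approximation may be poor",
                    center, warn_below), call. = FALSE)
  half <- theta * sqrt(center)
  lower <- max(center - half, 0)
  upper <- center + half
  if (integer_bounds) {
    lower <- floor(lower)
    upper <- floor(upper)
  }
  structure(list(center = center, lower = lower, upper = upper,
                 theta = theta, method = "normal"),
            class = "interval_band")
}

#' Monte-Carlo band for a Poisson expectation
#'
#' Empirical central quantile interval of `Pois(lambda t)` draws, for small
#' expectations where the normal approximation is unreliable.
#'
#' @inheritParams normal_band
#' @param level coverage level in (0, 1).
#' @param n_samples number of Poisson draws (>= 1000).
#' @param seed integer seed; the interval is reproducible under a fixed seed.
#' @return A list of class `interval_band` with `method = "monte_carlo"`.
#' @export
monte_carlo_band <- function(rate, t, level = 0.99, n_samples = 10000L, seed = 1L) {
  check_rate(rate, "rate")
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1", call. = FALSE)
  if (n_samples < 1000L) stop("n_samples must be at least 1000", call. = FALSE)
  center <- rate * t
  if (center == 0) {
    return(structure(list(center = 0, lower = 0, upper = 0, level = level,
                          method = "monte_carlo"), class = "interval_band"))
  }
  draws <- with_seed(seed, stats::rpois(n_samples, center))
  alpha <- (1 - level) / 2
  q <- stats::quantile(draws, probs = c(alpha, 1 - alpha), names = FALSE, type = 1)
  structure(list(center = center, lower = q[1], upper = q[2], level = level,
                 method = "monte_carlo"), class = "interval_band")
}

#' @export
print.interval_band <- function(x, ...) {
  cat(sprintf("%s band: center %.2f, [%g, %g]\n", x$method, x$center, x$lower, x$upper))
  invisible(x)
}

#' Check whether a cumulative series is consistent with a constant rate
#'
#' Estimates `lambda*` from the series itself and checks that the observed
#' cumulative count stays inside the envelope
#' `[lambda* t - theta sqrt(lambda* t), lambda* t + theta sqrt(lambda* t)]`
#' for every day `t >= t_min`. This is a heuristic envelope (the default
#' `theta = 4` is deliberately generous and is not a calibrated pointwise or
#' path-wise test): a path that leaves the envelope, e.g. one that flat-lines
#' after a shock, is flagged with the violating days.
#'
#' @param series an [arrival_series()].
#' @param theta band multiplier; default 4.
#' @param t_min first day the envelope is enforced; defaults to the first day
#'   with `lambda* t >= 1`, where sqrt-scale bands are meaningful.
#' @return A list of class `constant_rate_check` with `pass` (logical),
#'   `lambda` (the estimate used), `violations` (integer days outside the
#'   envelope) and `t_min`.
#' @examples
#' s <- arrival_series(round(2 * (0:100)))
#' constant_rate_check(s)$pass  # TRUE
#' @export
constant_rate_check <- function(series, theta = 4, t_min = NULL) {
  stopifnot(inherits(series, "arrival_series"))
  lambda <- estimate_lambda(series)
  t <- 0:series$n
  if (is.null(t_min)) {
    t_min <- if (lambda > 0) ceiling(1 / lambda) else series$n + 1L
  }
  center <- lambda * t
  half <- theta * sqrt(center)
  active <- t >= t_min
  outside <- active & (series$M < center - half | series$M > center + half)
  structure(list(pass = !any(outside), lambda = lambda,
                 violations = t[outside], t_min = t_min, theta = theta),
            class = "constant_rate_check")
}

#' @export
print.constant_rate_check <- function(x, ...) {
  cat(sprintf("Constant-rate check (theta = %g, lambda* = %.4g): %s\n",
              x$theta, x$lambda, if (x$pass) "not rejected" else "REJECTED"))
  if (!x$pass)
    cat(sprintf("  %d violating day(s), first at t = %d\n",
                length(x$violations), min(x$violations)))
  invisible(x)
}

#' Forecast next year's flows from last year's arrivals
#'
#' Treats last year's observed arrivals `A_ij` as the Poisson rate for the
#' coming year (the arrivals are assumed to stem from a fixed pull rate acting
#' on an unobserved diaspora, so the expected count next year equals the count
#' just observed) and attaches normal-approximation bands with multiplier `z`.
#' When a `grouping` is supplied destinations are aggregated before banding,
#' so regional totals get their own (tighter, in relative terms) intervals.
#'
#' @param last_year_flows a [flow_matrix()] of last year's arrivals.
#' @param z band multiplier; default 1.96 (95% normal).
#' @param grouping optional named map destination -> group passed to
#'   [aggregate_destinations()].
#' @return A data.frame with columns `origin`, `destination`, `expected`,
#'   `lower`, `upper`; bounds are floored integer counts, lower clipped at 0.
#' @examples
#' fl <- flow_matrix(rbind(Africa = c(total = 131478)), window_days = 365)
#' forecast_next_year(fl)  # expected 131478, band (130767, 132188)
#' @export
forecast_next_year <- function(last_year_flows, z = 1.96, grouping = NULL) {
  stopifnot(inherits(last_year_flows, "flow_matrix"))
  flows <- last_year_flows
  if (!is.null(grouping)) flows <- aggregate_destinations(flows, grouping)
  cells <- expand.grid(origin = rownames(flows), destination = colnames(flows),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expected <- as.vector(unclass(flows))
  bands <- lapply(expected, function(a) {
    suppressWarnings(normal_band(rate = a, t = 1, theta = z))
  })
  data.frame(cells,
             expected = expected,
             lower = vapply(bands, `[[`, numeric(1), "lower"),
             upper = vapply(bands, `[[`, numeric(1), "upper"))
}
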