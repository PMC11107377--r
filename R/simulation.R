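#' Sample per-origin total arrivals
#'
#' Draws the total number of arrivals from each origin over a window of `t`
#' days as independent Poisson counts with means `lambda_i * t`.
#'
#' @param rates named vector of per-origin arrival rates `lambda_i`
#'   (persons/day), all nonnegative and finite.
#' @param t window length in days (> 0).
#' @param seed integer seed.
#' @return Named integer vector of sampled totals.
#' @export
sample_total_arrivals <- function(rates, t, seed = 1L) {
  if (!is.numeric(rates) || anyNA(rates) || any(rates < 0) || any(!is.finite(rates)))
    stop("rates must be finite nonnegative numbers", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0)
    stop("t must be a single positive number of days", call. = FALSE)
  draws <- with_seed(seed, stats::rpois(length(rates), rates * t))
  names(draws) <- names(rates)
  draws
}

#' Allocate arrivals to destinations
#'
#' Splits `m` arrivals over destinations with a single multinomial draw with
#' probabilities `probs`. The destination counts always sum to `m` exactly.
#'
#' @param m total arrivals to allocate (nonnegative integer).
#' @param probs probability vector over destinations (sums to 1).
#' @param seed integer seed.
#' @return Named integer vector of destination counts summing to `m`.
#' @export
allocate_destinations <- function(m, probs, seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m != round(m))
    stop("m must be a single nonnegative integer", call. = FALSE)
  check_probs(probs)
  counts <- if (m == 0) rep(0L, length(probs))
            else with_seed(seed, as.vector(stats::rmultinom(1, size = m, prob = probs)))
  names(counts) <- names(probs)
  counts
}

#' Simulate an ensemble of origin-destination flows
#'
#' Draws `n_runs` independent realizations of the hierarchical model: for each
#' run, per-origin totals `M_i ~ Pois(rho R_i t)` followed by a multinomial
#' allocation over destinations. Under `model = "diaspora"` the allocation
#' probabilities are the diaspora shares `R_ij / R_i`; under
#' `model = "gravity"` they are the population shares `P_j / P` (the same for
#' every origin), while the totals still come from the diaspora intensities so
#' the comparison isolates the assortativity component.
#'
#' Each run uses a child seed derived from `seed` and the run index, so an
#' ensemble is bitwise-reproducible and its runs do not share a stream.
#'
#' @param rho pull rate (persons^-1 day^-1).
#' @param stocks a [stock_matrix()]; every origin must have `R_i > 0`.
#' @param t window length in days (> 0).
#' @param n_runs number of runs (>= 1).
#' @param seed root integer seed.
#' @param model `"diaspora"` or `"gravity"`.
#' @param pop a [population_vector()], required for the gravity model; its
#'   labels must match the stock matrix's destinations.
#' @return An object of class `simulation_ensemble`: list with `runs` (list of
#'   [flow_matrix()]), `seed`, `model`, `rho` and `window_days`.
#' @examples
#' stocks <- stock_matrix(rbind(A = c(j1 = 50, j2 = 50)))
#' ens <- simulate_flows(2e-2, stocks, t = 200, n_runs = 5, seed = 7)
#' length(ens$runs)
#' @export
simulate_flows <- function(rho, stocks, t, n_runs = 100L, seed = 1L,
                           model = c("diaspora", "gravity"), pop = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(stocks, "stock_matrix"))
  check_rate(rho, "rho")
  if (n_runs < 1L) stop("n_runs must be at least 1", call. = FALSE)
  ri <- row_totals(stocks)
  if (any(ri == 0))
    stop("every origin needs a nonzero diaspora to simulate arrivals", call. = FALSE)
  probs <- if (model == "diaspora") {
    assortativity_probs(stocks)
  } else {
    if (is.null(pop)) stop("gravity model requires a population vector", call. = FALSE)
    if (!identical(names(pop), colnames(stocks)))
      stop("population labels must match stock destinations", call. = FALSE)
    g <- gravity_probs(pop)
    matrix(g, nrow = nrow(stocks), ncol = ncol(stocks), byrow = TRUE,
           dimnames = dimnames(stocks))
  }
  runs <- lapply(seq_len(n_runs), function(k) {
    with_seed(child_seed(seed, k), {
      totals <- stats::rpois(nrow(stocks), rho * ri * t)
      M <- t(vapply(seq_len(nrow(stocks)), function(i) {
        if (totals[i] == 0) rep(0L, ncol(stocks))
        else as.vector(stats::rmultinom(1, totals[i], probs[i, ]))
      }, integer(ncol(stocks))))
      dimnames(M) <- dimnames(stocks)
      flow_matrix(M, window_days = t)
    })
  })
  structure(list(runs = runs, seed = as.integer(seed), model = model,
                 rho = rho, window_days = t),
            class = "simulation_ensemble")
}

#' @export
print.simulation_ensemble <- function(x, ...) {
  cat(sprintf("Simulation ensemble: %d %s-model runs over %g days (seed %d)\n",
              length(x$runs), x$model, x$window_days, x$seed))
  invisible(x)
}

check_probs <- function(probs) {
  if (!is.numeric(probs) || anyNA(probs) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("probabilities must sum to 1 within 1e-12", call. = FALSE)
  invisible(TRUE)
}
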