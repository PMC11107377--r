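#' Specify a synthetic migration world
#'
#' A world spec fixes the statistical shape of a synthetic destination country:
#' how many origins and destinations exist, how unequal destination sizes are
#' (Zipf rank-size populations), how concentrated each origin's diaspora is
#' (Dirichlet concentration `alpha`: small values give homophilic,
#' few-destination diasporas), and how strongly diaspora placement tracks
#' population (`coupling`: 0 = independent of population, 1 = diasporas placed
#' by population shares, the regime where the gravity baseline is exact).
#'
#' Defaults echo a national register seen over roughly half a year: 20 origins,
#' 100 destinations, 1.5 million diaspora members in a country of 9 million,
#' pull rate 3.29e-4 per person per day, 200-day window.
#'
#' @param n_origins,n_destinations number of origins / destinations (>= 1).
#' @param diaspora_total total diaspora stock across all origins (persons).
#' @param population_total total destination-country population (persons).
#' @param zipf_exponent rank-size tail exponent for destination populations
#'   and origin diaspora totals; 1 is the classical city-size value.
#' @param alpha Dirichlet concentration (> 0) of per-origin destination
#'   distributions; this is the total concentration, so `alpha = 0.1` yields
#'   near-one-hot diasporas while large values approach the base distribution.
#' @param coupling in \[0, 1\]: weight of population shares (vs uniform) in the
#'   Dirichlet base distribution.
#' @param rho true pull rate (persons^-1 day^-1).
#' @param t observation window (days).
#' @param seed integer seed.
#' @return A list of class `world_spec`.
#' @export
world_spec <- function(n_origins = 20L, n_destinations = 100L,
                       diaspora_total = 1.5e6, population_total = 9e6,
                       zipf_exponent = 1, alpha = 1, coupling = 0.5,
                       rho = 3.29e-4, t = 200, seed = 1L) {
  stopifnot(n_origins >= 1L, n_destinations >= 1L, alpha > 0,
            coupling >= 0, coupling <= 1, rho >= 0, t > 0,
            diaspora_total > 0, population_total > 0, zipf_exponent >= 0)
  structure(list(n_origins = as.integer(n_origins),
                 n_destinations = as.integer(n_destinations),
                 diaspora_total = diaspora_total,
                 population_total = population_total,
                 zipf_exponent = zipf_exponent, alpha = alpha,
                 coupling = coupling, rho = rho, t = t,
                 seed = as.integer(seed)),
            class = "world_spec")
}

# integer counts proportional to ranks^-s summing (approximately) to total
zipf_counts <- function(n, s, total) {
  w <- (seq_len(n))^(-s)
  pmax(1, round(total * w / sum(w)))
}

rdirichlet1 <- function(alpha_vec) {
  g <- stats::rgamma(length(alpha_vec), shape = alpha_vec, rate = 1)
  if (sum(g) == 0) { # numerically degenerate draw under tiny concentrations
    out <- rep(0, length(alpha_vec))
    out[which.max(alpha_vec)] <- 1
    return(out)
  }
  g / sum(g)
}

#' Generate a synthetic migration world
#'
#' Draws destination populations (Zipf rank-size), per-origin destination
#' distributions (Dirichlet around a base that interpolates between uniform and
#' population shares), and places each origin's diaspora total multinomially
#' across destinations. The realized stocks define the world's true
#' assortativity `pi_ij = R_ij / R_i`, and together with the spec's pull rate
#' they form the generative truth that [generate_observations()] samples from.
#'
#' @param spec a [world_spec()].
#' @return A list of class `synthetic_world`: `stocks` ([stock_matrix()]),
#'   `pop` ([population_vector()]), `rho` (true pull rate), `t` (window),
#'   `assortativity` (row-stochastic matrix of true destination probabilities)
#'   and `spec`.
#' @export
generate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  with_seed(spec$seed, {
    nu <- spec$n_destinations
    mu <- spec$n_origins
    dest <- sprintf("d%03d", seq_len(nu))
    orig <- sprintf("o%02d", seq_len(mu))
    P <- zipf_counts(nu, spec$zipf_exponent, spec$population_total)
    names(P) <- dest
    pop_share <- P / sum(P)
    base <- spec$coupling * pop_share + (1 - spec$coupling) / nu
    Ri <- zipf_counts(mu, spec$zipf_exponent, spec$diaspora_total)
    R <- t(vapply(seq_len(mu), function(i) {
      pi_i <- rdirichlet1(spec$alpha * base)
      as.vector(stats::rmultinom(1, Ri[i], pi_i))
    }, integer(nu)))
    dimnames(R) <- list(orig, dest)
    stocks <- stock_matrix(R)
    structure(list(stocks = stocks, pop = population_vector(P),
                   rho = spec$rho, t = spec$t,
                   assortativity = assortativity_probs(stocks),
                   spec = spec),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d origins, %d destinations, %s diaspora members, rho = %g\n",
              nrow(x$stocks), ncol(x$stocks),
              format(sum(x$stocks), big.mark = ","), x$rho))
  invisible(x)
}

#' Sample observed arrivals from a synthetic world
#'
#' Generates the world's "observed" data from the model itself: for each
#' origin, daily arrival increments are Poisson with mean `rho * R_i`, each
#' day's arrivals are allocated to destinations multinomially with the world's
#' true assortativity, and the flow matrix is the exact sum of the daily
#' allocations. The per-origin cumulative series therefore ends at exactly the
#' flow matrix's row total.
#'
#' @param world a [generate_world()] result.
#' @param rho pull rate; defaults to the world's true rate.
#' @param t window in days; defaults to the world's window.
#' @param seed integer seed.
#' @return A list with `series` (named list of [arrival_series()], one per
#'   origin) and `flows` (a [flow_matrix()]).
#' @export
generate_observations <- function(world, rho = world$rho, t = world$t,
                                  seed = 1L) {
  stopifnot(inherits(world, "synthetic_world"))
  check_rate(rho, "rho")
  t <- as.integer(t)
  if (t < 1L) stop("t must be at least one day", call. = FALSE)
  stocks <- world$stocks
  ri <- row_totals(stocks)
  probs <- world$assortativity
  with_seed(seed, {
    out_flows <- matrix(0L, nrow(stocks), ncol(stocks), dimnames = dimnames(stocks))
    series <- vector("list", nrow(stocks))
    names(series) <- rownames(stocks)
    for (i in seq_len(nrow(stocks))) {
      daily <- stats::rpois(t, rho * ri[i])
      pos <- daily > 0
      if (any(pos)) {
        # rmultinom vectorizes over draws only at fixed size; allocate each
        # positive day at its own size
        alloc <- vapply(daily[pos], function(m)
          as.vector(stats::rmultinom(1, m, probs[i, ])), integer(ncol(stocks)))
        out_flows[i, ] <- as.integer(rowSums(alloc))
      }
      series[[i]] <- arrival_series(c(0, cumsum(daily)),
                                    origin = rownames(stocks)[i])
    }
    list(series = series, flows = flow_matrix(out_flows, window_days = t))
  })
}
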