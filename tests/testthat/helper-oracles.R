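# Independent brute-force oracles: each minimizes the stated least-squares
# objective directly (dense grid bracketing + Brent refinement), without using
# the closed-form estimators they are checked against.

brute_force_lambda <- function(M, upper = NULL) {
  n <- length(M) - 1
  t <- 0:n
  obj <- function(lambda) sum((M - lambda * t)^2)
  if (is.null(upper)) upper <- max(2 * max(M) / max(n, 1), 10)
  grid <- seq(0, upper, length.out = 2001)
  best <- grid[which.min(vapply(grid, obj, numeric(1)))]
  lo <- max(0, best - upper / 1000)
  hi <- best + upper / 1000
  stats::optimize(obj, c(lo, hi), tol = 1e-12)$minimum
}

brute_force_rho <- function(M, R, t, upper = NULL) {
  obj <- function(rho) sum((M - rho * R * t)^2)
  if (is.null(upper)) upper <- max(2 * max(M) / (t * min(R[R > 0])), 1e-3)
  grid <- seq(0, upper, length.out = 2001)
  best <- grid[which.min(vapply(grid, obj, numeric(1)))]
  lo <- max(0, best - upper / 1000)
  hi <- best + upper / 1000
  stats::optimize(obj, c(lo, hi), tol = 1e-15)$minimum
}

# seeded evaluation without touching the ambient RNG state afterwards
with_seed_for_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# mirrors the package's documented child-seed convention
child_seed_for_test <- function(seed, k) {
  as.integer((as.double(seed) + 1000003 * as.double(k)) %% 2147483647)
}

rdirichlet_test <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# small stock matrix shared across tests
toy_stocks <- function() {
  diasporaflow::stock_matrix(rbind(A = c(j1 = 10, j2 = 90),
                                   B = c(j1 = 150, j2 = 50)))
}

# wrap a list of flow matrices as an ensemble (for evaluation tests that need
# hand-built runs rather than simulated ones)
as_ensemble <- function(runs, model = "diaspora", seed = 1L) {
  structure(list(runs = runs, seed = seed, model = model, rho = NA_real_,
                 window_days = attr(runs[[1]], "window_days")),
            class = "simulation_ensemble")
}
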