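test_that("lambda estimator returns the slope of a perfectly linear series", {
  expect_equal(estimate_lambda(arrival_series(c(0, 2, 4, 6))), 2)
  expect_equal(estimate_lambda(arrival_series(rep(0, 10))), 0)
  for (lam0 in c(0, 1, 7, 50)) {
    M <- lam0 * (0:30)
    expect_equal(estimate_lambda(arrival_series(M)), lam0)
  }
  expect_error(estimate_lambda(arrival_series(c(0))), "at least one")
})

test_that("lambda estimator matches the brute-force least-squares oracle", {
  s <- arrival_series(c(0, 1, 5, 6))
  expect_equal(estimate_lambda(s), 6 * 29 / 84)
  expect_equal(estimate_lambda(s), brute_force_lambda(c(0, 1, 5, 6)),
               tolerance = 1e-10)
})

test_that("pull-rate estimator matches hand arithmetic and the oracle", {
  expect_equal(estimate_pull_rate(M = c(1, 4), R = c(100, 200), t = 10), 1.8e-3)
  expect_equal(estimate_pull_rate(M = c(1, 4), R = c(100, 200), t = 10),
               brute_force_rho(c(1, 4), c(100, 200), 10), tolerance = 1e-8)
  # noiseless recovery
  R <- c(3000, 12000, 800)
  expect_equal(estimate_pull_rate(5e-4 * R * 120, R, 120), 5e-4)
  expect_equal(estimate_pull_rate(c(0, 0), c(10, 20), 5), 0)
  expect_error(estimate_pull_rate(c(1, 2), c(0, 0), 5), "unidentifiable")
})

test_that("both closed forms equal brute-force minimizers on random instances", {
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(3:30, 1)
    lam0 <- runif(1, 0.5, 20)
    M <- cumsum(c(0, rpois(n, lam0)))
    est <- estimate_lambda(arrival_series(M))
    if (est > 1e-3) {
      expect_equal(est, brute_force_lambda(M), tolerance = 1e-8)
    }
    mu <- sample(2:20, 1)
    R <- rpois(mu, 5000) + 1
    t <- sample(5:30, 1)
    Mi <- rpois(mu, 3e-4 * R * t)
    rho <- estimate_pull_rate(Mi, R, t)
    if (rho > 1e-8) {
      expect_equal(rho, brute_force_rho(Mi, R, t), tolerance = 1e-8)
    }
  }
})

test_that("normal band reproduces the printed next-year interval", {
  b <- normal_band(rate = 131478, t = 1, theta = 1.96)
  expect_equal(b$lower, 130767)
  expect_equal(b$upper, 132188)
  expect_equal(b$center, 131478)
})

test_that("normal band handles edge cases and is monotone in theta and rate", {
  z <- normal_band(0, 10, 2)
  expect_equal(c(z$center, z$lower, z$upper), c(0, 0, 0))
  b <- suppressWarnings(normal_band(100, 1, 4, warn_below = 30))
  expect_equal(c(b$lower, b$upper), c(60, 140))
  expect_warning(normal_band(10, 1, 2), "approximation")
  expect_error(normal_band(100, 1, -1), "nonnegative")

  width <- function(rate, theta) {
    b <- normal_band(rate, 1, theta, integer_bounds = FALSE)
    b$upper - b$lower
  }
  thetas <- c(0, 1, 2, 4, 8)
  expect_true(!is.unsorted(vapply(thetas, function(th) width(1000, th), numeric(1))))
  rates <- c(50, 100, 1000, 10000)
  expect_true(!is.unsorted(vapply(rates, function(r) width(r, 2), numeric(1))))
})

test_that("monte carlo band matches exact Poisson quantiles and is reproducible", {
  b <- monte_carlo_band(rate = 4, t = 1, level = 0.99, n_samples = 1e5, seed = 3)
  exact <- qpois(c(0.005, 0.995), 4)
  expect_lte(abs(b$lower - exact[1]), 1)
  expect_lte(abs(b$upper - exact[2]), 1)
  b2 <- monte_carlo_band(rate = 4, t = 1, level = 0.99, n_samples = 1e5, seed = 3)
  expect_identical(b, b2)
  z <- monte_carlo_band(0, 10, 0.99)
  expect_equal(c(z$lower, z$upper), c(0, 0))
  expect_error(monte_carlo_band(4, 1, level = 1.2), "between 0 and 1")
})

test_that("constant-rate check accepts a noiseless path and flags a flat-lining one", {
  ok <- constant_rate_check(arrival_series(round(2 * (0:200))), theta = 4)
  expect_true(ok$pass)
  expect_length(ok$violations, 0)

  M <- c(2 * (0:100), rep(200, 100))
  bad <- constant_rate_check(arrival_series(M), theta = 4)
  expect_false(bad$pass)
  expect_true(any(bad$violations > 100)) # the flat regime is flagged
})

test_that("next-year forecast centers on last year's flows with floored bands", {
  africa <- flow_matrix(rbind(Africa = c(total = 131478)), window_days = 365)
  fc <- forecast_next_year(africa, z = 1.96)
  expect_equal(fc$expected, 131478)
  expect_equal(fc$lower, 130767)
  expect_equal(fc$upper, 132188)

  zero <- forecast_next_year(flow_matrix(rbind(A = c(j = 0)), 365))
  expect_equal(c(zero$expected, zero$lower, zero$upper), c(0, 0, 0))

  one <- forecast_next_year(flow_matrix(rbind(A = c(j = 10000)), 365), z = 2)
  expect_equal(c(one$lower, one$upper), c(9800, 10200))
})

test_that("forecast aggregates destinations before banding when grouped", {
  fl <- flow_matrix(rbind(A = c(j1 = 40000, j2 = 91478)), window_days = 365)
  fc <- forecast_next_year(fl, z = 1.96,
                           grouping = c(j1 = "total", j2 = "total"))
  expect_equal(nrow(fc), 1)
  expect_equal(fc$expected, 131478)
  expect_equal(c(fc$lower, fc$upper), c(130767, 132188))
})
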