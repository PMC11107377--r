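test_that("assortativity probabilities are diaspora shares", {
  one <- stock_matrix(rbind(A = c(j1 = 500)))
  expect_equal(unname(assortativity_probs(one, "A")), 1)

  two <- stock_matrix(rbind(A = c(j1 = 10, j2 = 90)))
  expect_equal(assortativity_probs(two, "A"), c(j1 = 0.1, j2 = 0.9))

  sym <- stock_matrix(rbind(A = c(j1 = 3, j2 = 3, j3 = 3)))
  expect_equal(unname(assortativity_probs(sym, "A")), rep(1 / 3, 3))
})

test_that("assortativity fails loudly for zero-diaspora origins and unknown labels", {
  s <- stock_matrix(rbind(A = c(j1 = 10, j2 = 90), B = c(j1 = 0, j2 = 0)))
  expect_error(assortativity_probs(s, "B"), "zero diaspora")
  expect_error(assortativity_probs(s, "Z"), "not present")
})

test_that("assortativity vectors are normalized for random stocks", {
  set.seed(42)
  for (rep in 1:20) {
    R <- matrix(rpois(30, 40) + 1, 5, 6)
    p <- assortativity_probs(stock_matrix(R))
    expect_true(all(abs(rowSums(p) - 1) < 1e-12))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("gravity probabilities are population shares, shared by all origins", {
  expect_equal(unname(gravity_probs(population_vector(c(50, 50)))), c(0.5, 0.5))
  expect_equal(unname(gravity_probs(population_vector(c(30, 70)))), c(0.3, 0.7))
  expect_equal(unname(gravity_probs(population_vector(c(1, 0, 0)))), c(1, 0, 0))
  expect_error(gravity_probs(population_vector(c(0, 0))), "positive")
})

test_that("expected flows reproduce the reference worked examples", {
  poland <- stock_matrix(rbind(PL = c(AT = 42580)))
  daily <- expected_flows(3.29e-4, poland, t = 1)
  expect_equal(unname(floor(daily + 0.5)[1, 1]), 14)
  expect_equal(14 * 200, 2800)

  yearly <- expected_flows(1 / 3031, stock_matrix(rbind(A = c(j = 10000))), t = 365)
  expect_equal(unname(floor(yearly + 0.5)[1, 1]), 1204)

  expect_true(all(expected_flows(3.29e-4, poland, t = 0) == 0))
  expect_error(expected_flows(3.29e-4, poland, t = -1), "nonnegative")
})

test_that("expected flows aggregate exactly over destination partitions", {
  set.seed(7)
  R <- matrix(rpois(40, 100), 4, 10,
              dimnames = list(paste0("o", 1:4), paste0("d", 1:10)))
  stocks <- stock_matrix(R)
  grouping <- setNames(rep(c("g1", "g2", "g3"), c(3, 3, 4)), colnames(R))
  fine <- expected_flows(2e-4, stocks, 150)
  coarse <- expected_flows(2e-4, aggregate_destinations(stocks, grouping), 150)
  expect_equal(t(rowsum(t(fine), grouping[colnames(fine)])), coarse,
               ignore_attr = TRUE)
  # row sums equal rho * R_i * t
  expect_equal(rowSums(fine), 2e-4 * row_totals(stocks) * 150)
})

test_that("scaling all stocks by k scales flows by k and leaves shares unchanged", {
  s <- toy_stocks()
  s3 <- stock_matrix(unclass(s) * 3)
  expect_equal(expected_flows(1e-3, s3, 10), 3 * expected_flows(1e-3, s, 10))
  expect_equal(assortativity_probs(s3), assortativity_probs(s))
})

test_that("diaspora and gravity shares coincide when stocks track population", {
  P <- c(j1 = 2000, j2 = 5000, j3 = 3000)
  R <- rbind(A = P * 2 / 100, B = P * 5 / 100) # R_ij proportional to P_j
  stocks <- stock_matrix(R)
  g <- gravity_probs(population_vector(P))
  for (o in rownames(R)) expect_equal(assortativity_probs(stocks, o), g)
})

test_that("arrival rates are linear in diaspora size", {
  s <- toy_stocks()
  expect_equal(unname(arrival_rate_from_diaspora(0, s)), c(0, 0))
  expect_equal(arrival_rate_from_diaspora(0.01, s), c(A = 1.0, B = 2.0))
  poland <- stock_matrix(rbind(PL = c(AT = 42580)))
  expect_equal(unname(arrival_rate_from_diaspora(3.29e-4, poland)), 14.00882,
               tolerance = 1e-6)
})

test_that("stock matrix validation rejects malformed input", {
  expect_error(stock_matrix(rbind(A = c(-1, 2))), "nonnegative")
  expect_error(stock_matrix(rbind(A = c(1.5, 2))), "integer")
  expect_error(stock_matrix(matrix(1, 2, 2, dimnames = list(c("A", "A"), NULL))),
               "unique")
})

test_that("overlapping or incomplete destination groupings are rejected", {
  s <- toy_stocks()
  expect_error(aggregate_destinations(s, c(j1 = "g")), "does not cover")
  expect_error(aggregate_destinations(s, setNames(c("g", "g"), c("j1", "j1"))),
               "named uniquely")
})
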