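#' Destination choice probabilities from diaspora shares
#'
#' Under the diaspora model a migrant from origin `i` chooses destination `j`
#' with probability equal to the share of the origin's diaspora already living
#' there, `pi_ij = R_ij / R_i`. If a destination hosts 10% of the diaspora
#' from `i`, the probability that a new migrant from `i` settles there is also
#' 10%.
#'
#' @param stocks a [stock_matrix()].
#' @param origin origin label (or, if `NULL`, probabilities for all origins
#'   are returned as a matrix).
#' @return A named probability vector over destinations summing to 1 (or a
#'   row-stochastic matrix when `origin = NULL`).
#' @section Zero diasporas: an origin with `R_i = 0` has no diaspora to read a
#'   destination distribution from; the model is inapplicable there and the
#'   function fails rather than returning arbitrary probabilities.
#' @examples
#' stocks <- stock_matrix(rbind(A = c(j1 = 10, j2 = 90)))
#' assortativity_probs(stocks, "A")  # 0.1, 0.9
#' @seealso [gravity_probs()] for the population-share baseline.
#' @export
assortativity_probs <- function(stocks, origin = NULL) {
  stopifnot(inherits(stocks, "stock_matrix"))
  if (is.null(origin)) {
    out <- t(vapply(rownames(stocks), function(o) assortativity_probs(stocks, o),
                    numeric(ncol(stocks))))
    dimnames(out) <- dimnames(stocks)
    return(out)
  }
  if (!origin %in% rownames(stocks))
    stop(sprintf("origin '%s' not present in stock matrix", origin), call. = FALSE)
  r <- unclass(stocks)[origin, ]
  ri <- sum(r)
  if (ri == 0)
    stop(sprintf(paste0("origin '%s' has zero diaspora (R_i = 0): the diaspora ",
                        "model is inapplicable in the absence of a pre-existing ",
                        "community"), origin), call. = FALSE)
  r / ri
}

#' Destination choice probabilities under the gravity baseline
#'
#' The population-share gravity baseline allocates arrivals to destinations
#' proportionally to their total population, `pi_j = P_j / P`, identically for
#' every origin. It carries no distance term: it is the comparator that
#' captures "big places attract more people" and nothing else.
#'
#' @param pop a [population_vector()].
#' @return A named probability vector over destinations summing to 1.
#' @examples
#' gravity_probs(population_vector(c(a = 30, b = 70)))  # 0.3, 0.7
#' @export
gravity_probs <- function(pop) {
  stopifnot(inherits(pop, "population_vector"))
  total <- sum(pop)
  if (total <= 0) stop("total population must be positive", call. = FALSE)
  unclass(pop) / total
}

#' Expected origin-destination flows over a window
#'
#' The expected number of arrivals from origin `i` to destination `j` over `t`
#' days is `E_ij = rho * R_ij * t`: linear in the local diaspora stock, so
#' expectations aggregate exactly from neighbourhoods to cities to countries.
#'
#' @param rho pull rate (arrivals per diaspora member per day), a single
#'   nonnegative number.
#' @param stocks a [stock_matrix()].
#' @param t window length in days (>= 0).
#' @return Matrix of expected counts with the stock matrix's dimnames.
#' @examples
#' stocks <- stock_matrix(rbind(PL = c(AT = 42580)))
#' expected_flows(3.29e-4, stocks, t = 200)  # ~2801.76, i.e. ~14/day
#' @export
expected_flows <- function(rho, stocks, t) {
  stopifnot(inherits(stocks, "stock_matrix"))
  check_rate(rho, "rho")
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a single nonnegative number of days", call. = FALSE)
  unclass(stocks) * rho * t
}

#' Per-origin arrival rates from diaspora sizes
#'
#' Converts diaspora totals into arrival intensities via `lambda_i = rho * R_i`:
#' a single pull rate applies to every origin, so the expected daily inflow
#' from an origin is proportional to how many of its nationals already live in
#' the destination country.
#'
#' @inheritParams expected_flows
#' @return Named vector of rates `lambda_i` (persons per day).
#' @examples
#' stocks <- stock_matrix(rbind(PL = c(AT = 42580)))
#' arrival_rate_from_diaspora(3.29e-4, stocks)  # ~14.0 persons/day
#' @export
arrival_rate_from_diaspora <- function(rho, stocks) {
  stopifnot(inherits(stocks, "stock_matrix"))
  check_rate(rho, "rho")
  rho * row_totals(stocks)
}

#' Aggregate destinations of a stock or flow matrix
#'
#' Rolls fine destinations (for example postal codes) up to coarser groups
#' (districts, cities) by summing columns. The grouping must be a partition:
#' every destination maps to exactly one group.
#'
#' @param x a [stock_matrix()] or [flow_matrix()] (or plain matrix).
#' @param grouping named character vector mapping every destination label to a
#'   group label.
#' @return Matrix of the same class with one column per group.
#' @export
aggregate_destinations <- function(x, grouping) {
  if (is.null(names(grouping)) || anyDuplicated(names(grouping)))
    stop("grouping must be named uniquely by destination", call. = FALSE)
  missing <- setdiff(colnames(x), names(grouping))
  if (length(missing))
    stop(sprintf("grouping does not cover destinations: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  g <- factor(grouping[colnames(x)], levels = unique(grouping[colnames(x)]))
  agg <- t(rowsum(t(unclass(x)), g))
  colnames(agg) <- levels(g)
  if (inherits(x, "stock_matrix")) return(stock_matrix(agg))
  if (inherits(x, "flow_matrix")) return(flow_matrix(agg, attr(x, "window_days")))
  agg
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x) || x < 0)
    stop(sprintf("%s must be a single finite nonnegative rate", name), call. = FALSE)
  invisible(TRUE)
}
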