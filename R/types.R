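#' Construct a diaspora stock matrix
#'
#' A stock matrix holds the diaspora counts `R[i, j]`: the number of people
#' from origin `i` already resident in destination `j` at the census date.
#' It is the model's only covariate: both the arrival intensity
#' (`lambda_i = rho * R_i`) and the destination assortativity
#' (`pi_ij = R_ij / R_i`) are read off it.
#'
#' @param R numeric matrix of nonnegative integer counts, origins in rows and
#'   destinations in columns. Dimnames are used as labels when present.
#' @param origins,destinations optional character labels overriding dimnames.
#' @return An object of class `stock_matrix`: the validated count matrix with
#'   unique row (origin) and column (destination) labels, plus a `row_totals`
#'   attribute `R_i = sum_j R_ij`.
#' @examples
#' stocks <- stock_matrix(rbind(PL = c(Vienna = 10, Graz = 90)))
#' row_totals(stocks)
#' @export
stock_matrix <- function(R, origins = NULL, destinations = NULL) {
  R <- as.matrix(R)
  if (ncol(R) < 1L) stop("stock matrix needs at least one destination", call. = FALSE)
  if (!is.numeric(R)) stop("stock counts must be numeric", call. = FALSE)
  if (anyNA(R)) stop("stock counts must not contain NA", call. = FALSE)
  if (any(R < 0)) stop("stock counts must be nonnegative", call. = FALSE)
  if (any(R != round(R))) stop("stock counts must be integers", call. = FALSE)
  if (!is.null(origins)) rownames(R) <- origins
  if (!is.null(destinations)) colnames(R) <- destinations
  if (is.null(rownames(R))) rownames(R) <- paste0("o", seq_len(nrow(R)))
  if (is.null(colnames(R))) colnames(R) <- paste0("d", seq_len(ncol(R)))
  if (anyDuplicated(rownames(R))) stop("origin labels must be unique", call. = FALSE)
  if (anyDuplicated(colnames(R))) stop("destination labels must be unique", call. = FALSE)
  structure(R, class = c("stock_matrix", "matrix", "array"))
}

#' @rdname stock_matrix
#' @param x a `stock_matrix`.
#' @export
row_totals <- function(x) {
  stopifnot(inherits(x, "stock_matrix") || is.matrix(x))
  rowSums(unclass(x))
}

#' @export
print.stock_matrix <- function(x, ...) {
  cat(sprintf("Diaspora stock matrix: %d origins x %d destinations, %s persons\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  print(unclass(x), ...)
  invisible(x)
}

#' Construct a destination population vector
#'
#' Destination populations `P_j` drive the gravity baseline, which allocates
#' arrivals proportionally to population shares `P_j / P` for every origin.
#'
#' @param P nonnegative numeric counts (persons), optionally named.
#' @param destinations optional character labels overriding names.
#' @return An object of class `population_vector` (named numeric vector).
#' @examples
#' population_vector(c(Vienna = 1900000, Graz = 290000))
#' @export
population_vector <- function(P, destinations = NULL) {
  if (!is.numeric(P) || anyNA(P)) stop("populations must be numeric and non-NA", call. = FALSE)
  if (any(P < 0)) stop("populations must be nonnegative", call. = FALSE)
  if (!is.null(destinations)) names(P) <- destinations
  if (is.null(names(P))) names(P) <- paste0("d", seq_along(P))
  if (anyDuplicated(names(P))) stop("destination labels must be unique", call. = FALSE)
  structure(P, class = "population_vector")
}

#' @export
print.population_vector <- function(x, ...) {
  cat(sprintf("Destination populations: %d destinations, %s persons total\n",
              length(x), format(sum(x), big.mark = ",")))
  print(unname(cbind(destination = names(x), population = unclass(x))), ...)
  invisible(x)
}

#' Construct a cumulative arrival series
#'
#' The observed cumulative number of arrivals `M(t)` from one origin over
#' days `t = 0, 1, ..., n`, the input to [estimate_lambda()]. The series is
#' window-relative: `M(0) = 0` by convention, and counts never decrease.
#'
#' @param M nondecreasing nonnegative integer counts of length `n + 1`,
#'   starting at day 0.
#' @param origin origin label.
#' @return An object of class `arrival_series` with fields `origin`, `n`
#'   (number of observed days) and `M`.
#' @examples
#' arrival_series(c(0, 2, 4, 6), origin = "PL")
#' @export
arrival_series <- function(M, origin = "origin") {
  if (!is.numeric(M) || anyNA(M)) stop("series must be numeric and non-NA", call. = FALSE)
  if (length(M) < 1L) stop("series must contain day 0", call. = FALSE)
  if (any(M < 0)) stop("cumulative counts must be nonnegative", call. = FALSE)
  if (any(M != round(M))) stop("cumulative counts must be integers", call. = FALSE)
  if (is.unsorted(M)) stop("cumulative counts must be nondecreasing", call. = FALSE)
  structure(list(origin = as.character(origin), n = length(M) - 1L, M = as.numeric(M)),
            class = "arrival_series")
}

#' @export
print.arrival_series <- function(x, ...) {
  cat(sprintf("Cumulative arrivals from %s over %d days: M(n) = %d\n",
              x$origin, x$n, as.integer(x$M[length(x$M)])))
  invisible(x)
}

#' Construct a flow matrix
#'
#' Integer arrival counts `M[i, j]` from origin `i` to destination `j`
#' accumulated over an observation window of `window_days` days.
#'
#' @param M nonnegative integer matrix, origins in rows.
#' @param window_days length of the observation window in days (> 0).
#' @return An object of class `flow_matrix` with a `window_days` attribute.
#' @export
flow_matrix <- function(M, window_days) {
  M <- as.matrix(M)
  if (anyNA(M) || !is.numeric(M)) stop("flows must be numeric and non-NA", call. = FALSE)
  if (any(M < 0)) stop("flows must be nonnegative", call. = FALSE)
  if (any(M != round(M))) stop("flows must be integer counts", call. = FALSE)
  if (!is.numeric(window_days) || length(window_days) != 1L || window_days <= 0)
    stop("window_days must be a single positive number", call. = FALSE)
  if (is.null(rownames(M))) rownames(M) <- paste0("o", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("d", seq_len(ncol(M)))
  structure(M, window_days = as.numeric(window_days),
            class = c("flow_matrix", "matrix", "array"))
}

#' @export
print.flow_matrix <- function(x, ...) {
  cat(sprintf("Flow matrix: %d origins x %d destinations over %g days, %s arrivals\n",
              nrow(x), ncol(x), attr(x, "window_days"), format(sum(x), big.mark = ",")))
  print(unclass(x), ...)
  invisible(x)
}

# shared label-alignment guard
check_labels_match <- function(a, b, what) {
  if (!identical(rownames(a), rownames(b)) || !identical(colnames(a), colnames(b)))
    stop(sprintf("%s: origin/destination labels do not match", what), call. = FALSE)
  invisible(TRUE)
}

# round-half-up, used for human-readable point expectations
round_half_up <- function(x) floor(x + 0.5)
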