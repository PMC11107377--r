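#' Read and write long-format stock CSV
#'
#' Stock files are long-format CSV with header `origin,destination,count`.
#' Pairs absent from the file are zeros; duplicate (origin, destination) pairs
#' and negative or fractional counts are rejected with the offending line
#' number (header = line 1).
#'
#' @param path path to a CSV file.
#' @return [read_stock_matrix()] returns a [stock_matrix()].
#' @export
read_stock_matrix <- function(path) {
  df <- read_checked_csv(path, c("origin", "destination", "count"))
  key <- paste(df$origin, df$destination, sep = "\r")
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1] + 1L
    stop(sprintf("%s: duplicate origin-destination pair at line %d", path, line),
         call. = FALSE)
  }
  check_count_column(df$count, path, "count")
  origins <- unique(df$origin)
  dests <- unique(df$destination)
  R <- matrix(0, length(origins), length(dests), dimnames = list(origins, dests))
  R[cbind(df$origin, df$destination)] <- df$count
  stock_matrix(R)
}

#' @rdname read_stock_matrix
#' @param stocks a [stock_matrix()].
#' @export
write_stock_matrix <- function(stocks, path) {
  stopifnot(inherits(stocks, "stock_matrix"))
  df <- matrix_to_long(unclass(stocks), "count")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write destination population CSV
#'
#' Header `destination,population`.
#'
#' @param path path to a CSV file.
#' @return A [population_vector()].
#' @export
read_population <- function(path) {
  df <- read_checked_csv(path, c("destination", "population"))
  check_count_column(df$population, path, "population")
  if (anyDuplicated(df$destination))
    stop(sprintf("%s: duplicate destination", path), call. = FALSE)
  population_vector(stats::setNames(df$population, df$destination))
}

#' @rdname read_population
#' @param pop a [population_vector()].
#' @export
write_population <- function(pop, path) {
  utils::write.csv(data.frame(destination = names(pop),
                              population = as.integer(pop)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write per-origin cumulative arrival series CSV
#'
#' Header `origin,day,cumulative` with 0-based days; each origin must have a
#' complete day range starting at 0.
#'
#' @param path path to a CSV file.
#' @return A named list of [arrival_series()].
#' @export
read_arrival_series <- function(path) {
  df <- read_checked_csv(path, c("origin", "day", "cumulative"))
  check_count_column(df$day, path, "day")
  check_count_column(df$cumulative, path, "cumulative")
  out <- lapply(split(df, df$origin), function(d) {
    d <- d[order(d$day), ]
    if (!identical(as.integer(d$day), seq.int(0L, nrow(d) - 1L)))
      stop(sprintf("%s: origin '%s' does not have complete days 0..n",
                   path, d$origin[1]), call. = FALSE)
    arrival_series(d$cumulative, origin = d$origin[1])
  })
  out[unique(df$origin)]
}

#' @rdname read_arrival_series
#' @param series a named list of [arrival_series()].
#' @export
write_arrival_series <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(origin = s$origin, day = 0:s$n, cumulative = as.integer(s$M))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write flow CSV
#'
#' Header `origin,destination,count`; the window length is carried separately.
#'
#' @param path path to a CSV file.
#' @param window_days observation window of the file's counts (days).
#' @return A [flow_matrix()].
#' @export
read_flow_matrix <- function(path, window_days) {
  s <- read_stock_matrix(path) # same long format and validation
  flow_matrix(unclass(s), window_days = window_days)
}

#' @rdname read_flow_matrix
#' @param flows a [flow_matrix()].
#' @export
write_flow_matrix <- function(flows, path) {
  df <- matrix_to_long(unclass(flows), "count")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a destination grouping CSV
#'
#' Header `destination,group`; returns the named map used by
#' [aggregate_destinations()] and [estimate_ratio()].
#'
#' @param path path to a CSV file.
#' @return Named character vector destination -> group.
#' @export
read_grouping <- function(path) {
  df <- read_checked_csv(path, c("destination", "group"))
  if (anyDuplicated(df$destination))
    stop(sprintf("%s: destination mapped to more than one group", path),
         call. = FALSE)
  stats::setNames(as.character(df$group), df$destination)
}

#' Load a run configuration
#'
#' YAML (or JSON) file mirroring the pipeline options: input paths, band
#' multipliers, observed-count filter, run count, seed, model tag and output
#' directory. Referenced input files must exist at load time.
#'
#' @param path path to a YAML/JSON config file.
#' @return A named list of class `run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  defaults <- list(theta = 4, z = 1.96, filter = 5, runs = 100L, seed = 1L,
                   model = "diaspora", out = "diasporaflow-out")
  cfg <- utils::modifyList(defaults, cfg)
  if (cfg$theta < 0 || cfg$z < 0) stop("band multipliers must be >= 0", call. = FALSE)
  if (cfg$runs < 1) stop("runs must be >= 1", call. = FALSE)
  for (f in intersect(c("stocks", "series", "flows", "populations"), names(cfg))) {
    if (!file.exists(cfg[[f]]))
      stop(sprintf("config references missing file: %s", cfg[[f]]), call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

matrix_to_long <- function(m, value_name) {
  df <- expand.grid(origin = rownames(m), destination = colnames(m),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df[[value_name]] <- as.integer(as.vector(m))
  df[order(df$origin, df$destination), , drop = FALSE]
}

read_checked_csv <- function(path, columns) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e) stop(sprintf("%s: malformed CSV (%s)",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  if (!identical(names(df), columns))
    stop(sprintf("%s: expected header '%s'", path, paste(columns, collapse = ",")),
         call. = FALSE)
  df
}

check_count_column <- function(x, path, column) {
  bad <- which(is.na(x) | !is.finite(x) | x < 0 | x != round(x))
  if (length(bad))
    stop(sprintf("%s: column '%s' must hold nonnegative integers (line %d)",
                 path, column, bad[1] + 1L), call. = FALSE)
  invisible(TRUE)
}
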