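#' Mean-square error of a simulated ensemble against observed flows
#'
#' For each run in the ensemble, computes the mean squared difference between
#' simulated and observed cell counts over the cells whose observed arrivals
#' exceed `min_count_filter` (rarely-used destinations are excluded the same
#' way sparse postal codes are dropped when plotting). The per-run values and
#' their mean summarise how far the model's plausible draws sit from what was
#' actually observed.
#'
#' @param ensemble a [simulate_flows()] ensemble.
#' @param observed a [flow_matrix()] with identical labels.
#' @param min_count_filter evaluate only cells with observed count strictly
#'   above this value; default 0 (all cells).
#' @param per_origin if `TRUE`, also return the mean MSE split by origin.
#' @return An object of class `evaluation_report`: list with `per_run_mse`,
#'   `mean_mse`, `n_cells`, and optionally `per_origin_mse`.
#' @export
ensemble_mse <- function(ensemble, observed, min_count_filter = 0,
                         per_origin = FALSE) {
  stopifnot(inherits(ensemble, "simulation_ensemble"),
            inherits(observed, "flow_matrix"))
  if (min_count_filter < 0) stop("min_count_filter must be >= 0", call. = FALSE)
  check_labels_match(ensemble$runs[[1]], observed, "ensemble_mse")
  obs <- unclass(observed)
  keep <- obs > min_count_filter
  if (!any(keep))
    stop("no cells pass the observed-count filter", call. = FALSE)
  per_run <- vapply(ensemble$runs, function(run) {
    mean((unclass(run)[keep] - obs[keep])^2)
  }, numeric(1))
  out <- list(per_run_mse = per_run, mean_mse = mean(per_run),
              n_cells = sum(keep), min_count_filter = min_count_filter,
              model = ensemble$model)
  if (per_origin) {
    out$per_origin_mse <- vapply(rownames(obs), function(o) {
      k <- keep[o, ]
      if (!any(k)) return(NA_real_)
      mean(vapply(ensemble$runs,
                  function(run) mean((unclass(run)[o, k] - obs[o, k])^2),
                  numeric(1)))
    }, numeric(1))
  }
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("MSE over %d runs (%s model, %d cells, filter > %g): mean %.4g\n",
              length(x$per_run_mse), x$model, x$n_cells, x$min_count_filter,
              x$mean_mse))
  invisible(x)
}

#' Ratio of mean ensemble MSEs between two models
#'
#' Convenience comparison: mean per-run MSE of `baseline` divided by that of
#' `ensemble`, so values above 1 mean the baseline errs more.
#'
#' @param ensemble,baseline `evaluation_report` objects from [ensemble_mse()].
#' @return A single dimensionless ratio.
#' @export
mse_ratio <- function(baseline, ensemble) {
  stopifnot(inherits(ensemble, "evaluation_report"),
            inherits(baseline, "evaluation_report"))
  baseline$mean_mse / ensemble$mean_mse
}

#' Per-group modeled/observed estimate ratios
#'
#' For each origin and destination group, the ratio of summed modeled to
#' summed observed arrivals. A ratio of 1 means perfect calibration; above 1
#' the model overestimates the group, below 1 it underestimates. Groups with
#' zero observed arrivals cannot be divided and are returned as `NA` with
#' `flagged = TRUE` rather than dropped silently.
#'
#' @param expected numeric matrix of modeled arrivals (origins x destinations).
#' @param observed a [flow_matrix()] with the same labels.
#' @param grouping named map destination -> group defining a partition; when
#'   omitted every destination is its own group.
#' @return A data.frame with columns `origin`, `group`, `expected`, `observed`,
#'   `ratio`, `flagged`.
#' @export
estimate_ratio <- function(expected, observed, grouping = NULL) {
  stopifnot(inherits(observed, "flow_matrix"))
  expected <- as.matrix(expected)
  check_labels_match(expected, observed, "estimate_ratio")
  if (is.null(grouping)) {
    grouping <- stats::setNames(colnames(observed), colnames(observed))
  }
  empty <- setdiff(unique(grouping), unique(grouping[colnames(observed)]))
  if (length(empty))
    stop(sprintf("grouping contains empty group(s): %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  exp_g <- aggregate_destinations(expected, grouping)
  obs_g <- aggregate_destinations(unclass(observed), grouping)
  cells <- expand.grid(origin = rownames(obs_g), group = colnames(obs_g),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  e <- as.vector(exp_g)
  o <- as.vector(obs_g)
  data.frame(cells, expected = e, observed = o,
             ratio = ifelse(o > 0, e / o, NA_real_),
             flagged = o == 0)
}
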