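# Poststratification estimators.
#
# Two algebraically equivalent routes to the poststratified mean:
#   (1) weight every unit by its cell's N_j/n_j and average
#       (sum_j sum_i Y_ij * N_j/n_j) / sum_j N_j;
#   (2) aggregate stratum means with population weights
#       sum_j N_j * Ybar_j / sum_j N_j.
# Route (1) is inverse-probability weighting with the saturated inclusion
# propensity p_j = n_j/N_j; route (2) is standardization of the sampled units
# to the external covariate distribution. Both are exposed, and their
# equivalence is asserted property-style in the test suite.

new_estimate <- function(value, method, n_cells, total_weight) {
  structure(
    list(value = value, method = method,
         n_effective_cells = n_cells, total_weight = total_weight),
    class = "poststrat_estimate"
  )
}

#' @export
print.poststrat_estimate <- function(x, ...) {
  cat(sprintf("<estimate> %s mean = %.6g (%.1f%%) | cells = %d | total weight = %s\n",
              x$method, x$value, 100 * x$value, x$n_effective_cells,
              format(x$total_weight, big.mark = ",")))
  invisible(x)
}

#' Poststratification cell weights
#'
#' Assigns each sample cell the weight \eqn{w_j = N_j/n_j}, the ratio of its
#' population count to its sample count — equivalently the inverse of the
#' estimated inclusion probability \eqn{\hat p_j = n_j/N_j}.
#'
#' Population cells with no sampled units violate positivity: under
#' `on_empty = "error"` they raise a structured positivity error naming the
#' cells; under `"drop_and_renormalize"` they are removed and the remaining
#' \eqn{N_j} rescaled multiplicatively so their sum recovers the original
#' population total, with a warning quantifying the dropped population
#' share. Sampled cells absent from the population table are always an
#' error — they signal a covariate-coding mismatch, not a statistical
#' condition.
#'
#' @param sample A `stratum_counts` object from [crosstab()].
#' @param population A [population_table] over the same covariates.
#' @param on_empty Policy for population cells with no sampled units.
#' @return A `weight_table`: covariate columns plus `N`, `n`, `w`, with
#'   attribute `scale = "population"` (so that \eqn{\sum_j n_j w_j = N}).
#' @seealso [normalize_weights()] for the mean-weight-1 scale.
#' @export
compute_cell_weights <- function(sample, population,
                                 on_empty = c("error", "drop_and_renormalize")) {
  on_empty <- match.arg(on_empty)
  al <- validate_alignment(sample, population)
  covs <- al$covariates
  if (nrow(al$sample_only) > 0L) {
    abort_validation(
      sprintf("sampled cell(s) absent from the population table: %s",
              format_cells(al$sample_only[covs])),
      cells = al$sample_only[covs]
    )
  }
  m <- al$matched
  if (nrow(al$population_only) > 0L) {
    if (on_empty == "error") {
      abort_positivity(
        sprintf("population cell(s) with no sampled units: %s",
                format_cells(al$population_only[covs])),
        cells = al$population_only[covs]
      )
    }
    dropped <- sum(al$population_only$N)
    total <- attr(population, "total")
    m$N <- m$N * total / sum(m$N)
    warning(sprintf(
      "dropped %d population cell(s) with no sampled units (%.2f%% of the population); remaining N_j renormalized",
      nrow(al$population_only), 100 * dropped / total
    ), call. = FALSE)
  }
  out <- m[c(covs, "N", "n")]
  out$w <- out$N / out$n
  rownames(out) <- NULL
  structure(
    out,
    covariates = covs,
    scale = "population",
    total = sum(out$N),
    class = c("weight_table", "data.frame")
  )
}

#' Rescale a weight table to mean weight one
#'
#' The population scale (\eqn{w_j = N_j/n_j}, summing to \eqn{N} over units)
#' is the default; the normalized scale rescales so unit weights average 1
#' (\eqn{\sum_j n_j w_j = n}), the convention many variance heuristics
#' expect. Every estimator here is invariant to the choice.
#'
#' @param weights A `weight_table`.
#' @return The rescaled `weight_table` with `scale = "normalized"`.
#' @export
normalize_weights <- function(weights) {
  stopifnot(inherits(weights, "weight_table"))
  if (attr(weights, "scale") == "normalized") return(weights)
  n <- sum(weights$n)
  N <- sum(weights$n * weights$w)
  weights$w <- weights$w * n / N
  attr(weights, "scale") <- "normalized"
  weights
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("<weight_table> %d cells | scale = %s | covariates: %s\n",
              nrow(x), attr(x, "scale"), paste(covariates(x), collapse = ", ")))
  print(as.data.frame(x))
  invisible(x)
}

#' Per-unit weights from a weight table
#'
#' Maps each microdata row to its cell's weight.
#'
#' @param data A [microdata] object.
#' @param weights A `weight_table` from [compute_cell_weights()].
#' @return Numeric vector of unit weights, aligned with the rows of `data`.
#' @export
unit_weights <- function(data, weights) {
  stopifnot(inherits(data, "microdata"), inherits(weights, "weight_table"))
  covs <- covariates(weights)
  unknown <- setdiff(covs, covariates(data))
  if (length(unknown) > 0L) {
    abort_schema(sprintf("weight-table covariate(s) not in microdata: %s",
                         paste(unknown, collapse = ", ")))
  }
  pos <- match(cell_key(data, covs), cell_key(weights, covs))
  if (anyNA(pos)) {
    bad <- unique(as.data.frame(data)[is.na(pos), sort(covs), drop = FALSE])
    abort_validation(
      sprintf("microdata row(s) in cell(s) with no weight: %s", format_cells(bad)),
      cells = bad
    )
  }
  weights$w[pos]
}

#' Individual-level weighted poststratification estimate
#'
#' Computes \eqn{\sum_j \sum_i Y_{ij} w_j / \sum_j n_j w_j}: each unit is
#' weighted by its cell weight and the weighted outcomes averaged. With
#' weights \eqn{w_j = N_j/n_j} the denominator equals the population total
#' \eqn{N} and the result is the poststratified mean.
#'
#' @inheritParams unit_weights
#' @return A `poststrat_estimate` with `method = "weighted"`.
#' @export
weighted_mean <- function(data, weights) {
  w <- unit_weights(data, weights)
  y <- outcome_values(data)
  new_estimate(sum(w * y) / sum(w), "weighted",
               n_cells = nrow(weights), total_weight = sum(w))
}

#' Stratum-mean aggregation poststratification estimate
#'
#' Computes \eqn{\sum_j N_j \bar Y_j / \sum_j N_j}: stratum-specific outcome
#' means aggregated with population weights. Algebraically identical to
#' [weighted_mean()]; practically, cell means must be re-estimated per
#' outcome whereas unit weights transfer across analyses.
#'
#' @inheritParams compute_cell_weights
#' @return A `poststrat_estimate` with `method = "aggregated"`.
#' @export
cell_mean_aggregate <- function(sample, population) {
  al <- validate_alignment(sample, population)
  covs <- al$covariates
  if (nrow(al$sample_only) > 0L) {
    abort_validation(
      sprintf("sampled cell(s) absent from the population table: %s",
              format_cells(al$sample_only[covs])),
      cells = al$sample_only[covs]
    )
  }
  if (nrow(al$population_only) > 0L) {
    abort_positivity(
      sprintf("population cell(s) with no sample mean: %s",
              format_cells(al$population_only[covs])),
      cells = al$population_only[covs]
    )
  }
  m <- al$matched
  new_estimate(sum(m$N * m$ybar) / sum(m$N), "aggregated",
               n_cells = nrow(m), total_weight = sum(m$N))
}

#' Crude (unweighted) sample mean
#'
#' The plain sample mean of the outcome — valid for the target population
#' only under simple random sampling.
#'
#' @param data A [microdata] object.
#' @return A `poststrat_estimate` with `method = "crude"`.
#' @export
crude_mean <- function(data) {
  stopifnot(inherits(data, "microdata"))
  if (nrow(data) == 0L) abort_validation("cannot take the crude mean of empty microdata")
  new_estimate(mean(outcome_values(data)), "crude",
               n_cells = 1L, total_weight = nrow(data))
}
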