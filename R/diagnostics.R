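# Assumption and weight diagnostics: the standard causal-inference toolbox
# (weight distribution summaries, covariate balance, positivity reports)
# applied to poststratification weights.

#' Summarize a unit-weight distribution
#'
#' Reports the spread of the unit weights together with the Kish effective
#' sample size \eqn{ESS = (\sum w)^2 / \sum w^2} and the design effect
#' \eqn{n/ESS}. The Kish form is the standard survey heuristic for the
#' information content of a weighted sample; highly unequal weights (a few
#' cells carrying most of the population) show up as ESS far below n.
#'
#' @param weights Positive numeric vector of per-unit weights (see
#'   [unit_weights()]).
#' @return A `weight_summary`: `n`, `min`, `max`, `mean`,
#'   `effective_sample_size`, `design_effect`, `max_weight_share`.
#' @export
weight_summary <- function(weights) {
  if (length(weights) == 0L) abort_validation("empty weight vector")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort_validation("all weights must be positive and finite")
  }
  ess <- sum(weights)^2 / sum(weights^2)
  structure(
    list(n = length(weights), min = min(weights), max = max(weights),
         mean = mean(weights), effective_sample_size = ess,
         design_effect = length(weights) / ess,
         max_weight_share = max(weights) / sum(weights)),
    class = "weight_summary"
  )
}

#' @export
print.weight_summary <- function(x, ...) {
  cat(sprintf(
    "<weight_summary> n = %d | w in [%.4g, %.4g], mean %.4g | ESS = %.1f (deff %.2f) | max share %.3g\n",
    x$n, x$min, x$max, x$mean, x$effective_sample_size, x$design_effect,
    x$max_weight_share))
  invisible(x)
}

#' Covariate balance before and after weighting
#'
#' For each covariate, compares the sample's level proportions before and
#' after weighting against the target population's, plus the full joint
#' cross-classification (the cells Table-style census comparisons print).
#' For covariates used as poststratifiers the after-weighting distribution
#' matches the target exactly, by construction.
#'
#' @param data A [microdata] object.
#' @param weights Per-unit numeric weights, or a `weight_table` to map via
#'   [unit_weights()].
#' @param population A [population_table] covering the requested covariates.
#' @param covariates Covariates to report (default: the population table's).
#' @return A `balance_table` data frame: `covariate`, `level`, `before`,
#'   `after`, `target` (proportions) and `diff_after = |after - target|`.
#' @export
balance_table <- function(data, weights, population, covariates = NULL) {
  stopifnot(inherits(data, "microdata"), inherits(population, "population_table"))
  if (inherits(weights, "weight_table")) weights <- unit_weights(data, weights)
  if (length(weights) != nrow(data)) {
    abort_validation("`weights` must align with the microdata rows")
  }
  if (is.null(covariates)) covariates <- covariates(population)
  missing_cov <- setdiff(covariates, covariates(population))
  if (length(missing_cov) > 0L) {
    abort_schema(sprintf("covariate(s) absent from the population table: %s",
                         paste(missing_cov, collapse = ", ")))
  }
  missing_md <- setdiff(covariates, covariates(data))
  if (length(missing_md) > 0L) {
    abort_schema(sprintf("covariate(s) absent from the microdata: %s",
                         paste(missing_md, collapse = ", ")))
  }
  covariates <- canonical_covariates(covariates)
  pop <- as.data.frame(population)

  one_margin <- function(label, sample_levels, pop_levels) {
    lv <- sort(unique(c(sample_levels, pop_levels)))
    before <- vapply(lv, function(l) mean(sample_levels == l), numeric(1L))
    after <- vapply(lv, function(l) sum(weights[sample_levels == l]) / sum(weights),
                    numeric(1L))
    target <- vapply(lv, function(l) sum(pop$N[pop_levels == l]) / sum(pop$N),
                     numeric(1L))
    data.frame(covariate = label, level = lv, before = before, after = after,
               target = target, diff_after = abs(after - target),
               stringsAsFactors = FALSE)
  }

  parts <- lapply(covariates, function(cv) {
    one_margin(cv, as.data.frame(data)[[cv]], pop[[cv]])
  })
  if (length(covariates) > 1L) {
    joint_sample <- do.call(paste, c(as.data.frame(data)[covariates], sep = "/"))
    joint_pop <- do.call(paste, c(pop[covariates], sep = "/"))
    parts <- c(parts, list(
      one_margin(paste(covariates, collapse = ":"), joint_sample, joint_pop)
    ))
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, class = c("balance_table", "data.frame"))
}

#' @export
print.balance_table <- function(x, ...) {
  cat("<balance_table> proportions before/after weighting vs. target\n")
  df <- as.data.frame(x)
  df$before <- sprintf("%.1f%%", 100 * df$before)
  df$after <- sprintf("%.1f%%", 100 * df$after)
  df$target <- sprintf("%.1f%%", 100 * df$target)
  df$diff_after <- sprintf("%.2f pp", 100 * df$diff_after)
  print(df)
  invisible(x)
}

#' Positivity report with per-cell inclusion fractions
#'
#' Augments the [validate_alignment()] report with the estimated inclusion
#' probability \eqn{\hat p_j = n_j / N_j} for each matched cell. Population
#' cells with no sampled units are the positivity violations; the report is
#' descriptive and never raises.
#'
#' @inheritParams validate_alignment
#' @return A `positivity_report`: the alignment report plus `inclusion`
#'   (matched cells with `n`, `N`, `p_hat`) and `violations`
#'   (the population-only cells).
#' @export
positivity_report <- function(sample, population) {
  al <- validate_alignment(sample, population)
  inc <- al$matched[c(al$covariates, "n", "N")]
  inc$p_hat <- inc$n / inc$N
  structure(
    list(alignment = al, inclusion = inc, violations = al$population_only,
         covariates = al$covariates),
    class = "positivity_report"
  )
}

#' @export
print.positivity_report <- function(x, ...) {
  print(x$alignment)
  cat("inclusion fractions p_hat = n/N:\n")
  print(x$inclusion)
  if (nrow(x$violations) > 0L) {
    cat("positivity violations (N > 0, n = 0):", format_cells(x$violations[x$covariates]), "\n")
  }
  invisible(x)
}
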