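# Monte-Carlo laboratory for selection bias. A finite population is created
# once, with fixed covariates X and fixed outcomes Y; each replication draws
# a random inclusion indicator. This encodes the sampling-theory stance that
# outcomes are fixed while inclusion is random, and makes the two assumption
# violations explicit, separate knobs:
#   * outcome_dependence: additive shift of the inclusion probability for
#     units with Y = 1 — breaks conditional independence Y _||_ delta | X;
#   * reactivity: additive shift of the observed outcome upon inclusion —
#     breaks consistency Y = Y^{delta=0} = Y^{delta=1}.
# Both are 0 by default (all assumptions hold). Shifts that push any
# probability outside [0, 1] are rejected, never clipped.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Configure a selection-bias simulation
#'
#' The joint covariate distribution is specified cell by cell: one row per
#' cell with its population proportion `prop`, its Bernoulli outcome
#' probability `q`, and its base inclusion probability `s`.
#'
#' @param cells Data frame with the covariate columns plus `prop`, `q`, `s`.
#' @param population_size Number of units in the finite population.
#' @param outcome_dependence Additive shift of the inclusion probability for
#'   units with `Y = 1`; `0` means conditional independence holds.
#' @param reactivity Additive shift applied to the observed outcome of
#'   included units; `0` means consistency holds.
#' @param seed Master seed; replication seeds are derived as `seed + rep`.
#' @param replications Number of Monte-Carlo replications.
#' @return A `sim_config` list.
#' @examples
#' sim_config(
#'   data.frame(sex = c("men", "women"), prop = c(0.5, 0.5),
#'              q = c(0.3, 0.1), s = c(0.4, 0.6)),
#'   population_size = 2000, seed = 7, replications = 50
#' )
#' @export
sim_config <- function(cells, population_size, outcome_dependence = 0,
                       reactivity = 0, seed = 1L, replications = 100L) {
  if (!is.data.frame(cells)) abort_config("`cells` must be a data frame")
  covs <- setdiff(names(cells), c("prop", "q", "s"))
  if (length(covs) == 0L) abort_config("`cells` must carry at least one covariate column")
  for (col in c("prop", "q", "s")) {
    if (!col %in% names(cells)) abort_config(sprintf("`cells` lacks column '%s'", col))
    if (!is.numeric(cells[[col]]) || anyNA(cells[[col]])) {
      abort_config(sprintf("column '%s' must be numeric with no missing values", col))
    }
  }
  if (abs(sum(cells$prop) - 1) > 1e-9) {
    abort_config(sprintf("cell proportions sum to %.12f, not 1", sum(cells$prop)))
  }
  if (any(cells$prop < 0)) abort_config("cell proportions must be nonnegative")
  if (any(cells$q < 0 | cells$q > 1)) abort_config("outcome probabilities q must lie in [0, 1]")
  if (any(cells$s < 0 | cells$s > 1)) abort_config("inclusion probabilities s must lie in [0, 1]")
  shifted <- cells$s + outcome_dependence
  if (any(shifted < 0 | shifted > 1)) {
    abort_config("s + outcome_dependence leaves [0, 1] for some cell; rejected, not clipped")
  }
  if (!is.numeric(population_size) || length(population_size) != 1L ||
      population_size < 1 || population_size != round(population_size)) {
    abort_config("`population_size` must be a positive integer")
  }
  if (replications < 1 || replications != round(replications)) {
    abort_config("`replications` must be a positive integer")
  }
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  for (cv in covs) cells[[cv]] <- clean_levels(cells[[cv]])
  if (anyDuplicated(cell_key(cells, covs))) abort_config("duplicate covariate cells")
  structure(
    list(cells = cells, covariates = canonical_covariates(covs),
         population_size = as.integer(population_size),
         outcome_dependence = outcome_dependence, reactivity = reactivity,
         seed = as.integer(seed), replications = as.integer(replications)),
    class = "sim_config"
  )
}

#' Generate a finite synthetic population
#'
#' Draws each unit's covariate cell from the configured joint distribution
#' and its outcome once from the cell's Bernoulli model. Covariates and
#' outcomes are then fixed: subsequent sampling never re-randomizes them.
#' Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_population` data frame (covariate columns plus `Y`) with
#'   attributes `true_mean` (the realized population mean of `Y`),
#'   `cell_index` and `covariates`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cells <- config$cells
  covs <- config$covariates
  with_seed(config$seed, {
    idx <- sample.int(nrow(cells), config$population_size, replace = TRUE,
                      prob = cells$prop)
    y <- stats::rbinom(config$population_size, 1L, cells$q[idx])
  })
  pop <- cells[idx, covs, drop = FALSE]
  pop$Y <- y
  rownames(pop) <- NULL
  structure(
    pop,
    covariates = covs,
    cell_index = idx,
    true_mean = mean(y),
    class = c("sim_population", "data.frame")
  )
}

#' Population table of a synthetic population
#'
#' Realized cell counts of a [generate_population()] output — the census the
#' poststratification step adjusts to.
#'
#' @param population A `sim_population`.
#' @return A [population_table] over the population's covariates.
#' @export
as_population_table <- function(population) {
  stopifnot(inherits(population, "sim_population"))
  covs <- attr(population, "covariates")
  key <- cell_key(population, covs)
  tab <- table(key)
  first <- match(names(tab), key)
  cells <- as.data.frame(population)[first, covs, drop = FALSE]
  cells$N <- as.numeric(tab)
  population_table(cells, covariates = covs)
}

#' Draw one nonprobability sample from a synthetic population
#'
#' Each unit is included independently with probability
#' `s_j + outcome_dependence * Y_i`; included units' observed outcome is
#' `Y_i + reactivity`. Only included units are returned, as unit-level
#' [microdata] with outcome column `y`.
#'
#' @param population A `sim_population`.
#' @param config The [sim_config()] that produced it.
#' @param rep_seed Seed for this replication's inclusion draw.
#' @return A [microdata] object of the included units.
#' @export
draw_sample <- function(population, config, rep_seed) {
  stopifnot(inherits(population, "sim_population"), inherits(config, "sim_config"))
  idx <- attr(population, "cell_index")
  p_inc <- config$cells$s[idx] + config$outcome_dependence * population$Y
  if (any(p_inc < 0 | p_inc > 1)) {
    abort_config("inclusion probability outside [0, 1]; rejected, not clipped")
  }
  delta <- with_seed(rep_seed, stats::runif(nrow(population)) < p_inc)
  covs <- attr(population, "covariates")
  sub <- as.data.frame(population)[delta, covs, drop = FALSE]
  sub$y <- population$Y[delta] + config$reactivity
  microdata(sub, covariates = covs, outcome = "y")
}

#' Closed-form expectations for a simulation configuration
#'
#' Analytic (large-replication) expectations of the crude and poststratified
#' estimators, conditional on the realized population: for cell j with
#' \eqn{M_j} units of which \eqn{K_j} have \eqn{Y = 1}, base inclusion
#' \eqn{s_j}, outcome dependence d and reactivity r,
#' \deqn{E[\hat\mu_{crude}] \approx \frac{\sum_j K_j (s_j + d)(1 + r) + (M_j - K_j) s_j r}
#'   {\sum_j K_j (s_j + d) + (M_j - K_j) s_j}}
#' and the poststratified expectation replaces the global ratio by the
#' population-share-weighted sum of the per-cell ratios. With d = r = 0 the
#' poststratified expectation equals the true population mean exactly.
#'
#' @param population A `sim_population`.
#' @param config The matching [sim_config()].
#' @return List with `crude`, `poststratified`, `true_mean`.
#' @export
analytic_expectations <- function(population, config) {
  stopifnot(inherits(population, "sim_population"), inherits(config, "sim_config"))
  idx <- attr(population, "cell_index")
  J <- nrow(config$cells)
  M <- tabulate(idx, nbins = J)
  K <- vapply(seq_len(J), function(j) sum(population$Y[idx == j]), numeric(1L))
  s <- config$cells$s
  d <- config$outcome_dependence
  r <- config$reactivity
  num <- K * (s + d) * (1 + r) + (M - K) * s * r
  den <- K * (s + d) + (M - K) * s
  keep <- M > 0 & den > 0
  list(
    crude = sum(num[keep]) / sum(den[keep]),
    poststratified = sum((M[keep] / sum(M)) * num[keep] / den[keep]),
    true_mean = mean(population$Y)
  )
}

#' Monte-Carlo bias study of crude vs. poststratified estimation
#'
#' Generates the finite population once, then repeatedly draws nonprobability
#' samples and applies both the crude mean and the poststratified mean
#' (stratum aggregation against the realized population table). Replications
#' in which some population cell receives no sampled units are positivity
#' failures: they are counted, reported as a rate, and excluded from the
#' estimate averages.
#'
#' @param config A [sim_config()] with `replications >= 2`.
#' @return A `bias_report`: data frame `estimates` (per estimator: mean
#'   estimate, true mean, bias, Monte-Carlo standard error, replications
#'   used), the per-replication estimates, the positivity failure rate, and
#'   the closed-form expectations from [analytic_expectations()].
#' @export
run_bias_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$replications < 2L) abort_config("a bias study needs replications >= 2")
  population <- generate_population(config)
  pop_table <- as_population_table(population)
  truth <- attr(population, "true_mean")
  crude <- ps <- rep(NA_real_, config$replications)
  failures <- 0L
  for (rep in seq_len(config$replications)) {
    smp <- draw_sample(population, config, rep_seed = config$seed + rep)
    if (nrow(smp) == 0L) { failures <- failures + 1L; next }
    sc <- crosstab(smp)
    est <- tryCatch(
      cell_mean_aggregate(sc, pop_table),
      poststrat_positivity_error = function(e) NULL
    )
    if (is.null(est)) { failures <- failures + 1L; next }
    crude[rep] <- crude_mean(smp)$value
    ps[rep] <- est$value
  }
  used <- sum(!is.na(ps))
  if (used < 2L) abort_config("fewer than 2 replications free of positivity failures")
  summarize <- function(x, label) {
    x <- x[!is.na(x)]
    data.frame(estimator = label, mean_estimate = mean(x), true_mean = truth,
               bias = mean(x) - truth, mc_se = stats::sd(x) / sqrt(length(x)),
               replications = length(x), stringsAsFactors = FALSE)
  }
  structure(
    list(
      estimates = rbind(summarize(crude, "crude"), summarize(ps, "poststratified")),
      per_replication = data.frame(replication = seq_len(config$replications),
                                   crude = crude, poststratified = ps),
      positivity_failure_rate = failures / config$replications,
      analytic = analytic_expectations(population, config),
      seed = config$seed, replications = config$replications
    ),
    class = "bias_report"
  )
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> %d replications | positivity failure rate %.3f | true mean %.6g\n",
              x$replications, x$positivity_failure_rate, x$estimates$true_mean[1L]))
  df <- x$estimates
  df$mean_estimate <- signif(df$mean_estimate, 6)
  df$bias <- signif(df$bias, 4)
  df$mc_se <- signif(df$mc_se, 4)
  print(df)
  cat(sprintf("closed-form expectations: crude %.6g, poststratified %.6g\n",
              x$analytic$crude, x$analytic$poststratified))
  invisible(x)
}
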