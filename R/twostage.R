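# Two-stage comparison of exposure groups drawn from nonprobability samples:
# stage 1 poststratifies each exposure group to its own target population
# (over the selection covariates W), stage 2 directly standardizes both
# groups to a common covariate distribution (over the confounders Z) so the
# contrast is comparable.
#
# W and Z may differ. When W = Z, stage 1 provably cancels out of the final
# estimate — within-cell reweighting leaves cell means unchanged — and only
# rescales; a note is emitted in that case. Allowing W != Z is the only
# reading under which stage 1 carries information into stage 2.

#' Specification for the two-stage comparison
#'
#' @param selection_covariates Variables `W` predicting sample inclusion,
#'   used to poststratify each exposure group in stage 1.
#' @param standardization_covariates Variables `Z` confounding exposure and
#'   outcome, used for the common standardization in stage 2.
#' @param group_populations Named list mapping each treatment level to its
#'   own [population_table] over `W` (the complete population of that
#'   exposure group).
#' @param standard_distribution A [population_table] over `Z`: the common
#'   covariate distribution both groups are standardized to.
#' @param treatment_levels Optional `c(a1, a0)`; the reported difference is
#'   the `a1` estimate minus the `a0` estimate. Defaults to the names of
#'   `group_populations` in descending order.
#' @return A `twostage_spec` list.
#' @export
twostage_spec <- function(selection_covariates, standardization_covariates,
                          group_populations, standard_distribution,
                          treatment_levels = NULL) {
  if (length(selection_covariates) == 0L) abort_schema("selection covariates W must be nonempty")
  if (length(standardization_covariates) == 0L) abort_schema("standardization covariates Z must be nonempty")
  if (is.null(names(group_populations)) || any(names(group_populations) == "")) {
    abort_schema("`group_populations` must be a named list keyed by treatment level")
  }
  for (nm in names(group_populations)) {
    if (!inherits(group_populations[[nm]], "population_table")) {
      abort_schema(sprintf("group population for level '%s' is not a population_table", nm))
    }
  }
  if (!inherits(standard_distribution, "population_table")) {
    abort_schema("`standard_distribution` must be a population_table")
  }
  if (is.null(treatment_levels)) {
    treatment_levels <- sort(names(group_populations), decreasing = TRUE)
  }
  if (length(treatment_levels) != 2L) {
    abort_schema("exactly two treatment levels are compared")
  }
  missing_pop <- setdiff(treatment_levels, names(group_populations))
  if (length(missing_pop) > 0L) {
    abort_schema(sprintf("no group population for level(s): %s",
                         paste(missing_pop, collapse = ", ")))
  }
  structure(
    list(selection_covariates = canonical_covariates(selection_covariates),
         standardization_covariates = canonical_covariates(standardization_covariates),
         group_populations = group_populations,
         standard_distribution = standard_distribution,
         treatment_levels = treatment_levels),
    class = "twostage_spec"
  )
}

#' Two-stage poststratify-then-standardize comparison
#'
#' Stage 1: within each exposure group `a`, compute poststratification
#' weights \eqn{w^{(a)}_j = N^{(a)}_j / n^{(a)}_j} over the `W` cells against
#' that group's own population table, correcting each group's selection into
#' the sample. Stage 2: form stage-1-weighted outcome means within each `Z`
#' cell and average them under the common standard distribution, so the two
#' group estimates refer to the same covariate mix and can be contrasted.
#'
#' @param data A [microdata] object with a declared treatment.
#' @param spec A [twostage_spec()].
#' @return A `standardized_comparison`: `per_group` (named numeric of
#'   standardized group means), `difference` (`a1` minus `a0`),
#'   `stage1_weight_tables` (per-group `weight_table`s).
#' @export
twostage_compare <- function(data, spec) {
  stopifnot(inherits(data, "microdata"), inherits(spec, "twostage_spec"))
  if (is.null(treatment_var(data))) {
    abort_schema("no treatment column declared in the microdata")
  }
  W <- spec$selection_covariates
  Z <- spec$standardization_covariates
  if (identical(W, Z)) {
    message("note: W = Z, so stage-1 weights only rescale and cancel from the stage-2 estimate")
  }
  std <- as.data.frame(spec$standard_distribution)
  std <- std[std$N > 0, , drop = FALSE]
  p_std <- std$N / sum(std$N)
  std_key <- cell_key(std, Z)
  treat <- treatment_values(data)
  y <- outcome_values(data)
  z_key_all <- cell_key(data, Z)

  per_group <- numeric(0)
  wtabs <- list()
  for (a in spec$treatment_levels) {
    rows <- which(treat == a)
    if (length(rows) == 0L) {
      abort_validation(sprintf("exposure group '%s' has no sampled units", a))
    }
    sub <- as.data.frame(data)[rows, , drop = FALSE]
    sub_md <- microdata(sub, covariates = covariates(data),
                        outcome = outcome_var(data), treatment = treatment_var(data))
    wt <- tryCatch(
      compute_cell_weights(crosstab(sub_md, W), spec$group_populations[[a]]),
      poststrat_positivity_error = function(e) {
        abort_positivity(
          sprintf("stage 1, group '%s': %s", a, conditionMessage(e)),
          cells = e$cells, stage = 1L, group = a
        )
      }
    )
    wtabs[[a]] <- wt
    w <- unit_weights(sub_md, wt)
    zk <- z_key_all[rows]
    num <- vapply(split(w * y[rows], factor(zk, levels = std_key)), sum, numeric(1L))
    den <- vapply(split(w, factor(zk, levels = std_key)), sum, numeric(1L))
    uncovered <- is.na(den) | den == 0
    if (any(uncovered)) {
      abort_positivity(
        sprintf("stage 2, group '%s': standard cell(s) with no units: %s",
                a, format_cells(std[uncovered, sort(Z), drop = FALSE])),
        cells = std[uncovered, sort(Z), drop = FALSE], stage = 2L, group = a
      )
    }
    per_group[a] <- sum((num / den) * p_std)
  }
  structure(
    list(per_group = per_group,
         difference = per_group[[spec$treatment_levels[1L]]] -
           per_group[[spec$treatment_levels[2L]]],
         stage1_weight_tables = wtabs,
         treatment_levels = spec$treatment_levels),
    class = "standardized_comparison"
  )
}

#' @export
print.standardized_comparison <- function(x, ...) {
  lv <- x$treatment_levels
  cat(sprintf("<standardized_comparison> %s: %.6g | %s: %.6g | difference: %.6g\n",
              lv[1L], x$per_group[[lv[1L]]], lv[2L], x$per_group[[lv[2L]]],
              x$difference))
  invisible(x)
}
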