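# Saturated (nonparametric) g-methods: inverse probability weighting and
# standardization for counterfactual means E[Y^a] and the average treatment
# effect. Propensities are cell frequencies — no parametric model — which is
# exactly the regime where IPW and standardization coincide.

#' Saturated propensity estimates from cell counts
#'
#' Estimates \eqn{\hat P(A = a \mid X = x_j)} nonparametrically as the
#' within-cell frequency of each treatment level. Cells where a globally
#' observed level has zero count are recorded as support gaps (positivity
#' gaps) rather than stored as zero probabilities.
#'
#' @param data A [microdata] object with a declared treatment.
#' @param covariates Covariates defining the cells (default: all declared).
#' @return A `propensity_table`: covariate columns, `level`, `count`, `p`,
#'   with attributes `levels` (all observed treatment levels) and `gaps`
#'   (data frame of cell/level pairs with zero support).
#' @export
estimate_propensity <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "microdata"))
  if (is.null(treatment_var(data))) {
    abort_schema("no treatment column declared in the microdata")
  }
  if (is.null(covariates)) covariates <- covariates(data)
  covariates <- canonical_covariates(covariates)
  a <- treatment_values(data)
  levels_all <- sort(unique(a))
  key <- cell_key(data, covariates)
  idx <- split(seq_len(nrow(data)), key)
  first <- vapply(idx, `[[`, integer(1L), 1L)
  cells <- as.data.frame(data)[first, covariates, drop = FALSE]
  entries <- vector("list", length(idx))
  gaps <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    aj <- a[idx[[j]]]
    tab <- table(aj)
    present <- names(tab)
    e <- cells[rep(j, length(present)), , drop = FALSE]
    e$level <- present
    e$count <- as.integer(tab)
    e$p <- as.numeric(tab) / length(aj)
    entries[[j]] <- e
    absent <- setdiff(levels_all, present)
    if (length(absent) > 0L) {
      g <- cells[rep(j, length(absent)), , drop = FALSE]
      g$level <- absent
      gaps[[j]] <- g
    }
  }
  out <- do.call(rbind, entries)
  out <- out[do.call(order, unname(as.list(out[c(covariates, "level")]))), , drop = FALSE]
  rownames(out) <- NULL
  gap_df <- if (all(vapply(gaps, is.null, logical(1L)))) {
    cells[0L, , drop = FALSE]
  } else {
    do.call(rbind, gaps[!vapply(gaps, is.null, logical(1L))])
  }
  rownames(gap_df) <- NULL
  structure(
    out,
    covariates = covariates,
    levels = levels_all,
    gaps = gap_df,
    class = c("propensity_table", "data.frame")
  )
}

#' @export
print.propensity_table <- function(x, ...) {
  gaps <- attr(x, "gaps")
  cat(sprintf("<propensity_table> levels: %s | %d cell-level entries | %d support gap(s)\n",
              paste(attr(x, "levels"), collapse = ", "), nrow(x), nrow(gaps)))
  print(as.data.frame(x))
  if (nrow(gaps) > 0L) {
    cat("  support gaps:", format_cells(gaps), "\n")
  }
  invisible(x)
}

new_counterfactual <- function(level, value, method, reference) {
  structure(
    list(level = level, value = value, method = method,
         reference_distribution = reference),
    class = "counterfactual_estimate"
  )
}

#' @export
print.counterfactual_estimate <- function(x, ...) {
  cat(sprintf("<counterfactual> E[Y^{%s}] = %.6g | method = %s | reference = %s\n",
              x$level, x$value, x$method, x$reference_distribution))
  invisible(x)
}

#' IPW estimate of a counterfactual mean
#'
#' Computes \eqn{\frac1n \sum_i Y_i I(A_i = a) / \hat P(A = a \mid X_i)}:
#' units at the requested level are inflated by their inverse propensity,
#' forming a pseudo-population in which treatment is independent of the
#' covariates. The reference covariate distribution is the sample's own.
#'
#' @param data A [microdata] object with a declared treatment.
#' @param a Treatment level whose counterfactual mean is estimated.
#' @param propensity A `propensity_table`; estimated from `data` by default.
#' @return A `counterfactual_estimate` with `method = "ipw"`.
#' @export
ipw_mean <- function(data, a, propensity = NULL) {
  stopifnot(inherits(data, "microdata"))
  if (is.null(treatment_var(data))) {
    abort_schema("no treatment column declared in the microdata")
  }
  if (is.null(propensity)) propensity <- estimate_propensity(data)
  covs <- covariates(propensity)
  treat <- treatment_values(data)
  sel <- treat == as.character(a)
  prop_key <- paste(cell_key(propensity, covs), propensity$level, sep = "\x1f")
  row_key <- paste(cell_key(data, covs), treat, sep = "\x1f")
  pos <- match(row_key[sel], prop_key)
  if (anyNA(pos)) {
    bad <- unique(as.data.frame(data)[which(sel)[is.na(pos)], sort(covs), drop = FALSE])
    abort_positivity(
      sprintf("unit(s) at level '%s' in cell(s) with no propensity: %s",
              a, format_cells(bad)),
      cells = bad
    )
  }
  y <- outcome_values(data)
  value <- sum(y[sel] / propensity$p[pos]) / nrow(data)
  new_counterfactual(as.character(a), value, "ipw", "sample")
}

# Cell outcome means restricted to treatment level `a` (all rows if a NULL),
# evaluated at the reference distribution. Shared by standardized_mean().
standardize_over <- function(data, a, reference, covs) {
  keep <- if (is.null(a)) rep(TRUE, nrow(data)) else treatment_values(data) == as.character(a)
  sub_key <- cell_key(data, covs)[keep]
  y <- outcome_values(data)[keep]
  if (inherits(reference, "population_table")) {
    if (!identical(covariates(reference), canonical_covariates(covs))) {
      abort_schema("reference table covariates differ from the requested covariates")
    }
    ref <- as.data.frame(reference)[reference$N > 0, , drop = FALSE]
    ref_key <- cell_key(ref, covs)
    p_ref <- ref$N / sum(ref$N)
    ref_cells <- ref[sort(covs)]
  } else {
    # sample reference: observed covariate distribution of the full data
    all_key <- cell_key(data, covs)
    tab <- table(all_key)
    ref_key <- names(tab)
    p_ref <- as.numeric(tab) / nrow(data)
    first <- match(ref_key, all_key)
    ref_cells <- as.data.frame(data)[first, sort(covs), drop = FALSE]
  }
  means <- vapply(split(y, factor(sub_key, levels = ref_key)), mean, numeric(1L))
  uncovered <- is.na(means)
  if (any(uncovered)) {
    abort_positivity(
      sprintf("reference cell(s) with no unit%s: %s",
              if (is.null(a)) "" else sprintf(" at level '%s'", a),
              format_cells(ref_cells[uncovered, , drop = FALSE])),
      cells = ref_cells[uncovered, , drop = FALSE]
    )
  }
  sum(means * p_ref)
}

#' Standardization (g-formula) estimate of a counterfactual mean
#'
#' Computes \eqn{\sum_x \hat E[Y \mid A = a, X = x]\, P(X = x)}: cell- and
#' level-specific outcome means averaged over a reference covariate
#' distribution. The reference may be the sample's observed distribution
#' (`reference = NULL`, the usual g-formula) or an external
#' [population_table] (direct standardization to a standard population;
#' with `a = NULL` and an external reference this is exactly the
#' stratum-aggregation form of poststratification).
#'
#' @inheritParams ipw_mean
#' @param a Treatment level; `NULL` uses all rows (no treatment
#'   restriction), for data where the "arm" is sample inclusion itself.
#' @param reference `NULL` for the sample covariate distribution, or a
#'   [population_table] over the same covariates.
#' @param covariates Covariates to standardize over (default: all declared).
#' @return A `counterfactual_estimate` with `method = "standardization"`.
#' @export
standardized_mean <- function(data, a = NULL, reference = NULL, covariates = NULL) {
  stopifnot(inherits(data, "microdata"))
  if (!is.null(a) && is.null(treatment_var(data))) {
    abort_schema("no treatment column declared in the microdata")
  }
  if (is.null(covariates)) covariates <- covariates(data)
  covariates <- canonical_covariates(covariates)
  value <- standardize_over(data, a, reference, covariates)
  new_counterfactual(if (is.null(a)) NA_character_ else as.character(a),
                     value, "standardization",
                     if (inherits(reference, "population_table")) "external" else "sample")
}

#' Average treatment effect
#'
#' \eqn{E[Y^{a_1}] - E[Y^{a_0}]} by saturated IPW or standardization.
#' Treatment may be any finite categorical; the ATE requires exactly two
#' named levels, defaulting to the two observed levels in descending order
#' (so a 0/1 treatment contrasts 1 against 0).
#'
#' @inheritParams standardized_mean
#' @param method `"ipw"` (sample reference only) or `"standardization"`.
#' @param levels Character vector `c(a1, a0)`; the effect is the `a1` mean
#'   minus the `a0` mean. Required when more than two levels are observed.
#' @return The effect estimate as a number, with the two counterfactual
#'   means attached as attributes `y1` and `y0`.
#' @export
ate <- function(data, reference = NULL, method = c("ipw", "standardization"),
                levels = NULL) {
  stopifnot(inherits(data, "microdata"))
  method <- match.arg(method)
  if (is.null(treatment_var(data))) {
    abort_schema("no treatment column declared in the microdata")
  }
  observed <- sort(unique(treatment_values(data)), decreasing = TRUE)
  if (is.null(levels)) {
    if (length(observed) != 2L) {
      abort_schema(sprintf(
        "treatment has %d observed level(s); supply `levels = c(a1, a0)`",
        length(observed)))
    }
    levels <- observed
  }
  if (length(levels) != 2L) abort_schema("`levels` must name exactly two treatment levels")
  if (method == "ipw") {
    if (!is.null(reference)) {
      abort_schema("IPW targets the sample covariate distribution; `reference` must be NULL")
    }
    prop <- estimate_propensity(data)
    e1 <- ipw_mean(data, levels[1L], prop)
    e0 <- ipw_mean(data, levels[2L], prop)
  } else {
    e1 <- standardized_mean(data, levels[1L], reference)
    e0 <- standardized_mean(data, levels[2L], reference)
  }
  structure(e1$value - e0$value, y1 = e1$value, y0 = e0$value, method = method)
}
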