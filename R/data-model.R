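# Domain containers: microdata (unit-level sample records), population tables
# (covariate-cell counts for the target population), stratum counts (the
# sample-side cross-classification) and the alignment report between the two.
#
# Conventions shared by every container:
#   * categorical levels are exact strings after trimming surrounding
#     whitespace; no case folding (silent coercion can merge distinct strata);
#   * covariate columns are stored in lexicographic order of their names and
#     cells are ordered by their levels, so all outputs are deterministic;
#   * delimited text is UTF-8 CSV with a header row (not auto-sniffed).

# Internal cell key: unit-separator-joined levels over the sorted covariates.
cell_key <- function(df, covariates) {
  do.call(paste, c(unname(as.list(df[sort(covariates)])), sep = "\x1f"))
}

canonical_covariates <- function(covariates) sort(unique(covariates))

order_cells <- function(df, covariates) {
  df[do.call(order, unname(as.list(df[sort(covariates)]))), , drop = FALSE]
}

clean_levels <- function(x) trimws(as.character(x))

check_no_missing <- function(values, column, what = "value") {
  bad <- which(is.na(values) | values == "")
  if (length(bad) > 0L) {
    abort_validation(
      sprintf("missing %s in column '%s' at row %d", what, column, bad[1L]),
      column = column, rows = bad
    )
  }
  invisible(values)
}

#' Construct unit-level microdata
#'
#' A `microdata` object holds one row per sampled unit: the categorical
#' auxiliary variables (covariates), an optional categorical treatment and a
#' numeric outcome. All rows are sampled units — the sample-inclusion
#' indicator is implicitly 1 for every record. Missing values are rejected,
#' never imputed: the cell-based estimators assume complete cells.
#'
#' @param data A data frame with one row per unit.
#' @param covariates Character vector of covariate column names.
#' @param outcome Name of the numeric (or 0/1) outcome column.
#' @param treatment Optional name of a categorical treatment column.
#' @return A `microdata` object (a data frame carrying the schema as
#'   attributes). Row order is preserved.
#' @examples
#' md <- microdata(
#'   data.frame(sex = c("men", "women"), obese = c(1, 0)),
#'   covariates = "sex", outcome = "obese"
#' )
#' @export
microdata <- function(data, covariates, outcome, treatment = NULL) {
  if (!is.data.frame(data)) abort_validation("`data` must be a data frame")
  if (length(covariates) == 0L) abort_schema("at least one covariate must be declared")
  declared <- c(covariates, outcome, treatment)
  missing_cols <- setdiff(declared, names(data))
  if (length(missing_cols) > 0L) {
    abort_schema(sprintf(
      "declared column(s) not present: %s", paste(missing_cols, collapse = ", ")
    ))
  }
  out <- as.data.frame(data[declared], stringsAsFactors = FALSE)
  for (cv in covariates) {
    out[[cv]] <- check_no_missing(clean_levels(out[[cv]]), cv, "covariate level")
  }
  y_raw <- out[[outcome]]
  if (is.character(y_raw) || is.factor(y_raw)) {
    y_chr <- trimws(as.character(y_raw))
    check_no_missing(y_chr, outcome, "outcome")
    y <- suppressWarnings(as.numeric(y_chr))
    if (anyNA(y)) {
      bad <- which(is.na(y))[1L]
      abort_validation(sprintf(
        "non-numeric outcome '%s' in column '%s' at row %d", y_chr[bad], outcome, bad
      ))
    }
  } else {
    y <- as.numeric(y_raw)
    if (anyNA(y)) {
      abort_validation(sprintf(
        "missing outcome in column '%s' at row %d", outcome, which(is.na(y))[1L]
      ))
    }
  }
  out[[outcome]] <- y
  if (!is.null(treatment)) {
    out[[treatment]] <- check_no_missing(
      clean_levels(out[[treatment]]), treatment, "treatment level"
    )
  }
  structure(
    out,
    covariates = canonical_covariates(covariates),
    outcome = outcome,
    treatment = treatment,
    class = c("microdata", "data.frame")
  )
}

#' Schema accessors for microdata
#'
#' @param x A `microdata` object.
#' @return `covariates()` the covariate names (lexicographic order),
#'   `outcome_var()` / `treatment_var()` the outcome / treatment column name
#'   (`NULL` when no treatment is declared), `outcome_values()` /
#'   `treatment_values()` the corresponding columns.
#' @export
covariates <- function(x) attr(x, "covariates")

#' @rdname covariates
#' @export
outcome_var <- function(x) attr(x, "outcome")

#' @rdname covariates
#' @export
treatment_var <- function(x) attr(x, "treatment")

#' @rdname covariates
#' @export
outcome_values <- function(x) x[[outcome_var(x)]]

#' @rdname covariates
#' @export
treatment_values <- function(x) {
  if (is.null(treatment_var(x))) NULL else x[[treatment_var(x)]]
}

#' @export
print.microdata <- function(x, ...) {
  cat(sprintf(
    "<microdata> %d units | covariates: %s | outcome: %s%s\n",
    nrow(x), paste(covariates(x), collapse = ", "), outcome_var(x),
    if (is.null(treatment_var(x))) "" else paste0(" | treatment: ", treatment_var(x))
  ))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("# ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read unit-level microdata from CSV
#'
#' Expects UTF-8, comma-separated text with a header row; one row per sampled
#' unit. Column roles are declared, not guessed.
#'
#' @inheritParams microdata
#' @param path Path to the CSV file.
#' @return A validated [microdata] object; row order follows the file.
#' @export
read_microdata <- function(path, covariates, outcome, treatment = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  microdata(raw, covariates = covariates, outcome = outcome, treatment = treatment)
}

#' Write microdata back to CSV
#'
#' @param x A [microdata] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_microdata <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a target-population table
#'
#' One row per covariate cell with the cell's population count \eqn{N_j}
#' (or its proportion \eqn{N_j/N}). Census sources publish both forms, so a
#' flag declares which is supplied; proportions are rescaled by `total` when
#' absolute counts are needed (all estimators are invariant to this scale).
#'
#' @param cells Data frame with one row per cell: the covariate columns plus
#'   a count column.
#' @param covariates Covariate column names.
#' @param count Name of the count column (default `"N"`).
#' @param proportions If `TRUE`, the count column holds proportions summing
#'   to 1; they are multiplied by `total` (or kept as shares when `total` is
#'   `NULL`).
#' @param total Population total used to rescale proportions.
#' @return A `population_table` object: covariate columns in lexicographic
#'   order plus a column `N`, with attribute `total`.
#' @examples
#' population_table(
#'   data.frame(sex = c("men", "women"), N = c(1000, 1000)),
#'   covariates = "sex"
#' )
#' @export
population_table <- function(cells, covariates, count = "N",
                             proportions = FALSE, total = NULL) {
  if (!is.data.frame(cells)) abort_validation("`cells` must be a data frame")
  if (length(covariates) == 0L) abort_schema("at least one covariate must be declared")
  missing_cols <- setdiff(c(covariates, count), names(cells))
  if (length(missing_cols) > 0L) {
    abort_schema(sprintf("column(s) not present: %s", paste(missing_cols, collapse = ", ")))
  }
  out <- as.data.frame(cells[c(covariates, count)], stringsAsFactors = FALSE)
  for (cv in covariates) {
    out[[cv]] <- check_no_missing(clean_levels(out[[cv]]), cv, "covariate level")
  }
  n_col <- suppressWarnings(as.numeric(out[[count]]))
  if (anyNA(n_col)) {
    abort_validation(sprintf("non-numeric count in column '%s' at row %d",
                             count, which(is.na(n_col))[1L]))
  }
  if (any(n_col < 0)) {
    abort_validation(sprintf("negative population count at row %d", which(n_col < 0)[1L]))
  }
  keys <- cell_key(out, covariates)
  if (anyDuplicated(keys)) {
    dup <- out[duplicated(keys), sort(covariates), drop = FALSE]
    abort_validation(sprintf("duplicate population cell(s): %s", format_cells(dup)))
  }
  if (isTRUE(proportions)) {
    if (abs(sum(n_col) - 1) > 1e-6) {
      abort_validation(sprintf("proportions sum to %.6f, not 1", sum(n_col)))
    }
    n_col <- n_col * (if (is.null(total)) 1 else total)
  }
  if (sum(n_col) <= 0) abort_validation("population total must be positive")
  out[[count]] <- NULL
  out <- out[sort(covariates)]
  out$N <- n_col
  out <- order_cells(out, covariates)
  rownames(out) <- NULL
  structure(
    out,
    covariates = canonical_covariates(covariates),
    total = sum(n_col),
    class = c("population_table", "data.frame")
  )
}

#' @export
print.population_table <- function(x, ...) {
  cat(sprintf("<population_table> %d cells | total N = %s | covariates: %s\n",
              nrow(x), format(attr(x, "total"), big.mark = ","),
              paste(covariates(x), collapse = ", ")))
  print(as.data.frame(x))
  invisible(x)
}

#' Read a target-population table from CSV
#'
#' @inheritParams population_table
#' @param path Path to the CSV file (one row per covariate cell).
#' @param count_column Name of the count column in the file.
#' @return A validated [population_table].
#' @export
read_population_table <- function(path, covariates, count_column = "N",
                                  proportions = FALSE, total = NULL) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                         colClasses = "character")
  population_table(raw, covariates = covariates, count = count_column,
                   proportions = proportions, total = total)
}

#' Write a population table to CSV
#'
#' @param x A [population_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-classify microdata into strata
#'
#' Builds the m-way contingency table over the requested covariates: one cell
#' per observed level combination, with the sample count \eqn{n_j} and the
#' stratum outcome mean \eqn{\bar Y_j}.
#'
#' @param data A [microdata] object.
#' @param covariates Covariates to cross-classify on (default: all declared).
#' @return A `stratum_counts` object: covariate columns, `n`, and `ybar`,
#'   one row per observed cell, ordered deterministically.
#' @export
crosstab <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "microdata"))
  if (is.null(covariates)) covariates <- covariates(data)
  if (length(covariates) == 0L) {
    abort_schema("empty covariate list: request the grand mean via crude_mean()")
  }
  unknown <- setdiff(covariates, covariates(data))
  if (length(unknown) > 0L) {
    abort_schema(sprintf("covariate(s) not declared in microdata: %s",
                         paste(unknown, collapse = ", ")))
  }
  covariates <- canonical_covariates(covariates)
  key <- cell_key(data, covariates)
  idx <- split(seq_len(nrow(data)), key)
  y <- outcome_values(data)
  first <- vapply(idx, `[[`, integer(1L), 1L)
  out <- as.data.frame(data)[first, covariates, drop = FALSE]
  out$n <- vapply(idx, length, integer(1L))
  out$ybar <- vapply(idx, function(i) mean(y[i]), numeric(1L))
  out <- order_cells(out, covariates)
  rownames(out) <- NULL
  structure(
    out,
    covariates = covariates,
    n_total = nrow(data),
    class = c("stratum_counts", "data.frame")
  )
}

#' @export
print.stratum_counts <- function(x, ...) {
  cat(sprintf("<stratum_counts> %d cells | n = %d | covariates: %s\n",
              nrow(x), attr(x, "n_total"), paste(covariates(x), collapse = ", ")))
  print(as.data.frame(x))
  invisible(x)
}

#' Check sample/population cell alignment
#'
#' Partitions the union of covariate cells into those present in both tables,
#' those with sampled units but no population count (`sample_only`, a
#' covariate-coding mismatch) and population cells with no sampled units
#' (`population_only`). A nonempty `population_only` list is exactly a
#' failure of positivity for sample inclusion: such strata carry no
#' empirical information. The report is purely descriptive — no error is
#' raised here.
#'
#' @param sample A `stratum_counts` object (see [crosstab()]).
#' @param population A [population_table] over the same covariates.
#' @return An `alignment_report`: list of data frames `matched` (with `n`
#'   and `N`), `sample_only`, `population_only`.
#' @export
validate_alignment <- function(sample, population) {
  stopifnot(inherits(sample, "stratum_counts"), inherits(population, "population_table"))
  cs <- covariates(sample)
  cp <- covariates(population)
  if (!identical(cs, cp)) {
    abort_schema(sprintf(
      "covariate mismatch: sample has (%s), population has (%s)",
      paste(cs, collapse = ", "), paste(cp, collapse = ", ")
    ))
  }
  covs <- cs
  pop <- as.data.frame(population)[population$N > 0, , drop = FALSE]
  ks <- cell_key(sample, covs)
  kp <- cell_key(pop, covs)
  in_both <- ks %in% kp
  matched <- as.data.frame(sample)[in_both, c(covs, "n", "ybar"), drop = FALSE]
  matched$N <- pop$N[match(ks[in_both], kp)]
  sample_only <- as.data.frame(sample)[!in_both, c(covs, "n"), drop = FALSE]
  population_only <- pop[!(kp %in% ks), c(covs, "N"), drop = FALSE]
  rownames(matched) <- rownames(sample_only) <- rownames(population_only) <- NULL
  structure(
    list(matched = matched, sample_only = sample_only,
         population_only = population_only, covariates = covs),
    class = "alignment_report"
  )
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("<alignment_report> %d matched | %d sample-only | %d population-only\n",
              nrow(x$matched), nrow(x$sample_only), nrow(x$population_only)))
  if (nrow(x$sample_only) > 0L) {
    cat("  sample-only cells (no population count):",
        format_cells(x$sample_only[x$covariates]), "\n")
  }
  if (nrow(x$population_only) > 0L) {
    cat("  population-only cells (positivity violated):",
        format_cells(x$population_only[x$covariates]), "\n")
  }
  invisible(x)
}
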