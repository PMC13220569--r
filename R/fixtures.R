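# Packaged worked examples.
#
# (1) The KoGES smoking illustration: a cohort of 10,030 Korean adults aged
#     40-69 at baseline 2001 — a nonprobability sample whose age-sex mix
#     differs from the 2001 census — with stratum smoking rates, used to
#     poststratify the crude smoking prevalence to the national age-sex
#     distribution.
# (2) A two-stratum obesity toy: a sample of 400 men (obesity rate 30%) and
#     600 women (10%) from a population of 1000 men and 1000 women.
#
# The published illustration reports stratum-level counts and rates, not
# unit-level records. The unit-level reconstruction expands each stratum to
# n_j units of which round(n_j * rate_j) carry outcome 1 — the rounding
# convention is this package's own, and it is why the reconstructed crude
# rate (~25.6%) differs in the last digit from the published 25.7%, which
# was computed on the unrounded source data.

#' The KoGES / 2001-census age-sex illustration table
#'
#' Six age-by-sex strata of Korean adults aged 40-69 in 2001: census
#' population counts, KoGES sample counts, and the stratum smoking rates
#' observed in the cohort.
#'
#' @return A data frame with columns `age_group`, `sex`, `census_n`,
#'   `sample_n`, `smoking_rate`.
#' @export
koges_table1 <- function() {
  data.frame(
    age_group = rep(c("40-49", "50-59", "60-69"), each = 2L),
    sex = rep(c("Men", "Women"), times = 3L),
    census_n = c(3886462, 3758072, 2208310, 2245444, 1493790, 1821163),
    sample_n = c(2354L, 2357L, 1234L, 1383L, 1170L, 1532L),
    smoking_rate = c(0.531, 0.036, 0.480, 0.031, 0.443, 0.049),
    stringsAsFactors = FALSE
  )
}

#' KoGES illustration: census population table
#'
#' @return A [population_table] of the six 2001-census age-sex cells
#'   (total 15,413,241).
#' @export
koges_census <- function() {
  t1 <- koges_table1()
  population_table(
    data.frame(age_group = t1$age_group, sex = t1$sex, N = t1$census_n),
    covariates = c("age_group", "sex")
  )
}

expand_strata <- function(cells, covariates, n_col, rate_col, outcome) {
  rows <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    n <- cells[[n_col]][j]
    pos <- round(n * cells[[rate_col]][j])
    df <- cells[rep(j, n), covariates, drop = FALSE]
    df[[outcome]] <- rep(c(1L, 0L), times = c(pos, n - pos))
    rows[[j]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' KoGES illustration: reconstructed unit-level sample
#'
#' Expands each Table stratum to its `sample_n` units, of which
#' `round(sample_n * smoking_rate)` are smokers (see the note on the
#' rounding convention in [koges_table1()]).
#'
#' @return A [microdata] object with 10,030 rows, covariates `age_group`
#'   and `sex`, and binary outcome `smoker`.
#' @export
koges_sample <- function() {
  t1 <- koges_table1()
  microdata(
    expand_strata(t1, c("age_group", "sex"), "sample_n", "smoking_rate", "smoker"),
    covariates = c("age_group", "sex"), outcome = "smoker"
  )
}

#' Obesity toy: unit-level sample
#'
#' 400 men with obesity rate 30% and 600 women with rate 10%.
#'
#' @return A [microdata] object with 1000 rows, covariate `sex`, binary
#'   outcome `obese`.
#' @export
obesity_sample <- function() {
  cells <- data.frame(sex = c("men", "women"), n = c(400L, 600L),
                      rate = c(0.30, 0.10), stringsAsFactors = FALSE)
  microdata(expand_strata(cells, "sex", "n", "rate", "obese"),
            covariates = "sex", outcome = "obese")
}

#' Obesity toy: census population table
#'
#' @return A [population_table] with 1000 men and 1000 women.
#' @export
obesity_census <- function() {
  population_table(data.frame(sex = c("men", "women"), N = c(1000, 1000)),
                   covariates = "sex")
}

#' Write the packaged fixtures as CSV files
#'
#' Writes `koges_table1_census.csv` (six census cells),
#' `koges_table1_sample.csv` (the 10,030-row unit-level reconstruction) and
#' `obesity_toy.csv` (the 1000-row toy) into `output_dir`. Idempotent:
#' regeneration is byte-identical.
#'
#' @param output_dir Directory to write into (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) ps_abort(sprintf("cannot create directory: %s", output_dir), "poststrat_io_error")
  }
  if (file.access(output_dir, mode = 2L) != 0L) {
    ps_abort(sprintf("directory not writable: %s", output_dir), "poststrat_io_error")
  }
  paths <- c(
    census = file.path(output_dir, "koges_table1_census.csv"),
    sample = file.path(output_dir, "koges_table1_sample.csv"),
    obesity = file.path(output_dir, "obesity_toy.csv")
  )
  write_population_table(koges_census(), paths[["census"]])
  write_microdata(koges_sample(), paths[["sample"]])
  write_microdata(obesity_sample(), paths[["obesity"]])
  invisible(paths)
}
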