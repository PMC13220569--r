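# Random study generators shared by the property-style tests. Callers set
# the RNG seed; everything here is plain base-R randomness.

# A random cross-classified study: microdata over one categorical covariate
# with J cells (each sampled at least once), plus a population table over
# the same cells. Binary outcomes unless `numeric_outcome`.
random_study <- function(J_max = 20L, n_cell_max = 15L, N_cell_max = 1000L,
                         treatment = FALSE, numeric_outcome = FALSE) {
  J <- sample.int(J_max, 1L)
  lv <- sprintf("c%02d", seq_len(J))
  n_j <- sample.int(n_cell_max, J, replace = TRUE)
  g <- rep(lv, times = n_j)
  y <- if (numeric_outcome) stats::rnorm(length(g)) else stats::rbinom(length(g), 1L, stats::runif(J)[match(g, lv)])
  df <- data.frame(g = g, y = y, stringsAsFactors = FALSE)
  if (treatment) {
    # guarantee both treatment levels somewhere in the data
    df$a <- as.character(stats::rbinom(nrow(df), 1L, 0.5))
    if (length(unique(df$a)) == 1L) df$a[1L] <- setdiff(c("0", "1"), df$a[1L])
  }
  pop <- population_table(
    data.frame(g = lv, N = sample.int(N_cell_max, J, replace = TRUE)),
    covariates = "g"
  )
  md <- microdata(df, covariates = "g", outcome = "y",
                  treatment = if (treatment) "a" else NULL)
  list(data = md, population = pop, J = J, levels = lv, n_j = n_j)
}

# The 8-unit two-cell treatment toy used across the g-methods tests:
# X = 0: A=1 with Y in {1, 0}; A=0 with Y in {0, 0}
# X = 1: A=1 with Y = 1;       A=0 with Y in {1, 0, 0}
gmethods_toy <- function() {
  microdata(
    data.frame(
      x = c("0", "0", "0", "0", "1", "1", "1", "1"),
      a = c("1", "1", "0", "0", "1", "0", "0", "0"),
      y = c(1, 0, 0, 0, 1, 1, 0, 0)
    ),
    covariates = "x", outcome = "y", treatment = "a"
  )
}
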