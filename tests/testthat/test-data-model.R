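test_that("read_microdata parses declared columns and validates outcomes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "age_group,sex,smoker",
    "40-49,Men,1", "40-49,Women,0", "50-59,Men,1",
    "50-59,Women,0", "60-69,Men,0", "60-69,Women,1"
  ), f)
  md <- read_microdata(f, covariates = c("age_group", "sex"), outcome = "smoker")
  expect_s3_class(md, "microdata")
  expect_equal(nrow(md), 6L)
  expect_identical(covariates(md), c("age_group", "sex"))
  expect_equal(outcome_values(md), c(1, 0, 1, 0, 0, 1))

  # declared column absent from the header
  expect_error(
    read_microdata(f, covariates = c("age_group", "region"), outcome = "smoker"),
    class = "poststrat_schema_error"
  )

  # non-numeric outcome names the offending value
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,smoker", "Men,yes", "Women,0"), f2)
  expect_error(
    read_microdata(f2, covariates = "sex", outcome = "smoker"),
    "non-numeric outcome", class = "poststrat_validation_error"
  )

  # missing covariate level names row and column
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,smoker", "Men,1", ",0"), f3)
  expect_error(
    read_microdata(f3, covariates = "sex", outcome = "smoker"),
    "row 2", class = "poststrat_validation_error"
  )
})

test_that("levels are trimmed but never case-folded", {
  md <- microdata(
    data.frame(sex = c(" Men", "Men ", "men"), y = c(1, 0, 1)),
    covariates = "sex", outcome = "y"
  )
  sc <- crosstab(md)
  expect_equal(nrow(sc), 2L)  # "Men" merged after trimming; "men" distinct
  expect_setequal(sc$sex, c("Men", "men"))
})

test_that("read_population_table validates counts, totals, and duplicates", {
  census <- system.file("extdata", "koges_table1_census.csv", package = "poststrat")
  pop <- read_population_table(census, covariates = c("age_group", "sex"))
  expect_s3_class(pop, "population_table")
  expect_equal(attr(pop, "total"), 15413241)
  expect_equal(nrow(pop), 6L)

  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,N", "men,1000", "women,1000"), f)
  expect_equal(attr(read_population_table(f, "sex"), "total"), 2000)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,age,N", "men,40-49,10", "men,40-49,20"), dup)
  expect_error(read_population_table(dup, c("sex", "age")),
               "duplicate", class = "poststrat_validation_error")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,N", "men,-5", "women,10"), neg)
  expect_error(read_population_table(neg, "sex"),
               "negative", class = "poststrat_validation_error")

  zero <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sex,N", "men,0", "women,0"), zero)
  expect_error(read_population_table(zero, "sex"),
               "positive", class = "poststrat_validation_error")
})

test_that("population tables accept proportions scaled by a supplied total", {
  pop <- population_table(
    data.frame(sex = c("men", "women"), share = c(0.25, 0.75)),
    covariates = "sex", count = "share", proportions = TRUE, total = 4000
  )
  expect_equal(pop$N, c(1000, 3000))
  expect_equal(attr(pop, "total"), 4000)
  expect_error(
    population_table(data.frame(sex = c("men", "women"), share = c(0.2, 0.3)),
                     covariates = "sex", count = "share", proportions = TRUE),
    "sum", class = "poststrat_validation_error"
  )
})

test_that("crosstab reproduces the worked-example contingency tables", {
  sc <- crosstab(koges_sample())
  expect_equal(sum(sc$n), 10030L)
  expect_equal(sc$n, c(2354L, 2357L, 1234L, 1383L, 1170L, 1532L))

  toy <- crosstab(obesity_sample())
  expect_equal(toy$n[toy$sex == "men"], 400L)
  expect_equal(toy$ybar[toy$sex == "men"], 0.30)
  expect_equal(toy$n[toy$sex == "women"], 600L)
  expect_equal(toy$ybar[toy$sex == "women"], 0.10)

  one <- crosstab(microdata(data.frame(g = "a", y = 0.7),
                            covariates = "g", outcome = "y"))
  expect_equal(one$n, 1L)
  expect_equal(one$ybar, 0.7)

  expect_error(crosstab(obesity_sample(), character(0)),
               class = "poststrat_schema_error")
})

test_that("crosstab totals and cell means hold on random tables", {
  set.seed(42)
  for (i in 1:25) {
    st <- random_study()
    sc <- crosstab(st$data)
    expect_identical(sum(sc$n), nrow(st$data))
    # cell means equal direct per-cell arithmetic means
    y <- outcome_values(st$data)
    g <- as.data.frame(st$data)$g
    expect_equal(sc$ybar, as.numeric(tapply(y, g, mean)[sc$g]), tolerance = 1e-15)
  }
})

test_that("writing and re-reading round-trips both containers", {
  set.seed(7)
  st <- random_study()
  f <- withr::local_tempfile(fileext = ".csv")
  write_microdata(st$data, f)
  back <- read_microdata(f, covariates = "g", outcome = "y")
  expect_equal(as.data.frame(back), as.data.frame(st$data))

  g <- withr::local_tempfile(fileext = ".csv")
  write_population_table(st$population, g)
  pback <- read_population_table(g, covariates = "g")
  expect_equal(as.data.frame(pback), as.data.frame(st$population))
  expect_equal(attr(pback, "total"), attr(st$population, "total"))
})

test_that("alignment partitions cells and flags positivity violations", {
  sc <- crosstab(koges_sample())
  al <- validate_alignment(sc, koges_census())
  expect_equal(nrow(al$matched), 6L)
  expect_equal(nrow(al$sample_only), 0L)
  expect_equal(nrow(al$population_only), 0L)

  # population has an extra cell the sample lacks -> positivity violation
  t1 <- koges_table1()
  pop_extra <- population_table(
    rbind(data.frame(age_group = t1$age_group, sex = t1$sex, N = t1$census_n),
          data.frame(age_group = "70-79", sex = "Men", N = 1000)),
    covariates = c("age_group", "sex")
  )
  al2 <- validate_alignment(sc, pop_extra)
  expect_equal(nrow(al2$population_only), 1L)
  expect_equal(al2$population_only$age_group, "70-79")

  # sample has a cell absent from the population
  md <- microdata(data.frame(sex = c("men", "other"), y = c(1, 0)),
                  covariates = "sex", outcome = "y")
  al3 <- validate_alignment(crosstab(md), obesity_census())
  expect_equal(al3$sample_only$sex, "other")

  # partition: |matched| + |sample_only| + |population_only| = |union|
  set.seed(11)
  for (i in 1:20) {
    st <- random_study()
    keep <- sample(c(TRUE, FALSE), nrow(st$population), replace = TRUE)
    if (!any(keep)) keep[1L] <- TRUE
    pop <- population_table(as.data.frame(st$population)[keep, , drop = FALSE],
                            covariates = "g")
    al <- validate_alignment(crosstab(st$data), pop)
    union_size <- length(unique(c(crosstab(st$data)$g, pop$g[pop$N > 0])))
    expect_equal(nrow(al$matched) + nrow(al$sample_only) + nrow(al$population_only),
                 union_size)
  }

  expect_error(
    validate_alignment(crosstab(md), koges_census()),
    "covariate mismatch", class = "poststrat_schema_error"
  )
})
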