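test_that("read_cohort drops rows with missing treatment/time/event and validates coding", {
  schema <- covariate_schema(c("age", "kras"), c("continuous", "binary"))
  df <- data.frame(age = c(50, 60, 70, 55, 65), kras = c(0, 1, 0, 1, 1),
                   trt = c(0, 1, NA, 1, 0), os = c(12, 24, 36, 48, 60),
                   death = c(1, 0, 1, 1, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  cols <- list(treatment = "trt", time = "os", event = "death")
  expect_message(co <- read_cohort(path, schema, cols), "dropped 1")
  expect_equal(n_patients(co), 4)

  df_bad <- df; df_bad$trt <- c(0, 1, 2, 1, 0)
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_cohort(path, schema, cols), "0/1")

  df_ok <- df; df_ok$trt <- c(0, 1, 1, 1, 0)
  write.csv(df_ok, path, row.names = FALSE)
  co2 <- read_cohort(path, schema, cols)
  expect_equal(n_patients(co2), 5)
  expect_equal(co2$X$age, df_ok$age)
})

test_that("write_cohort then read_cohort is the identity on complete data", {
  schema <- covariate_schema(c("age", "side"), c("continuous", "categorical"),
                             list(side = c("right", "left", "rectal")))
  co <- cohort(data.frame(age = c(50, 60, 70),
                          side = c("left", "right", "rectal")),
               a = c(0, 1, 1), t = c(10, 20, 30), y = c(1, 0, 1), schema)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path, schema,
                      list(id = "id", treatment = "treatment",
                           time = "time", event = "event"))
  expect_equal(back$X, co$X)
  expect_equal(back$a, co$a)
  expect_equal(back$t, co$t)
  expect_equal(back$y, co$y)
})

test_that("impute_missing fills median/mode, is idempotent, errors on empty column", {
  schema <- covariate_schema(c("x", "b"), c("continuous", "binary"))
  co <- cohort(data.frame(x = c(1, 2, NA, 3), b = c(0, 0, 1, NA)),
               a = c(0, 1, 0, 1), t = 1:4, y = c(1, 1, 0, 0), schema)
  suppressMessages(imp <- impute_missing(co))
  expect_equal(imp$X$x, c(1, 2, 2, 3))
  expect_equal(imp$X$b, c(0, 0, 1, 0))
  expect_equal(sum(attr(imp, "imputed")), 2)
  again <- impute_missing(imp)
  expect_identical(again$X, imp$X)

  complete <- cohort(data.frame(x = c(1, 2), b = c(0, 1)),
                     a = c(0, 1), t = c(1, 2), y = c(1, 1), schema)
  expect_identical(impute_missing(complete)$X, complete$X)

  all_na <- cohort(data.frame(x = c(NA_real_, NA_real_), b = c(0, 1)),
                   a = c(0, 1), t = c(1, 2), y = c(1, 1), schema)
  expect_error(impute_missing(all_na), "'x'")
})

test_that("split_by_treatment partitions the cohort preserving order", {
  co <- exp_cohort(9, a = c(0, 1, 0, 0, 1, 1, 0, 1, 0))
  parts <- split_by_treatment(co)
  expect_equal(n_patients(parts$untreated) + n_patients(parts$treated), 9)
  expect_equal(parts$untreated$ids, c(1, 3, 4, 7, 9))
  expect_equal(parts$treated$ids, c(2, 5, 6, 8))
  expect_length(intersect(parts$untreated$ids, parts$treated$ids), 0)

  all_t <- exp_cohort(3, a = c(1, 1, 1))
  expect_equal(n_patients(split_by_treatment(all_t)$untreated), 0)
})

test_that("one-hot encoding is deterministic with reference level dropped", {
  schema <- covariate_schema(c("x", "side"), c("continuous", "categorical"),
                             list(side = c("right", "left", "rectal")))
  co <- cohort(data.frame(x = c(1, 2, 3), side = c("right", "left", "rectal")),
               a = c(0, 1, 0), t = 1:3, y = c(1, 1, 1), schema)
  Z <- encode_cohort(co)
  expect_equal(colnames(Z), c("x", "side.left", "side.rectal"))
  expect_equal(Z[, "side.left"], c(0, 1, 0))
  expect_equal(Z[, "side.rectal"], c(0, 0, 1))
})

test_that("standardized mean differences match the pooled-SD formula", {
  ZA <- cbind(x = c(0, 2))
  ZB <- cbind(x = c(2, 4))
  expect_equal(unname(standardized_mean_differences(ZA, ZB)),
               -2 / sqrt(2), tolerance = 1e-12)
  # antisymmetry
  expect_equal(standardized_mean_differences(ZB, ZA),
               -standardized_mean_differences(ZA, ZB))
  # identical groups
  expect_equal(unname(standardized_mean_differences(ZA, ZA)), 0)
  # constant columns: equal means -> 0, unequal means -> signed Inf
  expect_equal(unname(standardized_mean_differences(cbind(x = c(1, 1)),
                                                    cbind(x = c(1, 1)))), 0)
  expect_equal(unname(standardized_mean_differences(cbind(x = c(2, 2)),
                                                    cbind(x = c(1, 1)))), Inf)
})
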