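#' Optimism-corrected bootstrap validation
#'
#' Efron-style bias correction of apparent performance: for each of `B`
#' resamples of the training rows (with replacement, same size) the model
#' recipe is refit; each metric is computed on the bootstrap sample
#' ("train") and on the original sample ("test"); the optimism is the mean
#' of train - test over resamples, and the corrected value is
#' apparent - optimism. Resampling covers the Cox fit only — matching is
#' treated as part of the fixed training-set construction, so the routine
#' validates the model-fitting process on the (possibly matched or
#' oversampled) training rows it is given.
#'
#' @param x training `cohort` (row multisets allowed).
#' @param recipe function(`cohort`) -> `cox_fit`; must be deterministic
#'   given the data.
#' @param metrics named list of functions(`cox_fit`, `cohort`) -> scalar.
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed governing all resampling.
#' @param conf level for the percentile interval over bootstrap test
#'   values (default 0.95).
#' @return An object of class `validation_report`: data frame with one row
#'   per metric (`apparent`, `optimism`, `corrected`, `ci_lower`,
#'   `ci_upper`) plus attributes `B`, `seed`, and the per-resample values.
#' @export
validate <- function(x, recipe, metrics, B = 100, seed = 1, conf = 0.95) {
  stopifnot(inherits(x, "cohort"), is.function(recipe), length(metrics) >= 1)
  if (is.null(names(metrics)) || any(!nzchar(names(metrics))))
    stop("metrics must be a named list")
  n <- n_patients(x)
  fit0 <- recipe(x)
  apparent <- vapply(metrics, function(f) f(fit0, x), numeric(1))
  train_vals <- matrix(NA_real_, B, length(metrics),
                       dimnames = list(NULL, names(metrics)))
  test_vals <- train_vals
  set.seed(seed)
  for (b in seq_len(B)) {
    fit_b <- NULL
    for (try in seq_len(10)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- cohort_rows(x, idx)
      if (sum(xb$y) < 1) next
      fit_b <- tryCatch(recipe(xb), error = function(e) NULL)
      if (!is.null(fit_b)) break
    }
    if (is.null(fit_b))
      stop("bootstrap resample ", b, " failed 10 times (no events or ",
           "degenerate fit)")
    train_vals[b, ] <- vapply(metrics, function(f) f(fit_b, xb), numeric(1))
    test_vals[b, ] <- vapply(metrics, function(f) f(fit_b, x), numeric(1))
  }
  optimism <- colMeans(train_vals - test_vals)
  ci <- apply(test_vals, 2, stats::quantile,
              probs = c((1 - conf) / 2, 1 - (1 - conf) / 2), type = 7)
  rep <- data.frame(metric = names(metrics), apparent = unname(apparent),
                    optimism = unname(optimism),
                    corrected = unname(apparent - optimism),
                    ci_lower = unname(ci[1, ]), ci_upper = unname(ci[2, ]),
                    row.names = NULL)
  structure(rep, class = c("validation_report", "data.frame"),
            B = B, seed = seed, train_values = train_vals,
            test_values = test_vals)
}

#' @export
print.validation_report <- function(x, digits = 4, ...) {
  cat("Bootstrap validation (B = ", attr(x, "B"), ", seed = ",
      attr(x, "seed"), ")\n", sep = "")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
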