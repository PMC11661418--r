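#' Fit a Cox proportional hazards model on (possibly duplicated) cohort rows
#'
#' Wraps [survival::coxph()] with Breslow tie handling and retains the
#' Breslow baseline survival curve so that absolute risks at a horizon can
#' be computed. Training rows may be a multiset (matched-with-replacement
#' or oversampled cohorts): Breslow's partial likelihood scales exactly
#' under row replication, so duplicated rows leave point estimates
#' unchanged (Efron's tie correction would not).
#'
#' @param x a complete `cohort` (see [impute_missing()]).
#' @param include_treatment if `TRUE`, the binary treatment indicator enters
#'   the design matrix as covariate `"treatment"`.
#' @return An object of class `cox_fit` with elements `coefficients`,
#'   `means` (training covariate means, centering the linear predictor),
#'   `base_times`/`base_surv` (Breslow baseline survival at the means),
#'   `includes_treatment`, `schema`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(x, include_treatment = FALSE) {
  stopifnot(inherits(x, "cohort"))
  if (sum(x$y) < 1) stop("cannot fit a Cox model: no events in the data")
  Z <- encode_cohort(x)
  if (include_treatment) Z <- cbind(Z, treatment = as.numeric(x$a))
  degen <- apply(Z, 2, function(v) max(v) - min(v) == 0)
  if (any(degen))
    stop("zero-variance design column(s): ",
         paste(colnames(Z)[degen], collapse = ", "))
  df <- data.frame(Z, check.names = FALSE)
  df$.t <- x$t
  df$.y <- x$y
  fml <- stats::as.formula(paste(
    "survival::Surv(.t, .y) ~",
    paste(sprintf("`%s`", colnames(Z)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50),
                         x = FALSE, y = TRUE, model = FALSE)
  if (anyNA(stats::coef(fit)))
    stop("Cox fit failed to estimate all coefficients (collinear design?)")
  sf <- survival::survfit(fit, se.fit = FALSE)  # baseline at covariate means
  structure(list(coefficients = stats::coef(fit),
                 means = fit$means,
                 base_times = sf$time,
                 base_surv = sf$surv,
                 includes_treatment = include_treatment,
                 schema = x$schema,
                 time_unit = x$time_unit,
                 n = n_patients(x), nevent = sum(x$y),
                 coxph = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox model: ", length(x$coefficients), " coefficients, n = ", x$n,
      " (", x$nevent, " events)",
      if (x$includes_treatment) ", includes treatment" else "", "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Linear predictor of a fitted Cox model on new cohort rows
#'
#' Centered at the training covariate means, matching the baseline curve.
#'
#' @param fit a `cox_fit`; @param x a complete `cohort`.
#' @return numeric vector of centered linear predictors.
#' @export
linear_predictor <- function(fit, x) {
  Z <- encode_cohort(x)
  if (fit$includes_treatment) Z <- cbind(Z, treatment = as.numeric(x$a))
  if (!identical(colnames(Z), names(fit$coefficients)))
    stop("cohort columns do not match the fitted model")
  drop(Z %*% fit$coefficients) - sum(fit$means * fit$coefficients)
}

baseline_surv_at <- function(fit, horizon) {
  if (!length(fit$base_times)) return(1)
  if (horizon > max(fit$base_times))
    warning("horizon ", horizon, " beyond baseline support (last time ",
            max(fit$base_times), "); using last survival value")
  idx <- findInterval(horizon, fit$base_times)
  if (idx == 0) 1 else fit$base_surv[idx]
}

#' Predicted probability of the event by a horizon
#'
#' `risk_i = 1 - S0(horizon)^exp(lp_i)` with `S0` the Breslow baseline
#' survival at the training covariate means and `lp` the centered linear
#' predictor. A horizon beyond the baseline support uses the last available
#' survival value with a warning.
#'
#' @param fit a `cox_fit`; @param x a complete `cohort`;
#' @param horizon prediction time in the cohort's time unit.
#' @return numeric vector of event probabilities in \[0, 1\].
#' @export
predict_risk <- function(fit, x, horizon) {
  lp <- linear_predictor(fit, x)
  s0 <- baseline_surv_at(fit, horizon)
  risk <- 1 - s0 ^ exp(lp)
  pmin(pmax(risk, 0), 1)
}
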