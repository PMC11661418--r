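#' Standard metric set at a horizon
#'
#' Named list of `function(fit, cohort)` metric closures suitable for
#' [validate()] and the suite tables: Harrell's C, Uno's C (tau =
#' horizon), Brier score, O/E ratio, ICI/E50/E90/Emax and calibration
#' slope.
#'
#' @param horizon evaluation time.
#' @param calibration include the smoothed-calibration metrics and slope
#'   (default TRUE; turn off for speed when only discrimination matters).
#' @return named list of metric functions.
#' @export
metric_set <- function(horizon, calibration = TRUE) {
  ms <- list(
    harrell_c = function(fit, x)
      harrell_c(x$t, x$y, predict_risk(fit, x, horizon)),
    uno_c = function(fit, x)
      uno_c(x$t, x$y, predict_risk(fit, x, horizon), tau = horizon),
    brier = function(fit, x)
      brier_score(x$t, x$y, predict_risk(fit, x, horizon), horizon),
    oe = function(fit, x)
      oe_ratio(x$t, x$y, predict_risk(fit, x, horizon), horizon))
  if (calibration) {
    cal <- function(which) function(fit, x) {
      risk <- predict_risk(fit, x, horizon)
      obs <- suppressWarnings(smoothed_calibration(x$t, x$y, risk, horizon))
      calibration_errors(obs, risk)[[which]]
    }
    ms$ici <- cal("ici"); ms$e50 <- cal("e50")
    ms$e90 <- cal("e90"); ms$emax <- cal("emax")
    ms$slope <- function(fit, x) calibration_slope(fit, x)
  }
  ms
}

#' Build the full prognostic model suite
#'
#' Runs the complete two-stage pipeline on one cohort and fits every model
#' of the comparison:
#' \describe{
#'   \item{model1}{Cox on the entire cohort, treatment as a binary
#'     covariate.}
#'   \item{model2A / model2B}{Cox on the raw untreated / treated arm.}
#'   \item{model3A / model3B}{Cox on the stratum-matched untreated /
#'     treated arm (stage 1 stratification + matching, then stage 2
#'     fitting), optionally oversampled.}
#'   \item{psmA / psmB}{Cox on the 1:1 propensity-matched arms.}
#' }
#'
#' @param x a complete `cohort`.
#' @param variant matching variant for strata with `m > alpha`:
#'   `"equalized"` or `"relaxed"`.
#' @param oversample_factor 1 (none), 2 or 3 for the matched cohorts.
#' @param psm_method `"glm"` or `"rf"`; @param caliper PSM caliper in
#'   logit-SD units (glm only).
#' @param horizon risk horizon; @param S stratum count; @param cutoff
#'   alpha cutoff.
#' @return An object of class `model_suite`: `fits` (named `cox_fit`
#'   list), `training` (named `cohort` list, the rows each model was fit
#'   on), `assignment`, `matched`, `psm_matched`, `sizes` (training row
#'   counts) and the configuration.
#' @export
build_model_suite <- function(x, variant = c("equalized", "relaxed"),
                              oversample_factor = 1, psm_method = c("glm", "rf"),
                              caliper = 0.2, horizon = 60, S = 10,
                              cutoff = 20) {
  variant <- match.arg(variant)
  psm_method <- match.arg(psm_method)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("model suite failed at stage '", name, "': ",
           conditionMessage(e), call. = FALSE))
  }
  arms <- split_by_treatment(x)
  fits <- list(); training <- list()
  training$model1 <- x
  fits$model1 <- stage("model1", fit_cox(x, include_treatment = TRUE))
  training$model2A <- arms$untreated
  fits$model2A <- stage("model2A", fit_cox(arms$untreated))
  training$model2B <- arms$treated
  fits$model2B <- stage("model2B", fit_cox(arms$treated))
  assignment <- stage("stratification",
                      risk_stratify(x, horizon = horizon, S = S,
                                    cutoff = cutoff))
  matched <- stage("matching",
                   match_stratified_cohort(x, assignment, variant = variant))
  matched_os <- oversample(matched, oversample_factor)
  training$model3A <- matched_os$untreated
  fits$model3A <- stage("model3A", fit_cox(matched_os$untreated))
  training$model3B <- matched_os$treated
  fits$model3B <- stage("model3B", fit_cox(matched_os$treated))
  prop <- stage("propensity", estimate_propensity(x, method = psm_method))
  psm <- stage("psm_matching", nearest_neighbor_match(prop, x, caliper))
  training$psmA <- psm$untreated
  fits$psmA <- stage("psmA", fit_cox(psm$untreated))
  training$psmB <- psm$treated
  fits$psmB <- stage("psmB", fit_cox(psm$treated))
  structure(list(fits = fits, training = training,
                 assignment = assignment, matched = matched,
                 psm_matched = psm,
                 sizes = vapply(training, n_patients, integer(1)),
                 variant = variant, oversample_factor = oversample_factor,
                 psm_method = psm_method, horizon = horizon),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat("Prognostic model suite (variant = ", x$variant, ", oversample = ",
      x$oversample_factor, ", psm = ", x$psm_method, ")\n", sep = "")
  print(x$sizes)
  invisible(x)
}

#' In-sample metric table for a model suite
#'
#' Evaluates each fitted model on its own training rows. `model1A` and
#' `model1B` are evaluation views of model1 on the untreated / treated
#' subsets, not separate fits.
#'
#' @param suite a `model_suite`.
#' @param calibration include calibration metrics (default TRUE).
#' @return data frame, one row per model/view.
#' @export
in_sample_table <- function(suite, calibration = TRUE) {
  ms <- metric_set(suite$horizon, calibration)
  arms <- split_by_treatment(suite$training$model1)
  views <- c(list(model1 = list(fit = suite$fits$model1,
                                data = suite$training$model1),
                  model1A = list(fit = suite$fits$model1,
                                 data = arms$untreated),
                  model1B = list(fit = suite$fits$model1,
                                 data = arms$treated)),
             lapply(setdiff(names(suite$fits), "model1"), function(nm)
               list(fit = suite$fits[[nm]], data = suite$training[[nm]])))
  names(views) <- c("model1", "model1A", "model1B",
                    setdiff(names(suite$fits), "model1"))
  rows <- lapply(names(views), function(nm) {
    v <- views[[nm]]
    vals <- vapply(ms, function(f) f(v$fit, v$data), numeric(1))
    data.frame(model = nm, n = n_patients(v$data), t(vals))
  })
  do.call(rbind, rows)
}

#' Bias-corrected metric table for a model suite
#'
#' Runs [validate()] for every fitted model on its own training rows and
#' collects apparent, optimism and corrected values per metric.
#'
#' @param suite a `model_suite`; @param B resamples (default 100);
#' @param seed integer seed; @param calibration include calibration
#'   metrics.
#' @return data frame with columns model, metric, apparent, optimism,
#'   corrected, ci_lower, ci_upper.
#' @export
bootstrap_table <- function(suite, B = 100, seed = 1, calibration = TRUE) {
  ms <- metric_set(suite$horizon, calibration)
  include_trt <- vapply(suite$fits, function(f) f$includes_treatment,
                        logical(1))
  rows <- lapply(names(suite$fits), function(nm) {
    recipe <- local({
      trt <- include_trt[[nm]]
      function(d) fit_cox(d, include_treatment = trt)
    })
    rep <- validate(suite$training[[nm]], recipe, ms, B = B, seed = seed)
    cbind(model = nm, as.data.frame(rep))
  })
  do.call(rbind, rows)
}
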