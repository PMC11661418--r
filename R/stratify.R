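#' Fit the baseline prognostic risk model on untreated patients
#'
#' Stage one of prognostic stratum matching: a Cox model is trained on the
#' untreated arm only, without the treatment column, so that predicted
#' risks for treated patients are counterfactual no-treatment risks.
#'
#' @param untreated a complete `cohort` containing only untreated patients.
#' @param min_per_coef guard: require at least this many patients per
#'   encoded coefficient plus 10 (default 1, i.e. `n >= K + 10`).
#' @return a `cox_fit` (see [fit_cox()]).
#' @export
fit_baseline_risk_model <- function(untreated, min_per_coef = 1) {
  stopifnot(inherits(untreated, "cohort"))
  if (any(untreated$a != 0))
    stop("baseline risk model must be fit on untreated patients only")
  K <- ncol(encode_cohort(untreated))
  if (n_patients(untreated) < min_per_coef * K + 10)
    stop("too few untreated patients (", n_patients(untreated),
         ") for ", K, " coefficients")
  fit_cox(untreated, include_treatment = FALSE)
}

#' Assign fixed-width risk strata
#'
#' Stratum `s` covers predicted risk `[(s-1)/S, s/S)`, the last bin closed
#' above; with the default `S = 10`, a risk of 0.25 falls in stratum 3
#' (probability-of-death range 0.2-0.3). These are fixed-width probability
#' bins, not empirical quantiles, so strata can be very unequally
#' populated — that imbalance is exactly what the matching stage corrects.
#'
#' @param risks numeric vector of event probabilities in \[0, 1\].
#' @param S number of strata (default 10).
#' @return integer vector of stratum indices in `1..S`.
#' @export
assign_strata <- function(risks, S = 10) {
  if (any(!is.finite(risks)) || any(risks < 0) || any(risks > 1))
    stop("risks must lie in [0, 1]")
  pmin(floor(risks * S) + 1L, S)
}

#' Per-stratum patient counts by treatment arm
#'
#' @param stratum integer stratum indices in `1..S`.
#' @param a binary treatment vector.
#' @param S number of strata.
#' @return an `S x 2` matrix with columns `untreated`, `treated`.
#' @export
stratum_census <- function(stratum, a, S = 10) {
  out <- matrix(0L, nrow = S, ncol = 2,
                dimnames = list(stratum = seq_len(S),
                                arm = c("untreated", "treated")))
  if (length(stratum)) {
    tab <- table(factor(stratum, levels = seq_len(S)),
                 factor(a, levels = c(0, 1)))
    out[] <- as.integer(tab)
  }
  out
}

#' Select the per-stratum matched-pair quota alpha
#'
#' Alpha is the smallest stratum-by-arm subgroup count that is at least the
#' cutoff (default 20): the smallest subgroup large enough for data
#' reduction. Subgroups below the cutoff fall back to exact 1-1 matching at
#' dispatch time instead of constraining alpha.
#'
#' @param census matrix from [stratum_census()].
#' @param cutoff minimum admissible subgroup size (default 20).
#' @return integer alpha.
#' @export
select_alpha <- function(census, cutoff = 20) {
  counts <- census[census > 0]
  eligible <- counts[counts >= cutoff]
  if (!length(eligible))
    stop("no stratum-arm subgroup has >= ", cutoff,
         " patients; consider coarser strata")
  min(eligible)
}

#' Stage-one risk stratification of a cohort
#'
#' Fits the baseline Cox model on the untreated arm, predicts the
#' probability of death within the horizon for every patient, bins the
#' cohort into `S` fixed-width risk strata and selects alpha.
#'
#' @param x a complete `cohort`.
#' @param horizon risk horizon in the cohort's time unit (default 60
#'   months, i.e. five years).
#' @param S number of strata (default 10).
#' @param cutoff alpha cutoff (default 20).
#' @return An object of class `stratum_assignment`: list with `risk`,
#'   `stratum`, `alpha`, `census`, `S`, `horizon` and the baseline
#'   `cox_fit` (`baseline_fit`).
#' @export
risk_stratify <- function(x, horizon = 60, S = 10, cutoff = 20) {
  arms <- split_by_treatment(x)
  fit <- fit_baseline_risk_model(arms$untreated)
  risk <- predict_risk(fit, x, horizon)
  stratum <- assign_strata(risk, S)
  census <- stratum_census(stratum, x$a, S)
  alpha <- select_alpha(census, cutoff)
  structure(list(risk = risk, stratum = stratum, alpha = alpha,
                 census = census, S = S, horizon = horizon,
                 baseline_fit = fit),
            class = "stratum_assignment")
}

#' @export
print.stratum_assignment <- function(x, ...) {
  cat("Risk stratification: S = ", x$S, ", alpha = ", x$alpha,
      ", horizon = ", x$horizon, "\n", sep = "")
  print(t(x$census))
  invisible(x)
}
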