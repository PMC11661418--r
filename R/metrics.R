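#' Kaplan-Meier estimator as an evaluable step function
#'
#' @param t times; @param y event indicators (1 = event).
#' @return An object of class `km_curve`: list with `time`, `surv`, and
#'   `fn`, a right-continuous step function with `S(0) = 1`.
#' @export
km_estimator <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 1)
  sf <- survival::survfit(survival::Surv(t, y) ~ 1, se.fit = FALSE)
  fn <- stats::stepfun(sf$time, c(1, sf$surv), right = FALSE)
  structure(list(time = sf$time, surv = sf$surv, fn = fn),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve over", length(x$time), "time points\n")
  invisible(x)
}

# censoring-distribution KM (events treated as censorings and vice versa);
# returns right-continuous G and its left limit G(t-)
censoring_km <- function(t, y) {
  km <- km_estimator(t, 1 - y)
  gleft <- stats::stepfun(km$time, c(1, km$surv), right = TRUE)
  list(G = km$fn, Gminus = gleft)
}

#' Harrell's concordance index
#'
#' Probability that, among usable pairs (the earlier time is an event),
#' the patient who dies earlier has the higher predicted risk. Ties in the
#' risk score count 1/2; pairs with tied times and both events are
#' unusable.
#'
#' @param t times; @param y event indicators; @param risk risk scores
#'   (higher = worse prognosis).
#' @return concordance in \[0, 1\].
#' @export
harrell_c <- function(t, y, risk) {
  stopifnot(length(t) == length(y), length(t) == length(risk))
  if (length(t) < 2) stop("need at least 2 subjects")
  cf <- survival::concordance(survival::Surv(t, y) ~ risk, reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no usable pairs: concordance undefined")
  as.numeric(cf$concordance)
}

#' Uno's IPCW concordance index
#'
#' Concordance reweighted by the inverse squared Kaplan-Meier estimate of
#' the censoring distribution, truncated at `tau`, correcting Harrell's C
#' for study-specific censoring. With no censoring it reduces exactly to
#' Harrell's C.
#'
#' @inheritParams harrell_c
#' @param tau truncation time (pairs with the earlier event after `tau`
#'   are excluded); defaults to the evaluation horizon.
#' @return concordance in \[0, 1\].
#' @export
uno_c <- function(t, y, risk, tau) {
  stopifnot(length(t) == length(y), length(t) == length(risk))
  cf <- survival::concordance(survival::Surv(t, y) ~ risk, reverse = TRUE,
                              timewt = "n/G2", ymax = tau)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no usable pairs before tau: concordance undefined")
  as.numeric(cf$concordance)
}

#' Brier score at a fixed horizon (Graf IPCW estimator)
#'
#' Mean squared error between predicted event probability and outcome
#' status at the horizon, with censoring handled by inverse probability of
#' censoring weights: subjects with an event before the horizon get weight
#' `1/G(t_i-)`, subjects still at risk at the horizon `1/G(horizon)`, and
#' subjects censored before the horizon weight 0. Without censoring this
#' is the plain mean squared error.
#'
#' @inheritParams harrell_c
#' @param risk predicted event probability by `horizon`, in \[0, 1\].
#' @param horizon evaluation time.
#' @return nonnegative score.
#' @export
brier_score <- function(t, y, risk, horizon) {
  stopifnot(length(t) == length(y), length(t) == length(risk))
  G <- censoring_km(t, y)
  g_h <- G$G(horizon)
  event_before <- t <= horizon & y == 1
  at_risk <- t > horizon
  w <- numeric(length(t))
  gm <- G$Gminus(t[event_before])
  if (any(gm <= 0) || (any(at_risk) && g_h <= 0))
    stop("censoring distribution reaches 0 before the horizon")
  w[event_before] <- 1 / gm
  w[at_risk] <- 1 / g_h
  err <- numeric(length(t))
  err[event_before] <- (1 - risk[event_before])^2
  err[at_risk] <- (0 - risk[at_risk])^2
  mean(w * err)
}

#' Observed/expected ratio at a fixed horizon
#'
#' Calibration-in-the-large: the observed event proportion by the horizon
#' (`1 - KM(horizon)`) divided by the mean predicted risk.
#'
#' @inheritParams brier_score
#' @return positive ratio (1 = calibrated in the large).
#' @export
oe_ratio <- function(t, y, risk, horizon) {
  pred <- mean(risk)
  if (pred <= 0) stop("mean predicted risk is zero")
  obs <- 1 - km_estimator(t, y)$fn(horizon)
  obs / pred
}

#' Smoothed observed event probabilities for calibration assessment
#'
#' Flexible recalibration underlying the ICI family: a Cox model for the
#' event is fitted on a natural cubic spline (3 knots) of
#' `cloglog(risk)`, and each subject's model-based observed probability of
#' the event by the horizon is returned. If the risks are (numerically)
#' constant the observed probability is `1 - KM(horizon)` for everyone.
#'
#' @inheritParams brier_score
#' @param knots number of spline knots (default 3, i.e. 2 df).
#' @return numeric vector of observed event probabilities.
#' @export
smoothed_calibration <- function(t, y, risk, horizon, knots = 3) {
  stopifnot(length(t) == length(y), length(t) == length(risk))
  if (length(t) < 50)
    warning("fewer than 50 subjects: smoothed calibration is unstable")
  r <- pmin(pmax(risk, 1e-8), 1 - 1e-8)
  if (stats::sd(r) < 1e-8)
    return(rep(1 - km_estimator(t, y)$fn(horizon), length(t)))
  cll <- log(-log(1 - r))
  basis <- splines::ns(cll, df = knots - 1)
  df <- data.frame(unclass(basis))
  names(df) <- paste0("s", seq_len(ncol(basis)))
  df$.t <- t; df$.y <- y
  fit <- survival::coxph(stats::as.formula(
    paste("survival::Surv(.t, .y) ~", paste(names(df)[seq_len(ncol(basis))],
                                            collapse = " + "))),
    data = df, ties = "breslow")
  sf <- survival::survfit(fit, se.fit = FALSE)
  idx <- findInterval(horizon, sf$time)
  s0 <- if (idx == 0) 1 else sf$surv[idx]
  lp <- stats::predict(fit, type = "lp")  # centered at means
  obs <- 1 - s0 ^ exp(lp)
  pmin(pmax(obs, 0), 1)
}

#' Calibration error summaries (ICI, E50, E90, Emax)
#'
#' Summaries of the absolute differences between smoothed observed and
#' predicted event probabilities: ICI is the mean, E50 the median, E90 the
#' 90th percentile (linear interpolation between order statistics), Emax
#' the maximum.
#'
#' @param observed smoothed observed probabilities (see
#'   [smoothed_calibration()]).
#' @param risk predicted probabilities.
#' @return named numeric vector `c(ici, e50, e90, emax)`.
#' @export
calibration_errors <- function(observed, risk) {
  stopifnot(length(observed) == length(risk))
  if (!length(observed)) stop("empty input")
  ad <- abs(observed - risk)
  c(ici = mean(ad),
    e50 = unname(stats::quantile(ad, 0.5, type = 7)),
    e90 = unname(stats::quantile(ad, 0.9, type = 7)),
    emax = max(ad))
}

#' Calibration slope of a fitted Cox model on evaluation data
#'
#' The coefficient of the model's linear predictor when entered as the
#' sole covariate of a Cox model refit on the evaluation sample. On the
#' model's own training data the slope is exactly 1 (maximum-likelihood
#' self-consistency); below 1 on fresh data indicates overfitting.
#'
#' @param fit a `cox_fit`; @param x evaluation `cohort` with >= 1 event.
#' @return the slope (numeric scalar).
#' @export
calibration_slope <- function(fit, x) {
  lp <- linear_predictor(fit, x)
  if (stats::sd(lp) < 1e-12)
    stop("constant linear predictor: slope undefined")
  if (sum(x$y) < 1) stop("no events in the evaluation sample")
  refit <- survival::coxph(survival::Surv(x$t, x$y) ~ lp, ties = "breslow",
                           control = survival::coxph.control(eps = 1e-9,
                                                             iter.max = 50))
  unname(stats::coef(refit))
}

#' All discrimination and calibration metrics at a horizon
#'
#' Convenience wrapper: Harrell's C, Uno's C (tau = horizon), Brier score,
#' O/E ratio, ICI/E50/E90/Emax (via smoothed calibration) and calibration
#' slope for one fitted model on one evaluation cohort.
#'
#' @param fit a `cox_fit`; @param x evaluation `cohort`;
#' @param horizon evaluation time.
#' @return named numeric vector of metrics.
#' @export
evaluate_model <- function(fit, x, horizon) {
  risk <- predict_risk(fit, x, horizon)
  obs <- smoothed_calibration(x$t, x$y, risk, horizon)
  c(harrell_c = harrell_c(x$t, x$y, risk),
    uno_c = uno_c(x$t, x$y, risk, tau = horizon),
    brier = brier_score(x$t, x$y, risk, horizon),
    oe = oe_ratio(x$t, x$y, risk, horizon),
    calibration_errors(obs, risk),
    slope = calibration_slope(fit, x))
}
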