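#' Configuration for the synthetic confounded-cohort generator
#'
#' Defaults emulate the statistical structure of an observational surgical
#' oncology cohort: about 1,800 patients, 10 mixed-type prognostic
#' covariates (4 continuous, 4 binary, 2 three-level categorical), roughly
#' two thirds treated, treatment assignment confounded with prognosis
#' (patients with more favorable covariates are more likely to be
#' treated), exponential-baseline proportional-hazards survival with a
#' median near 66 months, a five-year (60-month) endpoint and ~45%
#' independent right-censoring.
#'
#' @param n cohort size.
#' @param K_continuous,K_binary,K_categorical covariate counts; each
#'   categorical covariate has 3 levels.
#' @param beta_outcome true log-hazard coefficients on the encoded scale
#'   (length `K_continuous + K_binary + 2*K_categorical`).
#' @param gamma_propensity true treatment log-odds coefficients (same
#'   length); the default is `-confounding * beta_outcome`, i.e. healthier
#'   patients are likelier to be treated.
#' @param confounding scalar strength of the default confounding (0 = a
#'   randomized cohort).
#' @param treatment_effect log hazard ratio of treatment (default -0.3,
#'   protective).
#' @param prevalence target marginal treatment probability (sets the
#'   propensity intercept; default 2/3).
#' @param shape,scale Weibull baseline (shape 1 = exponential; scale in
#'   months).
#' @param censoring target censoring fraction in \[0, 1).
#' @param horizon evaluation horizon (months).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n = 1800, K_continuous = 4, K_binary = 4,
                             K_categorical = 2, beta_outcome = NULL,
                             gamma_propensity = NULL, confounding = 1,
                             treatment_effect = -0.3, prevalence = 2 / 3,
                             shape = 1, scale = 96, censoring = 0.45,
                             horizon = 60) {
  K <- K_continuous + K_binary + 2 * K_categorical
  if (is.null(beta_outcome)) {
    beta_outcome <- c(rep(c(0.35, 0.25), length.out = K_continuous),
                      rep(c(0.45, 0.30), length.out = K_binary),
                      rep(c(0.25, 0.50), length.out = 2 * K_categorical))
  }
  if (length(beta_outcome) != K)
    stop("beta_outcome must have length ", K, " (encoded scale)")
  if (is.null(gamma_propensity)) gamma_propensity <- -confounding * beta_outcome
  if (length(gamma_propensity) != K)
    stop("gamma_propensity must have length ", K)
  stopifnot(n > 0, censoring >= 0, censoring < 1, shape > 0, scale > 0)
  structure(list(n = n, K_continuous = K_continuous, K_binary = K_binary,
                 K_categorical = K_categorical, beta_outcome = beta_outcome,
                 gamma_propensity = gamma_propensity,
                 treatment_effect = treatment_effect,
                 prevalence = prevalence, shape = shape, scale = scale,
                 censoring = censoring, horizon = horizon),
            class = "generator_config")
}

default_schema <- function(cfg) {
  nm <- c(paste0("x", seq_len(cfg$K_continuous), recycle0 = TRUE),
          paste0("b", seq_len(cfg$K_binary), recycle0 = TRUE),
          paste0("c", seq_len(cfg$K_categorical), recycle0 = TRUE))
  kinds <- c(rep("continuous", cfg$K_continuous),
             rep("binary", cfg$K_binary),
             rep("categorical", cfg$K_categorical))
  cats <- stats::setNames(
    rep(list(c("L1", "L2", "L3")), cfg$K_categorical),
    paste0("c", seq_len(cfg$K_categorical), recycle0 = TRUE))
  covariate_schema(nm, kinds, cats)
}

#' Generate a confounded synthetic survival cohort with known truth
#'
#' Covariates are standard normal (continuous), Bernoulli(0.4) (binary) or
#' three-level categorical with probabilities (0.5, 0.3, 0.2). Treatment
#' is Bernoulli on a logistic propensity over the encoded covariates, with
#' the intercept solved so the marginal treatment rate matches the
#' configured prevalence. Event times follow a Weibull-baseline
#' proportional-hazards model,
#' `S(t | x, a) = exp(-(t/scale)^shape * exp(beta'x + effect*a))`, and
#' censoring is an independent uniform window calibrated to the target
#' censoring fraction. The returned `truth` record carries everything a
#' recovery test needs.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with `cohort` (a complete `cohort`) and `truth` (list:
#'   `beta`, `gamma`, `effect`, `lp`, `propensity`, `risk` — the true
#'   probability of death by the horizon given covariates and assigned
#'   treatment — `event_time`, `censor_time`).
#' @export
generate_cohort <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  n <- config$n
  schema <- default_schema(config)
  X <- data.frame(matrix(nrow = n, ncol = 0))
  for (j in seq_len(config$K_continuous))
    X[[paste0("x", j)]] <- stats::rnorm(n)
  for (j in seq_len(config$K_binary))
    X[[paste0("b", j)]] <- stats::rbinom(n, 1, 0.4)
  for (j in seq_len(config$K_categorical))
    X[[paste0("c", j)]] <- sample(c("L1", "L2", "L3"), n, replace = TRUE,
                                  prob = c(0.5, 0.3, 0.2))
  tmp <- cohort(X, a = rep(0L, n), t = rep(1, n), y = rep(0L, n),
                schema = schema)
  Z <- encode_cohort(tmp)
  # propensity with intercept solved for the target prevalence
  # center the encoded covariates at their theoretical means so the
  # Weibull scale sets the risk of the average patient directly
  zbar <- c(rep(0, config$K_continuous), rep(0.4, config$K_binary),
            rep(c(0.3, 0.2), config$K_categorical))
  Zc <- sweep(Z, 2, zbar)
  eta <- drop(Zc %*% config$gamma_propensity)
  ic <- stats::uniroot(function(c0) mean(stats::plogis(c0 + eta)) -
                         config$prevalence,
                       interval = c(-20, 20))$root
  prop <- stats::plogis(ic + eta)
  a <- stats::rbinom(n, 1, prop)
  # proportional-hazards event times, Weibull baseline
  lp <- drop(Zc %*% config$beta_outcome) + config$treatment_effect * a
  u <- stats::runif(n)
  event_time <- config$scale * (-log(u) / exp(lp))^(1 / config$shape)
  # uniform censoring window calibrated to the target censoring fraction
  if (config$censoring > 0) {
    cens_frac <- function(cmax) mean(pmin(event_time / cmax, 1)) -
      config$censoring
    lo <- 1e-6; hi <- max(event_time) * 100
    if (cens_frac(hi) > 0) {
      warning("censoring target ", config$censoring,
              " unattainable; using minimal censoring window")
      cmax <- hi
    } else {
      cmax <- stats::uniroot(cens_frac, interval = c(lo, hi))$root
    }
    censor_time <- stats::runif(n, 0, cmax)
  } else {
    censor_time <- rep(Inf, n)
  }
  t_obs <- pmin(event_time, censor_time)
  y <- as.integer(event_time <= censor_time)
  risk_true <- 1 - exp(-(config$horizon / config$scale)^config$shape *
                         exp(lp))
  co <- cohort(X, a = a, t = t_obs, y = y, schema = schema)
  list(cohort = co,
       truth = list(beta = config$beta_outcome,
                    gamma = config$gamma_propensity,
                    effect = config$treatment_effect,
                    lp = lp, propensity = prop, risk = risk_true,
                    event_time = event_time, censor_time = censor_time,
                    config = config, seed = seed))
}

#' Generate a small random matching instance for solver tests
#'
#' Either fully random nonnegative distances, or a "planted" instance
#' whose optimum is known by construction: the diagonal cells get small
#' distances, all off-diagonal cells large ones, so the identity pairing
#' is the unique optimum and its total is the diagonal sum.
#'
#' @param m,n arm sizes (`m <= n`); @param alpha pair quota;
#' @param law `"uniform"` or `"planted"`; @param seed integer seed.
#' @return a [matching_instance()]; for planted instances the attribute
#'   `"planted_total"` holds the known optimal total for exact 1-1 /
#'   equalized-with-`alpha = m` matching.
#' @export
generate_matching_instance <- function(m, n, alpha,
                                       law = c("uniform", "planted"),
                                       seed = 1) {
  law <- match.arg(law)
  stopifnot(m <= n)
  set.seed(seed)
  if (law == "uniform") {
    D <- matrix(stats::runif(m * n), m, n)
    inst <- matching_instance(D, alpha)
  } else {
    D <- matrix(stats::runif(m * n, 10, 20), m, n)
    diag_vals <- stats::runif(m, 0, 1)
    D[cbind(seq_len(m), seq_len(m))] <- diag_vals
    inst <- matching_instance(D, alpha)
    attr(inst, "planted_total") <- sum(diag_vals)
  }
  inst
}
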