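# Small fixtures built in code; no stored data.

one_cov_schema <- function() covariate_schema("x", "continuous")

# cohort with a single continuous covariate and exponential survival:
# hazard = rate * exp(beta * x), no censoring unless cens_max given
exp_cohort <- function(n, beta = 0, rate = 0.1, x = NULL, a = NULL,
                       cens_max = Inf, seed = 1) {
  set.seed(seed)
  if (is.null(x)) x <- rnorm(n)
  if (is.null(a)) a <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate * exp(beta * x))
  cc <- if (is.finite(cens_max)) runif(n, 0, cens_max) else rep(Inf, n)
  cohort(data.frame(x = x), a = a, t = pmin(tt, cc),
         y = as.integer(tt <= cc), schema = one_cov_schema())
}

# hand-built cox_fit with a known exponential baseline S0(t) = exp(-rate*t),
# coefficient beta on covariate "x", centered at mean 0
manual_exp_fit <- function(beta = log(2), rate = 0.1, tmax = 100) {
  times <- seq(0.01, tmax, by = 0.01)
  structure(list(coefficients = c(x = beta), means = c(x = 0),
                 base_times = times, base_surv = exp(-rate * times),
                 includes_treatment = FALSE, schema = one_cov_schema(),
                 time_unit = "years", n = NA_integer_, nevent = NA_integer_),
            class = "cox_fit")
}

small_confounded <- function(n = 400, seed = 1, confounding = 1)
  generate_cohort(generator_config(n = n, confounding = confounding),
                  seed = seed)
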