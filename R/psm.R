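#' Estimate propensity scores for treatment
#'
#' Probability of receiving treatment given the encoded covariates, via
#' logistic regression (`"glm"`) or a random forest (`"rf"`, 500 trees).
#' Scores are clipped to (1e-6, 1 - 1e-6) so the logit is always finite;
#' clipping is reported when it occurs (e.g. under separation).
#'
#' @param x a complete `cohort` with both arms nonempty.
#' @param method `"glm"` (default) or `"rf"`.
#' @return An object of class `propensity_fit` with `scores`, `method`,
#'   and the underlying model.
#' @export
estimate_propensity <- function(x, method = c("glm", "rf")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "cohort"))
  if (length(unique(x$a)) < 2) stop("both treatment arms must be nonempty")
  Z <- encode_cohort(x)
  if (method == "glm") {
    df <- data.frame(Z, check.names = FALSE)
    df$.a <- x$a
    fit <- suppressWarnings(
      stats::glm(stats::as.formula(
        paste(".a ~", paste(sprintf("`%s`", colnames(Z)), collapse = " + "))),
        family = stats::binomial(), data = df))
    scores <- stats::fitted(fit)
  } else {
    fit <- randomForest::randomForest(x = Z, y = factor(x$a, levels = c(0, 1)),
                                      ntree = 500)
    scores <- stats::predict(fit, Z, type = "prob")[, "1"]
  }
  eps <- 1e-6
  if (any(scores < eps | scores > 1 - eps))
    warning("propensity scores at the boundary clipped to (",
            format(eps), ", 1 - ", format(eps), ")")
  scores <- pmin(pmax(scores, eps), 1 - eps)
  structure(list(scores = as.numeric(scores), method = method, model = fit),
            class = "propensity_fit")
}

#' 1:1 nearest-neighbor propensity score matching without replacement
#'
#' Greedy matching on the logit of the propensity score: minority-arm
#' patients are visited in descending score order and each takes the
#' closest still-unused majority patient. With `method = "glm"` a caliper
#' of `caliper` times the SD of the logit scores discards pairs that are
#' too far apart (so patients can be lost from both arms); the random
#' forest comparator applies no caliper, so when the untreated arm is the
#' minority it is retained in full.
#'
#' @param fit a `propensity_fit` for `x`.
#' @param x the same complete `cohort`.
#' @param caliper caliper width in logit-SD units (default 0.2); only
#'   applied when `fit$method == "glm"`.
#' @return a `matched_cohorts` (no stratum provenance; `pairs` data frame
#'   with ids and logit distances).
#' @export
nearest_neighbor_match <- function(fit, x, caliper = 0.2) {
  stopifnot(inherits(fit, "propensity_fit"), inherits(x, "cohort"))
  lgt <- stats::qlogis(fit$scores)
  use_caliper <- identical(fit$method, "glm") && is.finite(caliper)
  width <- if (use_caliper) caliper * stats::sd(lgt) else Inf
  iu <- which(x$a == 0); it <- which(x$a == 1)
  if (!length(iu) || !length(it)) stop("both arms must be nonempty")
  if (length(iu) <= length(it)) { minor <- iu; major <- it }
  else { minor <- it; major <- iu }
  minor <- minor[order(lgt[minor], decreasing = TRUE)]
  used <- rep(FALSE, length(major))
  pu <- integer(0); pt <- integer(0); dists <- numeric(0)
  for (i in minor) {
    d <- abs(lgt[major] - lgt[i])
    d[used] <- Inf
    j <- which.min(d)
    if (!is.finite(d[j]) || d[j] > width) next
    used[j] <- TRUE
    k <- major[j]
    pu <- c(pu, if (x$a[i] == 0) i else k)
    pt <- c(pt, if (x$a[i] == 0) k else i)
    dists <- c(dists, d[j])
  }
  if (!length(pu)) {
    warning("no pairs within the caliper; matched cohorts are empty")
    empty <- cohort_rows(x, integer(0))
    return(structure(list(untreated = empty, treated = empty,
                          untreated_rows = integer(0),
                          treated_rows = integer(0),
                          pairs = data.frame(), variant = "psm",
                          caliper_width = width),
                     class = "matched_cohorts"))
  }
  structure(list(untreated = cohort_rows(x, pu), treated = cohort_rows(x, pt),
                 untreated_rows = pu, treated_rows = pt,
                 pairs = data.frame(untreated_id = x$ids[pu],
                                    treated_id = x$ids[pt],
                                    logit_distance = dists),
                 variant = "psm", caliper_width = width),
            class = "matched_cohorts")
}
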