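test_that("normalization centers and scales with the pooled sample SD", {
  Z <- cbind(x = c(0, 2))
  expect_equal(normalize_covariates(Z)[, 1], c(-1, 1) / sqrt(2))
  # constant column maps to zero
  Zc <- cbind(x = c(0, 2), k = c(5, 5))
  expect_equal(normalize_covariates(Zc)[, "k"], c(0, 0))
  # non-degenerate columns end up mean 0, sample SD 1
  set.seed(4)
  Zr <- matrix(rnorm(60), 20, 3)
  Nr <- normalize_covariates(Zr)
  expect_equal(colMeans(Nr), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(Nr, 2, sd), rep(1, 3), tolerance = 1e-12)
})

test_that("distance matrix is the root-sum-square of normalized differences", {
  N <- normalize_covariates(cbind(x = c(0, 2)))
  D <- compute_distance_matrix(N[1, , drop = FALSE], N[2, , drop = FALSE])
  expect_equal(D[1, 1], sqrt(2), tolerance = 1e-12)
  expect_equal(compute_distance_matrix(cbind(1, 2), cbind(1, 2))[1, 1], 0)
  # K identical unit differences -> sqrt(K)
  K <- 5
  expect_equal(compute_distance_matrix(matrix(0, 1, K),
                                       matrix(1, 1, K))[1, 1], sqrt(K))
  expect_error(compute_distance_matrix(matrix(0, 1, 2), matrix(0, 1, 3)),
               "same number")
})

test_that("equalized matching selects exactly alpha optimal pairs", {
  D <- matrix(c(1, 10, 10, 2), 2, 2, byrow = TRUE)
  s2 <- solve_equalized_matching(matching_instance(D, alpha = 2))
  expect_equal(s2$total_distance, 3)
  expect_equal(unname(s2$pairs), cbind(c(1, 2), c(1, 2)))
  s1 <- solve_equalized_matching(matching_instance(D, alpha = 1))
  expect_equal(s1$total_distance, 1)
  expect_equal(unname(s1$pairs), cbind(1, 1))
  expect_error(solve_equalized_matching(matching_instance(D, alpha = 3)),
               "exact_one_to_one|infeasible")
})

test_that("exact 1-1 matching covers all of A with deterministic tie-breaking", {
  s <- solve_exact_one_to_one(matching_instance(rbind(c(5, 2, 7)), alpha = 1))
  expect_equal(unname(s$pairs), cbind(1, 2))
  expect_equal(s$total_distance, 2)
  # tie: both diagonals total 3; lexicographic preference picks (1,1),(2,2)
  tie <- matching_instance(matrix(c(1, 2, 1, 2), 2, 2, byrow = TRUE), alpha = 2)
  st <- solve_exact_one_to_one(tie)
  expect_equal(st$total_distance, 3)
  expect_equal(unname(st$pairs), cbind(c(1, 2), c(1, 2)))
})

test_that("relaxed matching reuses patients up to capacity two", {
  inst <- matching_instance(rbind(c(1, 4)), alpha = 2)
  s <- solve_relaxed_matching(inst)
  expect_equal(s$total_distance, 5)
  expect_equal(unname(s$pairs), cbind(c(1, 1), c(1, 2)))
  s1 <- solve_relaxed_matching(matching_instance(rbind(c(1, 4)), alpha = 1))
  expect_equal(s1$total_distance, 1)
  expect_error(solve_relaxed_matching(matching_instance(rbind(c(1, 4)),
                                                        alpha = 5)),
               "infeasible")
  # relaxed must never beat capacity rules: each patient at most twice
  set.seed(9)
  inst2 <- matching_instance(matrix(runif(12), 3, 4), alpha = 6)
  s2 <- solve_relaxed_matching(inst2)
  expect_true(all(s2$count_A <= 2) && all(s2$count_B <= 2))
  expect_equal(nrow(s2$pairs), 6)
})

test_that("solvers equal the brute-force oracle on random instances", {
  n_cases <- 0L
  for (seed in 1:75) {
    set.seed(seed)
    m <- sample(1:6, 1)
    n <- m + sample.int(7 - m, 1) - 1
    D <- matrix(round(runif(m * n), 3), m, n)

    a_eq <- sample(1:m, 1)
    inst <- matching_instance(D, a_eq)
    expect_equal(solve_equalized_matching(inst)$total_distance,
                 brute_force_matching(inst, "equalized")$total_distance,
                 tolerance = 1e-12)

    expect_equal(solve_exact_one_to_one(inst)$total_distance,
                 brute_force_matching(inst, "exact_one_to_one")$total_distance,
                 tolerance = 1e-12)

    a_rx <- sample(1:min(4, 2 * m, m * n), 1)
    inst_rx <- matching_instance(D, a_rx)
    expect_equal(solve_relaxed_matching(inst_rx)$total_distance,
                 brute_force_matching(inst_rx, "relaxed")$total_distance,
                 tolerance = 1e-12)
    n_cases <- n_cases + 3L
  }
  expect_gte(n_cases, 200L)
})

test_that("relaxed optimum never exceeds the equalized optimum", {
  for (seed in 1:20) {
    set.seed(seed + 500)
    m <- sample(2:6, 1); n <- m + sample.int(7 - m, 1) - 1
    D <- matrix(runif(m * n), m, n)
    alpha <- sample(1:m, 1)
    inst <- matching_instance(D, alpha)
    expect_lte(solve_relaxed_matching(inst)$total_distance,
               solve_equalized_matching(inst)$total_distance + 1e-12)
  }
})

test_that("planted matching instances recover the known optimum", {
  inst <- generate_matching_instance(3, 3, alpha = 3, law = "planted",
                                     seed = 5)
  s <- solve_exact_one_to_one(inst)
  expect_equal(s$total_distance, attr(inst, "planted_total"),
               tolerance = 1e-12)
  expect_equal(unname(s$pairs), cbind(1:3, 1:3))
  # seeded determinism
  i1 <- generate_matching_instance(2, 5, alpha = 2, seed = 7)
  i2 <- generate_matching_instance(2, 5, alpha = 2, seed = 7)
  expect_identical(i1$D, i2$D)
})

test_that("total distance is invariant to patient order within a stratum", {
  set.seed(31)
  D <- matrix(runif(30), 5, 6)
  inst <- matching_instance(D, alpha = 3)
  base <- solve_equalized_matching(inst)$total_distance
  for (k in 1:5) {
    pr <- sample(5); pc <- sample(6)
    perm <- matching_instance(D[pr, pc], alpha = 3)
    expect_equal(solve_equalized_matching(perm)$total_distance, base,
                 tolerance = 1e-9)
  }
})

test_that("stratified matching dispatches per stratum and equalizes arms", {
  gen <- small_confounded(n = 2000, seed = 8)
  co <- gen$cohort
  asg <- risk_stratify(co)
  m <- suppressMessages(match_stratified_cohort(co, asg, "equalized"))
  cen <- asg$census
  for (s in seq_len(asg$S)) {
    msize <- min(cen[s, ])
    if (msize == 0) {
      expect_equal(sum(m$census_matched[s, ]), 0)
    } else if (msize <= asg$alpha) {
      # exact 1-1: whole minority arm retained
      expect_equal(unname(m$census_matched[s, ]), rep(msize, 2))
    } else {
      expect_equal(unname(m$census_matched[s, ]), rep(asg$alpha, 2))
    }
  }
  # conservation: equal arm counts, never exceeding the original cohort
  expect_equal(n_patients(m$untreated), n_patients(m$treated))
  expect_lte(n_patients(m$untreated) + n_patients(m$treated), n_patients(co))
  # capacity audit per stratum: nobody twice under equalized matching
  for (s in seq_len(asg$S)) {
    ids_u <- m$untreated$ids[asg$stratum[m$untreated_rows] == s]
    expect_equal(anyDuplicated(ids_u), 0)
  }
})

test_that("relaxed stratified matching respects capacity two per stratum", {
  gen <- small_confounded(n = 1200, seed = 13)
  co <- gen$cohort
  asg <- risk_stratify(co)
  m <- suppressMessages(match_stratified_cohort(co, asg, "relaxed"))
  for (s in seq_len(asg$S)) {
    rows_s <- m$untreated_rows[asg$stratum[m$untreated_rows] == s]
    if (length(rows_s))
      expect_lte(max(table(rows_s)), 2)
  }
})

test_that("matching improves covariate balance on confounded cohorts", {
  gen <- small_confounded(n = 2000, seed = 17)
  co <- gen$cohort
  arms <- split_by_treatment(co)
  before <- mean(abs(standardized_mean_differences(
    encode_cohort(arms$untreated), encode_cohort(arms$treated))))
  asg <- risk_stratify(co)
  m <- suppressMessages(match_stratified_cohort(co, asg))
  after <- mean(abs(standardized_mean_differences(
    encode_cohort(m$untreated), encode_cohort(m$treated))))
  expect_lt(after, before)
})

test_that("oversampling replicates rows without changing the distinct census", {
  gen <- small_confounded(n = 1000, seed = 21)
  co <- gen$cohort
  asg <- risk_stratify(co)
  m <- suppressMessages(match_stratified_cohort(co, asg))
  expect_identical(oversample(m, 1), m)
  m3 <- oversample(m, 3)
  expect_equal(n_patients(m3$untreated), 3 * n_patients(m$untreated))
  expect_equal(table(m3$untreated$ids), 3 * table(m$untreated$ids))
  expect_identical(m3$census_matched, m$census_matched)
  expect_error(oversample(m, 0), ">= 1")
})
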