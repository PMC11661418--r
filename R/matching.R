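#' Normalize covariates within a stratum
#'
#' Columns are centered and scaled by the pooled sample mean and SD
#' (denominator n-1) of all stratum members — both arms together — so that
#' cross-arm distances are measured on one common scale. Zero-variance
#' columns map to 0.
#'
#' @param Z numeric matrix of encoded covariates (stratum members x K).
#' @return matrix of the same shape with columns standardized.
#' @export
normalize_covariates <- function(Z) {
  if (nrow(Z) < 2) stop("need at least 2 members to normalize")
  mu <- colMeans(Z)
  sd <- apply(Z, 2, stats::sd)
  out <- sweep(Z, 2, mu)
  keep <- sd > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2, sd[keep], "/")
  out[, !keep] <- 0
  out
}

#' Pairwise Euclidean distance matrix between two normalized groups
#'
#' `d_ij = sqrt(sum_k (x_ik - x_jk)^2)` — the root-sum-square of
#' differences between normalized covariates.
#'
#' @param normA,normB numeric matrices with identical columns.
#' @return `nrow(normA) x nrow(normB)` matrix of nonnegative distances.
#' @export
compute_distance_matrix <- function(normA, normB) {
  if (ncol(normA) != ncol(normB))
    stop("groups must have the same number of covariate columns")
  sq <- outer(rowSums(normA^2), rowSums(normB^2), "+") -
    2 * tcrossprod(normA, normB)
  sqrt(pmax(sq, 0))
}

#' Construct a per-stratum matching instance
#'
#' Convention: A is the smaller arm (m patients), B the larger (`n_B`).
#'
#' @param D `m x n_B` matrix of nonnegative finite distances.
#' @param alpha required pair count for the equalized/relaxed formulations.
#' @param A_ids,B_ids optional identifiers (default row/column indices).
#' @param stratum_index optional stratum label.
#' @return An object of class `matching_instance`.
#' @export
matching_instance <- function(D, alpha, A_ids = NULL, B_ids = NULL,
                              stratum_index = NA_integer_) {
  D <- as.matrix(D)
  if (any(!is.finite(D)) || any(D < 0))
    stop("distances must be finite and nonnegative")
  if (nrow(D) > ncol(D))
    stop("A must be the smaller arm: nrow(D) <= ncol(D)")
  if (is.null(A_ids)) A_ids <- seq_len(nrow(D))
  if (is.null(B_ids)) B_ids <- seq_len(ncol(D))
  structure(list(D = D, alpha = as.integer(alpha), m = nrow(D),
                 n_B = ncol(D), A_ids = A_ids, B_ids = B_ids,
                 stratum_index = stratum_index),
            class = "matching_instance")
}

# Deterministic tie-break: among equally optimal matchings prefer pairings
# aligned with low (i, j) indices by subtracting an epsilon bonus
# proportional to i*j (rearrangement inequality favours the identity-like
# pairing). Epsilon is far below the smallest nonzero distance gap, and the
# per-pair constant shift is irrelevant because each formulation fixes the
# pair count.
perturb_for_ties <- function(D) {
  vals <- sort(unique(as.vector(D)))
  gaps <- diff(vals)
  g0 <- if (length(gaps) && any(gaps > 0)) min(gaps[gaps > 0]) else
    max(max(D), 1)
  eps <- g0 / (4 * (nrow(D) * ncol(D))^2 + 4)
  D + eps * (nrow(D) * ncol(D) - outer(seq_len(nrow(D)), seq_len(ncol(D))))
}

new_match_solution <- function(inst, pairs, formulation) {
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  colnames(pairs) <- c("A", "B")
  total <- sum(inst$D[pairs])
  structure(list(pairs = pairs,
                 count_A = tabulate(pairs[, 1], inst$m),
                 count_B = tabulate(pairs[, 2], inst$n_B),
                 total_distance = total,
                 formulation = formulation,
                 stratum_index = inst$stratum_index),
            class = "match_solution")
}

#' @export
print.match_solution <- function(x, ...) {
  cat("Matching (", x$formulation, "): ", nrow(x$pairs),
      " pairs, total distance ", format(x$total_distance), "\n", sep = "")
  invisible(x)
}

#' Equalized 1-1 prognostic stratum matching
#'
#' Minimizes total distance subject to each patient matched at most once
#' and at least `alpha` pairs selected; with nonnegative distances exactly
#' `alpha` pairs are chosen, so every stratum solved this way contributes
#' the same number of patients per arm ("equalization").
#'
#' @param inst a [matching_instance()] with `m >= alpha`.
#' @return a `match_solution`.
#' @export
solve_equalized_matching <- function(inst) {
  stopifnot(inherits(inst, "matching_instance"))
  if (inst$m < inst$alpha)
    stop("equalized matching infeasible: m = ", inst$m, " < alpha = ",
         inst$alpha, "; use solve_exact_one_to_one()")
  pairs <- mcf_match(perturb_for_ties(inst$D), 1L, 1L, inst$alpha)
  new_match_solution(inst, pairs, "equalized")
}

#' Exact 1-1 matching of the full minority arm
#'
#' Every patient in the smaller arm A is matched to exactly one distinct
#' partner in B at minimum total distance (the rectangular assignment
#' problem). Used for strata too small to afford data reduction.
#'
#' @param inst a [matching_instance()].
#' @return a `match_solution` with exactly `m` pairs.
#' @export
solve_exact_one_to_one <- function(inst) {
  stopifnot(inherits(inst, "matching_instance"))
  pairs <- mcf_match(perturb_for_ties(inst$D), 1L, 1L, inst$m)
  new_match_solution(inst, pairs, "exact_one_to_one")
}

#' Relaxed prognostic stratum matching (capacity 2, with replacement)
#'
#' Like the equalized formulation but each patient on either side may take
#' part in up to two (distinct) pairs, so small arms can still fill the
#' `alpha`-pair quota by reusing patients.
#'
#' @param inst a [matching_instance()] with `2 * min(m, n_B) >= alpha`.
#' @return a `match_solution` with exactly `alpha` pairs.
#' @export
solve_relaxed_matching <- function(inst) {
  stopifnot(inherits(inst, "matching_instance"))
  if (2L * min(inst$m, inst$n_B) < inst$alpha)
    stop("relaxed matching infeasible: capacity 2*min(m, n_B) = ",
         2L * min(inst$m, inst$n_B), " < alpha = ", inst$alpha)
  pairs <- mcf_match(perturb_for_ties(inst$D), 2L, 2L, inst$alpha)
  new_match_solution(inst, pairs, "relaxed")
}

#' Match a stratified cohort, stratum by stratum
#'
#' For each risk stratum: the smaller arm is labelled A; covariates are
#' normalized over the pooled stratum members; if `m <= alpha` the whole
#' minority arm is matched exactly 1-1, otherwise the configured variant
#' (equalized or relaxed) selects `alpha` pairs. Strata with an empty arm
#' contribute no pairs (logged). Matched arms are assembled as row
#' multisets of the original cohort — under relaxed matching a patient in
#' two pairs contributes two rows.
#'
#' @param x the complete `cohort` that was stratified.
#' @param assignment a `stratum_assignment` from [risk_stratify()].
#' @param variant `"equalized"` (default) or `"relaxed"` — the formulation
#'   used where `m > alpha`.
#' @return An object of class `matched_cohorts`: `untreated`/`treated`
#'   (row-multiset `cohort`s), `provenance` (per-pair stratum, ids,
#'   formulation), `pair_counts` per stratum, and `census_matched`
#'   (distinct-patient counts per stratum and arm).
#' @export
match_stratified_cohort <- function(x, assignment,
                                    variant = c("equalized", "relaxed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(assignment, "stratum_assignment"))
  if (length(assignment$stratum) != n_patients(x))
    stop("assignment does not cover the cohort")
  Z <- encode_cohort(x)
  alpha <- assignment$alpha
  rows_u <- integer(0); rows_t <- integer(0)
  prov <- list()
  pair_counts <- integer(assignment$S)
  census <- matrix(0L, assignment$S, 2,
                   dimnames = list(stratum = seq_len(assignment$S),
                                   arm = c("untreated", "treated")))
  for (s in seq_len(assignment$S)) {
    iu <- which(assignment$stratum == s & x$a == 0)
    it <- which(assignment$stratum == s & x$a == 1)
    if (length(iu) == 0 || length(it) == 0) {
      if (length(iu) + length(it) > 0)
        message("stratum ", s, ": one arm empty (",
                length(iu), " untreated, ", length(it),
                " treated); no pairs")
      next
    }
    if (length(iu) <= length(it)) {
      idxA <- iu; idxB <- it; a_is_untreated <- TRUE
    } else {
      idxA <- it; idxB <- iu; a_is_untreated <- FALSE
    }
    members <- c(idxA, idxB)
    Zn <- normalize_covariates(Z[members, , drop = FALSE])
    D <- compute_distance_matrix(Zn[seq_along(idxA), , drop = FALSE],
                                 Zn[length(idxA) + seq_along(idxB), ,
                                    drop = FALSE])
    inst <- matching_instance(D, alpha, A_ids = x$ids[idxA],
                              B_ids = x$ids[idxB], stratum_index = s)
    sol <- tryCatch({
      if (inst$m <= alpha) solve_exact_one_to_one(inst)
      else if (variant == "equalized") solve_equalized_matching(inst)
      else solve_relaxed_matching(inst)
    }, error = function(e) stop("stratum ", s, ": ", conditionMessage(e),
                                call. = FALSE))
    oa <- idxA[sol$pairs[, "A"]]
    ob <- idxB[sol$pairs[, "B"]]
    su <- if (a_is_untreated) oa else ob
    st <- if (a_is_untreated) ob else oa
    rows_u <- c(rows_u, su)
    rows_t <- c(rows_t, st)
    pair_counts[s] <- nrow(sol$pairs)
    census[s, "untreated"] <- length(unique(su))
    census[s, "treated"] <- length(unique(st))
    prov[[length(prov) + 1L]] <-
      data.frame(stratum = s, untreated_id = x$ids[su],
                 treated_id = x$ids[st], formulation = sol$formulation)
  }
  if (!length(rows_u)) stop("no stratum produced any matched pairs")
  structure(list(untreated = cohort_rows(x, rows_u),
                 treated = cohort_rows(x, rows_t),
                 untreated_rows = rows_u, treated_rows = rows_t,
                 provenance = do.call(rbind, prov),
                 pair_counts = pair_counts,
                 census_matched = census,
                 variant = variant, alpha = alpha),
            class = "matched_cohorts")
}

#' @export
print.matched_cohorts <- function(x, ...) {
  cat("Matched cohorts (", if (!is.null(x$variant)) x$variant else "psm",
      "): ", n_patients(x$untreated), " untreated rows, ",
      n_patients(x$treated), " treated rows\n", sep = "")
  if (!is.null(x$pair_counts))
    cat("  pairs per stratum: ", paste(x$pair_counts, collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' Oversample matched cohorts
#'
#' Replicates every matched row exactly `factor` times, growing the
#' training multiset while leaving the distinct-patient census unchanged —
#' the matched structure is preserved, only the effective sample size for
#' the downstream Cox fit grows.
#'
#' @param matched a `matched_cohorts`.
#' @param factor positive integer replication factor (1 = identity;
#'   2 and 3 are the duplicate / triple settings).
#' @return a `matched_cohorts` with replicated rows.
#' @export
oversample <- function(matched, factor = 1L) {
  stopifnot(inherits(matched, "matched_cohorts"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("oversampling factor must be >= 1")
  if (factor == 1L) return(matched)
  rep_rows <- function(co) cohort_rows(co, rep(seq_len(n_patients(co)),
                                               times = factor))
  out <- matched
  out$untreated <- rep_rows(matched$untreated)
  out$treated <- rep_rows(matched$treated)
  out$oversample_factor <- factor
  out
}
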