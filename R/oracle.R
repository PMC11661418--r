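all_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}

#' Brute-force matching oracle
#'
#' Exhaustively enumerates every feasible binary selection of pairs for the
#' requested formulation and returns a global optimum. Intended purely as
#' an independent correctness check for the flow-based solvers on tiny
#' instances (`m * n_B <= 36`).
#'
#' @param inst a [matching_instance()].
#' @param formulation `"equalized"`, `"exact_one_to_one"` or `"relaxed"`.
#' @return a `match_solution` attaining the global minimum total distance.
#' @export
brute_force_matching <- function(inst,
                                 formulation = c("equalized",
                                                 "exact_one_to_one",
                                                 "relaxed")) {
  formulation <- match.arg(formulation)
  stopifnot(inherits(inst, "matching_instance"))
  m <- inst$m; n <- inst$n_B; D <- inst$D
  if (m * n > 36) stop("instance too large for enumeration (m*n > 36)")
  best <- Inf; best_pairs <- NULL
  consider <- function(pairs) {
    tot <- if (nrow(pairs)) sum(D[pairs]) else 0
    if (tot < best) {
      best <<- tot
      best_pairs <<- pairs
    }
  }
  if (formulation %in% c("equalized", "exact_one_to_one")) {
    # choose the matched rows, then every injective column assignment
    k <- if (formulation == "equalized") inst$alpha else m
    if (k > m || k > n) stop("infeasible: need ", k, " pairs")
    if (k == 0) {
      consider(matrix(integer(0), 0, 2))
    } else {
      row_sets <- utils::combn(m, k, simplify = FALSE)
      col_sets <- utils::combn(n, k, simplify = FALSE)
      for (rs in row_sets)
        for (cs in col_sets)
          for (p in all_permutations(cs))
            consider(cbind(rs, p))
    }
  } else {
    # relaxed: alpha distinct cells, each row and column used <= 2 times
    k <- inst$alpha
    if (2 * min(m, n) < k) stop("infeasible capacity for alpha = ", k)
    cells <- which(matrix(TRUE, m, n))
    rows <- ((cells - 1) %% m) + 1
    cols <- ((cells - 1) %/% m) + 1
    rc <- integer(m); cc <- integer(n)
    chosen <- integer(k)
    recurse <- function(start, depth) {
      if (depth == k) {
        consider(cbind(rows[chosen], cols[chosen]))
        return(invisible())
      }
      if (length(cells) - start + 1 < k - depth) return(invisible())
      for (idx in start:length(cells)) {
        r <- rows[idx]; cl <- cols[idx]
        if (rc[r] < 2 && cc[cl] < 2) {
          rc[r] <<- rc[r] + 1L; cc[cl] <<- cc[cl] + 1L
          chosen[depth + 1L] <<- idx
          recurse(idx + 1L, depth + 1L)
          rc[r] <<- rc[r] - 1L; cc[cl] <<- cc[cl] - 1L
        }
      }
      invisible()
    }
    if (k == 0) consider(matrix(integer(0), 0, 2)) else recurse(1L, 0L)
  }
  if (is.null(best_pairs)) stop("no feasible selection found")
  new_match_solution(inst, best_pairs, formulation)
}
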