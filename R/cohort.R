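#' Define a covariate schema
#'
#' A schema names each prognostic covariate and declares how it is handled:
#' `"continuous"` columns stay numeric, `"binary"` columns must be coded
#' 0/1, and `"categorical"` columns carry an ordered set of category labels
#' used for deterministic one-hot encoding (first category is the dropped
#' reference level).
#'
#' @param names character vector of unique covariate names.
#' @param kinds character vector, one of `"continuous"`, `"binary"`,
#'   `"categorical"` per covariate.
#' @param categories named list mapping each categorical covariate to its
#'   ordered category labels (>= 2 each).
#' @return An object of class `covariate_schema`.
#' @examples
#' covariate_schema(c("age", "kras", "side"),
#'                  c("continuous", "binary", "categorical"),
#'                  categories = list(side = c("right", "left", "rectal")))
#' @export
covariate_schema <- function(names, kinds, categories = list()) {
  kinds <- match.arg(kinds, c("continuous", "binary", "categorical"),
                     several.ok = TRUE)
  if (length(kinds) == 1L) kinds <- rep(kinds, length(names))
  stopifnot(length(names) == length(kinds))
  if (anyDuplicated(names))
    stop("covariate names must be unique")
  for (nm in names[kinds == "categorical"]) {
    if (is.null(categories[[nm]]) || length(categories[[nm]]) < 2L)
      stop("categorical covariate '", nm, "' needs >= 2 category labels")
  }
  structure(list(names = as.character(names), kinds = kinds,
                 categories = categories),
            class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema (", length(x$names), " covariates)\n", sep = "")
  for (i in seq_along(x$names)) {
    extra <- if (x$kinds[i] == "categorical")
      paste0(" [", paste(x$categories[[x$names[i]]], collapse = ", "), "]")
    else ""
    cat("  ", x$names[i], ": ", x$kinds[i], extra, "\n", sep = "")
  }
  invisible(x)
}

new_cohort <- function(ids, X, a, t, y, schema, time_unit = "months") {
  n <- length(ids)
  stopifnot(nrow(X) == n, length(a) == n, length(t) == n, length(y) == n)
  if (anyNA(a) || anyNA(t) || anyNA(y))
    stop("treatment, time and event vectors must be complete")
  if (!all(a %in% c(0, 1))) stop("treatment must be coded 0/1")
  if (!all(y %in% c(0, 1))) stop("event indicator must be coded 0/1")
  if (any(t < 0)) stop("times must be nonnegative")
  rownames(X) <- NULL
  structure(list(ids = ids, X = X, a = as.integer(a), t = as.numeric(t),
                 y = as.integer(y), schema = schema, time_unit = time_unit),
            class = "cohort")
}

#' Assemble a cohort from in-memory vectors
#'
#' @param X data.frame of raw covariates, columns matching `schema`.
#' @param a binary treatment vector (1 = treated).
#' @param t nonnegative time to event or censoring.
#' @param y event indicator (1 = event observed).
#' @param schema a [covariate_schema()].
#' @param ids optional patient identifiers (default `1:n`).
#' @param time_unit `"months"` (default) or `"years"`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(X, a, t, y, schema, ids = NULL,
                   time_unit = c("months", "years")) {
  time_unit <- match.arg(time_unit)
  missing_cols <- setdiff(schema$names, names(X))
  if (length(missing_cols))
    stop("covariates missing from X: ", paste(missing_cols, collapse = ", "))
  if (is.null(ids)) ids <- seq_len(nrow(X))
  new_cohort(ids, X[, schema$names, drop = FALSE], a, t, y, schema, time_unit)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort: ", length(x$ids), " patients, ", length(x$schema$names),
      " covariates (", x$time_unit, ")\n", sep = "")
  cat("  treated ", sum(x$a == 1), " / untreated ", sum(x$a == 0),
      "; events ", sum(x$y), "\n", sep = "")
  nmiss <- sum(is.na(x$X))
  if (nmiss) cat("  missing covariate cells: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' Number of patients in a cohort
#' @param x a `cohort`.
#' @return integer patient count.
#' @export
n_patients <- function(x) length(x$ids)

#' Subset a cohort by row index
#'
#' Indices may repeat: matched cohorts under relaxed matching and
#' oversampled training sets are row multisets of the original cohort.
#'
#' @param x a `cohort`; @param i integer row indices.
#' @return a `cohort` with rows `i` (ids preserved, so provenance survives).
#' @export
cohort_rows <- function(x, i) {
  new_cohort(x$ids[i], x$X[i, , drop = FALSE], x$a[i], x$t[i], x$y[i],
             x$schema, x$time_unit)
}

#' Read a patient cohort from CSV
#'
#' Rows missing treatment, time or event are excluded (these fields are not
#' imputable); covariate missingness is preserved for [impute_missing()].
#' The drop count is reported on stderr.
#'
#' @param path CSV file with a header row.
#' @param schema a [covariate_schema()].
#' @param columns named list with entries `treatment`, `time`, `event` and
#'   optionally `id`, giving the CSV column names.
#' @param time_unit `"months"` (default) or `"years"`.
#' @return A `cohort`.
#' @export
read_cohort <- function(path, schema, columns, time_unit = c("months", "years")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(unlist(columns[c("treatment", "time", "event")]), schema$names)
  unknown <- setdiff(need, names(df))
  if (length(unknown))
    stop("columns not found in ", path, ": ", paste(unknown, collapse = ", "))
  a <- df[[columns$treatment]]
  t <- df[[columns$time]]
  y <- df[[columns$event]]
  keep <- !(is.na(a) | is.na(t) | is.na(y))
  if (any(!keep))
    message("read_cohort: dropped ", sum(!keep),
            " row(s) with missing treatment/time/event")
  a <- a[keep]; t <- t[keep]; y <- y[keep]
  if (!all(a %in% c(0, 1)))
    stop("treatment column must be coded 0/1; found values ",
         paste(sort(unique(a)), collapse = ", "))
  ids <- if (!is.null(columns$id)) df[[columns$id]][keep] else which(keep)
  cohort(df[keep, , drop = FALSE], a, t, y, schema, ids = ids,
         time_unit = time_unit)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()] on complete data. Optional provenance columns
#' (stratum, multiplicity) may be appended by the caller beforehand.
#'
#' @param x a `cohort`; @param path output file; @param columns as in
#'   [read_cohort()] (defaults `id`, `treatment`, `time`, `event`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path,
                         columns = list(id = "id", treatment = "treatment",
                                        time = "time", event = "event")) {
  df <- x$X
  df[[columns$id]] <- x$ids
  df[[columns$treatment]] <- x$a
  df[[columns$time]] <- x$t
  df[[columns$event]] <- x$y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Single imputation of missing covariates
#'
#' Continuous covariates are imputed with the column median, binary and
#' categorical covariates with the mode (ties broken toward the first
#' category in schema order). The imputation mask is attached as attribute
#' `"imputed"`. Idempotent.
#'
#' @param x a `cohort` (treatment/time/event already complete by
#'   construction).
#' @return A complete `cohort`.
#' @export
impute_missing <- function(x) {
  stopifnot(inherits(x, "cohort"))
  mask <- is.na(x$X)
  if (!any(mask)) {
    attr(x, "imputed") <- mask
    return(x)
  }
  for (j in seq_along(x$schema$names)) {
    nm <- x$schema$names[j]
    col <- x$X[[nm]]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss))
      stop("covariate '", nm, "' is entirely missing; cannot impute")
    if (x$schema$kinds[j] == "continuous") {
      fill <- stats::median(col[!miss])
    } else {
      lev <- if (x$schema$kinds[j] == "categorical")
        x$schema$categories[[nm]] else sort(unique(col[!miss]))
      counts <- table(factor(col[!miss], levels = lev))
      fill <- lev[which.max(counts)]
      if (is.numeric(col)) fill <- as.numeric(fill)
    }
    col[miss] <- fill
    x$X[[nm]] <- col
  }
  message("impute_missing: filled ", sum(mask), " covariate cell(s)")
  attr(x, "imputed") <- mask
  x
}

#' Split a cohort by treatment arm
#'
#' @param x a `cohort`.
#' @return list with elements `untreated` and `treated`, order preserved
#'   within each part.
#' @export
split_by_treatment <- function(x) {
  list(untreated = cohort_rows(x, which(x$a == 0)),
       treated = cohort_rows(x, which(x$a == 1)))
}

#' One-hot encode a cohort's covariates
#'
#' Continuous and binary columns pass through; each categorical column
#' becomes indicator columns for its non-reference categories
#' (`name.category`), reference = first category in schema order. Encoding
#' is deterministic given the schema regardless of which categories are
#' present in the data.
#'
#' @param x a complete `cohort`.
#' @return numeric matrix Z (n x K) with column names; attribute
#'   `"schema"` carries the schema.
#' @export
encode_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (anyNA(x$X)) stop("cohort has missing covariates; run impute_missing()")
  cols <- list()
  for (j in seq_along(x$schema$names)) {
    nm <- x$schema$names[j]
    if (x$schema$kinds[j] == "categorical") {
      lev <- x$schema$categories[[nm]]
      f <- factor(x$X[[nm]], levels = lev)
      if (anyNA(f))
        stop("covariate '", nm, "' has values outside its declared categories")
      for (l in lev[-1L])
        cols[[paste0(nm, ".", l)]] <- as.numeric(f == l)
    } else {
      v <- as.numeric(x$X[[nm]])
      if (any(!is.finite(v)))
        stop("covariate '", nm, "' has non-finite values")
      cols[[nm]] <- v
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- NULL
  attr(Z, "schema") <- x$schema
  Z
}

#' Standardized mean differences between two groups
#'
#' Effect-size balance diagnostic: for each encoded covariate column,
#' `SMD = (mean_A - mean_B) / pooled SD` with the pooled SD computed from
#' the two sample SDs. A column constant in both groups has SMD 0 when the
#' means agree and `Inf` (with sign) otherwise.
#'
#' @param groupA,groupB encoded covariate matrices (from [encode_cohort()])
#'   with identical columns.
#' @return named numeric vector of SMDs (sign: A minus B).
#' @export
standardized_mean_differences <- function(groupA, groupB) {
  if (!identical(colnames(groupA), colnames(groupB)))
    stop("groups must share the same encoded columns")
  mA <- colMeans(groupA); mB <- colMeans(groupB)
  vA <- apply(groupA, 2, stats::var)
  vB <- apply(groupB, 2, stats::var)
  pooled <- sqrt((vA + vB) / 2)
  d <- mA - mB
  smd <- ifelse(pooled > 0, d / pooled,
                ifelse(abs(d) < .Machine$double.eps^0.5, 0, sign(d) * Inf))
  names(smd) <- colnames(groupA)
  smd
}
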