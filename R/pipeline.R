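#' Run the full comparison pipeline and write report files
#'
#' End-to-end orchestration: load a CSV cohort (or generate a synthetic
#' one), impute, build the model suite, and write (i) training-cohort
#' sizes, (ii) the in-sample metric table, (iii) the bias-corrected
#' bootstrap table with percentile intervals, (iv) the stratum census
#' before and after matching, and (v) the matched cohorts with provenance
#' columns. Tables are written as TSV plus a combined JSON; a single seed
#' governs all randomness.
#'
#' @param config named list. Either `input` (list: `path`, `schema`,
#'   `columns`, optional `time_unit`) or `synthetic` (arguments for
#'   [generator_config()]); plus optional `variant`, `oversample_factor`,
#'   `psm_method`, `caliper`, `horizon`, `S`, `cutoff`, `B`. May also be
#'   the path of a YAML file holding that list (schemas as
#'   name/kind/categories records).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, a list with the suite, both tables and the file
#'   paths written.
#' @export
run_comparison <- function(config, out_dir, seed = 1) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  if (!xor(is.null(config$input), is.null(config$synthetic)))
    stop("config must supply exactly one of 'input' or 'synthetic'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  say <- function(stage) message(sprintf("[%7.1fs] %s",
                                         proc.time()[["elapsed"]] - t0, stage))
  if (!is.null(config$synthetic)) {
    say("generating synthetic cohort")
    gen <- generate_cohort(do.call(generator_config, config$synthetic),
                           seed = seed)
    co <- gen$cohort
  } else {
    say(paste("reading", config$input$path))
    co <- read_cohort(config$input$path, config$input$schema,
                      config$input$columns,
                      time_unit = config$input$time_unit %||% "months")
  }
  co <- impute_missing(co)
  say("building model suite")
  set.seed(seed)  # rf propensity and any downstream randomness
  suite <- build_model_suite(
    co,
    variant = config$variant %||% "equalized",
    oversample_factor = config$oversample_factor %||% 1,
    psm_method = config$psm_method %||% "glm",
    caliper = config$caliper %||% 0.2,
    horizon = config$horizon %||% 60,
    S = config$S %||% 10,
    cutoff = config$cutoff %||% 20)
  say("in-sample metrics")
  insample <- in_sample_table(suite)
  say("bootstrap validation")
  boot <- bootstrap_table(suite, B = config$B %||% 100, seed = seed)
  say("writing outputs")
  paths <- list(
    sizes = file.path(out_dir, "cohort_sizes.tsv"),
    insample = file.path(out_dir, "in_sample_metrics.tsv"),
    bootstrap = file.path(out_dir, "bootstrap_metrics.tsv"),
    census = file.path(out_dir, "stratum_census.tsv"),
    matched_untreated = file.path(out_dir, "matched_untreated.csv"),
    matched_treated = file.path(out_dir, "matched_treated.csv"),
    json = file.path(out_dir, "report.json"))
  utils::write.table(data.frame(model = names(suite$sizes),
                                n = unname(suite$sizes)),
                     paths$sizes, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(insample, paths$insample, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(boot, paths$bootstrap, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  census <- data.frame(stratum = seq_len(suite$assignment$S),
                       before_untreated = suite$assignment$census[, 1],
                       before_treated = suite$assignment$census[, 2],
                       after_untreated = suite$matched$census_matched[, 1],
                       after_treated = suite$matched$census_matched[, 2])
  utils::write.table(census, paths$census, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_matched <- function(part, rows, path) {
    df <- part$X
    df$id <- part$ids
    df$treatment <- part$a; df$time <- part$t; df$event <- part$y
    df$stratum <- suite$assignment$stratum[rows]
    mult <- ave(rep(1L, length(rows)), rows, FUN = sum)
    df$multiplicity <- mult
    utils::write.csv(df, path, row.names = FALSE)
  }
  write_matched(suite$matched$untreated, suite$matched$untreated_rows,
                paths$matched_untreated)
  write_matched(suite$matched$treated, suite$matched$treated_rows,
                paths$matched_treated)
  jsonlite::write_json(list(sizes = as.list(suite$sizes),
                            in_sample = insample, bootstrap = boot,
                            census = census, seed = seed),
                       paths$json, auto_unbox = TRUE, digits = NA)
  say("done")
  invisible(list(suite = suite, in_sample = insample, bootstrap = boot,
                 census = census, paths = paths))
}

read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$input) && !is.null(cfg$input$schema)) {
    sc <- cfg$input$schema
    cats <- list()
    for (e in sc) if (!is.null(e$categories))
      cats[[e$name]] <- as.character(e$categories)
    cfg$input$schema <- covariate_schema(
      vapply(sc, `[[`, character(1), "name"),
      vapply(sc, `[[`, character(1), "kind"),
      cats)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
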