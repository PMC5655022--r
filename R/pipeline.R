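## Pipeline orchestration ---------------------------------------------------
##
## One call runs: simulate (or load) a cohort -> extract features -> score
## questionnaires -> build difference datasets per (game, area) -> evaluate
## the model suite with repeated stratified CV -> rank progress indicators.
## Results are written as CSV/TSV mirroring the published table shapes
## (percent, two decimals), plus a provenance JSON sufficient to reproduce
## every output.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()] to simulate, or a directory written by
#'   [write_cohort()].
#' @param games,areas Subsets to analyse (defaults: all).
#' @param models Model names to evaluate (defaults: all eight).
#' @param variant Preprocessing variant: `"raw"`, `"raw_pca"`, `"norm"`,
#'   `"norm_pca"`.
#' @param mode Session pairing: `"first_last"` or `"consecutive"`.
#' @param folds,repetitions CV settings.
#' @param top_k Indicators admitted per ranking criterion.
#' @param extraction An [extraction_config()].
#' @param seed Master seed for CV partitioning and model fits.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(), games = GAME_IDS,
                            areas = AREAS, models = MODEL_NAMES,
                            variant = "norm", mode = "first_last",
                            folds = 10L, repetitions = 10L, top_k = 5L,
                            extraction = extraction_config(), seed = 1L) {
  variant <- match.arg(variant, c("raw", "raw_pca", "norm", "norm_pca"))
  mode <- match.arg(mode, c("first_last", "consecutive"))
  models <- vapply(models, function(m) match.arg(m, MODEL_NAMES),
                   character(1))
  structure(list(cohort = cohort, games = games, areas = areas,
                 models = unname(models), variant = variant, mode = mode,
                 folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 top_k = as.integer(top_k), extraction = extraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full recognition pipeline
#'
#' @param config A [pipeline_config()].
#' @param out Optional output directory; when given, writes `results.csv`
#'   (per game/area/model CV rows), `indicators.tsv`, `relevance.tsv` and
#'   `provenance.json`.
#' @param quiet Suppress per-stage progress on stderr.
#' @return List with `results` (data frame), `relevance`, `indicators`,
#'   `features`, `scores`.
#' @export
run_pipeline <- function(config, out = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("[%s] %.1fs", name, proc.time()[3] - t0)
    r
  }
  cohort <- stage("cohort", {
    if (inherits(config$cohort, "cohort_config"))
      simulate_cohort(config$cohort)
    else read_cohort(config$cohort)
  })
  features <- stage("extract",
                    extract_cohort_features(cohort$sessions,
                                            config$extraction))
  scores <- stage("label", cohort_area_scores(cohort$sessions))
  results <- list()
  relevance <- list()
  for (g in config$games) {
    for (a in config$areas) {
      diff <- tryCatch(build_diff_samples(features, scores, g, a,
                                          config$mode),
                       error = function(e) NULL)
      if (is.null(diff) || nlevels(droplevels(diff$label)) < 2) next
      rel_diff <- if (config$mode == "consecutive") diff else
        tryCatch(build_diff_samples(features, scores, g, a, "consecutive"),
                 error = function(e) diff)
      relevance[[paste(g, a)]] <- relevance_records(rel_diff)
      for (m in config$models) {
        cv <- repeated_stratified_cv(
          model_spec(m, seed = config$seed), diff$x, diff$label,
          folds = config$folds, repetitions = config$repetitions,
          seed = config$seed, variant = config$variant)
        mt <- cv$metrics
        results[[length(results) + 1L]] <- data.frame(
          game = g, area = a, method = m, n = cv$n,
          accuracy = round(100 * cv$mean_accuracy, 2),
          ci = round(100 * cv$ci_halfwidth, 2),
          precision_p = round(100 * mt$progress[["precision"]], 2),
          recall_p = round(100 * mt$progress[["recall"]], 2),
          f_p = round(100 * mt$progress[["f"]], 2),
          precision_n = round(100 * mt$no_progress[["precision"]], 2),
          recall_n = round(100 * mt$no_progress[["recall"]], 2),
          f_n = round(100 * mt$no_progress[["f"]], 2),
          variant = config$variant, mode = config$mode,
          stringsAsFactors = FALSE)
      }
      say("[train] %s/%s done", g, a)
    }
  }
  results <- if (length(results)) do.call(rbind, results) else
    data.frame()
  relevance <- if (length(relevance)) do.call(rbind, relevance) else
    data.frame()
  rownames(relevance) <- NULL
  indicators <- if (nrow(relevance))
    rank_indicators(relevance, config$top_k) else data.frame()
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out, "results.csv"),
                     row.names = FALSE)
    utils::write.table(relevance, file.path(out, "relevance.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(indicators, file.path(out, "indicators.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    prov <- list(package_version =
                   as.character(utils::packageVersion("playprogress")),
                 seed = config$seed, variant = config$variant,
                 mode = config$mode, folds = config$folds,
                 repetitions = config$repetitions,
                 models = config$models, games = config$games,
                 areas = config$areas,
                 cohort = if (inherits(config$cohort, "cohort_config"))
                   unclass(config$cohort)[setdiff(names(config$cohort),
                                                  "effect_map")]
                 else config$cohort)
    jsonlite::write_json(prov, file.path(out, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(results = results, relevance = relevance, indicators = indicators,
       features = features, scores = scores)
}
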