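# Orchestration: a declarative run configuration tying the stages
# simulate -> features -> stats -> predict together, with artifact files
# and a reproducibility manifest.

#' Build a run configuration
#'
#' @param stages ordered subset of `c("simulate", "features", "stats",
#'   "predict")`
#' @param out_dir output directory for artifacts
#' @param seed master seed
#' @param synth a [synth_config()] (for the simulate stage)
#' @param features a [feature_options()]
#' @param min_duration_s minimum clean-signal rule applied before feature
#'   extraction (seconds)
#' @param n_perm permutations for the group statistics
#' @param target,models,grid,repeats,outer_k,inner_k prediction settings
#'   (see [run_two_layer_cv()])
#' @param write_raw_data also persist the raw per-subject signals
#' @return object of class `run_config`
#' @export
run_config <- function(stages = c("simulate", "features", "stats", "predict"),
                       out_dir = tempfile("resteeg_run_"),
                       seed = 1,
                       synth = synth_config(seed = seed),
                       features = feature_options(),
                       min_duration_s = 0,
                       n_perm = 10000,
                       target = "group",
                       models = "logistic_l1",
                       grid = model_grid(),
                       repeats = 10, outer_k = 10, inner_k = 10,
                       write_raw_data = FALSE) {
  known <- c("simulate", "features", "stats", "predict")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  structure(list(stages = stages, out_dir = out_dir, seed = seed,
                 synth = synth, features = features,
                 min_duration_s = min_duration_s, n_perm = n_perm,
                 target = target, models = models, grid = grid,
                 repeats = repeats, outer_k = outer_k, inner_k = inner_k,
                 write_raw_data = write_raw_data),
            class = "run_config")
}

#' Execute a pipeline run
#'
#' Runs the configured stages in order, writing each stage's artifact to
#' the run directory together with a manifest (configuration hash, package
#' and R versions, per-stage wall time). Identical configurations and
#' seeds give identical artifacts.
#'
#' @param config a [run_config()]
#' @param cohort optional pre-built `synth_cohort` (skips the simulate
#'   stage's generation)
#' @param quiet suppress progress messages
#' @return list with `cohort`, `features` ([feature_table()]),
#'   `age_screen`, `stats`, `cv` and `manifest`
#' @export
run_pipeline <- function(config, cohort = NULL, quiet = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timing <- list()
  res <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say("stage %-9s done in %.1f s", stage, timing[[stage]])
    v
  }
  if ("simulate" %in% config$stages) {
    res$cohort <- clock("simulate", {
      ch <- cohort %||% generate_cohort(config$synth,
                                        return_recordings = FALSE)
      write_cohort(ch, file.path(config$out_dir, "cohort"),
                   write_data = config$write_raw_data)
      ch
    })
  } else {
    if (is.null(cohort)) stop("later stages need a cohort")
    res$cohort <- cohort
  }
  if ("features" %in% config$stages) {
    res$features <- clock("features", {
      ft <- extract_cohort_features(res$cohort, config$features,
                                    min_duration_s = config$min_duration_s,
                                    progress = !quiet)
      write_feature_table(ft, file.path(config$out_dir, "features.tsv"))
      ft
    })
    res$age_screen <- clock("age_screen", {
      sc <- age_screen(res$features)
      jsonlite::write_json(
        list(per_type = sc$per_type,
             n_flagged_columns = length(sc$flagged_columns)),
        file.path(config$out_dir, "age_screen.json"),
        auto_unbox = TRUE, digits = NA)
      sc
    })
    res$features <- detrend_age(res$features, res$age_screen)
  }
  if ("stats" %in% config$stages) {
    res$stats <- clock("stats", {
      st <- group_stats(res$features, n_perm = config$n_perm,
                        seed = config$seed)
      jsonlite::write_json(st$per_type,
                           file.path(config$out_dir, "group_stats.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.table(st$per_feature,
                         file.path(config$out_dir, "group_stats.tsv"),
                         sep = "\t", quote = FALSE)
      st
    })
  }
  if ("predict" %in% config$stages) {
    res$cv <- clock("predict", {
      cv <- run_two_layer_cv(res$features, target = config$target,
                             models = config$models, grid = config$grid,
                             repeats = config$repeats,
                             outer_k = config$outer_k,
                             inner_k = config$inner_k, seed = config$seed)
      jsonlite::write_json(cv$summary,
                           file.path(config$out_dir, "cv_report.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.table(cv$folds[, setdiff(names(cv$folds), "selected")],
                         file.path(config$out_dir, "cv_folds.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      cv
    })
  }
  cfg_json <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                               auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(
    config_hash = fnv1a32(as.character(cfg_json)),
    seed = config$seed,
    stages = config$stages,
    timing_s = timing,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("resteeg")),
    artifacts = list.files(config$out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
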