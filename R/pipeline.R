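# End-to-end orchestration: simulate -> extract -> filter-icc -> select ->
# wavelet -> evaluate -> report, with one global seed fanned out
# deterministically to the stages and a checksummed artifact manifest.

#' Pipeline configuration
#'
#' Collects every stage's parameters and a single global seed. Stage seeds
#' are derived deterministically from the global seed and the stage name,
#' so one number reproduces the whole run.
#'
#' @param out_dir Output directory for stage artifacts.
#' @param cohort A [cohort_config()] (its `seed` is overridden by the
#'   derived stage seed).
#' @param bin_width Gray-level bin width for extraction (default 64).
#' @param target_spacing Isotropic resampling target, mm (default 1).
#' @param icc_threshold Reliability cutoff (default 0.75).
#' @param lasso_folds CV folds for selection (default 10).
#' @param banks Filter banks to profile (default all 31).
#' @param classifiers Specs for evaluation (default all 8 families).
#' @param folds,repeats Repeated-CV design for evaluation.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("wavemics_run_"),
                            cohort = cohort_config(),
                            bin_width = 64,
                            target_spacing = 1,
                            icc_threshold = 0.75,
                            lasso_folds = 10,
                            banks = filter_banks(),
                            classifiers = default_classifiers(),
                            folds = 5,
                            repeats = 100,
                            seed = 1) {
  bad <- setdiff(banks, filter_banks())
  if (length(bad)) {
    abort(sprintf("unknown filter bank(s): %s; valid banks: %s",
                  paste(bad, collapse = ", "),
                  paste(filter_banks(), collapse = ", ")))
  }
  structure(list(out_dir = out_dir, cohort = cohort, bin_width = bin_width,
                 target_spacing = target_spacing,
                 icc_threshold = icc_threshold, lasso_folds = lasso_folds,
                 banks = banks, classifiers = classifiers, folds = folds,
                 repeats = repeats, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order on a synthetic cohort, writing each stage's
#' artifact (CSV/JSON) under `config$out_dir` and returning everything
#' in-memory as well. A manifest lists every artifact with its MD5 checksum
#' and the seed that produced it.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage messages.
#' @return A list of class `wavemics_run`: `cohort`, `icc`, `selection`,
#'   `selected_table`, `profiles`, `grid`, `comparison` (per metric),
#'   `best`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  artifacts <- character(0)
  t_all <- Sys.time()

  stage_seed <- function(stage) derive_seed(config$seed, stage)

  say("[simulate] generating cohort (n = %d)", config$cohort$n_patients)
  cc <- config$cohort
  cc$seed <- stage_seed("simulate")
  cohort <- generate_cohort(cc)

  say("[filter-icc] extracting repeated segmentations and computing ICC")
  rel <- reliability_filter_cohort(cohort, threshold = config$icc_threshold,
                                   bin_width = config$bin_width,
                                   target_spacing = config$target_spacing,
                                   resample = FALSE)
  icc_path <- file.path(config$out_dir, "icc.csv")
  readr::write_csv(rel$icc, icc_path)
  artifacts <- c(artifacts, icc_path)
  say("[filter-icc] %d / %d features kept", length(rel$kept),
      nrow(rel$icc))

  say("[select] z-score + LASSO (10-fold CV)")
  z <- zscore_fit(rel$table)
  ztbl <- zscore_apply(z, rel$table)
  sel <- lasso_select(ztbl, folds = config$lasso_folds,
                      seed = stage_seed("select"), min_features = 4)
  selected <- assemble_rows(ztbl, sel$features)
  sel_path <- file.path(config$out_dir, "selection.json")
  jsonlite::write_json(list(lambda = sel$lambda, features = sel$features,
                            coefficients = as.list(sel$coefficients),
                            seed = stage_seed("select")),
                       sel_path, auto_unbox = TRUE, digits = NA)
  tbl_path <- file.path(config$out_dir, "selected_features.csv")
  write_feature_table(selected, tbl_path)
  artifacts <- c(artifacts, sel_path, tbl_path)
  say("[select] %d features at lambda = %.4g", length(sel$features),
      sel$lambda)

  say("[wavelet] building %d profile tables", length(config$banks))
  profiles <- build_all_profiles(selected, config$banks)
  for (b in names(profiles)) {
    p <- file.path(config$out_dir, sprintf("profile_%s.csv", b))
    write_feature_table(profiles[[b]], p)
    artifacts <- c(artifacts, p)
  }

  say("[evaluate] %d banks x %d classifiers, %d x %d-fold CV",
      length(config$banks), length(config$classifiers), config$repeats,
      config$folds)
  grid <- evaluate_grid(selected, profiles, config$classifiers,
                        folds = config$folds, repeats = config$repeats,
                        seed = stage_seed("evaluate"))
  for (m in c("accuracy", "auc", "f1")) {
    p <- file.path(config$out_dir, sprintf("grid_%s.csv", m))
    readr::write_csv(grid_metric_table(grid, m), p)
    artifacts <- c(artifacts, p)
  }

  say("[report] comparisons and best model")
  comparison <- lapply(c(auc = "auc", accuracy = "accuracy", f1 = "f1"),
                       function(m) comparison_table(grid, m))
  best <- select_best(grid)
  rep_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(
    list(best = as.list(best),
         comparison = comparison,
         seed = config$seed),
    rep_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  artifacts <- c(artifacts, rep_path)

  manifest <- tibble::tibble(
    artifact = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    seed = config$seed
  )
  readr::write_csv(manifest, file.path(config$out_dir, "manifest.csv"))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  structure(list(cohort = cohort, icc = rel$icc, selection = sel,
                 selected_table = selected, profiles = profiles, grid = grid,
                 comparison = comparison, best = best, manifest = manifest,
                 config = config),
            class = "wavemics_run")
}

#' @export
print.wavemics_run <- function(x, ...) {
  cat("<wavemics_run>\n")
  cat(sprintf("  cohort: %d patients (%s)\n", nrow(x$cohort),
              paste(sprintf("%s=%d", names(table(x$cohort$label)),
                            table(x$cohort$label)), collapse = ", ")))
  cat(sprintf("  kept after ICC: %d features; selected: %d\n",
              sum(x$icc$kept), length(x$selection$features)))
  cat(sprintf("  grid: %d cells; best: %s + %s (AUC %.3f)\n",
              nrow(x$grid), x$best$bank, x$best$classifier, x$best$auc))
  invisible(x)
}
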