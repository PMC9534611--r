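# Repeated stratified cross-validation of the classifier families, the
# bank x classifier evaluation grid, best-cell selection, the DeLong test
# and the percent-increase comparison rows.

# Rank-based (Mann-Whitney) AUC of scores for the positive class.
auc_score <- function(scores, y) {
  pos <- y == positive_class()
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

f1_score <- function(scores, y, threshold = 0.5) {
  pos <- positive_class()
  pred <- scores >= threshold
  truth <- y == pos
  tp <- sum(pred & truth)
  if (tp == 0) return(0)
  prec <- tp / sum(pred)
  rec <- tp / sum(truth)
  2 * prec * rec / (prec + rec)
}

stratified_folds <- function(y, folds) {
  id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

scale_matrix <- function(X, center, scale) {
  keep <- scale > 0 & is.finite(scale)
  sweep(sweep(X[, keep, drop = FALSE], 2, center[keep]), 2, scale[keep], `/`)
}

#' Repeated stratified k-fold cross-validation of one classifier
#'
#' For every repeat a fresh stratified fold assignment is drawn (repeat `r`
#' uses seed `seed + r - 1`); within each fold, features are z-scored with
#' training-part statistics only, the model is trained, and accuracy, AUC
#' and F1 (positive class GBM) are measured on the held-out part. Means are
#' taken over all repeats x folds. The out-of-fold scores of the first
#' repeat are pooled and retained for pairwise ROC testing.
#'
#' @param tbl Feature table with `label` and numeric feature columns.
#' @param spec A [classifier_spec()].
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 100).
#' @param seed Base seed.
#' @return An object of class `wavemics_eval`: `accuracy`, `auc`, `f1`
#'   (means), `per_fold` tibble, `scores` (first-repeat pooled out-of-fold
#'   scores) and `y`.
#' @export
repeated_cv <- function(tbl, spec, folds = 5, repeats = 100, seed = 1) {
  y <- droplevels(factor(tbl$label, levels = c("GBM", "MET")))
  if (nlevels(y) < 2) abort("`label` must contain both classes.")
  if (min(table(y)) < folds) {
    abort(sprintf("smallest class has fewer than %d members.", folds))
  }
  feats <- feature_columns(tbl)
  X <- as.matrix(tbl[, feats])
  if (any(!is.finite(X))) abort("feature matrix must be finite.")
  recs <- vector("list", repeats * folds)
  first_scores <- rep(NA_real_, nrow(X))
  rec_i <- 0L
  for (r in seq_len(repeats)) {
    with_seed(seed + r - 1L, {
      fid <- stratified_folds(y, folds)
      for (k in seq_len(folds)) {
        tr <- fid != k
        mu <- colMeans(X[tr, , drop = FALSE])
        sg <- apply(X[tr, , drop = FALSE], 2, sd)
        Xtr <- scale_matrix(X[tr, , drop = FALSE], mu, sg)
        Xte <- scale_matrix(X[!tr, , drop = FALSE], mu, sg)
        fit <- train_classifier(spec, Xtr, y[tr])
        sc <- score_classifier(fit, Xte)
        if (r == 1L) first_scores[!tr] <- sc
        rec_i <- rec_i + 1L
        recs[[rec_i]] <- c(r, k,
                           mean((sc >= 0.5) == (y[!tr] == positive_class())),
                           auc_score(sc, y[!tr]),
                           f1_score(sc, y[!tr]))
      }
    })
  }
  per_fold <- tibble::as_tibble(do.call(rbind, recs), .name_repair = "minimal")
  names(per_fold) <- c("repeat", "fold", "accuracy", "auc", "f1")
  structure(
    list(accuracy = mean(per_fold$accuracy),
         auc = mean(per_fold$auc, na.rm = TRUE),
         f1 = mean(per_fold$f1),
         per_fold = per_fold,
         scores = first_scores, y = y,
         family = spec$family, folds = folds, repeats = repeats,
         seed = seed),
    class = "wavemics_eval"
  )
}

#' @export
print.wavemics_eval <- function(x, ...) {
  cat(sprintf("<wavemics_eval> %s: accuracy %.3f, AUC %.3f, F1 %.3f (%d x %d-fold CV)\n",
              x$family, x$accuracy, x$auc, x$f1, x$repeats, x$folds))
  invisible(x)
}

#' @method tidy wavemics_eval
#' @export
tidy.wavemics_eval <- function(x, ...) x$per_fold

#' @method glance wavemics_eval
#' @export
glance.wavemics_eval <- function(x, ...) {
  tibble::tibble(family = x$family, accuracy = x$accuracy, auc = x$auc,
                 f1 = x$f1, folds = x$folds, repeats = x$repeats)
}

#' Evaluate the classifier grid over plain and wavelet features
#'
#' Runs [repeated_cv()] for every (filter bank, classifier) combination:
#' the plain selected-feature table occupies bank `"none"`, and each
#' profile table its bank id. With all 31 banks and 8 families this is the
#' full 248-cell wavelet grid plus the 8 plain cells.
#'
#' @param plain_tbl The assembled selected-feature table.
#' @param profiles Named list of profile tables from [build_all_profiles()]
#'   (may be a subset of banks).
#' @param specs Named list of [classifier_spec()]s (default all 8).
#' @inheritParams repeated_cv
#' @return A tibble of class `wavemics_eval_grid`: `bank`, `classifier`,
#'   `accuracy`, `auc`, `f1`, plus a `result` list column with the full
#'   [repeated_cv()] objects.
#' @export
evaluate_grid <- function(plain_tbl, profiles, specs = default_classifiers(),
                          folds = 5, repeats = 100, seed = 1) {
  tabs <- c(list(none = plain_tbl), profiles)
  ids <- plain_tbl$patient_id
  for (nm in names(profiles)) {
    if (!is.null(ids) && !identical(profiles[[nm]]$patient_id, ids)) {
      abort(sprintf("profile table '%s' rows are not aligned to the plain table.", nm))
    }
  }
  cells <- tidyr::expand_grid(bank = names(tabs), classifier = names(specs))
  results <- purrr::pmap(cells, function(bank, classifier) {
    repeated_cv(tabs[[bank]], specs[[classifier]], folds = folds,
                repeats = repeats,
                seed = derive_seed(seed, paste(bank, classifier)))
  })
  out <- dplyr::mutate(cells,
    accuracy = purrr::map_dbl(results, "accuracy"),
    auc = purrr::map_dbl(results, "auc"),
    f1 = purrr::map_dbl(results, "f1"),
    result = results
  )
  class(out) <- c("wavemics_eval_grid", class(out))
  out
}

#' Metric table of an evaluation grid
#'
#' One row per filter bank, one column per classifier — the layout of the
#' published per-metric comparison grids.
#'
#' @param grid A `wavemics_eval_grid`.
#' @param metric `"accuracy"`, `"auc"` or `"f1"`.
#' @param wavelet_only Drop the plain (`"none"`) row (default TRUE).
#' @return A tibble, banks in rows, classifiers in columns.
#' @export
grid_metric_table <- function(grid, metric = c("accuracy", "auc", "f1"),
                              wavelet_only = TRUE) {
  metric <- match.arg(metric)
  g <- grid[, c("bank", "classifier", metric)]
  if (wavelet_only) g <- g[g$bank != "none", ]
  tidyr::pivot_wider(g, names_from = "classifier", values_from = metric)
}

#' Select the best (bank, classifier) cell
#'
#' Argmax over the wavelet cells by mean AUC; ties broken by accuracy,
#' then F1, then lexicographically smaller bank id.
#'
#' @param grid A `wavemics_eval_grid`.
#' @return One-row tibble with the winning cell and its metrics.
#' @export
select_best <- function(grid) {
  g <- grid[grid$bank != "none", , drop = FALSE]
  if (!nrow(g)) g <- grid
  ord <- order(-g$auc, -g$accuracy, -g$f1, g$bank, g$classifier)
  g[ord[1], c("bank", "classifier", "accuracy", "auc", "f1")]
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the ROC curves of two score vectors for the same patients
#' (two-sided).
#'
#' @param scores1,scores2 Numeric score vectors for the same patients.
#' @param y Two-level factor (GBM/MET) of true labels.
#' @return List with `p_value`, `auc1`, `auc2`.
#' @export
delong_test <- function(scores1, scores2, y) {
  y <- factor(y, levels = c("GBM", "MET"))
  if (nlevels(droplevels(y)) < 2) abort("`y` must contain both classes.")
  if (any(!is.finite(scores1)) || any(!is.finite(scores2))) {
    abort("scores must be finite.")
  }
  r1 <- pROC::roc(response = y, predictor = scores1,
                  levels = c("MET", "GBM"), direction = "<", quiet = TRUE)
  r2 <- pROC::roc(response = y, predictor = scores2,
                  levels = c("MET", "GBM"), direction = "<", quiet = TRUE)
  if (identical(scores1, scores2)) {
    return(list(p_value = 1, auc1 = as.numeric(pROC::auc(r1)),
                auc2 = as.numeric(pROC::auc(r2))))
  }
  tst <- suppressWarnings(
    pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  )
  list(p_value = as.numeric(tst$p.value),
       auc1 = as.numeric(pROC::auc(r1)),
       auc2 = as.numeric(pROC::auc(r2)))
}

#' Percent increase of a wavelet metric over the plain metric
#'
#' `100 * (wavelet - plain) / plain`, rounded to one decimal.
#'
#' @param wavelet_metric,plain_metric Metric values; `plain_metric` must be
#'   positive.
#' @return Signed percent, one decimal.
#' @export
#' @examples
#' percent_increase(0.99, 0.88)   # +12.5
#' percent_increase(0.96, 0.55)   # +74.5
percent_increase <- function(wavelet_metric, plain_metric) {
  if (!is.finite(plain_metric) || plain_metric <= 0) {
    abort("`plain_metric` must be > 0.")
  }
  round(100 * (wavelet_metric - plain_metric) / plain_metric, 1)
}

#' Comparison rows: best wavelet cell vs plain model per classifier
#'
#' For each classifier family, finds its best filter bank by the chosen
#' metric, compares against the plain (no-wavelet) cell, computes the
#' percent increase, and (when first-repeat scores are available) the
#' DeLong p-value between the two models' pooled out-of-fold scores.
#'
#' @param grid A `wavemics_eval_grid` containing a `"none"` bank.
#' @param metric `"accuracy"`, `"auc"` or `"f1"`.
#' @param alpha Significance level for the flag (default 0.05).
#' @return A tibble with one row per classifier: best bank, both metric
#'   values, `pct_increase`, `p_value`, `significant`.
#' @export
comparison_table <- function(grid, metric = c("auc", "accuracy", "f1"),
                             alpha = 0.05) {
  metric <- match.arg(metric)
  plain <- grid[grid$bank == "none", ]
  wav <- grid[grid$bank != "none", ]
  if (!nrow(plain) || !nrow(wav)) {
    abort("grid must contain both plain ('none') and wavelet cells.")
  }
  purrr::map_dfr(unique(wav$classifier), function(cl) {
    wc <- wav[wav$classifier == cl, ]
    best <- wc[order(-wc[[metric]], wc$bank), ][1, ]
    pl <- plain[plain$classifier == cl, ]
    p_val <- NA_real_
    if (nrow(pl) == 1 && !is.null(best$result[[1]]$scores) &&
        !anyNA(best$result[[1]]$scores) && !anyNA(pl$result[[1]]$scores)) {
      p_val <- delong_test(best$result[[1]]$scores, pl$result[[1]]$scores,
                           best$result[[1]]$y)$p_value
    }
    tibble::tibble(
      classifier = cl,
      best_bank = best$bank,
      wavelet = best[[metric]],
      plain = pl[[metric]],
      pct_increase = percent_increase(best[[metric]], pl[[metric]]),
      p_value = p_val,
      significant = !is.na(p_val) & p_val < alpha
    )
  })
}
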