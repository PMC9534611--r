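# Z-score normalization with train-only statistics and L1-penalized
# logistic feature selection.

#' Fit / apply z-score normalization
#'
#' `zscore_fit()` learns per-feature means and standard deviations from
#' training rows only; zero-variance columns are flagged and dropped.
#' `zscore_apply()` standardizes any table with those training statistics,
#' so held-out rows never leak into the normalization.
#'
#' @param tbl A feature table tibble (identifier/label columns pass through).
#' @return `zscore_fit()`: an object of class `zscore_model`;
#'   `zscore_apply()`: the transformed tibble restricted to retained
#'   features.
#' @export
#' @examples
#' tbl <- generate_feature_table(feature_table_config(n_patients = 10, seed = 1))
#' z <- zscore_fit(tbl)
#' round(colMeans(zscore_apply(z, tbl)[, 3:5]), 10)
zscore_fit <- function(tbl) {
  feats <- feature_columns(tbl)
  if (nrow(tbl) < 2) abort("need at least 2 training rows.")
  mu <- vapply(feats, function(f) mean(tbl[[f]]), numeric(1))
  sigma <- vapply(feats, function(f) sd(tbl[[f]]), numeric(1))
  drop <- sigma == 0 | !is.finite(sigma)
  if (any(drop)) {
    warn(sprintf("dropping %d zero-variance feature(s).", sum(drop)))
  }
  structure(list(mean = mu[!drop], sd = sigma[!drop],
                 features = feats[!drop], dropped = feats[drop]),
            class = "zscore_model")
}

#' @rdname zscore_fit
#' @param model A `zscore_model` from [zscore_fit()].
#' @export
zscore_apply <- function(model, tbl) {
  stopifnot(inherits(model, "zscore_model"))
  keep <- intersect(c("patient_id", "label"), names(tbl))
  out <- tbl[, keep, drop = FALSE]
  scaled <- lapply(setNames(model$features, model$features), function(f) {
    (tbl[[f]] - model$mean[[f]]) / model$sd[[f]]
  })
  dplyr::bind_cols(out, tibble::as_tibble(scaled))
}

#' LASSO logistic feature selection with stratified 10-fold CV
#'
#' Fits an L1-penalized logistic regression over a penalty grid, picks the
#' penalty minimizing the mean cross-validated binomial deviance
#' (stratified folds), and returns the features with nonzero coefficients
#' at that penalty, in input column order.
#'
#' @param tbl A normalized feature table with a binary `label` column.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param min_features If the deviance-minimizing penalty selects fewer
#'   features than this, the penalty is relaxed along the glmnet path until
#'   at least this many are selected (default 1; the wavelet stage needs 4).
#' @return An object of class `wavemics_selection`: `lambda`, `features`,
#'   `coefficients`, and the `cv` object.
#' @export
lasso_select <- function(tbl, folds = 10, seed = 1, min_features = 1) {
  feats <- feature_columns(tbl)
  y <- tbl$label
  if (length(unique(y)) < 2) abort("`label` must contain both classes.")
  yb <- as.integer(y == levels(factor(y))[1])
  if (min(table(yb)) < folds) {
    abort("each class needs at least `folds` patients for stratified CV.")
  }
  X <- as.matrix(tbl[, feats])
  foldid <- with_seed(seed, {
    id <- integer(length(yb))
    for (cl in unique(yb)) {
      idx <- which(yb == cl)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    id
  })
  cv <- glmnet::cv.glmnet(X, yb, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = FALSE)
  pick_lambda <- cv$lambda.min
  nonzero_at <- function(lam) {
    cf <- as.matrix(coef(cv$glmnet.fit, s = lam))[-1, 1]
    names(cf)[cf != 0]
  }
  sel <- nonzero_at(pick_lambda)
  if (length(sel) < min_features) {
    for (lam in cv$lambda[cv$lambda < pick_lambda]) {
      sel <- nonzero_at(lam)
      pick_lambda <- lam
      if (length(sel) >= min_features) break
    }
  }
  if (!length(sel)) {
    abort("no feature selected; weaken the penalty (e.g. lower `min_features` pressure or increase sample size).")
  }
  cf <- as.matrix(coef(cv$glmnet.fit, s = pick_lambda))[-1, 1]
  sel <- feats[feats %in% sel]   # input column order
  structure(list(lambda = pick_lambda, features = sel,
                 coefficients = cf[sel], cv = cv, n = nrow(tbl)),
            class = "wavemics_selection")
}

#' @export
print.wavemics_selection <- function(x, ...) {
  cat(sprintf("<wavemics_selection> %d feature(s) at lambda = %.4g\n",
              length(x$features), x$lambda))
  invisible(x)
}

#' Assemble the selected-feature row(s) in canonical order
#'
#' Reorders selected feature columns sequence-major (T1W, T2W, T1C, FLAIR),
#' preserving the original within-sequence column order, so every patient's
#' machine-learning input row has a canonical layout regardless of the
#' order selection returned them in.
#'
#' @param tbl A feature table containing the selected columns.
#' @param features Character vector of selected feature names (columns
#'   named `<sequence>_...`).
#' @return A tibble with `patient_id`, `label` and the reordered columns.
#' @export
assemble_rows <- function(tbl, features) {
  if (!length(features)) abort("empty selection; use a weaker penalty.")
  seq_of <- sub("_.*$", "", features)
  ord <- order(match(seq_of, mri_sequences()), match(features, names(tbl)))
  canon <- features[ord]
  keep <- intersect(c("patient_id", "label"), names(tbl))
  dplyr::bind_cols(tbl[, keep, drop = FALSE],
                   tbl[, canon, drop = FALSE])
}

#' @method tidy wavemics_selection
#' @export
tidy.wavemics_selection <- function(x, ...) {
  tibble::tibble(feature = x$features,
                 coefficient = unname(x$coefficients))
}

#' @method glance wavemics_selection
#' @export
glance.wavemics_selection <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, n_selected = length(x$features),
                 n_obs = x$n)
}
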