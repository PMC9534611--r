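# Intraclass correlation reliability filtering of features measured under
# repeated segmentations.

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Computed from the ANOVA mean squares of the patients x occasions matrix:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `n` patients
#' and `k` occasions. A matrix with zero total variance (all measurements
#' identical) is perfect agreement on a constant and returns 1.
#'
#' @param measurements Numeric matrix, patients in rows (>= 3), measurement
#'   occasions in columns (>= 2), no missing cells.
#' @return A single number in (-Inf, 1].
#' @export
#' @examples
#' m <- cbind(c(1, 2, 3, 4, 5), c(1.1, 2.1, 2.9, 4.2, 4.8))
#' icc(m)
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (nrow(m) < 3 || ncol(m) < 2) {
    abort("need at least 3 patients and 2 occasions.")
  }
  if (any(!is.finite(m))) abort("measurements must be finite.")
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  if (all(m == m[1])) return(1)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) return(1)
  (msr - mse) / denom
}

#' Build reliability stacks from repeated-segmentation feature tables
#'
#' Given one feature table per measurement occasion (same patients, same
#' columns), returns per-feature patients x occasions matrices.
#'
#' @param tables Named list of feature table tibbles (one per occasion).
#' @return Named list of matrices, one per feature column.
#' @export
reliability_stack <- function(tables) {
  stopifnot(length(tables) >= 2)
  feats <- feature_columns(tables[[1]])
  ids <- tables[[1]]$patient_id
  for (t in tables[-1]) {
    if (!identical(t$patient_id, ids) ||
        !identical(feature_columns(t), feats)) {
      abort("all occasion tables must share patients and feature columns.")
    }
  }
  out <- lapply(feats, function(f) {
    do.call(cbind, lapply(tables, function(t) t[[f]]))
  })
  names(out) <- feats
  out
}

#' Filter features by intra- and inter-observer ICC
#'
#' A feature is kept iff both its intra-observer ICC (one reader's repeated
#' sessions) and its inter-observer ICC (both readers' first sessions)
#' strictly exceed the threshold. Features present in only one stack are
#' excluded with a warning. Input order of kept names is preserved.
#'
#' @param intra,inter Named lists of patients x occasions matrices (as from
#'   [reliability_stack()]).
#' @param threshold Reliability cutoff (default 0.75, strict `>`).
#' @return A tibble with `feature`, `icc_intra`, `icc_inter`, `kept`, of
#'   class `wavemics_icc`.
#' @export
filter_by_icc <- function(intra, inter, threshold = 0.75) {
  common <- intersect(names(intra), names(inter))
  orphan <- setdiff(union(names(intra), names(inter)), common)
  if (length(orphan)) {
    warn(sprintf("%d feature(s) missing one reliability stack; excluded: %s",
                 length(orphan),
                 paste(head(orphan, 5), collapse = ", ")))
  }
  common <- names(intra)[names(intra) %in% common]  # preserve input order
  out <- tibble::tibble(
    feature = common,
    icc_intra = vapply(common, function(f) icc(intra[[f]]), numeric(1)),
    icc_inter = vapply(common, function(f) icc(inter[[f]]), numeric(1))
  )
  out$kept <- out$icc_intra > threshold & out$icc_inter > threshold
  attr(out, "threshold") <- threshold
  class(out) <- c("wavemics_icc", class(out))
  out
}

#' Reliability-filter a cohort's features from its repeated segmentations
#'
#' Extracts the feature table under each of the four reader/session masks,
#' then applies [filter_by_icc()]: intra-observer from reader 1's two
#' sessions, inter-observer from both readers' first sessions.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @inheritParams extract_features
#' @param threshold Reliability cutoff (default 0.75).
#' @return List with `icc` (the [filter_by_icc()] tibble), `kept` (feature
#'   names), and `table` (the reader-1-session-1 feature table restricted
#'   to kept features).
#' @export
reliability_filter_cohort <- function(cohort, threshold = 0.75,
                                      bin_width = 64, target_spacing = 1,
                                      resample = TRUE) {
  occ_needed <- c("r1s1", "r1s2", "r2s1")
  tabs <- lapply(occ_needed, function(o) {
    extract_cohort(cohort, occasion = o, bin_width = bin_width,
                   target_spacing = target_spacing, resample = resample)
  })
  names(tabs) <- occ_needed
  intra <- reliability_stack(tabs[c("r1s1", "r1s2")])
  inter <- reliability_stack(tabs[c("r1s1", "r2s1")])
  res <- filter_by_icc(intra, inter, threshold)
  kept <- res$feature[res$kept]
  list(icc = res, kept = kept,
       table = dplyr::select(tabs$r1s1, dplyr::all_of(c("patient_id", "label",
                                                        kept))))
}
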