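# Neighborhood gray-tone difference features (5). For each voxel with at
# least one 26-neighbor inside the mask, the absolute difference between its
# gray level and the mean level of those neighbors is accumulated per level.

ngtdm_feature_names <- function() {
  c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
}

#' Neighborhood gray-tone difference features
#'
#' Coarseness of a perfectly flat ROI (zero total difference) is capped at
#' 1e6; Busyness and Strength fall back to 0 when their denominators vanish.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(droi) {
  lv <- droi$levels
  ns <- neighbor_summaries(lv)
  sel <- which(!is.na(lv) & ns$nb_cnt > 0)
  if (!length(sel)) abort("no voxel has an in-mask neighbor: degenerate ROI.")
  lev <- lv[sel]
  abar <- ns$nb_sum[sel] / ns$nb_cnt[sel]
  nvp <- length(sel)
  levels_present <- sort(unique(lev))
  n_i <- vapply(levels_present, function(l) sum(lev == l), numeric(1))
  s_i <- vapply(levels_present, function(l) sum(abs(l - abar[lev == l])),
                numeric(1))
  p_i <- n_i / nvp
  ngp <- length(levels_present)
  iv <- levels_present

  coarse <- if (sum(p_i * s_i) > 0) 1 / sum(p_i * s_i) else 1e6
  contrast <- if (ngp > 1) {
    (sum(outer(p_i, p_i) * outer(iv, iv, `-`)^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / nvp)
  } else 0
  busy_den <- sum(abs(outer(iv * p_i, iv * p_i, `-`)))
  busy <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0
  pij_sum <- outer(p_i, p_i, `+`)
  dij <- abs(outer(iv, iv, `-`))
  cx_num <- outer(p_i * s_i, p_i * s_i, `+`)
  complexity <- sum(dij * cx_num / pij_sum) / nvp
  strength <- if (sum(s_i) > 0) {
    sum(pij_sum * outer(iv, iv, `-`)^2) / sum(s_i)
  } else 0

  setNames(c(busy, coarse, complexity, contrast, strength),
           ngtdm_feature_names())
}
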