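# Gray-level dependence matrix features (14). The dependence of a voxel is
# 1 + the number of its 26-neighbors inside the mask with the same gray
# level (alpha = 0), so dependence sizes run from 1 (isolated) to 27.

gldm_feature_names <- function() {
  c("DependenceEntropy", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "DependenceVariance",
    "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
    "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
    "SmallDependenceLowGrayLevelEmphasis")
}

#' Gray-level dependence features
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of length 14.
#' @export
gldm_features <- function(droi) {
  lv <- droi$levels
  ns <- neighbor_summaries(lv)
  inside <- which(!is.na(lv))
  if (!length(inside)) abort("empty ROI.")
  i <- lv[inside]
  j <- ns$eq_cnt[inside] + 1L
  nz <- length(inside)
  p <- rep(1 / nz, nz)
  mu_i <- mean(i)
  mu_j <- mean(j)
  gi <- table(i)
  gj <- table(j)
  pij <- as.vector(table(i, j)) / nz
  setNames(c(
    shannon_entropy(pij),
    sum(gj^2) / nz,
    sum(gj^2) / nz^2,
    mean((j - mu_j)^2),
    sum(gi^2) / nz,
    mean((i - mu_i)^2),
    mean(i^2),
    mean(j^2),
    mean(i^2 * j^2),
    mean(j^2 / i^2),
    mean(1 / i^2),
    mean(1 / j^2),
    mean(i^2 / j^2),
    mean(1 / (i^2 * j^2))
  ), gldm_feature_names())
}
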