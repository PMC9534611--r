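# First-order intensity statistics (18 features). Order statistics and
# moments are computed on the raw ROI intensities; Entropy and Uniformity on
# the discretized gray-level histogram.

firstorder_feature_names <- function() {
  c("10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
    "Kurtosis", "Maximum", "MeanAbsoluteDeviation", "Mean", "Median",
    "Minimum", "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
    "Skewness", "TotalEnergy", "Uniformity", "Variance")
}

#' First-order intensity features
#'
#' The 18 first-order statistics of the ROI: percentiles, moments, energy
#' and histogram entropy/uniformity. `Entropy` and `Uniformity` use the
#' discretized gray levels; everything else uses raw intensities.
#' `Variance`, `Skewness` and `Kurtosis` are population moments (divide by
#' N), and `Kurtosis` is not excess-corrected; a constant ROI has Kurtosis 0
#' by the 0/0 -> 0 convention. `TotalEnergy` scales `Energy` by the voxel
#' volume in mm^3.
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of length 18.
#' @export
firstorder_features <- function(droi) {
  x <- droi$raw
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  p <- tabulate(droi$levels[droi$mask], droi$n_levels) / n
  vox_vol <- prod(droi$spacing)
  out <- c(
    q[1], q[5], sum(x^2), shannon_entropy(p), q[4] - q[2],
    if (m2 > 0) m4 / m2^2 else 0,
    max(x), mean(abs(x - m)), m, q[3], min(x), max(x) - min(x),
    if (length(robust)) mean(abs(robust - mean(robust))) else 0,
    sqrt(mean(x^2)),
    if (m2 > 0) m3 / m2^1.5 else 0,
    vox_vol * sum(x^2), sum(p^2), m2
  )
  setNames(out, firstorder_feature_names())
}
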