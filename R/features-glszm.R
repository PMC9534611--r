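# Gray-level size-zone matrix features (16): zones are 26-connected
# components of equal gray level; a single matrix per ROI (no directions).

glszm_feature_names <- function() {
  c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "SmallAreaEmphasis",
    "SmallAreaHighGrayLevelEmphasis", "SmallAreaLowGrayLevelEmphasis",
    "ZoneEntropy", "ZonePercentage", "ZoneVariance")
}

#' Gray-level size-zone features
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of length 16.
#' @export
glszm_features <- function(droi) {
  zones <- level_zones(droi$levels)
  if (!nrow(zones)) abort("empty ROI: no zones.")
  n_vox <- sum(droi$mask)
  nz <- nrow(zones)
  i <- zones$level
  s <- zones$size
  w <- rep(1, nz)                 # each zone counts once
  p <- w / nz
  mu_i <- sum(i * p)
  mu_s <- sum(s * p)
  # grouped counts for the non-uniformity terms
  gi <- tapply(w, factor(i, levels = sort(unique(i))), sum)
  gs <- tapply(w, factor(s, levels = sort(unique(s))), sum)
  setNames(c(
    sum(gi^2) / nz,
    sum(gi^2) / nz^2,
    sum((i - mu_i)^2 * p),
    sum(i^2 * p),
    sum(s^2 * p),
    sum(i^2 * s^2 * p),
    sum(s^2 / i^2 * p),
    sum(p / i^2),
    sum(gs^2) / nz,
    sum(gs^2) / nz^2,
    sum(p / s^2),
    sum(i^2 / s^2 * p),
    sum(p / (i^2 * s^2)),
    shannon_entropy(as.vector(table(i, s)) / nz),
    nz / n_vox,
    sum((s - mu_s)^2 * p)
  ), glszm_feature_names())
}
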