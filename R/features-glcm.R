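# Gray-level co-occurrence matrix features (24). Matrices are built per
# direction (13 unique 3D offsets at Chebyshev distance 1), symmetrized and
# normalized to sum 1; each statistic is averaged over the directions that
# contain at least one co-occurring pair.

glcm_feature_names <- function() {
  c("Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
    "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
    "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
    "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
    "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")
}

# Normalized symmetric co-occurrence matrix for one direction, or NULL when
# the direction has no co-occurring pair inside the mask.
glcm_matrix <- function(lv, d, n_levels) {
  pr <- level_pairs(lv, d)
  if (!length(pr$a)) return(NULL)
  counts <- tabulate((pr$a - 1L) * n_levels + pr$b, n_levels^2) +
    tabulate((pr$b - 1L) * n_levels + pr$a, n_levels^2)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P / sum(P)
}

glcm_statistics <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)          # equals px by symmetry
  mux <- sum(seq_len(ng) * px)
  muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal-band and anti-diagonal-band distributions
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))

  autoc <- sum(i * j * P)
  da <- sum(k_diff * p_diff)
  contrast <- sum(k_diff^2 * p_diff)
  corr <- if (sigx > 0 && sigy > 0) (autoc - mux * muy) / (sigx * sigy) else 1

  hx <- shannon_entropy(px)
  hy <- shannon_entropy(py)
  hxy <- shannon_entropy(as.vector(P))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P * xlog2_of(pxpy))
  hxy2 <- shannon_entropy(as.vector(pxpy))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0

  mcc <- {
    nz <- which(px > 0)
    if (length(nz) < 2) 1 else {
      Pn <- P[nz, nz, drop = FALSE]
      Q <- sweep(Pn / px[nz], 2, py[nz], `/`) %*% t(Pn)
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, min(1, ev[2])))
    }
  }

  setNames(c(
    autoc,
    sum((i + j - mux - muy)^4 * P),
    sum((i + j - mux - muy)^3 * P),
    sum((i + j - mux - muy)^2 * P),
    contrast,
    corr,
    da,
    shannon_entropy(p_diff),
    sum((k_diff - da)^2 * p_diff),
    sum(p_diff / (1 + k_diff)),
    sum(p_diff / (1 + k_diff^2)),
    sum(p_diff / (1 + k_diff^2 / ng^2)),
    sum(p_diff / (1 + k_diff / ng)),
    imc1,
    imc2,
    sum(p_diff[-1] / k_diff[-1]^2),
    mux,
    sum(P^2),
    hxy,
    mcc,
    max(P),
    sum(k_sum * p_sum),
    shannon_entropy(p_sum),
    sum((seq_len(ng) - mux)^2 * px)
  ), glcm_feature_names())
}

# log2 with zeros mapped to zero contribution (for cross-entropy terms)
xlog2_of <- function(p) {
  out <- array(0, dim(p))
  pos <- p > 0
  out[pos] <- log2(p[pos])
  out
}

#' Gray-level co-occurrence features
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of length 24. On a single-level ROI the
#'   undefined statistics take their limiting conventions (Correlation,
#'   MCC = 1; entropies and contrast terms 0; JointEnergy 1).
#' @export
glcm_features <- function(droi) {
  lv <- droi$levels
  ng <- droi$n_levels
  dirs <- texture_directions()
  acc <- NULL
  nd <- 0L
  for (k in seq_len(nrow(dirs))) {
    P <- glcm_matrix(lv, dirs[k, ], ng)
    if (is.null(P)) next
    st <- glcm_statistics(P)
    acc <- if (is.null(acc)) st else acc + st
    nd <- nd + 1L
  }
  if (nd == 0L) abort("no co-occurring voxel pairs in any direction: degenerate ROI.")
  acc / nd
}
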