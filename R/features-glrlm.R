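# Gray-level run-length matrix features (16): runs of equal gray level
# along each of the 13 directions, statistics averaged over directions.

glrlm_feature_names <- function() {
  c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis")
}

# Run-length matrix (levels x run lengths) for one direction.
glrlm_matrix <- function(lv, d, n_levels) {
  idx <- which(!is.na(lv))
  co <- arrayInd(idx, dim(lv))
  lev <- lv[idx]
  pivot <- which(d != 0)[1]
  t <- co[, pivot] * d[pivot]              # strictly +1 per step (d[pivot] = +1)
  lid <- co - outer(t, d)                  # constant along a line
  ord <- order(lid[, 1], lid[, 2], lid[, 3], t)
  lev <- lev[ord]; t <- t[ord]; lid <- lid[ord, , drop = FALSE]
  n <- length(lev)
  if (n == 0) return(NULL)
  new_run <- c(TRUE, lev[-1] != lev[-n] | t[-1] != t[-n] + 1 |
                 rowSums(abs(lid[-1, , drop = FALSE] -
                               lid[-n, , drop = FALSE])) > 0)
  run_id <- cumsum(new_run)
  run_len <- tabulate(run_id)
  run_lev <- lev[new_run]
  maxlen <- max(run_len)
  P <- matrix(0, n_levels, maxlen)
  cnt <- table(factor(run_lev, levels = seq_len(n_levels)),
               factor(run_len, levels = seq_len(maxlen)))
  P[] <- as.numeric(cnt)
  P
}

glrlm_statistics <- function(P, n_voxels) {
  nr <- sum(P)
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ncol(P))
  j <- matrix(seq_len(ncol(P)), ng, ncol(P), byrow = TRUE)
  p <- P / nr
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  setNames(c(
    sum(rowSums(P)^2) / nr,
    sum(rowSums(P)^2) / nr^2,
    sum((i - mu_i)^2 * p),
    sum(P * i^2) / nr,
    sum(P * j^2) / nr,
    sum(P * i^2 * j^2) / nr,
    sum(P * j^2 / i^2) / nr,
    sum(P / i^2) / nr,
    shannon_entropy(as.vector(p)),
    sum(colSums(P)^2) / nr,
    sum(colSums(P)^2) / nr^2,
    nr / n_voxels,
    sum((j - mu_j)^2 * p),
    sum(P / j^2) / nr,
    sum(P * i^2 / j^2) / nr,
    sum(P / (i^2 * j^2)) / nr
  ), glrlm_feature_names())
}

#' Gray-level run-length features
#'
#' @param droi A [discretize()]d ROI.
#' @return Named numeric vector of length 16 (statistics averaged over the
#'   13 directions).
#' @export
glrlm_features <- function(droi) {
  lv <- droi$levels
  n_vox <- sum(droi$mask)
  dirs <- texture_directions()
  acc <- NULL
  nd <- 0L
  for (k in seq_len(nrow(dirs))) {
    P <- glrlm_matrix(lv, dirs[k, ], droi$n_levels)
    if (is.null(P)) next
    st <- glrlm_statistics(P, n_vox)
    acc <- if (is.null(acc)) st else acc + st
    nd <- nd + 1L
  }
  if (nd == 0L) abort("empty ROI: no runs.")
  acc / nd
}
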