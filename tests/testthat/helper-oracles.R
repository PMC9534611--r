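# Independent brute-force oracles. Every function here recomputes a
# quantity from its textbook definition with naive loops, sharing no code
# with the package implementation.

# ---- first order ----------------------------------------------------------
oracle_firstorder <- function(x, levels, n_levels, vox_vol) {
  n <- length(x)
  m <- sum(x) / n
  mom <- function(k) sum((x - m)^k) / n
  qt <- function(p) as.numeric(quantile(x, p, type = 7))
  p <- sapply(seq_len(n_levels), function(l) sum(levels == l)) / n
  p <- p[p > 0]
  rob <- x[x >= qt(0.1) & x <= qt(0.9)]
  c(
    `10Percentile` = qt(0.1), `90Percentile` = qt(0.9),
    Energy = sum(x^2), Entropy = -sum(p * log2(p)),
    InterquartileRange = qt(0.75) - qt(0.25),
    Kurtosis = if (mom(2) > 0) mom(4) / mom(2)^2 else 0,
    Maximum = max(x), MeanAbsoluteDeviation = sum(abs(x - m)) / n,
    Mean = m, Median = as.numeric(median(x)), Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (mom(2) > 0) mom(3) / mom(2)^1.5 else 0,
    TotalEnergy = vox_vol * sum(x^2), Uniformity = sum(p^2),
    Variance = mom(2)
  )
}

# ---- shared helpers for texture oracles -----------------------------------
# All 26 neighbor offsets / the 13 canonical directions, written out by hand.
oracle_directions <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    d <- c(dx, dy, dz)
    if (all(d == 0)) next
    nz <- d[d != 0]
    if (nz[1] > 0) out[[length(out) + 1]] <- d
  }
  out
}

in_bounds <- function(co, dm) {
  all(co >= 1) && all(co <= dm)
}

# ---- GLCM -----------------------------------------------------------------
# Naive voxel-pair enumeration for one direction; symmetric, normalized.
oracle_glcm_matrix <- function(lv, d, ng) {
  dm <- dim(lv)
  P <- matrix(0, ng, ng)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    nb <- c(x, y, z) + d
    if (!in_bounds(nb, dm)) next
    b <- lv[nb[1], nb[2], nb[3]]
    if (is.na(b)) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  if (sum(P) == 0) return(NULL)
  P / sum(P)
}

oracle_glcm_stat <- function(P, what) {
  ng <- nrow(P)
  tot <- 0
  px <- rowSums(P); py <- colSums(P)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    tot <- tot + switch(what,
      Autocorrelation = i * j * p,
      Contrast = (i - j)^2 * p,
      JointEnergy = p^2,
      JointEntropy = if (p > 0) -p * log2(p) else 0,
      ClusterTendency = (i + j - mux - muy)^2 * p,
      Id = p / (1 + abs(i - j)),
      Idm = p / (1 + (i - j)^2),
      InverseVariance = if (i != j) p / (i - j)^2 else 0,
      SumSquares = (i - mux)^2 * p,
      stop("unknown")
    )
  }
  tot
}

# ---- GLRLM ----------------------------------------------------------------
# Walk every line in direction d, counting maximal equal-level runs.
oracle_glrlm_matrix <- function(lv, d, ng) {
  dm <- dim(lv)
  runs <- list()
  visited <- array(FALSE, dm)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    start <- c(x, y, z)
    prev <- start - d
    if (in_bounds(prev, dm)) next   # only begin at line starts
    co <- start
    cur_lev <- NA; cur_len <- 0
    while (in_bounds(co, dm)) {
      v <- lv[co[1], co[2], co[3]]
      if (is.na(v)) {
        if (cur_len > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- NA; cur_len <- 0
      } else if (!is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1
      } else {
        if (cur_len > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
        cur_lev <- v; cur_len <- 1
      }
      co <- co + d
    }
    if (cur_len > 0) runs[[length(runs) + 1]] <- c(cur_lev, cur_len)
  }
  if (!length(runs)) return(NULL)
  rl <- do.call(rbind, runs)
  P <- matrix(0, ng, max(rl[, 2]))
  for (r in seq_len(nrow(rl))) {
    P[rl[r, 1], rl[r, 2]] <- P[rl[r, 1], rl[r, 2]] + 1
  }
  P
}

# ---- GLSZM ----------------------------------------------------------------
# Breadth-first flood fill over the 26-neighborhood per gray level.
oracle_glszm_zones <- function(lv) {
  dm <- dim(lv)
  seen <- array(FALSE, dm)
  zones <- list()
  offsets <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx || dy || dz) offsets[[length(offsets) + 1]] <- c(dx, dy, dz)
  }
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (seen[x, y, z] || is.na(lv[x, y, z])) next
    lev <- lv[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      co <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (d in offsets) {
        nb <- co + d
        if (!in_bounds(nb, dm)) next
        if (seen[nb[1], nb[2], nb[3]]) next
        v <- lv[nb[1], nb[2], nb[3]]
        if (!is.na(v) && v == lev) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  do.call(rbind, zones)
}

# ---- GLDM / NGTDM ---------------------------------------------------------
oracle_neighbors <- function(lv, x, y, z) {
  dm <- dim(lv)
  out <- numeric(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (!dx && !dy && !dz) next
    nb <- c(x + dx, y + dy, z + dz)
    if (!in_bounds(nb, dm)) next
    v <- lv[nb[1], nb[2], nb[3]]
    if (!is.na(v)) out <- c(out, v)
  }
  out
}

oracle_gldm_pairs <- function(lv) {
  dm <- dim(lv)
  out <- NULL
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- lv[x, y, z]
    if (is.na(v)) next
    nb <- oracle_neighbors(lv, x, y, z)
    out <- rbind(out, c(v, sum(nb == v) + 1))
  }
  out   # columns: gray level, dependence size
}

oracle_ngtdm <- function(lv) {
  dm <- dim(lv)
  lev <- c(); adiff <- c()
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- lv[x, y, z]
    if (is.na(v)) next
    nb <- oracle_neighbors(lv, x, y, z)
    if (!length(nb)) next
    lev <- c(lev, v)
    adiff <- c(adiff, abs(v - mean(nb)))
  }
  list(lev = lev, adiff = adiff)
}

# ---- 2D DWT ---------------------------------------------------------------
# Direct convolve-and-downsample with explicit symmetric index folding.
oracle_ext_index <- function(i, n) {
  # half-sample symmetric extension, period 2n
  t <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n)
  if (t < n) t + 1 else 2 * n - t
}

oracle_dwt1 <- function(x, f) {
  n <- length(x)
  L <- length(f)
  outlen <- floor((n + L - 1) / 2)
  out <- numeric(outlen)
  for (k in seq_len(outlen)) {
    # y[k] = sum_m f[m] * ext[2k + L - 2 - m + 1] over the padded signal
    s <- 0
    for (m in seq_len(L)) {
      pos <- 2 * k - m + 1          # position in the (unpadded) signal frame
      s <- s + f[m] * x[oracle_ext_index(pos, n)]
    }
    out[k] <- s
  }
  out
}

oracle_dwt2 <- function(M, lo, hi) {
  pass_rows <- function(A, f) {
    cols <- lapply(seq_len(ncol(A)), function(j) oracle_dwt1(A[, j], f))
    do.call(cbind, cols)
  }
  pass_cols <- function(A, f) {
    rows <- lapply(seq_len(nrow(A)), function(i) oracle_dwt1(A[i, ], f))
    do.call(rbind, rows)
  }
  lo_r <- pass_rows(M, lo)
  hi_r <- pass_rows(M, hi)
  list(cA = pass_cols(lo_r, lo), cH = pass_cols(hi_r, lo),
       cV = pass_cols(lo_r, hi), cD = pass_cols(hi_r, hi))
}

# ---- ICC ------------------------------------------------------------------
# ICC(2,1) via an explicit two-way ANOVA fitted with aov().
oracle_icc21 <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
    occ = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- summary(aov(y ~ subj + occ, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["occ", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# ---- AUC difference permutation test --------------------------------------
oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# Permutation oracle for comparing two correlated ROC curves: swap the two
# models' scores patient-wise at random and recompute the AUC difference.
oracle_roc_permutation <- function(s1, s2, pos, n_perm = 2000, seed = 1) {
  obs <- abs(oracle_auc(s1, pos) - oracle_auc(s2, pos))
  set.seed(seed)
  n <- length(s1)
  hits <- 0
  for (b in seq_len(n_perm)) {
    flip <- runif(n) < 0.5
    a1 <- ifelse(flip, s2, s1)
    a2 <- ifelse(flip, s1, s2)
    if (abs(oracle_auc(a1, pos) - oracle_auc(a2, pos)) >= obs - 1e-12) {
      hits <- hits + 1
    }
  }
  (hits + 1) / (n_perm + 1)
}
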