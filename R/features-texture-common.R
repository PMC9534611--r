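# Shared machinery for the gray-level texture matrices: the 13 unique 3D
# direction offsets at Chebyshev distance 1, shifted-level pair gathering,
# and 26-connected components.

# One offset per +/- pair, first nonzero component positive.
texture_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  unname(g[keep, , drop = FALSE])  # 13 x 3
}

# Level array shifted by -d: entry [i] holds level at voxel i + d (NA outside).
shift_levels <- function(lv, d) {
  out <- shift_array(lv, -d[1], 1, fill = NA_integer_)
  out <- shift_array(out, -d[2], 2, fill = NA_integer_)
  shift_array(out, -d[3], 3, fill = NA_integer_)
}

# Co-occurring level pairs (a at voxel, b at voxel + d), both inside the mask.
level_pairs <- function(lv, d) {
  b <- shift_levels(lv, d)
  ok <- !is.na(lv) & !is.na(b)
  list(a = lv[ok], b = b[ok])
}

# Connected components of same-level masked voxels under 26-connectivity.
# Returns a data.frame with one row per zone: level, size.
level_zones <- function(lv) {
  idx <- which(!is.na(lv))
  n <- length(idx)
  pos <- match(seq_along(lv), idx)        # voxel linear id -> node id
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  dirs <- texture_directions()
  d3 <- dim(lv)
  stride <- c(1L, d3[1], d3[1] * d3[2])
  coords <- arrayInd(idx, d3)
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    nb_coords <- sweep(coords, 2, d, `+`)
    ok <- nb_coords[, 1] >= 1 & nb_coords[, 1] <= d3[1] &
      nb_coords[, 2] >= 1 & nb_coords[, 2] <= d3[2] &
      nb_coords[, 3] >= 1 & nb_coords[, 3] <= d3[3]
    nb_lin <- as.integer((nb_coords[ok, , drop = FALSE] - 1) %*% stride) + 1L
    from <- which(ok)
    to <- pos[nb_lin]
    good <- !is.na(to) & lv[idx[from]] == lv[idx[to]]
    from <- from[good]; to <- to[good]
    for (e in seq_along(from)) {
      ra <- find(from[e]); rb <- find(to[e])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  lev <- lv[idx[as.integer(names(sizes))]]
  data.frame(level = as.integer(lev), size = as.integer(sizes))
}

# Count, per masked voxel, the 26-neighbors inside the mask whose level is
# equal (for GLDM) and the neighbor level sum/count (for NGTDM).
neighbor_summaries <- function(lv) {
  dirs <- texture_directions()
  eq_cnt <- array(0L, dim(lv))
  nb_sum <- array(0, dim(lv))
  nb_cnt <- array(0L, dim(lv))
  for (k in seq_len(nrow(dirs))) {
    for (sgn in c(1, -1)) {
      b <- shift_levels(lv, sgn * dirs[k, ])
      has <- !is.na(b)
      cmp <- has & !is.na(lv)
      eqv <- array(FALSE, dim(lv))
      eqv[cmp] <- b[cmp] == lv[cmp]
      eq_cnt <- eq_cnt + eqv
      nb_sum[has] <- nb_sum[has] + b[has]
      nb_cnt <- nb_cnt + has
    }
  }
  list(eq_cnt = eq_cnt, nb_sum = nb_sum, nb_cnt = nb_cnt)
}
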