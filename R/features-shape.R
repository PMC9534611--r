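# Shape features (14) from the binary mask: mesh-based volume/area, PCA
# axis lengths, and maximum diameters.

shape_feature_names <- function() {
  c("Elongation", "Flatness", "LeastAxisLength", "MajorAxisLength",
    "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
    "Maximum2DDiameterSlice", "Maximum3DDiameter", "MeshVolume",
    "MinorAxisLength", "Sphericity", "SurfaceArea", "SurfaceVolumeRatio",
    "VoxelVolume")
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 3000) {  # keep the quadratic pass bounded
    keep <- unique(c(
      apply(pts, 2, which.min), apply(pts, 2, which.max),
      which.max(rowSums(sweep(pts, 2, colMeans(pts))^2))
    ))
    hull <- pts[keep, , drop = FALSE]
    d0 <- max(stats::dist(hull))
    ctr <- colMeans(pts)
    r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
    far <- pts[r >= max(r) * 0.7, , drop = FALSE]
    if (nrow(far) <= 3000) return(max(stats::dist(far), d0))
    return(d0)
  }
  max(stats::dist(pts))
}

#' Shape features of a 3D ROI
#'
#' The 14 morphological features: axis lengths and their ratios from a
#' principal-component analysis of the foreground voxel-center coordinates
#' (axis length = `4 * sqrt(eigenvalue)`), mesh-derived volume, surface
#' area and sphericity (`(36 pi V^2)^(1/3) / A`), maximum 3D and in-plane
#' diameters over boundary voxels, and the voxel-count volume. Meshing
#' triangulates the 0.5 iso-surface of a Gaussian-smoothed mask indicator;
#' masks too small to support a mesh (e.g. a single voxel) fall back to the
#' voxel volume and the summed exposed voxel-face area.
#'
#' @param mask An [roi_mask()] with at least one foreground voxel.
#' @return Named numeric vector of length 14; lengths in mm, areas mm^2,
#'   volumes mm^3.
#' @export
shape_features <- function(mask) {
  mv <- mask$voxels
  sp <- mask$spacing
  idx <- which(mv)
  if (!length(idx)) abort("mask has no foreground voxels.")
  n <- length(idx)
  coords <- sweep(arrayInd(idx, dim(mv)) - 1, 2, sp, `*`)
  vox_vol <- n * prod(sp)

  # PCA axis lengths (population covariance)
  if (n > 1) {
    cc <- sweep(coords, 2, colMeans(coords))
    ev <- sort(eigen(crossprod(cc) / n, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1

  mesh <- mask_mesh(mv, sp, smooth_sigma = 1)
  if (mesh$area <= 0 || mesh$volume <= 0) {
    # degenerate mask: voxelized fallback
    mesh$volume <- vox_vol
    mesh$area <- exposed_face_area(mv, sp)
  }
  spher <- (36 * pi * mesh$volume^2)^(1 / 3) / mesh$area

  # boundary voxels for the diameter features
  bnd <- mask_shells(mv)$inner
  bidx <- which(bnd)
  bco <- sweep(arrayInd(bidx, dim(mv)) - 1, 2, sp, `*`)
  max3d <- max_pairwise_dist(bco)
  per_plane_max <- function(plane_axis, keep_axes) {
    key <- bco[, plane_axis]
    vals <- split.data.frame(bco[, keep_axes, drop = FALSE], key)
    max(vapply(vals, function(m) {
      if (nrow(m) < 2) 0 else max(stats::dist(m))
    }, numeric(1)))
  }
  d_slice <- per_plane_max(3, c(1, 2))   # axial plane (x, y)
  d_col <- per_plane_max(2, c(1, 3))     # coronal plane (x, z)
  d_row <- per_plane_max(1, c(2, 3))     # sagittal plane (y, z)

  setNames(
    c(elong, flat, least, major, d_col, d_row, d_slice, max3d, mesh$volume,
      minor, spher, mesh$area, mesh$area / mesh$volume, vox_vol),
    shape_feature_names()
  )
}

# Summed area of voxel faces exposed to background (degenerate-mask fallback).
exposed_face_area <- function(mv, sp) {
  face_areas <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  total <- 0
  for (axis in 1:3) {
    for (sgn in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L); d[axis] <- sgn
      nb <- shift_array(mv, d[1], 1, fill = FALSE)
      nb <- shift_array(nb, d[2], 2, fill = FALSE)
      nb <- shift_array(nb, d[3], 3, fill = FALSE)
      nb <- array(as.logical(nb), dim(mv))
      total <- total + sum(mv & !nb) * face_areas[axis]
    }
  }
  total
}
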