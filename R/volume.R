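# Image volumes, ROI masks, resampling and gray-level discretization.

#' Create an image volume
#'
#' A minimal container for one MRI sequence: a 3D numeric array of voxel
#' intensities plus its physical geometry. Axes are indexed (x, y, z) with
#' voxel-center coordinates `origin + (index - 1) * spacing` in mm.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing Numeric length-3, mm per voxel along each axis (all > 0).
#' @param origin Numeric length-3, mm position of the first voxel center.
#' @return An object of class `image_volume`.
#' @export
#' @examples
#' v <- image_volume(array(rnorm(8 * 8 * 8), c(8, 8, 8)), spacing = c(1, 1, 1))
#' dim(v$voxels)
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array.")
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive numbers (mm).")
  }
  structure(
    list(voxels = voxels, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' Create a binary ROI mask
#'
#' @param voxels 3D array coercible to logical; `TRUE` marks tumor voxels.
#' @param spacing Numeric length-3, mm per voxel.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array.")
  }
  v <- array(as.logical(voxels), dim(voxels))
  if (anyNA(v)) abort("mask voxels must be 0/1 without missing values.")
  structure(list(voxels = v, spacing = as.numeric(spacing)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s voxels, %d foreground\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels)))
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over RNifti. Spacing is taken from (written into) the NIfTI
#' pixdim; masks are stored as uint8.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param volume,mask Objects created by [image_volume()] / [roi_mask()].
#' @return `read_volume()` returns an `image_volume`; `read_mask()` an
#'   `roi_mask`; the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) > 0.5, dim(img)[1:3]),
           spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

# Trilinear sample of a 3D array at fractional 1-based voxel coordinates
# (n_points x 3 matrix), clamped at the grid edges.
trilinear_sample <- function(arr, coords) {
  d <- dim(arr)
  cl <- function(x, n) pmin(pmax(x, 1), n)
  x <- cl(coords[, 1], d[1]); y <- cl(coords[, 2], d[2]); z <- cl(coords[, 3], d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x0 <- pmax(x0, 1L)
  y0 <- pmin(floor(y), max(d[2] - 1L, 1L)); y0 <- pmax(y0, 1L)
  z0 <- pmin(floor(z), max(d[3] - 1L, 1L)); z0 <- pmax(z0, 1L)
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) ((k - 1) * d[2] + (j - 1)) * d[1] + i
  v <- as.vector(arr)
  v000 <- v[idx(x0, y0, z0)]; v100 <- v[idx(x1, y0, z0)]
  v010 <- v[idx(x0, y1, z0)]; v110 <- v[idx(x1, y1, z0)]
  v001 <- v[idx(x0, y0, z1)]; v101 <- v[idx(x1, y0, z1)]
  v011 <- v[idx(x0, y1, z1)]; v111 <- v[idx(x1, y1, z1)]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Resample a volume and its mask to isotropic spacing
#'
#' The intensity volume is interpolated trilinearly and the mask by nearest
#' neighbor, on a grid that spans the same physical extent with the target
#' spacing. A volume already at the target spacing is returned unchanged.
#'
#' @param volume An [image_volume()].
#' @param mask The matching [roi_mask()] (same grid).
#' @param target_spacing Numeric length 1 or 3, mm (default 1 mm isotropic).
#' @return A list with elements `volume` and `mask` on the new grid.
#' @export
#' @examples
#' v <- image_volume(array(1, c(8, 8, 8)), spacing = c(2, 2, 2))
#' m <- roi_mask(array(TRUE, c(8, 8, 8)), spacing = c(2, 2, 2))
#' out <- resample_isotropic(v, m, 1)
#' dim(out$volume$voxels)
resample_isotropic <- function(volume, mask, target_spacing = 1) {
  if (length(target_spacing) == 1L) target_spacing <- rep(target_spacing, 3)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0)) {
    abort("`target_spacing` must be positive on each axis.")
  }
  if (!identical(dim(volume$voxels), dim(mask$voxels))) {
    abort("volume and mask grids differ.")
  }
  if (isTRUE(all.equal(volume$spacing, target_spacing, tolerance = 1e-9))) {
    return(list(volume = volume, mask = mask))
  }
  d_old <- dim(volume$voxels)
  d_new <- pmax(1L, as.integer(round(d_old * volume$spacing / target_spacing)))
  # fractional source coordinates of the new voxel centers (same origin)
  ax <- lapply(1:3, function(a) {
    1 + (seq_len(d_new[a]) - 1) * target_spacing[a] / volume$spacing[a]
  })
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vox <- array(trilinear_sample(volume$voxels, coords), d_new)
  nn <- lapply(1:3, function(a) {
    pmin(pmax(as.integer(round(ax[[a]])), 1L), d_old[a])
  })
  mvox <- array(mask$voxels[as.matrix(expand.grid(nn[[1]], nn[[2]], nn[[3]]))],
                d_new)
  if (!any(mvox)) abort("mask is empty after resampling: degenerate ROI.")
  list(volume = image_volume(vox, target_spacing, volume$origin),
       mask = roi_mask(mvox, target_spacing))
}

#' Discretize ROI intensities with a fixed bin width
#'
#' Gray levels are `floor((v - min) / bin_width) + 1` over the voxels inside
#' the mask, so levels are consecutive positive integers anchored at the ROI
#' minimum; the number of levels follows from the ROI range, not a fixed
#' level count.
#'
#' @param volume An [image_volume()].
#' @param mask The matching [roi_mask()].
#' @param bin_width Positive intensity width per gray level (default 64).
#' @return An object of class `discretized_roi` with elements `levels`
#'   (integer array, `NA` outside the mask), `mask`, `n_levels`, `bin_width`,
#'   `spacing` and `raw` (intensities inside the mask).
#' @export
#' @examples
#' v <- image_volume(array(c(0, 63, 64, 200, 0, 0, 0, 0), c(2, 2, 2)))
#' m <- roi_mask(array(c(1, 1, 1, 1, 0, 0, 0, 0), c(2, 2, 2)))
#' d <- discretize(v, m, bin_width = 64)
#' d$n_levels
discretize <- function(volume, mask, bin_width = 64) {
  stopifnot_scalar_number(bin_width, "bin_width", positive = TRUE)
  inside <- mask$voxels
  if (!any(inside)) abort("mask has no foreground voxels.")
  vals <- volume$voxels[inside]
  if (any(!is.finite(vals))) abort("non-finite intensities inside the mask.")
  lev <- array(NA_integer_, dim(volume$voxels))
  lev[inside] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  structure(
    list(levels = lev, mask = inside, n_levels = max(lev, na.rm = TRUE),
         bin_width = bin_width, spacing = volume$spacing, raw = vals),
    class = "discretized_roi"
  )
}

#' @export
print.discretized_roi <- function(x, ...) {
  cat(sprintf("<discretized_roi> %d voxels, %d gray levels (bin width %g)\n",
              sum(x$mask), x$n_levels, x$bin_width))
  invisible(x)
}
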