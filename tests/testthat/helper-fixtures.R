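# Shared fixture builders: everything is generated in code at test time.

# A small cohort with in-bounds lesions for a 20^3 grid.
tiny_cohort_config <- function(n = 6, seed = 1, jitter = 0.05,
                               shape = c(20, 20, 20)) {
  cohort_config(
    n_patients = n,
    volume_shape = shape,
    tumor_radius_range = list(GBM = c(4.5, 6.5), MET = c(3.5, 5.5)),
    reader_jitter = jitter,
    seed = seed
  )
}

# Discretized ROI from an explicit level array (NA = background); raw
# intensities default to the levels themselves.
droi_from_levels <- function(lev_arr, bin_width = 1, spacing = c(1, 1, 1)) {
  mask <- !is.na(lev_arr)
  structure(
    list(levels = lev_arr, mask = mask,
         n_levels = max(lev_arr, na.rm = TRUE),
         bin_width = bin_width, spacing = spacing,
         raw = as.numeric(lev_arr[mask])),
    class = "discretized_roi"
  )
}

# Random small discretized ROI (full cube, no background) under a seed.
random_droi <- function(dim3 = c(4, 4, 4), n_levels = 3, seed = 1) {
  set.seed(seed)
  lev <- array(sample.int(n_levels, prod(dim3), replace = TRUE), dim3)
  droi_from_levels(lev)
}

# A digital ball mask of radius r mm on a 1 mm grid.
ball_mask <- function(r = 10) {
  n <- 2 * ceiling(r) + 5
  c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  roi_mask(array((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2,
                 c(n, n, n)))
}

# Volume + mask pair holding the given ROI intensity vector in a cube.
cube_case <- function(values, side = NULL, spacing = c(1, 1, 1)) {
  side <- side %||% ceiling(length(values)^(1 / 3))
  n <- side^3
  stopifnot(n >= length(values))
  vox <- array(0, c(side, side, side))
  msk <- array(FALSE, c(side, side, side))
  vox[seq_along(values)] <- values
  msk[seq_along(values)] <- TRUE
  list(volume = image_volume(vox, spacing), mask = roi_mask(msk, spacing))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
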