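# Shape and first-order features: closed forms, analytic limits, and the
# direct-formula oracle.

test_that("a digital ball is nearly spherical, isotropic, and sized right", {
  m <- ball_mask(10)
  f <- shape_features(m)
  expect_length(f, 14)
  expect_gte(f[["Sphericity"]], 0.95)
  expect_lte(f[["Sphericity"]], 1.0)
  expect_gte(f[["Elongation"]], 0.95)
  expect_lte(f[["Elongation"]], 1.0)
  expect_gte(f[["Flatness"]], 0.95)
  # analytic values with a few percent discretization tolerance
  expect_equal(f[["MeshVolume"]], 4 / 3 * pi * 1000, tolerance = 0.06)
  expect_equal(f[["SurfaceArea"]], 4 * pi * 100, tolerance = 0.04)
  expect_equal(f[["VoxelVolume"]], sum(m$voxels))
  expect_equal(f[["Maximum3DDiameter"]], 20, tolerance = 0.08)
  expect_equal(f[["Maximum2DDiameterSlice"]], 20, tolerance = 0.08)
})

test_that("single-voxel masks return defined degenerate shape values", {
  m <- roi_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)))
  f <- shape_features(m)
  expect_equal(f[["VoxelVolume"]], 1)
  expect_equal(f[["MeshVolume"]], 1)      # voxelized fallback
  expect_equal(f[["SurfaceArea"]], 6)
  expect_true(all(is.finite(f)))
})

test_that("axis lengths scale with anisotropic spacing", {
  vox <- array(FALSE, c(12, 6, 6))
  vox[2:11, 2:5, 2:5] <- TRUE
  long <- shape_features(roi_mask(vox, spacing = c(1, 1, 1)))
  expect_gt(long[["MajorAxisLength"]], long[["LeastAxisLength"]])
  expect_lt(long[["Elongation"]], 1)
  # stretching the long axis by spacing doubles its PCA length
  stretched <- shape_features(roi_mask(vox, spacing = c(2, 1, 1)))
  expect_equal(stretched[["MajorAxisLength"]] / long[["MajorAxisLength"]], 2,
               tolerance = 1e-8)
})

test_that("first-order closed forms hold on constant and tiny ROIs", {
  n <- 8
  cs <- cube_case(rep(5, n), side = 2)
  f <- firstorder_features(discretize(cs$volume, cs$mask, 64))
  expect_length(f, 18)
  expect_equal(f[["Variance"]], 0)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Uniformity"]], 1)
  expect_equal(f[["Energy"]], 25 * n)
  expect_equal(f[["Kurtosis"]], 0)   # 0/0 convention on a constant ROI

  cs2 <- cube_case(c(1, 2, 3, 4), side = 2)
  f2 <- firstorder_features(discretize(cs2$volume, cs2$mask, 1))
  expect_equal(f2[["Mean"]], 2.5)
  expect_equal(f2[["Range"]], 3)
  expect_equal(f2[["Median"]], 2.5)
})

test_that("first-order features match the direct-formula oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    vals <- rnorm(60, mean = 100, sd = 25)
    cs <- cube_case(vals, side = 4)
    d <- discretize(cs$volume, cs$mask, bin_width = 10)
    got <- firstorder_features(d)
    want <- oracle_firstorder(d$raw, d$levels[d$mask], d$n_levels,
                              prod(d$spacing))
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("all 107 features are translation invariant", {
  co <- generate_cohort(tiny_cohort_config(n = 4, seed = 31,
                                           shape = c(18, 18, 18)))
  v <- co$volumes[[1]]$T1C
  m <- co$masks[[1]]$r1s1
  f0 <- extract_features(v, m, resample = FALSE)
  shift_by <- function(arr, s, fill) {
    out <- array(fill, dim(arr) + 4L)
    out[s + seq_len(dim(arr)[1]), s + seq_len(dim(arr)[2]),
        s + seq_len(dim(arr)[3])] <- arr
    out
  }
  v2 <- image_volume(shift_by(v$voxels, 2L, 0), v$spacing)
  m2 <- roi_mask(shift_by(m$voxels, 2L, FALSE), m$spacing)
  f1 <- extract_features(v2, m2, resample = FALSE)
  # diameters/PCA depend only on relative coordinates; everything else on
  # masked intensities -- whole-voxel shifts change nothing
  expect_equal(f1, f0, tolerance = 1e-10)
})

test_that("the per-sequence panel and patient row have the printed layout", {
  co <- generate_cohort(tiny_cohort_config(n = 4, seed = 41))
  fv <- extract_features(co$volumes[[1]]$T1W, co$masks[[1]]$r1s1)
  expect_length(fv, 107)
  fam <- sub("_.*$", "", names(fv))
  expect_equal(unname(table(fam)[c("shape", "firstorder", "glcm", "glrlm",
                                   "glszm", "gldm", "ngtdm")]),
               c(14L, 18L, 24L, 16L, 16L, 14L, 5L),
               ignore_attr = TRUE)
  row <- extract_patient(co$volumes[[1]], co$masks[[1]]$r1s1)
  expect_length(row, 428)
  expect_true(all(grepl("^(T1W|T2W|T1C|FLAIR)_", names(row))))
  # identical volumes for two sequences give identical sub-vectors
  vols <- co$volumes[[1]]
  vols$T2W <- vols$T1W
  row2 <- extract_patient(vols, co$masks[[1]]$r1s1)
  expect_equal(unname(row2[paste0("T2W_", feature_names_107())]),
               unname(row2[paste0("T1W_", feature_names_107())]))
  # missing sequence errors by name
  expect_error(extract_patient(vols[c("T1W", "T2W", "T1C")],
                               co$masks[[1]]$r1s1), "FLAIR")
})
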