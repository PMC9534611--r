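# The wavelet profile stage: filter bank inventory, the 2D DWT against
# independent references, criterion formulas, and profile assembly.

test_that("the filter bank set has 31 members with the right family split", {
  banks <- filter_banks()
  expect_length(banks, 31)
  expect_equal(sum(grepl("^bior", banks)), 11)
  expect_equal(sum(grepl("^db", banks)), 8)
  expect_equal(sum(grepl("^sym", banks)), 7)
  expect_equal(sum(grepl("^coif", banks)), 5)
  expect_identical(grep("^db", banks, value = TRUE), paste0("db", 2:9))
  expect_identical(grep("^sym", banks, value = TRUE), paste0("sym", 2:8))
  expect_identical(grep("^coif", banks, value = TRUE), paste0("coif", 1:5))
})

test_that("signals reshape to 4 rows with recorded zero padding", {
  m12 <- reshape_signal(1:12)
  expect_equal(dim(m12), c(4, 3))
  expect_equal(attr(m12, "n_pad"), 0L)
  m10 <- reshape_signal(1:10)
  expect_equal(dim(m10), c(4, 3))
  expect_equal(attr(m10, "n_pad"), 2L)
  # round trip on the unpadded cells (row-major layout)
  flat <- as.vector(t(m10))
  expect_equal(flat[1:10], 1:10)
  expect_equal(flat[11:12], c(0, 0))
  expect_error(reshape_signal(1:3), "at least 4")
})

test_that("constant matrices have vanishing detail coefficients", {
  for (bank in c("db2", "sym4", "coif1", "bior2.2")) {
    q <- dwt2_single_level(matrix(3.7, 4, 4), bank)
    expect_lt(max(abs(c(q$cH, q$cV, q$cD))), 1e-10)
    expect_equal(dim(q$cA), dim(q$cH))
    expect_equal(dim(q$cV), dim(q$cD))
  }
})

test_that("db2 coefficients match frozen reference values (symmetric mode)", {
  # independently computed with an established wavelet library on this
  # fixed 4x4 integer matrix
  M <- matrix(1:16, 4, 4, byrow = TRUE)
  q <- dwt2_single_level(M, "db2")
  ref_cA <- matrix(c(4.5, 5.267949192431123, 9.5,
                     7.571796769724491, 8.339745962155616, 12.571796769724493,
                     24.5, 25.267949192431125, 29.5), 3, 3, byrow = TRUE)
  ref_cH_col1 <- c(-3.464101615137754, 0, 3.464101615137755)
  ref_cV_row1 <- c(-0.866025403784439, 0, 0.866025403784439)
  expect_equal(q$cA, ref_cA, tolerance = 1e-12)
  expect_equal(q$cH[, 1], ref_cH_col1, tolerance = 1e-12)
  expect_equal(q$cV[1, ], ref_cV_row1, tolerance = 1e-12)
  expect_lt(max(abs(q$cD)), 1e-12)
})

test_that("the DWT equals brute-force convolve-and-downsample per family", {
  set.seed(8)
  for (bank in c("db3", "sym4", "coif1", "bior2.2", "bior1.3")) {
    f <- wavemics:::get_filter(bank)
    for (dims in list(c(4, 4), c(6, 8), c(8, 5))) {
      M <- matrix(rnorm(prod(dims)), dims[1], dims[2])
      got <- dwt2_single_level(M, bank)
      want <- oracle_dwt2(M, f$dec_lo, f$dec_hi)
      for (nm in c("cA", "cH", "cV", "cD")) {
        expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("orthogonal banks conserve energy under periodization", {
  set.seed(12)
  for (bank in c("db2", "db5", "sym4", "coif2")) {
    M <- matrix(rnorm(64), 8, 8)
    q <- dwt2_single_level(M, bank, mode = "periodization")
    e_out <- sum(q$cA^2) + sum(q$cH^2) + sum(q$cV^2) + sum(q$cD^2)
    expect_equal(e_out, sum(M^2), tolerance = 1e-10)
  }
  # biorthogonal banks are not energy preserving; no assertion there
})

test_that("unknown filter banks are rejected with the valid list", {
  expect_error(dwt2_single_level(matrix(1:16, 4), "db99"), "bior1.3")
  expect_error(build_all_profiles(
    tibble::tibble(label = factor(c("GBM", "MET"), c("GBM", "MET")),
                   a = c(1, 2), b = c(3, 4), c = c(5, 6), d = c(7, 8)),
    banks = "haar"), "valid banks")
})

test_that("matrix criteria follow their closed forms", {
  z <- matrix(0, 2, 2)
  cz <- matrix_criteria(z)
  expect_equal(unname(cz[c("max", "energy", "entropy")]), c(0, 0, 0))
  m <- matrix(c(1, -1, 1, -1), 2)
  cm <- matrix_criteria(m)
  expect_equal(cm[["energy"]], 4)
  expect_equal(cm[["entropy"]], 2)       # uniform p = 1/4 over 4 cells
  set.seed(4)
  r <- matrix(rnorm(9), 3)
  cr <- matrix_criteria(r)
  x <- as.vector(r)
  expect_equal(cr[["max"]], max(x), tolerance = 1e-12)
  expect_equal(cr[["median"]], median(x), tolerance = 1e-12)
  expect_equal(cr[["sd"]], sd(x), tolerance = 1e-12)
  p <- x^2 / sum(x^2)
  expect_equal(cr[["entropy"]], -sum(p * log2(p)), tolerance = 1e-12)
})

test_that("pair regression reproduces closed-form OLS", {
  ca <- matrix(c(1, 2, 3, 4, 5, 6), 2)
  expect_equal(unname(pair_regression(ca, 2 * ca)), c(2, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  # fixed 6-point hand computation
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1, 11.9)
  fit <- lm(y ~ x)
  got <- pair_regression(matrix(x, 2), matrix(y, 2))
  expect_equal(got[["slope"]], unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(got[["se"]], summary(fit)$coefficients[2, 2], tolerance = 1e-10)
  # degenerate cA
  dg <- pair_regression(matrix(1, 2, 3), matrix(rnorm(6), 2))
  expect_equal(unname(dg), c(0, 0), ignore_attr = TRUE)
  expect_true(attr(dg, "degenerate"))
})

test_that("whole-signal criteria are energy and waveform length", {
  expect_equal(unname(whole_signal_criteria(rep(3, 5))), c(45, 0))
  expect_equal(unname(whole_signal_criteria(c(0, 1, 0, 1))), c(2, 3))
  set.seed(5)
  v <- rnorm(17)
  w <- whole_signal_criteria(v)
  expect_equal(w[["energy"]], sum(v^2), tolerance = 1e-12)
  expect_equal(w[["wavelength"]], sum(abs(diff(v))), tolerance = 1e-12)
})

test_that("profiles have the 28 + 6 + 2 block structure", {
  p <- build_profile(as.numeric(1:12), "db5")
  expect_length(p, 36)
  nm <- wavelet_profile_names()
  expect_identical(names(p), nm)
  expect_equal(sum(grepl("^(cA|cH|cV|cD)_", nm)), 28)
  expect_equal(sum(grepl("^(slope|se)_", nm)), 6)
  expect_equal(sum(grepl("^signal_", nm)), 2)
  expect_equal(p[["signal_energy"]], sum((1:12)^2))
})

test_that("profile tables are deterministic and row-stable", {
  tbl <- tibble::tibble(
    patient_id = c("A", "B", "C"),
    label = factor(c("GBM", "MET", "GBM"), c("GBM", "MET")),
    T1W_a = c(1, 4, 1), T2W_b = c(2, 5, 2), T1C_c = c(3, 6, 3),
    FLAIR_d = c(4, 7, 4)
  )
  profs <- build_all_profiles(tbl, banks = c("db2", "coif1"))
  expect_named(profs, c("db2", "coif1"))
  expect_equal(dim(profs$db2), c(3, 38))
  # identical patients A and C get identical profiles
  expect_equal(unlist(profs$db2[1, -(1:2)]), unlist(profs$db2[3, -(1:2)]))
  # shuffling rows permutes but does not change values
  shuf <- build_all_profiles(tbl[c(2, 3, 1), ], banks = "db2")$db2
  expect_equal(dplyr::arrange(shuf, patient_id)$cA_energy,
               dplyr::arrange(profs$db2, patient_id)$cA_energy)
})

test_that("profiles scale covariantly with the input row", {
  set.seed(6)
  v <- rnorm(12)
  cs <- 2.5
  for (bank in c("db4", "bior3.3", "sym5", "coif3")) {
    p1 <- build_profile(v, bank)
    p2 <- build_profile(cs * v, bank)
    for (mat in c("cA", "cH", "cV", "cD")) {
      expect_equal(p2[[paste0(mat, "_energy")]],
                   cs^2 * p1[[paste0(mat, "_energy")]], tolerance = 1e-10)
      expect_equal(p2[[paste0(mat, "_entropy")]],
                   p1[[paste0(mat, "_entropy")]], tolerance = 1e-10)
      for (cr in c("max", "min", "mean", "median")) {
        expect_equal(p2[[paste0(mat, "_", cr)]],
                     cs * p1[[paste0(mat, "_", cr)]], tolerance = 1e-10)
      }
      expect_equal(p2[[paste0(mat, "_sd")]], cs * p1[[paste0(mat, "_sd")]],
                   tolerance = 1e-10)
    }
    for (d in c("cH", "cV", "cD")) {
      expect_equal(p2[[paste0("slope_", d)]], p1[[paste0("slope_", d)]],
                   tolerance = 1e-10)
    }
    expect_equal(p2[["signal_energy"]], cs^2 * p1[["signal_energy"]],
                 tolerance = 1e-10)
  }
})
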