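# The cohort and feature-table generators: determinism, class balance,
# perturbation behavior, and planted-signal calibration.

test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- tiny_cohort_config(n = 4, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$label, b$label)
  for (i in seq_len(nrow(a))) {
    expect_identical(a$volumes[[i]]$T1W$voxels, b$volumes[[i]]$T1W$voxels)
    expect_identical(a$masks[[i]]$r2s2$voxels, b$masks[[i]]$r2s2$voxels)
  }
})

test_that("zero reader jitter yields identical repeated masks", {
  co <- generate_cohort(tiny_cohort_config(n = 4, seed = 3, jitter = 0))
  for (i in seq_len(nrow(co))) {
    for (occ in c("r1s2", "r2s1", "r2s2")) {
      expect_identical(co$masks[[i]][[occ]]$voxels, co$masks[[i]]$r1s1$voxels)
    }
    expect_identical(co$masks[[i]]$r1s1$voxels, co$mask_true[[i]]$voxels)
  }
})

test_that("the default cohort composition is 91 patients, 51 GBM / 40 MET", {
  cfg <- cohort_config(n_patients = 91, class_balance = 51 / 91)
  co <- generate_cohort(
    cohort_config(n_patients = 91, class_balance = 51 / 91,
                  volume_shape = c(10, 10, 10),
                  tumor_radius_range = list(GBM = c(2, 3.5), MET = c(2, 3)),
                  seed = 1)
  )
  expect_equal(sum(co$label == "GBM"), 51)
  expect_equal(sum(co$label == "MET"), 40)
  expect_equal(unname(cfg$n_patients), 91L)
})

test_that("repeated segmentations overlap by at least 0.8 Dice at default jitter", {
  co <- generate_cohort(tiny_cohort_config(n = 6, seed = 11))
  occ <- c("r1s1", "r1s2", "r2s1", "r2s2")
  for (i in seq_len(nrow(co))) {
    for (a in 1:3) for (b in (a + 1):4) {
      expect_gte(dice_overlap(co$masks[[i]][[occ[a]]], co$masks[[i]][[occ[b]]]),
                 0.8)
    }
  }
})

test_that("degenerate volume shapes and configs are rejected", {
  expect_error(cohort_config(volume_shape = c(6, 20, 20)), "8 voxels")
  expect_error(cohort_config(n_patients = 2), "at least 4")
  expect_error(cohort_config(class_balance = 1), "strictly between")
  expect_error(
    cohort_config(volume_shape = c(20, 20, 20),
                  tumor_radius_range = list(GBM = c(6, 12), MET = c(4, 6))),
    "half the field of view"
  )
  expect_error(feature_table_config(n_patients = 0), "positive")
  expect_error(feature_table_config(n_informative = 1000), "cannot exceed")
})

test_that("feature tables have 428 named columns and exact planted shifts", {
  cfg <- feature_table_config(n_patients = 40, n_informative = 12,
                              effect_size = 3, noise_sd = 1e-9, seed = 5)
  tbl <- generate_feature_table(cfg)
  feats <- setdiff(names(tbl), c("patient_id", "label"))
  expect_length(feats, 428)
  expect_true(all(grepl("^(T1W|T2W|T1C|FLAIR)_", feats)))
  info <- attr(tbl, "informative")
  expect_length(info, 12)
  # with negligible noise the class-conditional mean difference is the
  # planted shift effect_size * noise_sd
  for (f in info) {
    d <- mean(tbl[[f]][tbl$label == "GBM"]) - mean(tbl[[f]][tbl$label == "MET"])
    expect_equal(d, 3e-9, tolerance = 1e-2)
  }
  expect_identical(generate_feature_table(cfg), generate_feature_table(cfg))
})

test_that("null tables (effect 0) keep two-class t-tests at the nominal level", {
  n_flagged <- 0L
  n_total <- 0L
  for (s in 1:8) {
    tbl <- generate_feature_table(
      feature_table_config(n_patients = 40, n_features_per_sequence = 25,
                           n_informative = 10, effect_size = 0, seed = s)
    )
    feats <- setdiff(names(tbl), c("patient_id", "label"))
    pv <- vapply(feats, function(f) {
      t.test(tbl[[f]] ~ tbl$label)$p.value
    }, numeric(1))
    n_flagged <- n_flagged + sum(pv < 0.05)
    n_total <- n_total + length(pv)
  }
  # binomial(800, 0.05): mean 40, sd ~6.9; allow 4 sd
  expect_lt(n_flagged / n_total, 0.05 + 4 * sqrt(0.05 * 0.95 / n_total))
})

test_that("informative-column AUC is non-decreasing in effect size", {
  mean_auc <- function(es) {
    aucs <- c()
    for (s in 1:5) {
      tbl <- generate_feature_table(
        feature_table_config(n_patients = 60, n_features_per_sequence = 10,
                             n_informative = 5, effect_size = es, seed = s)
      )
      pos <- tbl$label == "GBM"
      for (f in attr(tbl, "informative")) {
        r <- rank(tbl[[f]])
        n1 <- sum(pos); n0 <- sum(!pos)
        a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
        aucs <- c(aucs, max(a, 1 - a))
      }
    }
    mean(aucs)
  }
  curve <- vapply(c(0, 1, 2, 4), mean_auc, numeric(1))
  expect_true(all(diff(curve) > -0.02))
  expect_gt(curve[4], curve[1] + 0.2)
})
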