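# Z-score normalization (no leakage) and LASSO selection.

test_that("training columns standardize to mean 0, sd 1; validation does not", {
  tbl <- generate_feature_table(
    feature_table_config(n_patients = 40, n_features_per_sequence = 10,
                         n_informative = 5, effect_size = 2, seed = 2))
  train <- tbl[1:28, ]
  valid <- tbl[29:40, ]
  z <- zscore_fit(train)
  zt <- zscore_apply(z, train)
  feats <- setdiff(names(zt), c("patient_id", "label"))
  expect_true(all(abs(colMeans(zt[feats])) < 1e-10))
  expect_true(all(abs(apply(zt[feats], 2, sd) - 1) < 1e-10))
  zv <- zscore_apply(z, valid)
  expect_gt(max(abs(colMeans(zv[feats]))), 1e-3)   # no leakage in general
})

test_that("constant columns are dropped with a warning", {
  tbl <- generate_feature_table(
    feature_table_config(n_patients = 10, n_features_per_sequence = 5,
                         n_informative = 2, seed = 3))
  tbl$T1W_shape_x001 <- 7
  expect_warning(z <- zscore_fit(tbl), "zero-variance")
  expect_false("T1W_shape_x001" %in% z$features)
  expect_true("T1W_shape_x001" %in% z$dropped)
  expect_error(zscore_fit(tbl[1, ]), "at least 2")
})

test_that("LASSO recovers most planted informative columns", {
  hits <- 0; total <- 0
  for (seed in 1:5) {
    tbl <- generate_feature_table(
      feature_table_config(n_patients = 200, n_informative = 10,
                           effect_size = 2, seed = seed))
    z <- zscore_fit(tbl)
    sel <- lasso_select(zscore_apply(z, tbl), folds = 10, seed = seed)
    hits <- hits + sum(attr(tbl, "informative") %in% sel$features)
    total <- total + 10
  }
  expect_gte(hits / total, 0.8)
})

test_that("selection is reproducible and rejects degenerate labels", {
  tbl <- generate_feature_table(
    feature_table_config(n_patients = 60, n_features_per_sequence = 20,
                         n_informative = 6, effect_size = 1.5, seed = 9))
  z <- zscore_fit(tbl)
  zt <- zscore_apply(z, tbl)
  a <- lasso_select(zt, seed = 4)
  b <- lasso_select(zt, seed = 4)
  expect_identical(a$features, b$features)
  expect_equal(a$lambda, b$lambda)
  one <- zt
  one$label <- factor(rep("GBM", nrow(one)), levels = c("GBM", "MET"))
  expect_error(lasso_select(one), "both classes")
})

test_that("an extreme penalty empties the selection", {
  tbl <- generate_feature_table(
    feature_table_config(n_patients = 60, n_features_per_sequence = 20,
                         n_informative = 6, effect_size = 1.5, seed = 10))
  zt <- zscore_apply(zscore_fit(tbl), tbl)
  sel <- lasso_select(zt, seed = 1)
  cf <- as.matrix(coef(sel$cv$glmnet.fit, s = 1e6))[-1, 1]
  expect_equal(sum(cf != 0), 0)
})

test_that("a duplicated informative column does not kill recovery", {
  tbl <- generate_feature_table(
    feature_table_config(n_patients = 120, n_features_per_sequence = 25,
                         n_informative = 4, effect_size = 2, seed = 11))
  info <- attr(tbl, "informative")
  dup_src <- info[1]
  tbl$T1W_dup_x999 <- tbl[[dup_src]]
  zt <- zscore_apply(zscore_fit(tbl), tbl)
  sel <- lasso_select(zt, seed = 2)
  expect_true(any(c(dup_src, "T1W_dup_x999") %in% sel$features))
})

test_that("row assembly is sequence-major and canonical", {
  tbl <- tibble::tibble(
    patient_id = "P1", label = factor("GBM", c("GBM", "MET")),
    FLAIR_glcm_a = 4, T1W_shape_b = 1, T1C_glrlm_c = 3, T2W_firstorder_d = 2
  )
  out <- assemble_rows(tbl, c("FLAIR_glcm_a", "T1C_glrlm_c",
                              "T1W_shape_b", "T2W_firstorder_d"))
  expect_equal(setdiff(names(out), c("patient_id", "label")),
               c("T1W_shape_b", "T2W_firstorder_d", "T1C_glrlm_c",
                 "FLAIR_glcm_a"))
  # permuting the request yields the same canonical row
  out2 <- assemble_rows(tbl, c("T2W_firstorder_d", "FLAIR_glcm_a",
                               "T1W_shape_b", "T1C_glrlm_c"))
  expect_identical(out, out2)
  expect_error(assemble_rows(tbl, character(0)), "empty selection")
})

test_that("tidiers expose the selection compactly", {
  tbl <- generate_feature_table(
    feature_table_config(n_patients = 60, n_features_per_sequence = 20,
                         n_informative = 6, effect_size = 2, seed = 12))
  sel <- lasso_select(zscore_apply(zscore_fit(tbl), tbl), seed = 3)
  td <- tidy(sel)
  expect_named(td, c("feature", "coefficient"))
  expect_true(all(td$coefficient != 0))
  gl <- glance(sel)
  expect_equal(gl$n_selected, nrow(td))
})
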