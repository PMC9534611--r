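# Repeated CV, the evaluation grid, the DeLong test and the comparison rows.

sep_table <- function(n = 40, seed = 1) {
  # linearly separable two-class table
  set.seed(seed)
  lab <- factor(rep(c("GBM", "MET"), each = n / 2), c("GBM", "MET"))
  tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    label = lab,
    f1 = ifelse(lab == "GBM", 3, -3) + rnorm(n, sd = 0.3),
    f2 = rnorm(n),
    f3 = rnorm(n),
    f4 = rnorm(n)
  )
}

test_that("logistic regression saturates on separable data", {
  res <- repeated_cv(sep_table(), classifier_spec("LR"), folds = 5,
                     repeats = 3, seed = 1)
  expect_equal(res$auc, 1.0, tolerance = 1e-8)
  expect_gte(res$accuracy, 0.99)
  expect_gte(res$f1, 0.99)
  expect_equal(nrow(res$per_fold), 15)
})

test_that("every classifier family trains, scores in [0,1], and separates", {
  tbl <- sep_table(40, seed = 2)
  for (fam in names(default_classifiers())) {
    res <- repeated_cv(tbl, classifier_spec(fam), folds = 5, repeats = 1,
                       seed = 3)
    expect_true(all(res$scores >= 0 & res$scores <= 1), info = fam)
    expect_gte(res$auc, 0.9)
    expect_true(res$accuracy >= 0 && res$accuracy <= 1)
  }
})

test_that("permuted labels are calibrated to chance AUC", {
  tbl <- sep_table(40, seed = 7)
  null_aucs <- sapply(1:8, function(p) {
    perm <- tbl
    set.seed(p)
    perm$label <- sample(perm$label)
    repeated_cv(perm, classifier_spec("LR"), folds = 5, repeats = 2,
                seed = 50 + p)$auc
  })
  expect_lt(abs(mean(null_aucs) - 0.5), 0.05)
})

test_that("repeated CV is deterministic under a fixed seed", {
  tbl <- sep_table(30, seed = 4)
  a <- repeated_cv(tbl, classifier_spec("RF"), folds = 5, repeats = 2, seed = 9)
  b <- repeated_cv(tbl, classifier_spec("RF"), folds = 5, repeats = 2, seed = 9)
  expect_identical(a$per_fold, b$per_fold)
  expect_identical(a$scores, b$scores)
})

test_that("undersized classes and degenerate labels are rejected", {
  tbl <- sep_table(12)
  expect_error(repeated_cv(tbl[1:8, ], classifier_spec("LR"), folds = 5),
               "fewer than")
  one <- tbl
  one$label <- factor(rep("GBM", nrow(one)), c("GBM", "MET"))
  expect_error(repeated_cv(one, classifier_spec("LR")), "both classes")
})

test_that("the grid covers banks x classifiers and flags misalignment", {
  tbl <- sep_table(30, seed = 6)
  profs <- build_all_profiles(
    dplyr::rename(tbl, T1W_a = "f1", T2W_b = "f2", T1C_c = "f3",
                  FLAIR_d = "f4"),
    banks = c("db2", "sym2")
  )
  specs <- default_classifiers()[c("LR", "KNN")]
  grid <- evaluate_grid(tbl, profs, specs, folds = 5, repeats = 1, seed = 2)
  expect_equal(nrow(grid), (2 + 1) * 2)
  expect_setequal(unique(grid$bank), c("none", "db2", "sym2"))
  expect_true(all(grid$accuracy >= 0 & grid$accuracy <= 1))
  expect_true(all(grid$auc >= 0 & grid$auc <= 1))
  bad <- profs
  bad$db2 <- bad$db2[c(2:nrow(bad$db2), 1), ]
  expect_error(evaluate_grid(tbl, bad, specs, repeats = 1), "not aligned")
})

test_that("best-cell selection follows the declared tie-breaks", {
  g <- tibble::tibble(
    bank = c("none", "db5", "db2", "coif1"),
    classifier = c("LR", "LR", "RF", "RF"),
    accuracy = c(0.9, 0.91, 0.93, 0.93),
    auc = c(0.95, 0.99, 0.97, 0.97),
    f1 = c(0.9, 0.9, 0.9, 0.9),
    result = list(NULL, NULL, NULL, NULL)
  )
  class(g) <- c("wavemics_eval_grid", class(g))
  expect_equal(select_best(g)$bank, "db5")      # dominant AUC
  g$auc[2] <- 0.97
  # three-way AUC tie -> accuracy tie between db2/coif1 -> lexicographic
  expect_equal(select_best(g)$bank, "coif1")
})

test_that("identical score vectors give DeLong p = 1", {
  set.seed(11)
  y <- factor(rep(c("GBM", "MET"), each = 20), c("GBM", "MET"))
  s <- runif(40)
  expect_equal(delong_test(s, s, y)$p_value, 1)
})

test_that("the DeLong AUC equals the Mann-Whitney statistic", {
  set.seed(13)
  y <- factor(rep(c("GBM", "MET"), 20), c("GBM", "MET"))
  s1 <- runif(40) + (y == "GBM") * 0.4
  s2 <- runif(40)
  dl <- delong_test(s1, s2, y)
  expect_equal(dl$auc1, oracle_auc(s1, y == "GBM"), tolerance = 1e-12)
  expect_equal(dl$auc2, oracle_auc(s2, y == "GBM"), tolerance = 1e-12)
})

test_that("DeLong p-values track a permutation oracle within MC error", {
  set.seed(17)
  n <- 40
  y <- factor(rep(c("GBM", "MET"), each = n / 2), c("GBM", "MET"))
  base <- rnorm(n) + (y == "GBM") * 1.2
  s1 <- base + rnorm(n, sd = 0.4)
  s2 <- 0.65 * base + rnorm(n, sd = 1.1)
  p_dl <- delong_test(s1, s2, y)$p_value
  p_perm <- oracle_roc_permutation(s1, s2, y == "GBM", n_perm = 2000, seed = 3)
  se <- sqrt(p_perm * (1 - p_perm) / 2000)
  expect_lt(abs(p_dl - p_perm), max(4 * se, 0.1))
})

test_that("percent increase reproduces the published comparison arithmetic", {
  expect_equal(percent_increase(0.99, 0.88), 12.5)
  expect_equal(percent_increase(0.96, 0.55), 74.5)
  expect_equal(percent_increase(0.7, 0.7), 0)
  expect_error(percent_increase(0.9, 0), "plain_metric")
})

test_that("comparison rows are internally consistent", {
  tbl <- sep_table(30, seed = 19)
  profs <- build_all_profiles(
    dplyr::rename(tbl, T1W_a = "f1", T2W_b = "f2", T1C_c = "f3",
                  FLAIR_d = "f4"),
    banks = c("db2", "db5")
  )
  grid <- evaluate_grid(tbl, profs, default_classifiers()[c("LR", "DT")],
                        folds = 5, repeats = 1, seed = 23)
  cmp <- comparison_table(grid, "auc")
  expect_equal(nrow(cmp), 2)
  for (i in seq_len(nrow(cmp))) {
    expect_equal(cmp$pct_increase[i],
                 percent_increase(cmp$wavelet[i], cmp$plain[i]))
    wav_rows <- grid[grid$bank != "none" & grid$classifier == cmp$classifier[i], ]
    expect_equal(cmp$wavelet[i], max(wav_rows$auc))
  }
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1, na.rm = TRUE))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(29)
  y <- factor(rep(c("GBM", "MET"), 15), c("GBM", "MET"))
  s <- runif(30)
  a1 <- wavemics:::auc_score(s, y)
  expect_equal(wavemics:::auc_score(plogis(5 * s - 2), y), a1)
  expect_equal(wavemics:::auc_score(s^3, y), a1)
})
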