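test_that("feature matrix has exactly 50 named candidate columns", {
  tb <- fake_biomarker_table(n = 39)
  fm <- build_feature_matrix(tb)
  expect_equal(dim(fm$x), c(39, 50))
  expect_equal(sum(duplicated(colnames(fm$x))), 0)
  expect_equal(sum(fm$missing), 0)
  expect_equal(levels(fm$labels), c("early", "late"))
})

test_that("missing fellow-eye metrics propagate into the missingness mask", {
  tb <- fake_biomarker_table(n = 20)
  for (cl in grep("rrti_|t_fellow_|dT_|r_irl_ratio|r_orl_ratio",
                  names(tb), value = TRUE)) {
    tb[3, cl] <- NA
  }
  fm <- build_feature_matrix(tb)
  expect_true(fm$missing[3, "rrti_S8"])
  expect_true(fm$missing[3, "dT_S2"])
  expect_false(fm$missing[3, "rho_crao_c"])
  expect_false(any(fm$missing[-3, ]))
})

test_that("constant columns are flagged zero-variance and never selected", {
  tb <- fake_biomarker_table(n = 20)
  tb$rho_fellow_m2 <- 0.94
  fm <- build_feature_matrix(tb)
  expect_true("rho_fellow_m2" %in% fm$zero_variance)
  sel <- suppressWarnings(select_features(fm, k = 49))
  expect_false("rho_fellow_m2" %in% sel$feature)
})

test_that("imputation is the identity on complete data", {
  fm <- build_feature_matrix(fake_biomarker_table(n = 15))
  out <- impute_chained(fm, seed = 1)
  expect_identical(out$x, fm$x)
})

test_that("imputation fills a linearly dependent cell near its true value", {
  tb <- fake_biomarker_table(n = 25)
  truth <- tb$t_crao_S8[5]
  tb$t_crao_S8[5] <- NA                     # t_crao = t_fellow * rrti structure
  fm <- build_feature_matrix(tb)
  out <- impute_chained(fm, seed = 7)
  expect_false(anyNA(out$x[, "t_crao_S8"]))
  obs <- fm$x[!fm$missing[, "t_crao_S8"], "t_crao_S8"]
  expect_gte(out$x[5, "t_crao_S8"], min(obs))  # PMM draws observed donors
  expect_lte(out$x[5, "t_crao_S8"], max(obs))
  expect_lt(abs(out$x[5, "t_crao_S8"] - truth), 3 * sd(obs))
})

test_that("imputation never alters observed cells and is seed-deterministic", {
  tb <- fake_biomarker_table(n = 30)
  set.seed(3)
  for (cl in grep("^(t_crao_|rrti_)", names(tb), value = TRUE)) {
    tb[sample(30, 5), cl] <- NA
  }
  fm <- build_feature_matrix(tb)
  a <- impute_chained(fm, seed = 11)
  b <- impute_chained(fm, seed = 11)
  c2 <- impute_chained(fm, seed = 12)
  expect_identical(a$x, b$x)
  expect_false(identical(a$x, c2$x))
  obs <- !fm$missing
  expect_identical(a$x[obs], fm$x[obs])
})

test_that("MCAR missingness is recovered to stable column means", {
  tb <- fake_biomarker_table(n = 60)
  fm_full <- build_feature_matrix(tb)
  set.seed(8)
  cols <- grep("^(t_crao_|t_fellow_|dT_|rrti_)", colnames(fm_full$x), value = TRUE)
  tb_miss <- tb
  for (cl in cols) tb_miss[sample(60, 18), cl] <- NA    # 30% MCAR
  fm <- build_feature_matrix(tb_miss)
  out <- impute_chained(fm, seed = 21)
  for (cl in c("t_crao_S8", "rrti_S4", "dT_S2")) {
    full_mean <- mean(fm_full$x[, cl])
    expect_lt(abs(mean(out$x[, cl]) - full_mean), 0.10 * abs(full_mean) + 1e-9)
  }
})

test_that("a fully missing column is refused by name", {
  tb <- fake_biomarker_table(n = 10)
  tb$rrti_S3 <- NA_real_
  expect_error(impute_chained(build_feature_matrix(tb)), "rrti_S3")
})

test_that("selection ranks a planted signal first and gates redundancy", {
  set.seed(9)
  n <- 60
  tb <- fake_biomarker_table(n = n, signal = 0)          # kill the built-in signal
  y <- as.integer(tb$group == "late")
  tb$rho_crao_c <- y + rnorm(n, 0, 0.05)                 # planted near-label
  tb$rho_crao_m1 <- tb$rho_crao_c + rnorm(n, 0, 0.01)    # near-duplicate
  fm <- build_feature_matrix(tb)
  sel <- select_features(fm, k = 5)
  expect_true(sel$feature[1] %in% c("rho_crao_c", "rho_crao_m1"))
  # only one of the duplicated pair survives the redundancy gate
  expect_equal(sum(c("rho_crao_c", "rho_crao_m1") %in% sel$feature), 1)
  # permuted labels: the planted feature loses its standing
  fmp <- fm
  set.seed(10)
  fmp$labels <- sample(fm$labels)
  selp <- select_features(fmp, k = 5)
  expect_lt(selp$mi[1], sel$mi[1] / 2)
})

test_that("logistic report flags separation and labels itself apparent", {
  set.seed(12)
  tb <- fake_biomarker_table(n = 40, signal = 0)
  tb$rho_crao_c <- ifelse(tb$group == "late", 2, 1) + rnorm(40, 0, 0.01)
  fm <- build_feature_matrix(tb)
  rep <- fit_logistic_report(fm, c("rho_crao_c", "rrti_S8"))
  expect_true(rep$separation_flag)
  expect_true(rep$apparent)
  expect_equal(rep$roc$auc, 1.0)
  expect_equal(rep$misclassified, 0)
  expect_equal(sum(rep$confusion), 40)
})

test_that("apparent AUC under null labels stays near chance", {
  set.seed(14)
  n <- 400
  tb <- fake_biomarker_table(n = n, signal = 0)
  tb$group <- factor(sample(c("early", "late"), n, replace = TRUE),
                     levels = c("early", "late"))
  fm <- build_feature_matrix(tb)
  rep <- fit_logistic_report(fm, c("rho_crao_c", "rrti_S8", "t_crao_S4"))
  expect_lt(rep$roc$auc, 0.65)
})

test_that("the model is at least as discriminative as its best single feature", {
  tb <- fake_biomarker_table(n = 50)
  fm <- build_feature_matrix(tb)
  feats <- c("rho_crao_c", "rrti_S8", "t_crao_S6")
  rep <- fit_logistic_report(fm, feats)
  best_single <- max(vapply(feats, function(f) {
    roc(fm$x[, f], fm$labels)$auc
  }, numeric(1)))
  expect_gte(rep$roc$auc + 1e-9, best_single)
})

test_that("degenerate designs are refused", {
  tb <- fake_biomarker_table(n = 20)
  tb$rho_crao_c <- 1.5
  fm <- build_feature_matrix(tb)
  expect_error(fit_logistic_report(fm, "rho_crao_c"), "degenerate")
})
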