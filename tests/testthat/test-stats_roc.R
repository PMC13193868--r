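# independently written enumeration oracles (kept deliberately naive)
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)[x - y != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), length(d)))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  min(1, 2 * min(mean(w_all <= W + 1e-9), mean(w_all >= W - 1e-9)))
}

oracle_mw <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pool <- c(x, y)
  idx <- combn(length(pool), length(x))
  u_all <- apply(idx, 2, function(k) {
    sum(outer(pool[k], pool[-k], ">")) + 0.5 * sum(outer(pool[k], pool[-k], "=="))
  })
  list(U = U, p = min(1, 2 * min(mean(u_all <= U + 1e-9),
                                 mean(u_all >= U - 1e-9))))
}

oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  (sum(outer(s1, s0, ">")) + 0.5 * sum(outer(s1, s0, "=="))) /
    (length(s1) * length(s0))
}

test_that("signed-rank exact p matches hand results and sign enumeration", {
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), rep(0, 6))
  expect_equal(r$p_value, 2 / 2^6)           # all positive, m = 6
  expect_warning(r0 <- wilcoxon_signed_rank(1:5, 1:5), "zero")
  expect_equal(r0$p_value, 1)
  ra <- wilcoxon_signed_rank(c(-3, 3, -1, 1), rep(0, 4))
  expect_equal(ra$p_value, 1)                # antisymmetric differences
  set.seed(10)
  for (i in 1:25) {
    m <- sample(3:9, 1)
    x <- round(rnorm(m), 1)                  # rounding induces ties
    y <- round(rnorm(m), 1)
    if (all(x == y)) next
    expect_equal(wilcoxon_signed_rank(x, y, mode = "exact")$p_value,
                 oracle_wilcoxon_p(x, y), tolerance = 1e-12)
  }
})

test_that("signed-rank exact p agrees with base R where base R is exact", {
  set.seed(20)
  for (i in 1:15) {
    m <- sample(5:11, 1)
    x <- rnorm(m); y <- rnorm(m)             # continuous: no ties, no zeros
    expect_equal(wilcoxon_signed_rank(x, y, mode = "exact")$p_value,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # large-sample approximation tracks base R's corrected normal approximation
  set.seed(21)
  x <- rnorm(60); y <- rnorm(60, 0.3)
  expect_equal(wilcoxon_signed_rank(x, y, mode = "approx")$p_value,
               wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney exact p matches arrangement enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / choose(4, 2), tolerance = 1e-12)
  xi <- c(3, 1, 4, 1, 5)
  expect_equal(mann_whitney_u(xi, xi)$statistic, length(xi)^2 / 2)
  set.seed(30)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- round(rnorm(n1), 1); y <- round(rnorm(n2), 1)
    got <- mann_whitney_u(x, y, mode = "exact")
    want <- oracle_mw(x, y)
    expect_equal(got$statistic, want$U)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney approximation detects a 1-sd shift at n = 2000", {
  set.seed(31)
  x <- rnorm(2000); y <- rnorm(2000, 1)
  expect_lt(mann_whitney_u(x, y)$p_value, 1e-10)
  expect_equal(mann_whitney_u(x, y, mode = "approx")$p_value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("empirical ROC reproduces forced AUC values", {
  expect_equal(roc(c(4, 5, 6, 1, 2, 3), rep(c(TRUE, FALSE), each = 3))$auc, 1)
  expect_equal(roc(rep(7, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_equal(roc(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_error(roc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("trapezoidal AUC equals the rank statistic on random instances", {
  set.seed(40)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    r <- roc(scores, pos)
    expect_equal(r$auc, oracle_auc(scores, pos), tolerance = 1e-12)
    u <- mann_whitney_u(scores[pos], scores[!pos], mode = "approx")
    expect_equal(r$auc, u$statistic / (sum(pos) * sum(!pos)), tolerance = 1e-12)
    # cross-check against pROC on the same data
    pr <- suppressMessages(pROC::roc(pos, scores, direction = "<"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  }
})

test_that("ROC is invariant under strictly monotone score transforms", {
  set.seed(41)
  scores <- rnorm(40); pos <- runif(40) < 0.4
  a <- roc(scores, pos)$auc
  expect_equal(roc(exp(scores), pos)$auc, a, tolerance = 1e-12)
  expect_equal(roc(atan(scores) * 3 + 2, pos)$auc, a, tolerance = 1e-12)
  expect_equal(roc(-scores, pos, direction = "lesser")$auc, a, tolerance = 1e-12)
})

test_that("Youden cut-point maximizes J with the documented tie-break", {
  cp <- youden_cutpoint(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cp$youden_j, 0.5)
  expect_equal(cp$cutoff, 3.5)               # specificity-first tie-break
  expect_equal(cp$specificity, 1.0)
  cp2 <- youden_cutpoint(c(10, 11, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(cp2$sensitivity, 1)
  expect_equal(cp2$specificity, 1)
  expect_equal(cp2$youden_j, 1)
  cp3 <- youden_cutpoint(rep(5, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(cp3$youden_j, 0)
  expect_equal(cp3$cutoff, Inf)
  expect_equal(cp3$sensitivity, 0)
  expect_equal(cp3$specificity, 1)
})

test_that("Youden J equals the best tpr - fpr of the stored ROC", {
  set.seed(42)
  for (i in 1:30) {
    scores <- round(rnorm(30), 1)
    pos <- runif(30) < 0.5
    if (!any(pos) || all(pos)) next
    r <- roc(scores, pos)
    cp <- youden_cutpoint(scores, pos)
    expect_equal(cp$youden_j, max(r$tpr - r$fpr), tolerance = 1e-12)
  }
})

test_that("TTO trend recovers exact and null relationships", {
  tto <- seq(1, 40, length.out = 20)
  tr <- tto_trend(2 * tto + 1, tto)
  expect_equal(tr$r2, 1)
  expect_equal(tr$slope, 2)
  set.seed(50)
  trn <- tto_trend(rnorm(10000), runif(10000, 1, 48))
  expect_lt(trn$r2, 0.01)
  expect_true(is.na(tto_trend(rep(3, 10), 1:10)$r2))   # flagged, not zero
  expect_error(tto_trend(1:5, rep(2, 5)), "variance")
})

test_that("sector-wise AUC handles both clinical tasks and degenerate strata", {
  tb <- fake_biomarker_table(n = 60, signal = 0.05)
  a_diag <- sectorwise_auc(tb, "thickness", "diagnosis")
  expect_equal(names(a_diag), paste0("S", 1:9))
  expect_equal(unname(which.min(a_diag)), 1)           # fovea uninformative
  a_tmp <- sectorwise_auc(tb, "rrti", "temporal")
  expect_true(all(a_tmp[2:9] > 0.7))
  a_loc <- sectorwise_auc(tb, "ratio", "temporal")
  expect_equal(names(a_loc), c("m2", "m1", "c", "p1", "p2"))
  # a stratum with < 2 observations is not evaluable
  tb1 <- tb[c(which(tb$group == "early")[1], which(tb$group == "late")), ]
  expect_true(all(is.na(sectorwise_auc(tb1, "rrti", "temporal"))))
})

test_that("null diagnosis labels give chance-level sector AUCs", {
  set.seed(60)
  tb <- fake_biomarker_table(n = 80)
  for (s in paste0("S", 1:9)) tb[[paste0("t_crao_", s)]] <-
    tb[[paste0("t_fellow_", s)]] + rnorm(80, 0, 1e-6)  # fellow relabeled
  a <- sectorwise_auc(tb, "thickness", "diagnosis")
  expect_true(all(abs(a - 0.5) < 0.15))
})
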