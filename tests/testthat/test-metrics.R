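test_that("confusion tables follow the score >= cutoff rule", {
  ct <- confusion_at(c(0.9, 0.4), c(1, 0), 0.5)
  expect_equal(ct$TP, 1L); expect_equal(ct$TN, 1L)
  expect_equal(ct$FP, 0L); expect_equal(ct$FN, 0L)
  ct2 <- confusion_at(c(0.1, 0.2, 0.3), c(1, 0, 1), 0.5)
  expect_equal(ct2$TP + ct2$FP, 0L)
  # ties at the cutoff count as positive
  ct3 <- confusion_at(c(0.5, 0.5), c(1, 0), 0.5)
  expect_equal(ct3$TP, 1L); expect_equal(ct3$FP, 1L)
})

test_that("external-cohort confusion metrics reproduce published-style arithmetic", {
  # 5 positives / 55 negatives with 4 detected at the locked cutoff
  m <- classification_metrics(list(TP = 4, FN = 1, FP = 5, TN = 50))
  expect_equal(m$se_pct, 80.0)
  expect_equal(m$sp_pct, 90.9)
  expect_equal(m$bacc_pct, 85.5)
  m2 <- classification_metrics(list(TP = 3, FN = 2, FP = 22, TN = 33))
  expect_equal(m2$bacc_pct, 60.0)
  expect_equal(m2$se_pct, 60.0); expect_equal(m2$sp_pct, 60.0)
  m3 <- classification_metrics(list(TP = 5, FN = 0, FP = 0, TN = 55))
  expect_equal(m3$bacc_pct, 100.0)
  expect_equal(m3$youden, 1)
  expect_error(classification_metrics(list(TP = 0, FN = 0, FP = 1, TN = 9)),
               "class")
})

test_that("a table of reference confusion counts reproduces Se/Sp/Bacc to 1 decimal", {
  rows <- list(
    # training-style rows
    list(ct = c(7, 19, 36, 2), se = 77.8, sp = 65.5, bacc = 71.6),
    list(ct = c(9, 2, 53, 0), se = 100.0, sp = 96.4, bacc = 98.2),
    list(ct = c(9, 7, 48, 0), se = 100.0, sp = 87.3, bacc = 93.6),
    list(ct = c(9, 0, 55, 0), se = 100.0, sp = 100.0, bacc = 100.0),
    list(ct = c(9, 11, 44, 0), se = 100.0, sp = 80.0, bacc = 90.0),
    # testing-style rows
    list(ct = c(3, 22, 33, 2), se = 60.0, sp = 60.0, bacc = 60.0),
    list(ct = c(1, 10, 45, 4), se = 20.0, sp = 81.8, bacc = 50.9),
    list(ct = c(4, 22, 33, 1), se = 80.0, sp = 60.0, bacc = 70.0),
    list(ct = c(1, 0, 55, 4), se = 20.0, sp = 100.0, bacc = 60.0),
    list(ct = c(4, 5, 50, 1), se = 80.0, sp = 90.9, bacc = 85.5))
  for (r in rows) {
    m <- classification_metrics(list(TP = r$ct[1], FP = r$ct[2],
                                     TN = r$ct[3], FN = r$ct[4]))
    expect_equal(m$se_pct, r$se)
    expect_equal(m$sp_pct, r$sp)
    expect_equal(m$bacc_pct, r$bacc)
    expect_equal(m$bacc, (m$sensitivity + m$specificity) / 2, tolerance = 1e-12)
    expect_equal(m$youden, m$sensitivity + m$specificity - 1, tolerance = 1e-12)
  }
})

test_that("ROC AUC equals trapezoidal integration and detects separation", {
  set.seed(61)
  n <- 80
  y <- rbinom(n, 1, 0.4); y[1:2] <- c(0, 1)
  s <- round(runif(n), 2)
  got <- roc_auc_test(s, y)
  # trapezoidal oracle over all thresholds
  thr <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  se <- vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1))
  fp <- vapply(thr, function(t) mean(s[y == 0] >= t), numeric(1))
  trap <- sum(diff(fp) * (head(se, -1) + tail(se, -1)) / 2)
  expect_equal(got$auc, trap, tolerance = 1e-10)
  # perfect separation at 5/55 is significant
  sep <- roc_auc_test(c(rnorm(55, 0, 0.1), rnorm(5, 10, 0.1)),
                      rep(c(0, 1), c(55, 5)))
  expect_equal(sep$auc, 1)
  expect_lt(sep$p_value, 0.001)
})

test_that("null scores give a null AUC", {
  set.seed(62)
  s <- runif(1000)
  y <- rbinom(1000, 1, 0.5)
  r <- roc_auc_test(s, y)
  expect_lt(abs(r$auc - 0.5), 0.03)
  expect_gt(r$p_value, 0.001)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(63)
  s <- rnorm(60); y <- rbinom(60, 1, 0.3); y[1:2] <- c(0, 1)
  expect_equal(roc_auc_test(s, y)$auc, roc_auc_test(exp(s), y)$auc,
               tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(roc_auc_test(s, y)$auc, ref, tolerance = 1e-10)
})

test_that("decision curves honour their closed forms", {
  y <- rep(c(1, 0), c(10, 90))
  perfect <- c(rep(0.95, 10), rep(0.05, 90))
  dc <- decision_curve(perfect, y, thresholds = c(0.1, 0.2, 0.5))
  expect_equal(dc$nb_model, rep(0.1, 3), tolerance = 1e-12)  # prevalence
  expect_equal(dc$nb_none, rep(0, 3))
  expect_equal(dc$nb_all[1], 0.1 - 0.9 * (0.1 / 0.9), tolerance = 1e-12)
  # tiny threshold, everyone positive: model converges to treat-all
  dc2 <- decision_curve(runif(100, 0.5, 1), y, thresholds = 0.01)
  expect_equal(dc2$nb_model, dc2$nb_all, tolerance = 1e-12)
  expect_error(decision_curve(perfect, y, thresholds = c(0, 0.5)), "thresholds")
})

test_that("a useless model cannot beat treat-all at low thresholds", {
  set.seed(64)
  y <- rbinom(400, 1, 0.2)
  s <- runif(400)
  dc <- decision_curve(s, y, thresholds = c(0.02, 0.05, 0.1))
  expect_true(all(dc$nb_model <= dc$nb_all + 0.04))
})

test_that("report rows mirror the published column structure", {
  set.seed(65)
  X <- data.frame(f = c(rnorm(20, -1), rnorm(20, 1)))
  y <- rep(c(0, 1), each = 20)
  fit <- pcr_model(X, y, kind = "Combined", seed = 1)
  ev <- evaluate_model(fit, X, y)
  row <- report_row(fit, ev)
  expect_named(row, c("Model", "AUC", "p", "Cutoff_pct", "Se_pct", "Sp_pct",
                      "Bacc_pct", "Below_n", "Below_share_pct", "TN_n",
                      "TN_share_pct", "FN_n", "FN_share_pct", "Above_n",
                      "Above_share_pct", "FP_n", "FP_share_pct", "TP_n",
                      "TP_share_pct"))
  expect_equal(row$Below_n + row$Above_n, 40)
  expect_equal(row$TN_n + row$FN_n, row$Below_n)
  expect_equal(row$TP_n + row$FP_n, row$Above_n)
})
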