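# Cross-validation harness and the diagnostic-statistics suite.

test_that("fold plans partition the cohort with stratified proportions", {
  y <- rep(c(1L, 0L), times = c(66L, 18L))
  plan <- fold_plan(y, k = 3, stratified = TRUE, seed = 1L)
  sizes <- lengths(plan$folds)
  expect_equal(sort(sizes), c(28L, 28L, 28L))
  expect_setequal(unlist(plan$folds), seq_along(y))
  # converter proportion per fold within one subject of 66/84
  for (te in plan$folds)
    expect_lte(abs(sum(y[te] == 1L) - 22), 1)
})

test_that("cross-validation yields one out-of-fold prediction per subject", {
  set.seed(5)
  X <- matrix(rnorm(84 * 3), 84, 3)
  y <- rep(c(1L, 0L), times = c(66L, 18L))
  plan <- fold_plan(y, 3, TRUE, seed = 2L)
  # a perfect oracle factory reaches accuracy 1
  oracle <- function(xtr, ytr) {
    keep <- ytr  # closure over training labels unused; predict from the plant
    function(xt) as.integer(xt[, 1] > 0)
  }
  X[, 1] <- ifelse(y == 1L, abs(rnorm(84)) + 0.1, -abs(rnorm(84)) - 0.1)
  cv <- cross_validate(X, y, oracle, plan)
  expect_false(anyNA(cv$pred))
  expect_equal(mean(cv$pred == y), 1)
  expect_equal(sort(unique(cv$fold)), 1:3)
})

test_that("confusion matrices count the positive class correctly", {
  y <- rep(c(1L, 0L), times = c(66L, 18L))
  cm <- confusion_matrix(y, y)
  expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(66, 18, 0, 0))
  # inverting predictions swaps TP<->FN and TN<->FP
  cm2 <- confusion_matrix(y, 1L - y)
  expect_equal(c(cm2$TP, cm2$FN), c(0, 66))
  expect_equal(c(cm2$TN, cm2$FP), c(0, 18))
})

test_that("metric point estimates follow their definitions", {
  cm <- cis_reference_matrices()$shape  # TP 62, FP 9, TN 9, FN 4
  tab <- binary_metrics(cm)$table
  est <- function(m) tab$estimate[tab$metric == m]
  expect_equal(est("accuracy"), 71 / 84)
  expect_equal(est("sensitivity"), 62 / 66)
  expect_equal(est("specificity"), 9 / 18)
  expect_equal(est("ppv"), 62 / 71)
  expect_equal(est("npv"), 9 / 13)
  expect_equal(est("balanced_accuracy"), (62 / 66 + 9 / 18) / 2)
  expect_equal(est("dor"), (62 * 9) / (9 * 4))

  # all-0.5 matrix: every proportion 0.5, DOR 1
  tab2 <- binary_metrics(cm_counts(1, 1, 1, 1))$table
  expect_true(all(abs(tab2$estimate[1:6] - 0.5) < 1e-12))
  expect_equal(tab2$estimate[7], 1)

  # DOR identity with sensitivity and specificity
  se <- est("sensitivity"); sp <- est("specificity")
  expect_equal(est("dor"), se / (1 - se) * sp / (1 - sp))
})

test_that("Clopper-Pearson intervals are exact at the boundaries and calibrated", {
  expect_equal(unname(clopper_pearson(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson(10, 10)[2]), 1)
  ci <- clopper_pearson(71, 84)
  expect_equal(round(unname(ci), 2), c(0.75, 0.91))
  ci2 <- clopper_pearson(62, 66)
  expect_equal(round(unname(ci2), 2), c(0.85, 0.98))

  # empirical coverage over simulated binomial draws at p = 0.8, n = 84
  set.seed(40)
  x <- rbinom(2000, 84, 0.8)
  covered <- vapply(x, function(xi) {
    ci <- clopper_pearson(xi, 84)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.95)
})

test_that("predictive-value intervals behave at boundaries and shrink with n", {
  # degenerate PPV = 1 stays inside (0, 1]
  cm <- cm_counts(TP = 20, FP = 0, TN = 10, FN = 5)
  pv <- predictive_value_ci(cm, method = "standard")
  expect_true(pv$ppv["lower"] > 0 && pv$ppv["upper"] <= 1)
  expect_true(pv$ppv["lower"] < 1)

  # large-n consistency: widths shrink roughly like 1/sqrt(n)
  w <- vapply(c(1, 100), function(k) {
    cm <- cm_counts(62 * k, 9 * k, 9 * k, 4 * k)
    pv <- predictive_value_ci(cm, method = "standard")
    unname(pv$ppv["upper"] - pv$ppv["lower"])
  }, 0)
  expect_lt(w[2], w[1] / 5)

  # the simple binomial-logit variant is wider than the standard one here
  pv_std <- predictive_value_ci(cis_reference_matrices()$dis, method = "standard")
  pv_simple <- predictive_value_ci(cis_reference_matrices()$dis, method = "simple")
  expect_gt(pv_simple$ppv["upper"] - pv_simple$ppv["lower"],
            pv_std$ppv["upper"] - pv_std$ppv["lower"])
})

test_that("balanced-accuracy posterior interval is symmetric for symmetric matrices", {
  cm <- cm_counts(TP = 30, FP = 10, TN = 30, FN = 10)
  ci <- balanced_accuracy_interval(cm)
  centre <- mean(ci)
  # posterior of (S+P)/2 with S,P iid Beta(31,11): symmetric about its mean
  expect_equal(unname(ci[2] - centre), unname(centre - ci[1]), tolerance = 1e-3)
  # and the interval contains the point estimate for all reference matrices
  for (cm in cis_reference_matrices()) {
    tab <- binary_metrics(cm)$table
    ba <- tab$estimate[tab$metric == "balanced_accuracy"]
    ci <- balanced_accuracy_interval(cm)
    expect_true(ci[1] <= ba && ba <= ci[2])
  }
})

test_that("DOR interval requires Haldane for zero cells and matches the formula", {
  cm <- cis_reference_matrices()$dis
  d <- dor_ci(cm)
  se <- sqrt(1 / 62 + 1 / 14 + 1 / 4 + 1 / 4)
  expect_equal(unname(d["lower"]), exp(log(248 / 56) - qnorm(0.975) * se))
  expect_equal(unname(d["upper"]), exp(log(248 / 56) + qnorm(0.975) * se))

  cm0 <- cm_counts(TP = 10, FP = 0, TN = 5, FN = 2)
  expect_error(dor_ci(cm0), "haldane")
  d0 <- dor_ci(cm0, haldane = TRUE)
  expect_true(is.finite(d0["estimate"]) && is.finite(d0["upper"]))
  rep0 <- binary_metrics(cm0)
  expect_true(is.infinite(rep0$table$estimate[rep0$table$metric == "dor"]))
  expect_true(any(grepl("dor", rep0$flags)))
})

test_that("exact McNemar matches closed forms", {
  # b = 10, c = 0: p = 2 * 0.5^10
  y <- rep(1L, 10); a_ok <- rep(1L, 10); b_bad <- rep(0L, 10)
  res <- mcnemar_test(y, a_ok, b_bad)
  expect_equal(res$b, 10); expect_equal(res$c, 0)
  expect_equal(res$p_value, 2 * 0.5^10)

  # b = c: p = 1
  y2 <- rep(1L, 8)
  a2 <- c(rep(1L, 4), rep(0L, 4))
  b2 <- c(rep(0L, 4), rep(1L, 4))
  expect_equal(mcnemar_test(y2, a2, b2)$p_value, 1)

  # b = 12, c = 3: two-sided exact binomial tail sum
  y3 <- rep(1L, 15)
  a3 <- c(rep(1L, 12), rep(0L, 3))
  b3 <- c(rep(0L, 12), rep(1L, 3))
  expect_equal(mcnemar_test(y3, a3, b3)$p_value, 0.03515625)
  # zero discordant pairs
  expect_equal(mcnemar_test(y3, a3, a3)$p_value, 1)
})
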