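# Oblique random forest: separability, determinism, OOB behaviour, tuning,
# voting rules, importance scores, serialization.

test_that("separable Gaussian blobs give near-zero OOB and zero training error", {
  d <- gaussian_blobs(n = 100L, p = 5L, sep = 5, seed = 42L)
  f <- orf_fit(d$x, d$y, mtry = 3, ntree = 100, seed = 1L)
  expect_lte(f$oob_error, 0.05)
  expect_equal(mean(predict(f, d$x) != d$y), 0)
  expect_true(all(f$oob_error >= 0 & f$oob_error <= 1))
})

test_that("fitting is deterministic under a fixed seed", {
  d <- gaussian_blobs(n = 60L, p = 4L, sep = 2, seed = 9L)
  f1 <- orf_fit(d$x, d$y, mtry = 2, ntree = 50, seed = 123L)
  f2 <- orf_fit(d$x, d$y, mtry = 2, ntree = 50, seed = 123L)
  expect_identical(f1$oob_error, f2$oob_error)
  expect_identical(orf_to_json(f1), orf_to_json(f2))
})

test_that("permuted labels give OOB error near the permutation-null rate", {
  set.seed(77)
  n <- 120L
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rep(c(0L, 1L), times = c(48L, 72L))  # 60/40 imbalance
  y_perm <- sample(y)
  f <- orf_fit(X, y_perm, mtry = 3, ntree = 100, seed = 5L)
  # with no signal, error hovers around the minority-class rate
  expect_lt(abs(f$oob_error - mean(y_perm == 0L)), 0.1)
})

test_that("no linear node split separates XOR data", {
  set.seed(31)
  n <- 40L
  X <- cbind(rep(c(-1, -1, 1, 1), each = n / 4) + rnorm(n, 0, 0.05),
             rep(c(-1, 1, -1, 1), each = n / 4) + rnorm(n, 0, 0.05))
  y <- as.integer(X[, 1] * X[, 2] > 0)
  # brute-force oracle: no projection/threshold reaches impurity 0
  best <- Inf
  for (th in seq(0, pi, length.out = 181)) {
    proj <- X %*% c(cos(th), sin(th))
    o <- order(proj)
    for (i in 1:(n - 1)) {
      nl <- i; nr <- n - i
      ol <- sum(y[o[1:i]]); orr <- sum(y[o][(i + 1):n])
      g <- (nl - (ol^2 + (nl - ol)^2) / nl + nr - (orr^2 + (nr - orr)^2) / nr) / n
      best <- min(best, g)
    }
  }
  expect_gt(best, 0.05)
  # a depth-1 oblique tree (one linear split) therefore cannot be pure
  f <- orf_fit(X, y, mtry = 2, ntree = 1, max_depth = 1, seed = 2L)
  expect_gt(mean(predict(f, X) != y), 0.05)
  # while a full-depth forest solves XOR by composing splits
  f2 <- orf_fit(X, y, mtry = 2, ntree = 100, seed = 2L)
  expect_lte(f2$oob_error, 0.05)
})

test_that("pure training labels are rejected and tiny samples error", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(orf_fit(X, rep(1L, 20)), "single class")
  expect_error(orf_fit(X[1:5, ], c(0, 1, 0, 1, 0)), "at least 10")
})

test_that("vote ties break toward conversion and unanimity gives fraction 1", {
  # with mtry = p every node sees the strongly separating feature, so all
  # trees agree on all training points: unanimous vote fractions
  d <- gaussian_blobs(n = 50L, p = 3L, sep = 10, seed = 4L)
  f <- orf_fit(d$x, d$y, mtry = 3, ntree = 20, seed = 8L)
  frac <- predict(f, d$x, type = "fraction")
  expect_true(all(frac[d$y == 1] == 1))
  expect_true(all(frac[d$y == 0] == 0))
  # an exact 50/50 vote must classify as conversion (1)
  expect_identical(as.integer(0.5 >= 0.5), 1L)  # the decision rule
  X_tie <- matrix(0, 4, 3)                      # points at the boundary
  frac_tie <- predict(f, X_tie, type = "fraction")
  cls_tie <- predict(f, X_tie)
  expect_true(all(cls_tie[frac_tie == 0.5] == 1L))
})

test_that("tuning scans the ntree x mtry grid and returns the OOB argmin", {
  d <- gaussian_blobs(n = 80L, p = 18L, sep = 2.5, seed = 12L)
  tu <- orf_tune(d$x, d$y, orf_config(), seed = 3L)
  # default grid on p = 18: mtry {3, 4, 7} x ntree {100, 200, 300}
  expect_equal(nrow(tu$results), 9L)
  expect_setequal(unique(tu$results$mtry), c(3L, 4L, 7L))
  expect_setequal(unique(tu$results$ntree), c(100L, 200L, 300L))
  best_err <- tu$results$oob_error[tu$results$mtry == tu$best_mtry &
                                     tu$results$ntree == tu$best_ntree]
  expect_equal(tu$forest$oob_error, best_err)
  expect_lte(best_err, max(tu$results$oob_error))

  # degenerate single-point grid returns that point
  tu1 <- orf_tune(d$x, d$y, orf_config(mtry_grid = 4L, ntree_grid = 50L), seed = 3L)
  expect_equal(nrow(tu1$results), 1L)
  expect_equal(c(tu1$best_mtry, tu1$best_ntree), c(4L, 50L))
})

test_that("a duplicated feature does not derail the forest (ridge collinearity)", {
  d <- gaussian_blobs(n = 100L, p = 4L, sep = 3, seed = 21L)
  f0 <- orf_fit(d$x, d$y, mtry = 2, ntree = 100, seed = 6L)
  f1 <- orf_fit(cbind(d$x, d$x[, 1]), d$y, mtry = 2, ntree = 100, seed = 6L)
  expect_lt(f1$oob_error, f0$oob_error + 0.05)
})

test_that("every sample is out of bag for some tree at ntree = 100", {
  d <- gaussian_blobs(n = 100L, p = 3L, sep = 1, seed = 14L)
  f <- orf_fit(d$x, d$y, mtry = 2, ntree = 100, seed = 10L)
  oob_counts <- rowSums(f$inbag == 0)
  expect_true(all(oob_counts >= 1))
  expect_false(anyNA(f$oob_pred))
})

test_that("importance ranks a planted signal first and is reproducible", {
  set.seed(55)
  n <- 80L
  X <- matrix(rnorm(n * 5), n, 5)
  y <- as.integer(X[, 1] > 0)              # feature 1 fully determines y
  imp1 <- orf_importance(X, y, mtry = 2, ntree = 30, n_bootstrap = 10, seed = 9L)
  imp2 <- orf_importance(X, y, mtry = 2, ntree = 30, n_bootstrap = 10, seed = 9L)
  expect_identical(imp1$scores, imp2$scores)
  expect_equal(imp1$scores$feature[1], "x1")
  expect_gt(imp1$scores$mean_score[1], 0)
})

test_that("pure-noise features score non-positively on average", {
  set.seed(66)
  reps <- vapply(1:5, function(s) {
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- rep(0:1, 30)
    imp <- orf_importance(X, y, mtry = 2, ntree = 20, n_bootstrap = 5,
                          seed = 100L + s)
    mean(imp$scores$mean_score)
  }, 0)
  expect_lte(mean(reps), 0)
})

test_that("JSON serialization round-trips predictions exactly", {
  d <- gaussian_blobs(n = 60L, p = 6L, sep = 1.5, seed = 33L)
  colnames(d$x) <- paste0("f", 1:6)
  f <- orf_fit(d$x, d$y, mtry = 3, ntree = 40, seed = 17L)
  path <- tempfile(fileext = ".json")
  orf_to_json(f, path)
  f2 <- orf_from_json(path)
  expect_identical(predict(f, d$x), predict(f2, d$x))
  expect_identical(predict(f, d$x, type = "fraction"),
                   predict(f2, d$x, type = "fraction"))
  expect_equal(f2$feature_names, colnames(d$x))
})
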