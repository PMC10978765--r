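test_that("indices reproduce hand arithmetic on published group means", {
  hakim <- compute_indices(list(total_ventricles_ml = 129.2,
                                sylvian_basal_ml = 90.2,
                                high_convexity_sas_ml = 17.9))
  expect_equal(hakim$desh_index, (129.2 + 90.2) / 17.9, tolerance = 1e-12)
  expect_equal(hakim$venthi_index, 129.2 / 17.9, tolerance = 1e-12)
  expect_equal(hakim$sylhi_index, 90.2 / 17.9, tolerance = 1e-12)
  expect_equal(round(hakim$desh_index, 2), 12.26)
  expect_equal(round(hakim$venthi_index, 3), 7.218)
  expect_equal(round(hakim$sylhi_index, 3), 5.039)

  normal <- compute_indices(list(total_ventricles_ml = 26.9,
                                 sylvian_basal_ml = 42.9,
                                 high_convexity_sas_ml = 42.5))
  expect_equal(round(normal$desh_index, 3), 1.642)
  expect_equal(round(normal$venthi_index, 3), 0.633)
  expect_equal(round(normal$sylhi_index, 3), 1.009)
})

test_that("desh index is exactly venthi + sylhi and scale invariant", {
  set.seed(11)
  for (i in 1:200) {
    v <- list(total_ventricles_ml = runif(1, 1, 300),
              sylvian_basal_ml = runif(1, 1, 150),
              high_convexity_sas_ml = runif(1, 0.5, 80))
    ix <- compute_indices(v)
    expect_identical(ix$desh_index, ix$venthi_index + ix$sylhi_index)
    k <- runif(1, 0.01, 50)
    ixk <- compute_indices(lapply(v, `*`, k))
    expect_equal(unclass(ixk), unclass(ix), tolerance = 1e-12)
  }
})

test_that("index monotonicity: growing ventricles raises desh and venthi only", {
  base <- list(total_ventricles_ml = 50, sylvian_basal_ml = 40,
               high_convexity_sas_ml = 30)
  grown <- base; grown$total_ventricles_ml <- 80
  a <- compute_indices(base); b <- compute_indices(grown)
  expect_gt(b$desh_index, a$desh_index)
  expect_gt(b$venthi_index, a$venthi_index)
  expect_identical(b$sylhi_index, a$sylhi_index)
})

test_that("indices reject non-positive high-convexity volume", {
  expect_error(compute_indices(list(total_ventricles_ml = 10,
                                    sylvian_basal_ml = 10,
                                    high_convexity_sas_ml = 0)),
               "positive")
})

test_that("dice_score matches degenerate closed forms", {
  m <- array(0, c(5, 5, 5)); m[2:3, 2:3, 2:3] <- 1
  expect_equal(dice_score(m, m), 1, tolerance = 1e-6)
  empty <- array(0, c(5, 5, 5))
  expect_equal(dice_score(empty, empty), 1)   # eps/eps
  a <- array(0, c(10, 10, 1)); a[1:10, 1:10, 1] <- rep(c(1, 0), 50)
  b <- 1 - a
  expect_equal(dice_score(a, b), 1e-4 / (100 + 1e-4))
  expect_error(dice_score(a, array(0, c(9, 10, 1))), "grid")
})

test_that("dice_score equals the voxel-set oracle and is symmetric", {
  set.seed(42)
  for (i in 1:40) {
    d <- sample(2:8, 3, replace = TRUE)
    x <- array(runif(prod(d)) < 0.4, d)
    y <- array(runif(prod(d)) < 0.4, d)
    expect_identical(dice_score(x, y), dice_oracle(x, y))
    expect_identical(dice_score(x, y), dice_score(y, x))
  }
})

test_that("roc_analysis reproduces enumerated small-cohort results", {
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE),
                    n_boot = 50, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_gt(r$threshold, 0.2)
  expect_lt(r$threshold, 0.8)

  # all scores equal: ties counted one half
  r2 <- roc_analysis(rep(1, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     n_boot = 20, seed = 1)
  expect_equal(r2$auc, 0.5)

  # enumerated example: AUC 8/9, two cuts tie at sens+spec = 5/3
  suppressMessages(
    r3 <- roc_analysis(c(1, 3, 2, 4, 5, 0),
                       c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
                       n_boot = 20, seed = 1))
  expect_equal(r3$auc, 8 / 9)
  expect_true(r3$youden_tie)
  expect_equal(r3$sensitivity + r3$specificity, 5 / 3)
  expect_equal(r3$threshold, 1.5)  # tie broken toward higher sensitivity
})

test_that("roc_analysis AUC and threshold match brute-force oracles", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(6:30, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    scores <- round(rnorm(n, mean = labels), sample(c(1, 2), 1))
    r <- suppressMessages(roc_analysis(scores, labels, n_boot = 10, seed = i))
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    yo <- youden_oracle(scores, labels)
    expect_equal(r$sensitivity + r$specificity, yo$youden, tolerance = 1e-12)
    expect_equal(r$threshold, yo$threshold)
  }
})

test_that("roc_analysis agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- runif(40) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  scores <- rnorm(40, mean = 2 * labels)
  r <- suppressMessages(roc_analysis(scores, labels, n_boot = 10, seed = 1))
  pr <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                  direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("roc_analysis validates inputs", {
  expect_error(roc_analysis(1:4, c(TRUE, TRUE, TRUE, TRUE)), "both classes")
  expect_error(roc_analysis(1:3, c(TRUE, FALSE)), "length")
})

test_that("bootstrap CIs are seeded and bracket the estimate", {
  set.seed(3)
  labels <- rep(c(TRUE, FALSE), each = 15)
  scores <- rnorm(30, mean = 1.5 * labels)
  r1 <- roc_analysis(scores, labels, n_boot = 200, seed = 9)
  r2 <- roc_analysis(scores, labels, n_boot = 200, seed = 9)
  expect_identical(r1$auc_ci, r2$auc_ci)
  expect_lte(r1$auc_ci[1], r1$auc + 1e-12)
  expect_gte(r1$auc_ci[2], r1$auc - 1e-12)
})

test_that("pearson_with_ci matches the closed-form estimator", {
  expect_equal(pearson_with_ci(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_with_ci(1:10, -(1:10))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_with_ci(x, y)$r, r_hand, tolerance = 1e-12)
  expect_error(pearson_with_ci(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_with_ci(1:2, 1:2), "3 observations")
})
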