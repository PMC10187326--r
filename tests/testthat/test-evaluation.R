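test_that("MAPE and bias reproduce hand arithmetic", {
  expect_equal(mape(c(100, 200), c(100, 200)), 0)
  expect_equal(mape(c(100, 200), c(90, 220)), 10)
  expect_equal(mape(863, 971), abs(971 - 863) / 863 * 100)
  expect_equal(mean_bias_percent(c(100, 100), c(90, 110)), 0)
  expect_equal(mean_bias_percent(c(100, 200), c(110, 220)), 10)
  expect_error(mape(c(100, 0), c(90, 10)), "positive")
})

test_that("the absolute bias never exceeds the MAPE", {
  set.seed(3)
  for (i in 1:50) {
    true <- runif(8, 100, 2000)
    pred <- true * runif(8, 0.5, 1.5)
    expect_lte(abs(mean_bias_percent(true, pred)), mape(true, pred) + 1e-12)
  }
})

test_that("Spearman correlation handles monotone maps, reversal and ties", {
  x <- c(10, 40, 20, 80, 55)
  expect_equal(spearman(x, sqrt(x) + 3), 1)
  expect_equal(spearman(x, -x^3), -1)
  # hand-ranked table with one tie: ranks x = 1,2,3,4; y = 1, 2.5, 2.5, 4
  xt <- c(5, 10, 15, 20); yt <- c(1, 7, 7, 9)
  rx <- rank(xt); ry <- rank(yt)
  hand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman(xt, yt), hand, tolerance = 1e-12)
  expect_warning(r <- spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("Bland-Altman limits are symmetric and match hand sd", {
  z <- bland_altman(c(100, 200), c(100, 200))
  expect_equal(c(z$mean_diff, z$lower, z$upper), c(0, 0, 0))
  z <- bland_altman(c(100, 100), c(90, 110))
  expect_equal(z$mean_diff, 0)
  expect_equal(z$upper, 1.96 * sd(c(-10, 10)))
  expect_equal(z$lower, -z$upper)
  set.seed(4)
  z <- bland_altman(runif(10, 500, 1500), runif(10, 500, 1500))
  expect_equal(z$upper - z$mean_diff, z$mean_diff - z$lower, tolerance = 1e-12)
  expect_equal(nrow(z$payload), 10L)
})

test_that("ICC(A,1) matches the hand ANOVA on toy tables", {
  expect_equal(icc_agreement(c(10, 20, 30, 40), c(10, 20, 30, 40)), 1)
  # one rater constant, the other varying: agreement near zero
  expect_lt(abs(icc_agreement(c(5, 5, 5), c(1, 5, 9))), 0.35)
  # 4-pair toy table against the mean-squares formula computed by hand
  a <- c(9, 6, 8, 7); b <- c(8, 5, 9, 6)
  n <- 4; k <- 2
  x <- cbind(a, b); grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  mse <- (sum((x - grand)^2) - k * sum((rowMeans(x) - grand)^2) -
            n * sum((colMeans(x) - grand)^2)) / ((n - 1) * (k - 1))
  hand <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc_agreement(a, b), hand, tolerance = 1e-12)
  expect_warning(one <- icc_agreement(c(3, 3, 3), c(3, 3, 3)), "convention")
  expect_equal(one, 1)
})

test_that("classification metrics reproduce the hand confusion table", {
  truth <- c(rep("walk", 50), rep("nonwalk", 150))
  pred <- c(rep("walk", 40), rep("nonwalk", 10),   # TP 40, FN 10
            rep("walk", 20), rep("nonwalk", 130))  # FP 20, TN 130
  m <- classification_metrics(truth, pred)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 2 * (2 / 3) * 0.8 / (2 / 3 + 0.8), tolerance = 1e-12)
  expect_equal(m$accuracy, 0.85)
  po <- 0.85
  pe <- (60 * 50 + 140 * 150) / 200^2
  expect_equal(m$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  perfect <- classification_metrics(truth, truth)
  expect_true(all(unlist(perfect[c("precision", "recall", "f1", "kappa",
                                   "accuracy")]) == 1))
})

test_that("random predictions at the base rate give near-zero kappa", {
  set.seed(9)
  truth <- sample(c("walk", "nonwalk"), 4000, replace = TRUE, prob = c(0.2, 0.8))
  kappas <- replicate(30, {
    pred <- sample(c("walk", "nonwalk"), 4000, replace = TRUE, prob = c(0.2, 0.8))
    classification_metrics(truth, pred)$kappa
  })
  expect_lt(abs(mean(kappas)), 0.03)
})

test_that("no positive predictions yields missing precision", {
  m <- classification_metrics(c("walk", "nonwalk"), c("nonwalk", "nonwalk"))
  expect_true(is.na(m$precision))
})

test_that("grouped folds partition 39 participants into sizes 3 or 4", {
  set.seed(10)
  share <- runif(39, 0, 0.6)
  names(share) <- sprintf("P%02d", 1:39)
  f <- grouped_stratified_kfold(share, k = 10, seed = 2)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) %in% c(3, 4)))
  expect_identical(f, grouped_stratified_kfold(share, k = 10, seed = 2))
  expect_false(identical(f, grouped_stratified_kfold(share, k = 10, seed = 3)))
  expect_error(grouped_stratified_kfold(share[1:5], k = 10), "at least")
})

test_that("fold walking shares stay near the global share", {
  set.seed(11)
  share <- runif(60, 0.05, 0.55)
  f <- grouped_stratified_kfold(share, k = 10, seed = 4)
  global <- mean(share)
  fold_means <- tapply(share, f, mean)
  expect_true(all(abs(fold_means - global) <= 0.10 + 1e-9))
})

test_that("the harness rejects participant leakage", {
  expect_error(wristep:::assert_disjoint(c("a", "b"), c("c"), c("a")),
               "leakage")
  expect_true(wristep:::assert_disjoint(c("a", "b"), "c", "d"))
})

test_that("metrics are invariant to participant order", {
  set.seed(12)
  true <- runif(10, 200, 2000); pred <- true * runif(10, 0.8, 1.2)
  o <- sample(10)
  expect_equal(mape(true, pred), mape(true[o], pred[o]))
  expect_equal(mean_bias_percent(true, pred), mean_bias_percent(true[o], pred[o]))
  expect_equal(spearman(true, pred), spearman(true[o], pred[o]))
})

test_that("cross-validation recovers steps and labels on a small cohort", {
  cohort <- shared_cohort()
  res <- run_cv(cohort, k = 4, seed = 8,
                grid = default_peak_grid(prominence_step = 0.15,
                                         distance_step = 0.3,
                                         width_step = 0.5))
  expect_equal(res$pooled$n, length(cohort))
  expect_lt(res$pooled$mape, 15)
  expect_gt(res$pooled$classification$kappa, 0.8)
  # per-fold test sets are pairwise disjoint
  ids <- unlist(lapply(res$folds, function(f) f$per_participant$id))
  expect_false(anyDuplicated(ids) > 0)
  # both pooled MAPE aggregations are reported
  expect_true(is.finite(res$pooled$mape_fold_mean))
})
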