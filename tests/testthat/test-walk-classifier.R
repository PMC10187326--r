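test_that("configuration defaults encode the training recipe", {
  cfg <- classifier_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(unname(cfg$class_balance_target), c(0.10, 0.90))
  expect_equal(cfg$early_stop_patience, 5)
  expect_equal(cfg$backend, "features")
  expect_error(classifier_config(class_balance_target = c(walk = 0.3, nonwalk = 0.8)),
               "sum to 1")
})

test_that("augmentation is an isometry and the identity draw is a no-op", {
  set.seed(3)
  w <- matrix(rnorm(300), ncol = 3)
  expect_equal(augment_window(w, angle = 0, perm = 1:3, axis = c(1, 0, 0)), w,
               tolerance = 1e-12)
  for (i in 1:5) {
    aug <- augment_window(w)
    expect_equal(sqrt(rowSums(aug^2)), sqrt(rowSums(w^2)), tolerance = 1e-9)
  }
  a <- with_seed_for_test(11, augment_window(w))
  b <- with_seed_for_test(11, augment_window(w))
  expect_identical(a, b)
})

test_that("class weights hit the 10:90 target mass and fix the matched case", {
  lab <- c(rep("walk", 10), rep("nonwalk", 90))
  expect_equal(unname(class_weights(lab)), c(1, 1), tolerance = 1e-12)
  lab5050 <- c(rep("walk", 50), rep("nonwalk", 50))
  w <- class_weights(lab5050)
  mass <- c(w["walk"] * 50, w["nonwalk"] * 50)
  expect_equal(unname(mass[1] / sum(mass)), 0.10, tolerance = 1e-12)
  expect_equal(mean(w[ifelse(lab5050 == "walk", "walk", "nonwalk")]), 1,
               tolerance = 1e-12)
  expect_error(class_weights(rep("walk", 5)), "both classes")
})

make_separable <- function(n_walk, n_nonwalk, seed) {
  with_seed_for_test(seed, {
    wins <- c(
      lapply(seq_len(n_walk), function(i) {
        t <- seq(0, 9.99, by = 0.01)
        cbind(0.05 * rnorm(1000), 0.05 * rnorm(1000),
              1 + 0.5 * sin(2 * pi * 1.8 * t) + 0.05 * rnorm(1000))
      }),
      lapply(seq_len(n_nonwalk), function(i)
        cbind(0.02 * rnorm(1000), 0.02 * rnorm(1000), 1 + 0.02 * rnorm(1000)))
    )
    list(windows = wins,
         labels = c(rep("walk", n_walk), rep("nonwalk", n_nonwalk)))
  })
}

test_that("a separable problem is learned to training accuracy 1.0", {
  tr <- make_separable(30, 90, 21)
  va <- make_separable(8, 24, 22)
  m <- train_classifier(tr, va, classifier_config(max_train_epochs = 400), 100)
  pred <- predict_epochs(m, tr$windows)
  expect_equal(mean(pred$label == tr$labels), 1.0)
  # held-out generalization
  pv <- predict_epochs(m, va$windows)
  expect_gte(classification_metrics(va$labels, pv$label)$kappa, 0.9)
  # determinism of prediction
  expect_identical(pred$probability,
                   predict_epochs(m, tr$windows)$probability)
})

test_that("training history and early stopping follow the patience rule", {
  tr <- make_separable(20, 60, 31)
  va <- make_separable(6, 18, 32)
  m <- train_classifier(tr, va, classifier_config(max_train_epochs = 50), 100)
  h <- m$history
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(h)))
  expect_equal(m$best_epoch, which.min(h$val_loss))
  # never returns parameters from after the best-validation epoch
  expect_lte(m$best_epoch, nrow(h))
  expect_lte(nrow(h) - m$best_epoch, classifier_config()$early_stop_patience)
})

test_that("monotonically worsening validation loss stops after the patience", {
  # validation labels opposite to training labels: every step of progress on
  # the training set worsens validation loss from epoch 1 onward
  set.seed(41)
  X <- matrix(rnorm(400), ncol = 2)
  y <- as.numeric(X[, 1] > 0)
  cfg <- classifier_config(learning_rate = 0.05, max_train_epochs = 100,
                           batch_size = 200)
  fit <- wristep:::adam_logistic(X, y, rep(1, 200), X, 1 - y, rep(1, 200), cfg)
  expect_equal(fit$best_epoch, 1L)
  expect_equal(nrow(fit$history), 1L + cfg$early_stop_patience)
})

test_that("single-class splits and rate mismatches are rejected", {
  tr <- make_separable(10, 30, 51)
  bad <- list(windows = tr$windows[1:5], labels = rep("walk", 5))
  expect_error(train_classifier(bad, tr, classifier_config(), 100), "both")
  m <- train_classifier(tr, make_separable(4, 12, 52),
                        classifier_config(max_train_epochs = 30), 100)
  expect_error(predict_epochs(m, tr$windows, sample_rate = 50), "rate")
})

test_that("invalid epochs are labelled unknown and excluded", {
  tr <- make_separable(10, 30, 61)
  m <- train_classifier(tr, make_separable(4, 12, 62),
                        classifier_config(max_train_epochs = 30), 100)
  pred <- predict_epochs(m, tr$windows[1:4],
                         valid = c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(pred$label[c(2, 4)], c("unknown", "unknown"))
  expect_true(all(is.na(pred$probability[c(2, 4)])))
})

test_that("augmented training reduces sensitivity to test-time rotation", {
  tr <- shared_training_set()
  va <- tr$val
  cfg0 <- classifier_config(max_train_epochs = 150, seed = 2)
  cfg1 <- classifier_config(max_train_epochs = 150, seed = 2,
                            augment = TRUE, n_augment = 3)
  m0 <- train_classifier(tr$train, va, cfg0, 100)
  m1 <- train_classifier(tr$train, va, cfg1, 100)
  rotated <- with_seed_for_test(77, lapply(va$windows, augment_window))
  dp <- function(m) {
    a <- predict_epochs(m, va$windows)$probability
    b <- predict_epochs(m, rotated)$probability
    mean(abs(a - b))
  }
  expect_lt(dp(m1), dp(m0))
})

test_that("the resnet backend runs end to end with a reusable encoder", {
  enc <- resnet18_1d_encoder(seed = 4)
  w <- matrix(rnorm(600), ncol = 3)
  f1 <- wristep:::resnet_forward(enc, w)
  expect_length(f1, 256L)
  expect_identical(f1, wristep:::resnet_forward(enc, w))
  # weight-loading hook round trip
  enc2 <- resnet18_1d_encoder(weights = unclass(enc))
  expect_identical(wristep:::resnet_forward(enc2, w), f1)
})
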