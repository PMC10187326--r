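#' Walk-classifier configuration
#'
#' @param backend `"features"` (handcrafted epoch features + logistic
#'   regression; the default, trainable on a desktop CPU) or `"resnet18_1d"`
#'   (an 18-layer 1-D residual network encoder with a trainable linear head;
#'   the encoder is randomly initialized unless pretrained weights are
#'   supplied via `pretrained_weights`).
#' @param learning_rate Adam step size (default 1e-4).
#' @param class_balance_target named 2-vector summing to 1: the target
#'   walking / non-walking class mass after re-weighting (default 10% / 90%,
#'   matching free-living 24-h walking prevalence).
#' @param early_stop_patience stop when validation loss has made no new
#'   minimum for this many consecutive training epochs (default 5).
#' @param max_train_epochs maximum training epochs (default 300).
#' @param batch_size mini-batch size (default 64).
#' @param augment logical: augment training windows with random rotations and
#'   axis permutations (default `FALSE`).
#' @param n_augment augmented copies per training window when `augment`.
#' @param seed integer seed for initialization, batching and augmentation.
#' @param pretrained_weights optional encoder weights for the resnet backend
#'   (a list as produced by a prior fit, or a path to an RDS file).
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(backend = c("features", "resnet18_1d"),
                              learning_rate = 1e-4,
                              class_balance_target = c(walk = 0.10, nonwalk = 0.90),
                              early_stop_patience = 5,
                              max_train_epochs = 300,
                              batch_size = 64,
                              augment = FALSE,
                              n_augment = 2,
                              seed = 1L,
                              pretrained_weights = NULL) {
  backend <- match.arg(backend)
  if (abs(sum(class_balance_target) - 1) > 1e-9)
    stopf("class_balance_target must sum to 1")
  if (early_stop_patience < 1) stopf("early_stop_patience must be >= 1")
  structure(list(backend = backend, learning_rate = learning_rate,
                 class_balance_target = class_balance_target,
                 early_stop_patience = early_stop_patience,
                 max_train_epochs = max_train_epochs, batch_size = batch_size,
                 augment = augment, n_augment = n_augment, seed = as.integer(seed),
                 pretrained_weights = pretrained_weights),
            class = "classifier_config")
}

#' Random rotation / axis-permutation augmentation
#'
#' Applies a rotation by a uniform random angle about a uniform random axis,
#' then permutes the three axes in a uniform random order. Both operations
#' are isometries: per-sample vector magnitude is preserved, so the
#' gravity-removed magnitude signal is unchanged while axis-specific
#' structure is scrambled. Pass `angle`, `axis`, `perm` to make the draw
#' explicit (e.g. `angle = 0`, `perm = 1:3` is the identity).
#'
#' @param window n x 3 numeric matrix (one epoch of triaxial samples).
#' @param angle rotation angle in radians; drawn uniformly on `[0, 2*pi)` if
#'   `NULL`.
#' @param axis unit 3-vector rotation axis; drawn uniformly on the sphere if
#'   `NULL`.
#' @param perm permutation of `1:3`; drawn uniformly if `NULL`.
#' @return the augmented n x 3 matrix.
#' @export
augment_window <- function(window, angle = NULL, axis = NULL, perm = NULL) {
  window <- as.matrix(window)
  if (ncol(window) != 3L) stopf("window must be triaxial (3 columns)")
  if (is.null(angle)) angle <- runif(1, 0, 2 * pi)
  if (is.null(axis)) {
    axis <- rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
  } else {
    axis <- axis / sqrt(sum(axis^2))
  }
  if (is.null(perm)) perm <- sample(3L)
  # Rodrigues rotation matrix
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  (window %*% t(R))[, perm, drop = FALSE]
}

#' Class weights targeting a fixed walking prevalence
#'
#' Per-class weights proportional to `target_share / empirical_share`,
#' so the weighted class mass ratio equals the target (10:90 by default) and
#' the mean per-sample weight is 1. When the empirical balance already
#' matches the target the weights are (1, 1).
#'
#' @param labels character vector of `"walk"` / `"nonwalk"` labels.
#' @param target named 2-vector of target shares summing to 1.
#' @return named numeric vector `c(walk = , nonwalk = )`.
#' @export
class_weights <- function(labels, target = c(walk = 0.10, nonwalk = 0.90)) {
  labels <- labels[!is.na(labels)]
  emp <- c(walk = mean(labels == "walk"), nonwalk = mean(labels == "nonwalk"))
  if (any(emp == 0)) stopf("both classes must be present to compute class weights")
  target[c("walk", "nonwalk")] / emp
}

#' Handcrafted per-epoch features
#'
#' For each 10-s triaxial window: mean, SD and maximum of the
#' gravity-removed magnitude; dominant frequency in the 0.5--4 Hz gait band
#' and its fraction of total spectral power; the maximum autocorrelation over
#' lags 0.25--2 s (stride periodicity); the number of magnitude bursts above
#' 0.2 g (upward threshold crossings, a crude per-epoch step-impulse count);
#' and the three inter-axis covariances.
#'
#' @param windows list of n x 3 matrices.
#' @param sample_rate sampling rate in Hz.
#' @return numeric matrix, one row per window.
#' @export
epoch_features <- function(windows, sample_rate) {
  feat <- t(vapply(windows, function(w) {
    e <- sqrt(rowSums(w^2)) - 1
    n <- length(e)
    ec <- e - mean(e)
    # spectrum of the demeaned magnitude
    sp <- Mod(fft(ec))^2
    freqs <- (seq_len(n) - 1L) * sample_rate / n
    band <- which(freqs >= 0.5 & freqs <= 4)
    tot <- sum(sp[2:floor(n / 2)]) + 1e-12
    if (length(band)) {
      dom_i <- band[which.max(sp[band])]
      dom_freq <- freqs[dom_i]
      dom_frac <- sp[dom_i] / tot
    } else {
      dom_freq <- 0; dom_frac <- 0
    }
    lags <- seq.int(max(1L, round(0.25 * sample_rate)),
                    min(n - 2L, round(2 * sample_rate)))
    denom <- sum(ec^2) + 1e-12
    acf_peak <- max(vapply(lags, function(l)
      sum(ec[1:(n - l)] * ec[(l + 1):n]) / denom, numeric(1)))
    above <- e > 0.2
    bursts <- sum(diff(above) == 1L) + as.integer(above[1])
    cv <- stats::cov(w)
    c(enmo_mean = mean(e), enmo_sd = sd(e), enmo_max = max(e),
      dom_freq = dom_freq, dom_frac = dom_frac, acf_peak = acf_peak,
      bursts = bursts, cov_xy = cv[1, 2], cov_xz = cv[1, 3], cov_yz = cv[2, 3])
  }, numeric(10)))
  feat
}

#' Extract per-epoch sample windows from a recording
#'
#' @param rec a [raw_recording].
#' @param epochs an `epoch_set` from [window_epochs()].
#' @return list of n x 3 matrices, one per epoch.
#' @export
epoch_windows <- function(rec, epochs) {
  lapply(seq_len(nrow(epochs)), function(i)
    rec$samples[epochs$start_index[i]:epochs$end_index[i], , drop = FALSE])
}

weighted_ce_loss <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

# Mini-batch Adam on weighted logistic cross-entropy over a fixed design
# matrix. Returns parameters from the best-validation-loss epoch and the full
# per-epoch loss history.
adam_logistic <- function(X, y, w, Xv, yv, wv, cfg) {
  d <- ncol(X)
  theta <- numeric(d + 1L)  # (bias, coefs)
  m <- numeric(d + 1L); v <- numeric(d + 1L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate
  n <- nrow(X)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  since_best <- 0L
  step <- 0L
  for (ep in seq_len(cfg$max_train_epochs)) {
    idx <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      bi <- idx[start:min(start + cfg$batch_size - 1L, n)]
      eta <- theta[1] + X[bi, , drop = FALSE] %*% theta[-1]
      p <- 1 / (1 + exp(-eta))
      r <- w[bi] * (as.numeric(p) - y[bi]) / sum(w[bi])
      g <- c(sum(r), as.numeric(crossprod(X[bi, , drop = FALSE], r)))
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^step); vh <- v / (1 - b2^step)
      theta <- theta - lr * mh / (sqrt(vh) + eps)
    }
    pt <- as.numeric(1 / (1 + exp(-(theta[1] + X %*% theta[-1]))))
    pv <- as.numeric(1 / (1 + exp(-(theta[1] + Xv %*% theta[-1]))))
    tl <- weighted_ce_loss(pt, y, w)
    vl <- weighted_ce_loss(pv, yv, wv)
    if (!is.finite(tl) || !is.finite(vl))
      stopf("non-finite loss at epoch %d (train %g, val %g): check inputs/learning rate",
            ep, tl, vl)
    history <- rbind(history, data.frame(epoch = ep, train_loss = tl, val_loss = vl))
    if (vl < best$loss) {  # ties count as "not decreasing"
      best <- list(loss = vl, theta = theta, epoch = ep)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$early_stop_patience) break
    }
  }
  list(theta = best$theta, best_epoch = best$epoch, history = history)
}

prepare_training_set <- function(data, cfg, sample_rate, augment) {
  windows <- data$windows
  labels <- data$labels
  keep <- !is.na(labels)
  windows <- windows[keep]; labels <- labels[keep]
  if (augment && cfg$augment && cfg$n_augment > 0) {
    aug_w <- list(); aug_l <- character(0)
    for (k in seq_len(cfg$n_augment)) {
      aug_w <- c(aug_w, lapply(windows, augment_window))
      aug_l <- c(aug_l, labels)
    }
    windows <- c(windows, aug_w)
    labels <- c(labels, aug_l)
  }
  list(windows = windows, labels = labels)
}

#' Train the epoch walk classifier
#'
#' Trains the configured backend on labelled 10-s windows with weighted
#' cross-entropy (weights from [class_weights()], targeting the configured
#' 10:90 walking:non-walking balance), Adam optimization, and early stopping:
#' training halts once validation loss has made no new minimum for
#' `early_stop_patience` consecutive epochs, and the parameters from the
#' best-validation-loss epoch are returned. Train and validation sets must be
#' participant-disjoint (the cross-validation harness enforces this).
#'
#' @param train,val lists with elements `windows` (list of n x 3 matrices)
#'   and `labels` (character `"walk"` / `"nonwalk"`, `NA` for unknown).
#' @param config a [classifier_config()].
#' @param sample_rate sampling rate in Hz of the windows.
#' @return a `trained_classifier`: backend id, fitted parameters, feature
#'   standardization, per-epoch loss history, and a config snapshot.
#' @export
train_classifier <- function(train, val, config = classifier_config(),
                             sample_rate = 100) {
  for (nm in c("train", "val")) {
    lb <- get(nm)$labels
    if (length(unique(stats::na.omit(lb))) < 2L)
      stopf("%s set must contain both walk and nonwalk epochs", nm)
  }
  with_seed(config$seed, {
    tr <- prepare_training_set(train, config, sample_rate, augment = TRUE)
    va <- prepare_training_set(val, config, sample_rate, augment = FALSE)
    wts <- class_weights(tr$labels, config$class_balance_target)
    encoder <- NULL
    if (config$backend == "features") {
      X <- epoch_features(tr$windows, sample_rate)
      Xv <- epoch_features(va$windows, sample_rate)
    } else {
      encoder <- resnet18_1d_encoder(n_in = 3L,
                                     weights = resolve_pretrained(config$pretrained_weights),
                                     seed = config$seed)
      X <- resnet_features(encoder, tr$windows)
      Xv <- resnet_features(encoder, va$windows)
    }
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd); scl[scl < 1e-12] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    Xvs <- sweep(sweep(Xv, 2, ctr), 2, scl, "/")
    y <- as.numeric(tr$labels == "walk")
    yv <- as.numeric(va$labels == "walk")
    fit <- adam_logistic(Xs, y, wts[ifelse(y == 1, "walk", "nonwalk")],
                         Xvs, yv, wts[ifelse(yv == 1, "walk", "nonwalk")],
                         config)
    structure(list(backend = config$backend, theta = fit$theta,
                   center = ctr, scale = scl, encoder = encoder,
                   class_weights = wts, history = fit$history,
                   best_epoch = fit$best_epoch, config = config,
                   sample_rate = sample_rate, version = "1"),
              class = "trained_classifier")
  })
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier> backend %s, best epoch %d/%d (val loss %.4f)\n",
              x$backend, x$best_epoch, nrow(x$history),
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Predict walking probabilities for epochs
#'
#' Probability of walking per epoch, hard-labelled at 0.5. Invalid epochs
#' (mostly-missing data) receive label `"unknown"` and `NA` probability, and
#' are excluded from downstream metrics.
#'
#' @param model a `trained_classifier`.
#' @param windows list of n x 3 matrices, one per epoch.
#' @param sample_rate sampling rate of the windows; must match training.
#' @param valid logical per-epoch validity (default all valid).
#' @return data.frame with columns `probability` and `label`.
#' @export
predict_epochs <- function(model, windows, sample_rate = model$sample_rate,
                           valid = NULL) {
  if (!isTRUE(all.equal(sample_rate, model$sample_rate)))
    stopf("sample rate %g Hz does not match the model's training rate %g Hz",
          sample_rate, model$sample_rate)
  if (is.null(valid)) valid <- rep(TRUE, length(windows))
  out <- data.frame(probability = rep(NA_real_, length(windows)),
                    label = rep("unknown", length(windows)),
                    stringsAsFactors = FALSE)
  if (!any(valid)) return(out)
  X <- if (model$backend == "features") {
    epoch_features(windows[valid], model$sample_rate)
  } else {
    resnet_features(model$encoder, windows[valid])
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  p <- as.numeric(1 / (1 + exp(-(model$theta[1] + Xs %*% model$theta[-1]))))
  out$probability[valid] <- p
  out$label[valid] <- ifelse(p >= 0.5, "walk", "nonwalk")
  out
}
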