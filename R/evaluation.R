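#' Mean absolute percent error over participants
#'
#' Unweighted mean of per-participant absolute percent errors
#' `|pred - true| / true * 100`.
#'
#' @param true,pred per-participant step counts; `true` must be positive.
#' @return percent (>= 0).
#' @export
mape <- function(true, pred) {
  if (length(true) != length(pred)) stopf("true and pred must have equal length")
  if (any(true <= 0)) stopf("MAPE undefined: all true counts must be positive")
  mean(abs(pred - true) / true) * 100
}

#' Mean signed percent bias over participants
#'
#' Mean of `(pred - true) / true * 100`; negative values indicate
#' undercounting.
#'
#' @inheritParams mape
#' @return signed percent.
#' @export
mean_bias_percent <- function(true, pred) {
  if (length(true) != length(pred)) stopf("true and pred must have equal length")
  if (any(true <= 0)) stopf("bias undefined: all true counts must be positive")
  mean((pred - true) / true) * 100
}

#' Spearman rank correlation
#'
#' Average-rank tie handling (the default of [stats::cor()]). A constant
#' vector has no rank ordering; the correlation is returned as `NA` with a
#' warning.
#'
#' @inheritParams mape
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
spearman <- function(true, pred) {
  if (length(true) < 3L) stopf("need at least 3 pairs")
  if (sd(true) == 0 || sd(pred) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  cor(true, pred, method = "spearman")
}

#' Bland-Altman agreement analysis
#'
#' Differences `pred - true`; limits of agreement are the mean difference
#' plus/minus 1.96 standard deviations. The returned payload carries the
#' per-participant (mean of pair, difference) points for plotting.
#'
#' @inheritParams mape
#' @return list with `mean_diff`, `lower`, `upper`, and `payload`
#'   (data.frame with columns `mean` and `diff`).
#' @export
bland_altman <- function(true, pred) {
  if (length(true) < 2L) stopf("need at least 2 pairs")
  d <- pred - true
  m <- mean(d)
  s <- sd(d)
  list(mean_diff = m, lower = m - 1.96 * s, upper = m + 1.96 * s,
       payload = data.frame(mean = (pred + true) / 2, diff = d))
}

#' Intraclass correlation for annotator agreement
#'
#' Two-way random effects, absolute agreement, single rater -- ICC(A,1) --
#' computed from the ANOVA mean squares of the subjects-by-raters table.
#' When both raters are constant there is no disagreement to measure; 1 is
#' returned by convention with a warning.
#'
#' @param annotator_a,annotator_b paired counts from the two annotators.
#' @return ICC in `[-1, 1]`.
#' @export
icc_agreement <- function(annotator_a, annotator_b) {
  if (length(annotator_a) != length(annotator_b)) stopf("paired counts required")
  n <- length(annotator_a)
  if (n < 2L) stopf("need at least 2 pairs")
  x <- cbind(annotator_a, annotator_b)
  if (var(annotator_a) == 0 && var(annotator_b) == 0 &&
      all(annotator_a == annotator_b)) {
    warning("zero variance in both raters: ICC = 1 by convention")
    return(1)
  }
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ms_r <- k * sum((row_m - grand)^2) / (n - 1)
  ms_c <- n * sum((col_m - grand)^2) / (k - 1)
  ss_tot <- sum((x - grand)^2)
  ss_e <- ss_tot - k * sum((row_m - grand)^2) - n * sum((col_m - grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

#' Binary classification metrics for walking detection
#'
#' Walking is the positive class. Cohen's kappa is
#' `(po - pe) / (1 - pe)` with `pe` the chance agreement from the marginal
#' label frequencies. With no positive predictions, precision (and F1) are
#' undefined and returned as `NA`.
#'
#' @param true_labels,pred_labels character vectors of `"walk"` /
#'   `"nonwalk"`; positions that are `NA`/`"unknown"` in either are dropped.
#' @return named list: `precision`, `recall`, `f1`, `kappa`, `accuracy`,
#'   and the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
classification_metrics <- function(true_labels, pred_labels) {
  keep <- !is.na(true_labels) & !is.na(pred_labels) &
    true_labels != "unknown" & pred_labels != "unknown"
  tr <- true_labels[keep]; pr <- pred_labels[keep]
  if (!any(tr == "walk") || !any(tr == "nonwalk"))
    stopf("both classes must be present in the true labels")
  tp <- sum(tr == "walk" & pr == "walk")
  fp <- sum(tr == "nonwalk" & pr == "walk")
  fn <- sum(tr == "walk" & pr == "nonwalk")
  tn <- sum(tr == "nonwalk" & pr == "nonwalk")
  n <- tp + fp + fn + tn
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (is.na(precision) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(precision = precision, recall = recall, f1 = f1, kappa = kappa,
       accuracy = po, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Participant-grouped, class-stratified k-fold assignment
#'
#' Each participant is assigned to exactly one fold (no participant's data
#' can leak across folds); fold sizes differ by at most one. Stratification
#' orders participants by their walking-epoch fraction and deals consecutive
#' blocks across folds in random order, so every fold spans the class-share
#' spectrum.
#'
#' @param walk_share named numeric vector: per-participant fraction of
#'   walking epochs (names are participant ids).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return named integer vector of fold ids (1..k) per participant.
#' @export
grouped_stratified_kfold <- function(walk_share, k = 10, seed = 1L) {
  n <- length(walk_share)
  if (n < k) stopf("need at least k = %d participants, got %d", k, n)
  ids <- names(walk_share)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  with_seed(seed, {
    ord <- order(walk_share, runif(n))  # random tie-breaks
    fold <- integer(n)
    pos <- 1L
    while (pos <= n) {
      block <- ord[pos:min(pos + k - 1L, n)]
      fold[block] <- sample(k, length(block))
      pos <- pos + k
    }
    names(fold) <- ids
    fold
  })
}

# Stop loudly if any participant id appears in more than one of the three
# partitions; run as part of the harness, not only in tests.
assert_disjoint <- function(train_ids, val_ids, test_ids) {
  all_ids <- c(train_ids, val_ids, test_ids)
  if (anyDuplicated(all_ids))
    stopf("participant leakage across train/val/test: %s",
          paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  invisible(TRUE)
}

#' Evaluation report for one set of participants
#'
#' @param true_steps,pred_steps named per-participant step totals.
#' @param true_labels,pred_labels pooled epoch labels (optional).
#' @param stratum optional stratum label (e.g. gait subtype).
#' @return an `eval_report` list with per-participant APEs, MAPE, mean bias,
#'   Spearman r, Bland-Altman limits, and classification metrics.
#' @export
eval_report <- function(true_steps, pred_steps, true_labels = NULL,
                        pred_labels = NULL, stratum = NA_character_) {
  rep <- list(
    stratum = stratum,
    n = length(true_steps),
    per_participant = data.frame(
      id = if (is.null(names(true_steps))) as.character(seq_along(true_steps))
           else names(true_steps),
      true_steps = as.numeric(true_steps),
      pred_steps = as.numeric(pred_steps),
      ape = abs(pred_steps - true_steps) / true_steps * 100),
    mape = mape(true_steps, pred_steps),
    mean_bias = mean_bias_percent(true_steps, pred_steps),
    spearman = if (length(true_steps) >= 3) spearman(true_steps, pred_steps)
               else NA_real_,
    bland_altman = if (length(true_steps) >= 2) bland_altman(true_steps, pred_steps)
                   else NULL
  )
  if (!is.null(true_labels))
    rep$classification <- classification_metrics(true_labels, pred_labels)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d participants: MAPE %.1f%%, bias %+.1f%%, rho %.3f\n",
              x$n, x$mape, x$mean_bias, x$spearman))
  if (!is.null(x$classification))
    cat(sprintf("  classification: kappa %.3f, F1 %.3f, accuracy %.3f\n",
                x$classification$kappa, x$classification$f1,
                x$classification$accuracy))
  invisible(x)
}

#' End-to-end cross-validation of the hybrid step counter
#'
#' For each fold: the fold's participants are held out for testing; the
#' remaining participants are split 80/20 (at participant granularity) into
#' training and validation; the walk classifier is trained with early
#' stopping; the HMM smoother is fitted on the validation predictions; the
#' peak heuristics are tuned on the validation recordings; and the full
#' hybrid pipeline is evaluated on the held-out participants.
#' Participant-disjointness of train/validation/test is asserted inside the
#' harness.
#'
#' @param cohort list of participants as produced by [simulate_cohort()]
#'   (each with `id`, `recording`, `epochs`, `step_times`).
#' @param k number of folds (default 10).
#' @param config a [classifier_config()].
#' @param grid peak-parameter search grid (a coarse default keeps the
#'   exhaustive search tractable per fold).
#' @param seed integer seed for fold assignment and splits.
#' @param shuffle_labels permute epoch labels within participants before
#'   training (a null control; recovered kappa should be near 0).
#' @return list with `pooled` (an [eval_report] over all test participants;
#'   `mape` is the pooled per-participant mean, `mape_fold_mean` the mean of
#'   per-fold MAPEs), `folds` (per-fold reports), and `tuned_params`.
#' @export
run_cv <- function(cohort, k = 10, config = classifier_config(),
                   grid = default_peak_grid(prominence_step = 0.1,
                                            distance_step = 0.2,
                                            width_step = 0.3),
                   seed = 1L, shuffle_labels = FALSE) {
  ids <- vapply(cohort, `[[`, character(1), "id")
  names(cohort) <- ids
  if (shuffle_labels) {
    cohort <- lapply(seq_along(cohort), function(i) {
      p <- cohort[[i]]
      p$epochs$true_label <- with_seed(derive_seed(seed, paste0("shuffle", i)),
                                       sample(p$epochs$true_label))
      p
    })
    names(cohort) <- ids
  }
  walk_share <- vapply(cohort, function(p) mean(p$epochs$true_label == "walk"),
                       numeric(1))
  folds <- grouped_stratified_kfold(walk_share, k, seed)
  per_fold <- list()
  test_rows <- list()
  pooled_true_lab <- character(0); pooled_pred_lab <- character(0)
  tuned <- list()
  for (f in sort(unique(folds))) {
    test_ids <- ids[folds == f]
    rest <- ids[folds != f]
    n_val <- max(1L, round(0.2 * length(rest)))
    val_ids <- with_seed(derive_seed(seed, paste0("fold", f)),
                         sample(rest, n_val))
    train_ids <- setdiff(rest, val_ids)
    assert_disjoint(train_ids, val_ids, test_ids)
    gather <- function(sel) {
      list(windows = do.call(c, lapply(cohort[sel], function(p)
             epoch_windows(p$recording, p$epochs))),
           labels = do.call(c, lapply(cohort[sel], function(p)
             ifelse(p$epochs$valid, p$epochs$true_label, NA_character_))))
    }
    skip_fold <- function(sel) {
      any(vapply(list(gather(sel)$labels), function(l)
        length(unique(stats::na.omit(l))) < 2L, logical(1)))
    }
    if (skip_fold(train_ids) || skip_fold(val_ids)) {
      warning(sprintf("fold %d skipped: a split contains a single class", f))
      next
    }
    model <- train_classifier(gather(train_ids), gather(val_ids), config,
                              sample_rate = cohort[[1]]$recording$sample_rate)
    # HMM fitted on validation predictions, per recording
    val_pred <- lapply(cohort[val_ids], function(p) {
      predict_epochs(model, epoch_windows(p$recording, p$epochs),
                     valid = p$epochs$valid)$label
    })
    val_true <- lapply(cohort[val_ids], function(p) p$epochs$true_label)
    hmm <- fit_hmm(val_pred, val_true)
    pp <- tune_params(cohort[val_ids], grid)
    tuned[[length(tuned) + 1L]] <- pp
    fold_true <- numeric(0); fold_pred <- numeric(0)
    for (id in test_ids) {
      p <- cohort[[id]]
      ev <- hybrid_count(p$recording, model, hmm, pp)
      fold_true[id] <- length(p$step_times)
      fold_pred[id] <- ev$total
      pooled_true_lab <- c(pooled_true_lab,
                           ifelse(p$epochs$valid, p$epochs$true_label, "unknown"))
      pooled_pred_lab <- c(pooled_pred_lab, ev$epoch_labels)
    }
    per_fold[[length(per_fold) + 1L]] <-
      eval_report(fold_true, fold_pred, stratum = sprintf("fold%d", f))
    test_rows[[length(test_rows) + 1L]] <- data.frame(id = test_ids,
                                                      true = fold_true,
                                                      pred = fold_pred)
  }
  all_rows <- do.call(rbind, test_rows)
  pooled <- eval_report(stats::setNames(all_rows$true, all_rows$id),
                        stats::setNames(all_rows$pred, all_rows$id),
                        pooled_true_lab, pooled_pred_lab,
                        stratum = "pooled")
  pooled$mape_fold_mean <- mean(vapply(per_fold, `[[`, numeric(1), "mape"))
  list(pooled = pooled, folds = per_fold, tuned_params = tuned)
}
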