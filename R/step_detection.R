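#' Peak-detection parameters
#'
#' The three heuristics governing which local maxima of the conditioned
#' signal count as steps: minimum peak prominence (g), minimum time between
#' retained peaks (s), and maximum peak width at half prominence (s).
#' Values produced by [tune_params()] lie in the search ranges
#' prominence 0.1--1 g, distance 0.2--2 s, width 0.01--1 s.
#'
#' @param prominence minimum prominence in g.
#' @param distance minimum separation between retained peaks in seconds.
#' @param width_max maximum peak width at half prominence in seconds.
#' @return an object of class `peak_params`.
#' @export
peak_params <- function(prominence, distance, width_max) {
  if (prominence <= 0 || distance <= 0 || width_max <= 0)
    stopf("peak parameters must be positive")
  structure(list(prominence = prominence, distance = distance,
                 width_max = width_max), class = "peak_params")
}

#' @export
print.peak_params <- function(x, ...) {
  cat(sprintf("<peak_params> prominence %.3g g, distance %.3g s, width <= %.3g s\n",
              x$prominence, x$distance, x$width_max))
  invisible(x)
}

# All strict local maxima of `values` with their prominence and width at
# half prominence. Computing these once lets tuning re-screen thousands of
# parameter combinations by filtering instead of re-deriving peaks.
peak_candidates <- function(values, sample_rate) {
  n <- length(values)
  if (n < 3L) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  }
  # local maxima; a flat-topped run that rises into and falls out of a
  # plateau counts once, at the plateau midpoint
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (values[i] > values[i - 1L]) {
      j <- i
      while (j < n && values[j + 1L] == values[i]) j <- j + 1L
      if (j < n && values[j + 1L] < values[i])
        idx <- c(idx, (i + j) %/% 2L)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(idx)) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0)))
  }
  prom <- numeric(length(idx))
  wid <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]; h <- values[i]
    # walk left until a higher sample or the signal start; the minimum over
    # that stretch is the left base. Same to the right.
    j <- i - 1L; lmin <- h; lbase <- i
    while (j >= 1L && values[j] <= h) {
      if (values[j] < lmin) { lmin <- values[j]; lbase <- j }
      j <- j - 1L
    }
    j <- i + 1L; rmin <- h; rbase <- i
    while (j <= n && values[j] <= h) {
      if (values[j] < rmin) { rmin <- values[j]; rbase <- j }
      j <- j + 1L
    }
    prom[k] <- h - max(lmin, rmin)
    # width at half prominence: interpolated crossings of h - prom/2,
    # bounded by the prominence bases
    ref <- h - prom[k] / 2
    j <- i
    while (j > lbase && values[j - 1L] > ref) j <- j - 1L
    left <- if (j > lbase) (j - 1L) + (values[j] - ref) / (values[j] - values[j - 1L]) * -1 + 1
            else as.numeric(lbase)
    j <- i
    while (j < rbase && values[j + 1L] > ref) j <- j + 1L
    right <- if (j < rbase) j + (values[j] - ref) / (values[j] - values[j + 1L])
             else as.numeric(rbase)
    wid[k] <- (right - left) / sample_rate
  }
  data.frame(index = idx, height = values[idx], prominence = prom, width = wid)
}

# Screen candidates by prominence / width, then greedily enforce the minimum
# distance: peaks are visited in descending height order and any
# still-unremoved lower peak closer than `distance` is removed.
select_peaks <- function(cands, params, sample_rate) {
  keep <- cands$prominence >= params$prominence & cands$width <= params$width_max
  cands <- cands[keep, , drop = FALSE]
  m <- nrow(cands)
  if (m == 0L) return(integer(0))
  min_gap <- params$distance * sample_rate - 1e-9
  ord <- order(-cands$height, cands$index)
  alive <- rep(TRUE, m)
  pos <- cands$index
  for (r in ord) {
    if (!alive[r]) next
    lo <- pos[r] - min_gap; hi <- pos[r] + min_gap
    near <- which(alive & pos > lo & pos < hi)
    alive[setdiff(near, r)] <- FALSE
  }
  sort(cands$index[alive])
}

#' Detect step peaks in a conditioned signal
#'
#' Strict local maxima of the conditioned signal whose prominence (vertical
#' distance from the peak to its lowest contour line bounded by higher
#' samples or the signal ends) is at least `params$prominence` and whose
#' width at half prominence is at most `params$width_max`; among retained
#' peaks closer than `params$distance`, lower peaks are removed greedily in
#' descending height order.
#'
#' @param signal a `conditioned_signal` from [condition_signal()], or a
#'   numeric vector (then `sample_rate` must be given).
#' @param params a [peak_params].
#' @param sample_rate sampling rate in Hz when `signal` is a plain vector.
#' @return integer vector of peak sample indices (1-based), increasing.
#' @export
find_peaks <- function(signal, params, sample_rate = NULL) {
  if (inherits(signal, "conditioned_signal")) {
    sample_rate <- signal$sample_rate
    values <- signal$values
  } else {
    if (is.null(sample_rate)) stopf("sample_rate required for a plain numeric signal")
    values <- as.numeric(signal)
  }
  select_peaks(peak_candidates(values, sample_rate), params, sample_rate)
}

make_step_events <- function(peak_idx, sample_rate, epochs, labels) {
  epoch_len <- attr(epochs, "epoch_length")
  times <- (peak_idx - 1L) / sample_rate
  ep_of <- floor(times / epoch_len) + 1L
  counts <- integer(nrow(epochs))
  walk_ep <- which(labels == "walk")
  keep <- ep_of %in% walk_ep
  times <- times[keep]; ep_of <- ep_of[keep]
  tab <- table(factor(ep_of, levels = seq_len(nrow(epochs))))
  counts <- as.integer(tab)
  structure(list(step_times = times, epoch_counts = counts,
                 epoch_labels = labels, epoch_length = epoch_len,
                 total = length(times)),
            class = "step_events")
}

#' @export
print.step_events <- function(x, ...) {
  cat(sprintf("<step_events> %d steps across %d epochs (%d walking)\n",
              x$total, length(x$epoch_counts), sum(x$epoch_labels == "walk")))
  invisible(x)
}

#' Hybrid step count for one recording
#'
#' The full per-recording pipeline: condition the signal once, classify each
#' 10-s epoch, smooth the predicted labels with the HMM, detect peaks, and
#' keep only peaks falling inside epochs whose smoothed label is walking.
#' Non-walking epochs contribute exactly zero steps.
#'
#' @param rec a [raw_recording].
#' @param model a `trained_classifier` from [train_classifier()].
#' @param hmm an [hmm_params] smoother, or `NULL` to skip smoothing.
#' @param params a [peak_params].
#' @param epoch_length epoch length in seconds (default 10).
#' @return a `step_events` object: `step_times`, per-epoch `epoch_counts`
#'   (summing to `total`), and the smoothed `epoch_labels`.
#' @export
hybrid_count <- function(rec, model, hmm, params, epoch_length = 10) {
  epochs <- window_epochs(rec, epoch_length)
  if (nrow(epochs) == 0L) {
    warning("recording shorter than one epoch: zero steps")
    es <- data.frame(); attr(es, "epoch_length") <- epoch_length
    return(structure(list(step_times = numeric(0), epoch_counts = integer(0),
                          epoch_labels = character(0),
                          epoch_length = epoch_length, total = 0L),
                     class = "step_events"))
  }
  wins <- epoch_windows(rec, epochs)
  pred <- predict_epochs(model, wins, rec$sample_rate, valid = epochs$valid)
  labels <- pred$label
  if (!is.null(hmm)) labels <- viterbi_smooth(hmm, labels)
  cond <- condition_signal(rec)
  peaks <- find_peaks(cond, params)
  make_step_events(peaks, rec$sample_rate, epochs, labels)
}

# Step counting gated by an externally supplied label sequence (used during
# tuning, where ground-truth walking labels gate the peaks).
count_steps_gated <- function(cond, epochs, labels, params) {
  peaks <- find_peaks(cond, params)
  make_step_events(peaks, cond$sample_rate, epochs, labels)
}

#' Default peak-parameter search grid
#'
#' Exhaustive-search ranges: prominence 0.1--1 g, distance 0.2--2 s, width
#' 10 ms--1 s, at configurable resolution.
#'
#' @param prominence_step,distance_step,width_step grid resolutions in g, s, s.
#' @return data.frame of grid cells with columns `prominence`, `distance`,
#'   `width_max`.
#' @export
default_peak_grid <- function(prominence_step = 0.05, distance_step = 0.1,
                              width_step = 0.05) {
  rng <- function(lo, hi, by) unique(c(seq(lo, hi, by = by), hi))
  expand.grid(prominence = rng(0.1, 1, prominence_step),
              distance = rng(0.2, 2, distance_step),
              width_max = rng(0.01, 1, width_step))
}

#' Tune the peak heuristics on validation recordings
#'
#' Exhaustive grid search minimizing the per-participant mean absolute error
#' of total step count, with ground-truth walking labels gating the peaks
#' (so the tuned parameters are not confounded by classifier error). Ties
#' are broken toward higher prominence, then longer distance, then smaller
#' width (conservative counting).
#'
#' @param val_recordings list of participants, each a list with `recording`
#'   (a [raw_recording]) and `epochs` (a labelled `epoch_set` carrying
#'   `true_label` and true `step_count`).
#' @param grid data.frame of candidate cells (see [default_peak_grid()]).
#' @return the argmin [peak_params]; the evaluated grid with per-cell MAE is
#'   attached as attribute `"search"`.
#' @export
tune_params <- function(val_recordings, grid = default_peak_grid()) {
  if (!length(val_recordings)) stopf("validation set is empty")
  if (!nrow(grid)) stopf("grid is empty")
  prep <- lapply(val_recordings, function(vp) {
    cond <- condition_signal(vp$recording)
    list(cands = peak_candidates(cond$values, cond$sample_rate),
         sample_rate = cond$sample_rate,
         epochs = vp$epochs,
         true_total = sum(vp$epochs$step_count))
  })
  mae <- vapply(seq_len(nrow(grid)), function(g) {
    pp <- peak_params(grid$prominence[g], grid$distance[g], grid$width_max[g])
    errs <- vapply(prep, function(pr) {
      idx <- select_peaks(pr$cands, pp, pr$sample_rate)
      ev <- make_step_events(idx, pr$sample_rate, pr$epochs, pr$epochs$true_label)
      abs(ev$total - pr$true_total)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  ord <- order(mae, -grid$prominence, -grid$distance, grid$width_max)
  best <- ord[1]
  out <- peak_params(grid$prominence[best], grid$distance[best], grid$width_max[best])
  attr(out, "search") <- cbind(grid, mae = mae)
  out
}
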