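# Independent reference implementations used as oracles. These deliberately
# re-derive every quantity with plain loops and explicit definitions, not by
# calling package internals.

# Naive peak detector: strict local maxima, explicit contour search for
# prominence, half-prominence width by scanning, O(m^2) greedy distance
# pruning in descending height order.
naive_find_peaks <- function(values, sample_rate, prominence, distance, width_max) {
  n <- length(values)
  if (n < 3) return(integer(0))
  # local maxima, flat tops resolved to the plateau midpoint
  maxima <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (values[i] <= values[i - 1]) { i <- i + 1; next }
    j <- i
    while (j < n && values[j + 1] == values[i]) j <- j + 1
    if (j < n && values[j + 1] < values[i]) maxima <- c(maxima, (i + j) %/% 2)
    i <- j + 1
  }
  peaks <- list()
  for (i in maxima) {
    h <- values[i]
    # left contour: everything up to the nearest strictly higher sample
    higher_l <- which(values[seq_len(i - 1)] > h)
    lo <- if (length(higher_l)) max(higher_l) + 1L else 1L
    seg_l <- values[lo:(i - 1)]
    lmin <- min(seg_l)
    lbase <- lo + max(which(seg_l == lmin)) - 1L
    higher_r <- which(values[(i + 1):n] > h)
    hi <- if (length(higher_r)) i + min(higher_r) - 1L else n
    seg_r <- values[(i + 1):hi]
    rmin <- min(seg_r)
    rbase <- i + min(which(seg_r == rmin))
    prom <- h - max(lmin, rmin)
    # width at half prominence, clamped to the bases
    ref <- h - prom / 2
    j <- i
    while (j > lbase && values[j - 1] > ref) j <- j - 1
    left <- if (j > lbase) j - (values[j] - ref) / (values[j] - values[j - 1])
            else as.numeric(lbase)
    j <- i
    while (j < rbase && values[j + 1] > ref) j <- j + 1
    right <- if (j < rbase) j + (values[j] - ref) / (values[j] - values[j + 1])
             else as.numeric(rbase)
    peaks[[length(peaks) + 1L]] <-
      c(index = i, height = h, prom = prom, width = (right - left) / sample_rate)
  }
  if (!length(peaks)) return(integer(0))
  pk <- do.call(rbind, peaks)
  pk <- pk[pk[, "prom"] >= prominence & pk[, "width"] <= width_max, , drop = FALSE]
  m <- nrow(pk)
  if (m == 0) return(integer(0))
  ord <- order(-pk[, "height"], pk[, "index"])
  removed <- rep(FALSE, m)
  min_gap <- distance * sample_rate - 1e-9
  for (a in ord) {
    if (removed[a]) next
    for (b in seq_len(m)) {
      if (b != a && !removed[b] && abs(pk[b, "index"] - pk[a, "index"]) < min_gap)
        removed[b] <- TRUE
    }
  }
  sort(as.integer(pk[!removed, "index"]))
}

# Exhaustive Viterbi: enumerate all 2^T state paths, score each, return the
# maximum log-probability (and whether the argmax is unique).
brute_force_viterbi <- function(params, predicted) {
  T_ <- length(predicted)
  obs <- match(predicted, c("walk", "nonwalk"))
  paths <- as.matrix(expand.grid(rep(list(1:2), T_)))
  lp <- log(params$prior)
  lt <- log(params$transition)
  le <- log(params$emission)
  scores <- apply(paths, 1, function(s) {
    v <- lp[s[1]] + le[s[1], obs[1]]
    if (T_ > 1) for (t in 2:T_) v <- v + lt[s[t - 1], s[t]] + le[s[t], obs[t]]
    v
  })
  best <- which.max(scores)
  srt <- sort(scores, decreasing = TRUE)
  list(path = c("walk", "nonwalk")[paths[best, ]],
       logp = srt[1],
       unique = length(srt) < 2 || srt[1] - srt[2] > 1e-9)
}

random_hmm <- function() {
  rrow <- function() { r <- runif(2, 0.05, 1); r / sum(r) }
  hmm_params(rrow(), rbind(rrow(), rrow()), rbind(rrow(), rrow()))
}

# Piecewise-smooth random test signal with occasional sharp bumps.
random_signal <- function(n) {
  base <- cumsum(rnorm(n, sd = 0.05))
  bumps <- numeric(n)
  for (k in seq_len(sample(0:6, 1))) {
    c0 <- sample(n, 1); w <- sample(2:12, 1); a <- runif(1, 0.1, 1.5)
    idx <- max(1, c0 - w):min(n, c0 + w)
    bumps[idx] <- bumps[idx] + a * exp(-((idx - c0) / (w / 2))^2)
  }
  base + bumps + rnorm(n, sd = 0.02)
}

# Small shared synthetic cohort, built once per test run.
shared_cohort_env <- new.env()
shared_cohort <- function() {
  if (is.null(shared_cohort_env$cohort))
    shared_cohort_env$cohort <- simulate_cohort(12, duration = 300, seed = 42)
  shared_cohort_env$cohort
}
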