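#' Synthetic gait scenario
#'
#' Describes a simulated wrist-worn accelerometer recording: walking bouts at
#' controlled cadence, Gaussian arm/device noise, a static gravity
#' orientation, and optional non-wear gaps. Every quantity needed to derive
#' exact ground truth (step event times, epoch walk labels) is part of the
#' scenario, so downstream components can be tested without any real data.
#'
#' @param duration recording length in seconds.
#' @param sample_rate sampling rate in Hz (default 100, the usual
#'   research-device recording rate).
#' @param bouts a data.frame with columns `start` (s), `cadence` (steps/min),
#'   `n_steps`, or a list of length-3 vectors in that order. Bouts must be
#'   non-overlapping and fit within `[0, duration]`.
#' @param step_pulse_amplitude peak acceleration of one step pulse in g.
#' @param arm_noise_sd standard deviation of per-axis Gaussian noise in g.
#' @param baseline_orientation unit 3-vector: gravity direction in the device
#'   frame.
#' @param nonwear_gaps list of `c(start, end)` second intervals flagged as
#'   non-wear (missing samples).
#' @param seed integer RNG seed; identical scenarios produce bit-identical
#'   recordings.
#' @return an object of class `gait_scenario`.
#' @export
gait_scenario <- function(duration, sample_rate = 100, bouts = list(),
                          step_pulse_amplitude = 0.4, arm_noise_sd = 0.05,
                          baseline_orientation = c(0, 0, 1),
                          nonwear_gaps = list(), seed = 1L) {
  if (duration <= 0) stopf("duration must be positive")
  if (sample_rate <= 0) stopf("sample_rate must be positive")
  if (step_pulse_amplitude < 0 || arm_noise_sd < 0)
    stopf("amplitudes must be non-negative")
  if (is.data.frame(bouts)) {
    bouts <- lapply(seq_len(nrow(bouts)),
                    function(i) c(bouts$start[i], bouts$cadence[i], bouts$n_steps[i]))
  }
  bouts <- lapply(bouts, function(b) {
    b <- as.numeric(b)
    if (length(b) != 3L) stopf("each bout must be (start, cadence, n_steps)")
    if (b[2] <= 0) stopf("bout cadence must be positive")
    if (b[3] < 1 || b[3] != round(b[3])) stopf("bout n_steps must be a positive integer")
    b
  })
  pulse_dur <- 0.25
  spans <- t(vapply(bouts, function(b) {
    c(b[1] - pulse_dur / 2, b[1] + (b[3] - 1) * 60 / b[2] + pulse_dur / 2)
  }, numeric(2)))
  if (length(bouts)) {
    if (any(spans[, 1] < 0) || any(spans[, 2] > duration))
      stopf("bout extends past the recording: bouts must lie within [0, %g] s", duration)
    o <- order(spans[, 1])
    if (any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)]))
      stopf("bouts overlap: walking bouts must be non-overlapping")
  }
  g <- as.numeric(baseline_orientation)
  if (length(g) != 3L || abs(sqrt(sum(g^2)) - 1) > 1e-6)
    stopf("baseline_orientation must be a unit 3-vector")
  nonwear_gaps <- lapply(nonwear_gaps, function(gp) {
    gp <- as.numeric(gp)
    if (length(gp) != 2L || gp[1] >= gp[2]) stopf("each non-wear gap must be (start, end) with start < end")
    gp
  })
  structure(
    list(duration = duration, sample_rate = sample_rate, bouts = bouts,
         step_pulse_amplitude = step_pulse_amplitude,
         arm_noise_sd = arm_noise_sd, baseline_orientation = g,
         nonwear_gaps = nonwear_gaps, seed = as.integer(seed),
         pulse_duration = pulse_dur),
    class = "gait_scenario"
  )
}

#' @export
print.gait_scenario <- function(x, ...) {
  cat(sprintf("<gait_scenario> %g s at %g Hz, %d bout(s), %d step(s), %d non-wear gap(s), seed %d\n",
              x$duration, x$sample_rate, length(x$bouts),
              sum(vapply(x$bouts, `[`, numeric(1), 3)),
              length(x$nonwear_gaps), x$seed))
  invisible(x)
}

#' Simulate a wrist accelerometer recording with known step events
#'
#' Each step contributes a raised-cosine acceleration pulse of 0.25 s
#' duration applied along the gravity axis (a vertical-impact proxy), so the
#' gravity-removed signal magnitude rises by exactly the pulse amplitude at
#' the step instant. Steps within a bout are spaced `60 / cadence` seconds
#' apart. Per-axis Gaussian noise emulates arm movement and sensor noise.
#' Samples inside non-wear gaps are flagged missing. Epochs of 10 s are
#' labelled walking when they contain at least four true steps.
#'
#' @param scenario a [gait_scenario].
#' @return a list with elements `recording` ([raw_recording]), `step_times`
#'   (numeric vector of true step event times in seconds), and `epochs`
#'   (labelled `epoch_set`).
#' @export
simulate_recording <- function(scenario) {
  stopifnot(inherits(scenario, "gait_scenario"))
  fs <- scenario$sample_rate
  n <- round(scenario$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  amp_t <- numeric(n)  # gravity-axis pulse amplitude over time
  step_times <- numeric(0)
  half <- scenario$pulse_duration / 2
  for (b in scenario$bouts) {
    st <- b[1] + (seq_len(b[3]) - 1L) * 60 / b[2]
    step_times <- c(step_times, st)
    for (s in st) {
      i0 <- max(1L, ceiling((s - half) * fs) + 1L)
      i1 <- min(n, floor((s + half) * fs) + 1L)
      if (i1 < i0) next
      tt <- t[i0:i1]
      amp_t[i0:i1] <- amp_t[i0:i1] + scenario$step_pulse_amplitude *
        0.5 * (1 + cos(pi * (tt - s) / half))
    }
  }
  step_times <- sort(step_times)
  g <- scenario$baseline_orientation
  xyz <- outer(1 + amp_t, g)  # gravity plus gravity-axis step pulses
  if (scenario$arm_noise_sd > 0) {
    noise <- with_seed(scenario$seed,
                       matrix(rnorm(3L * n, sd = scenario$arm_noise_sd), ncol = 3L))
    xyz <- xyz + noise
  }
  miss <- rep(FALSE, n)
  for (gp in scenario$nonwear_gaps) miss[t >= gp[1] & t < gp[2]] <- TRUE
  rec <- raw_recording(xyz, fs, missing = miss)
  epochs <- label_epochs(window_epochs(rec, 10), step_times)
  list(recording = rec, step_times = step_times, epochs = epochs)
}

#' Simulate a multi-participant synthetic cohort
#'
#' Draws per-participant scenarios with randomized bout placement, cadence
#' (80--125 steps/min), pulse amplitude and noise level, producing the mixed
#' walking / non-walking recordings used by the cross-validation harness.
#'
#' @param n_participants number of participants.
#' @param duration recording length per participant in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param seed integer seed; participant seeds are derived from it.
#' @return a list of participants, each a list with `id`, `scenario`,
#'   `recording`, `step_times`, `epochs`.
#' @export
simulate_cohort <- function(n_participants, duration = 480, sample_rate = 100,
                            seed = 1L) {
  if (n_participants < 1) stopf("n_participants must be at least 1")
  lapply(seq_len(n_participants), function(p) {
    pseed <- derive_seed(seed, paste0("participant", p))
    sc <- with_seed(pseed, {
      n_bouts <- sample(2:4, 1)
      bouts <- list()
      cursor <- runif(1, 5, 20)
      for (b in seq_len(n_bouts)) {
        cadence <- runif(1, 80, 125)
        n_steps <- sample(40:120, 1)
        len <- (n_steps - 1) * 60 / cadence + 0.5
        if (cursor + len > duration - 5) break
        bouts[[length(bouts) + 1L]] <- c(cursor, cadence, n_steps)
        cursor <- cursor + len + runif(1, 15, 60)
      }
      gait_scenario(duration, sample_rate, bouts,
                    step_pulse_amplitude = runif(1, 0.35, 0.6),
                    arm_noise_sd = runif(1, 0.03, 0.08),
                    seed = pseed)
    })
    sim <- simulate_recording(sc)
    list(id = sprintf("P%03d", p), scenario = sc, recording = sim$recording,
         step_times = sim$step_times, epochs = sim$epochs)
  })
}
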