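#' Configuration for the acceleration-threshold baseline
#'
#' A transparent threshold-crossing step counter: the gravity-removed,
#' low-pass filtered signal magnitude is scanned for upward crossings of a
#' fixed acceleration threshold, with a refractory period so one stride
#' cannot register twice. Every constant is exposed so published parameter
#' sets can be dropped in without code changes.
#'
#' @param threshold_g crossing threshold in g (default 0.1).
#' @param refractory_s minimum time between counted crossings in seconds
#'   (default 0.3, i.e. a 200 steps/min ceiling).
#' @param lowpass_hz low-pass cutoff applied before counting (default 5).
#' @return a `ducharme_config` list.
#' @export
ducharme_config <- function(threshold_g = 0.1, refractory_s = 0.3,
                            lowpass_hz = 5) {
  structure(list(threshold_g = threshold_g, refractory_s = refractory_s,
                 lowpass_hz = lowpass_hz), class = "ducharme_config")
}

#' Acceleration-threshold baseline step counter
#'
#' @param rec a [raw_recording] in g.
#' @param cfg a [ducharme_config()].
#' @return a `step_events` object (all epochs treated as walking).
#' @export
ducharme_steps <- function(rec, cfg = ducharme_config()) {
  sig <- lowpass_signal(enmo_signal(rec), rec$sample_rate, cfg$lowpass_hz)
  above <- sig > cfg$threshold_g
  ups <- which(diff(c(FALSE, above)) == 1L)
  refr <- cfg$refractory_s * rec$sample_rate
  kept <- integer(0)
  last <- -Inf
  for (i in ups) {
    if (i - last >= refr) { kept <- c(kept, i); last <- i }
  }
  epochs <- window_epochs(rec, 10)
  labels <- rep("walk", nrow(epochs))
  make_step_events(kept, rec$sample_rate, epochs, labels)
}

#' Configuration for the Verisense-style peak-screening baseline
#'
#' Staged screening of candidate peaks on the raw vector magnitude at the
#' algorithm's native 15 Hz: a magnitude floor, a periodicity window on the
#' spacing between consecutive peaks, a similarity cap on the height
#' difference of alternating peaks, and a continuity requirement that
#' several surrounding inter-peak intervals show real movement. Constants
#' are sample-count based at 15 Hz and config-exposed.
#'
#' @param native_hz operating sample rate (default 15).
#' @param mag_thres minimum peak vector magnitude in g, gravity included
#'   (default 1.2).
#' @param period_min,period_max admissible spacing between consecutive peaks
#'   in samples at `native_hz` (defaults 5 and 15, i.e. 0.33--1 s).
#' @param sim_cap maximum height difference between peaks two apart, in g
#'   (default 0.5).
#' @param cont_win number of surrounding inter-peak intervals examined for
#'   continuity (default 4).
#' @param cont_thres how many of those intervals must show variance above
#'   `var_thres` (default 3).
#' @param var_thres minimum signal variance (g^2) for an interval to count
#'   as movement (default 0.001).
#' @return a `verisense_config` list.
#' @export
verisense_config <- function(native_hz = 15, mag_thres = 1.2,
                             period_min = 5, period_max = 15,
                             sim_cap = 0.5, cont_win = 4, cont_thres = 3,
                             var_thres = 0.001) {
  structure(list(native_hz = native_hz, mag_thres = mag_thres,
                 period_min = period_min, period_max = period_max,
                 sim_cap = sim_cap, cont_win = cont_win,
                 cont_thres = cont_thres, var_thres = var_thres),
            class = "verisense_config")
}

#' Verisense-style baseline step counter
#'
#' Input below the native rate is rejected (resample upstream); input above
#' it is linearly resampled down to the native rate internally.
#'
#' @param rec a [raw_recording] in g.
#' @param cfg a [verisense_config()].
#' @return a `step_events` object (all epochs treated as walking).
#' @export
verisense_steps <- function(rec, cfg = verisense_config()) {
  if (rec$sample_rate < cfg$native_hz)
    stopf("sample rate %g Hz is below the algorithm's native %g Hz; resample the recording first",
          rec$sample_rate, cfg$native_hz)
  if (rec$sample_rate != cfg$native_hz)
    rec <- resample_recording(rec, cfg$native_hz)
  vm <- sqrt(rowSums(rec$samples^2))
  vm[rec$missing] <- 1  # non-wear reads as resting gravity
  n <- length(vm)
  steps <- integer(0)
  if (n >= 3L && stats::var(vm) > cfg$var_thres) {
    core <- 2:(n - 1)
    cand <- core[vm[core] > vm[core - 1] & vm[core] >= vm[core + 1]]
    cand <- cand[vm[cand] >= cfg$mag_thres]
    if (length(cand) >= 2L) {
      gaps <- diff(cand)
      periodic_ok <- c(FALSE, gaps >= cfg$period_min & gaps <= cfg$period_max)
      sim_ok <- rep(TRUE, length(cand))
      if (length(cand) >= 3L)
        sim_ok[3:length(cand)] <-
          abs(vm[cand[3:length(cand)]] - vm[cand[1:(length(cand) - 2L)]]) <= cfg$sim_cap
      cont_ok <- vapply(seq_along(cand), function(i) {
        lo <- max(1L, i - cfg$cont_win); hi <- min(length(cand), i + cfg$cont_win)
        if (hi - lo < 1L) return(FALSE)
        ivars <- vapply(seq(lo, hi - 1L), function(j)
          stats::var(vm[cand[j]:cand[j + 1L]]), numeric(1))
        sum(ivars > cfg$var_thres, na.rm = TRUE) >= cfg$cont_thres
      }, logical(1))
      steps <- cand[periodic_ok & sim_ok & cont_ok]
    }
  }
  epochs <- window_epochs(rec, 10)
  make_step_events(steps, rec$sample_rate, epochs, rep("walk", nrow(epochs)))
}
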