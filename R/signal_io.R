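#' Raw triaxial accelerometer recording
#'
#' Container for a uniformly sampled wrist-worn accelerometer time series in
#' units of g. Samples flagged in `missing` (e.g. non-wear, unparseable rows)
#' are carried through resampling and excluded from epoch validity counts.
#'
#' @param samples numeric matrix or data.frame with columns `x`, `y`, `z` (g).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param start_time numeric offset in seconds (default 0) of the first sample.
#' @param missing logical vector, one flag per sample; default all `FALSE`.
#'
#' @return An object of class `raw_recording`: a list with elements `samples`
#'   (n x 3 matrix), `sample_rate`, `start_time`, `missing`.
#' @export
raw_recording <- function(samples, sample_rate, start_time = 0, missing = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stopf("samples must have 3 columns (x, y, z)")
  colnames(samples) <- c("x", "y", "z")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stopf("sample_rate must be a single positive number")
  if (is.null(missing)) missing <- rep(FALSE, nrow(samples))
  if (length(missing) != nrow(samples))
    stopf("missing mask length (%d) != number of samples (%d)",
          length(missing), nrow(samples))
  missing <- as.logical(missing) | !stats::complete.cases(samples)
  structure(
    list(samples = samples, sample_rate = sample_rate,
         start_time = start_time, missing = missing),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples at %g Hz (%.1f s), %d missing (%.1f%%)\n",
              n_samples(x), x$sample_rate, duration(x),
              sum(x$missing), 100 * mean(x$missing)))
  invisible(x)
}

#' @rdname raw_recording
#' @param rec a `raw_recording`.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' @rdname raw_recording
#' @export
duration <- function(rec) n_samples(rec) / rec$sample_rate

#' @rdname raw_recording
#' @export
sample_times <- function(rec) {
  rec$start_time + (seq_len(n_samples(rec)) - 1L) / rec$sample_rate
}

#' Read a recording from CSV
#'
#' Expects columns `time`, `x`, `y`, `z`. `time` is elapsed seconds or an
#' ISO-8601 timestamp; `x`, `y`, `z` are acceleration in g. Rows with
#' unparseable values are kept in place and flagged missing. The sample rate
#' is inferred from the median timestamp increment unless given.
#'
#' @param path path to a CSV file.
#' @param format input format; only `"csv"` is supported.
#' @param sample_rate optional sampling rate in Hz, overriding inference.
#' @return a [raw_recording].
#' @export
read_recording <- function(path, format = "csv", sample_rate = NULL) {
  format <- match.arg(format, "csv")
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, colClasses = list(character = "time"),
                          blank.lines.skip = FALSE, showProgress = FALSE)
  for (col in c("time", "x", "y", "z"))
    if (!col %in% names(dt)) stopf("missing required column '%s' in %s", col, path)
  tchr <- as.character(dt$time)
  tnum <- suppressWarnings(as.numeric(tchr))
  if (anyNA(tnum) && any(!is.na(tchr) & nzchar(tchr))) {
    tpos <- suppressWarnings(
      as.numeric(as.POSIXct(tchr, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))))
    if (sum(!is.na(tpos)) > sum(!is.na(tnum))) tnum <- tpos - min(tpos, na.rm = TRUE)
  }
  ok_t <- !is.na(tnum)
  if (any(diff(tnum[ok_t]) <= 0)) stopf("timestamps in %s are not strictly increasing", path)
  xyz <- cbind(x = suppressWarnings(as.numeric(dt$x)),
               y = suppressWarnings(as.numeric(dt$y)),
               z = suppressWarnings(as.numeric(dt$z)))
  miss <- !ok_t | !stats::complete.cases(xyz)
  if (is.null(sample_rate)) {
    dts <- diff(tnum[ok_t])
    if (length(dts) < 1L) stopf("cannot infer sample rate from %s", path)
    sample_rate <- 1 / stats::median(dts)
  }
  raw_recording(xyz, sample_rate,
                start_time = if (any(ok_t)) min(tnum[ok_t]) else 0,
                missing = miss)
}

#' Write a recording to CSV
#'
#' Columns `time` (elapsed seconds), `x`, `y`, `z` in g; missing samples are
#' written as empty fields so a round trip preserves the missing mask.
#'
#' @param rec a [raw_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  xyz <- rec$samples
  xyz[rec$missing, ] <- NA_real_
  dt <- data.table::data.table(time = sample_times(rec),
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  data.table::fwrite(dt, path, na = "")
  invisible(path)
}

#' Resample a recording by linear interpolation
#'
#' Interpolates each axis onto a uniform grid at `target_hz` spanning the
#' original recording. A resampled point is flagged missing when either of
#' its bracketing source samples is missing, so non-wear spans stay missing.
#'
#' @param rec a [raw_recording].
#' @param target_hz target sampling rate in Hz.
#' @return a [raw_recording] at `target_hz`.
#' @export
resample_recording <- function(rec, target_hz) {
  if (target_hz <= 0) stopf("target_hz must be positive")
  n <- n_samples(rec)
  if (n < 2L) stopf("recording must have at least 2 samples to resample")
  t_src <- (seq_len(n) - 1L) / rec$sample_rate
  t_new <- seq(0, t_src[n], by = 1 / target_hz)
  src <- rec$samples
  src[rec$missing, ] <- 0  # masked values must not poison interpolation
  xyz <- vapply(1:3, function(j) approx(t_src, src[, j], t_new)$y,
                numeric(length(t_new)))
  miss <- approx(t_src, as.numeric(rec$missing), t_new)$y > 0
  raw_recording(xyz, target_hz, start_time = rec$start_time, missing = miss)
}

#' Partition a recording into fixed-length epochs
#'
#' Tiles the recording with non-overlapping half-open windows
#' `[start, start + epoch_length)`; a trailing partial window is discarded.
#' An epoch is valid when at least 50% of its samples are non-missing.
#'
#' @param rec a [raw_recording].
#' @param epoch_length epoch length in seconds (default 10).
#' @return an `epoch_set`: a data.frame with one row per epoch and columns
#'   `epoch`, `start` (s), `start_index`, `end_index`, `valid`, `true_label`,
#'   `predicted_label`, `step_count`; attribute `epoch_length`.
#' @export
window_epochs <- function(rec, epoch_length = 10) {
  if (epoch_length <= 0) stopf("epoch_length must be positive")
  spe <- epoch_length * rec$sample_rate
  n_ep <- floor(n_samples(rec) / spe)
  idx <- seq_len(n_ep)
  start_index <- floor((idx - 1L) * spe) + 1L
  end_index <- floor(idx * spe)
  valid <- vapply(idx, function(i) {
    mean(!rec$missing[start_index[i]:end_index[i]]) >= 0.5
  }, logical(1))
  es <- data.frame(
    epoch = idx,
    start = (idx - 1L) * epoch_length,
    start_index = start_index,
    end_index = end_index,
    valid = valid,
    true_label = rep(NA_character_, n_ep),
    predicted_label = rep(NA_character_, n_ep),
    step_count = rep(NA_real_, n_ep),
    stringsAsFactors = FALSE
  )
  attr(es, "epoch_length") <- epoch_length
  attr(es, "sample_rate") <- rec$sample_rate
  class(es) <- c("epoch_set", "data.frame")
  es
}

#' Label epochs from ground-truth step times
#'
#' An epoch is labelled walking when it contains at least `min_steps` true
#' steps (default 4 per the 10-s epoch walking definition), else non-walking.
#'
#' @param epochs an `epoch_set` from [window_epochs()].
#' @param step_times ground-truth step event times in seconds.
#' @param min_steps minimum steps per epoch to count as walking.
#' @return the `epoch_set` with `true_label` and `step_count` filled in.
#' @export
label_epochs <- function(epochs, step_times, min_steps = 4) {
  len <- attr(epochs, "epoch_length")
  counts <- vapply(seq_len(nrow(epochs)), function(i) {
    s <- epochs$start[i]
    sum(step_times >= s & step_times < s + len)
  }, numeric(1))
  epochs$step_count <- counts
  epochs$true_label <- ifelse(counts >= min_steps, "walk", "nonwalk")
  epochs
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (%d valid)\n",
              nrow(x), attr(x, "epoch_length"), sum(x$valid)))
  if (!all(is.na(x$true_label)))
    cat(sprintf("  true labels: %d walk / %d nonwalk\n",
                sum(x$true_label == "walk", na.rm = TRUE),
                sum(x$true_label == "nonwalk", na.rm = TRUE)))
  invisible(x)
}
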