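#' Gravity-removed signal magnitude (ENMO-style)
#'
#' Per-sample Euclidean norm of the three axes minus 1 g. Negative values are
#' kept (no flooring), matching the signal used for peak detection. Missing
#' samples contribute 0 (they are excluded downstream via the epoch validity
#' mask).
#'
#' @param rec a [raw_recording] with calibrated samples in g.
#' @return numeric vector, one value per sample, in g.
#' @export
enmo_signal <- function(rec) {
  xyz <- rec$samples
  xyz[rec$missing, ] <- 0
  out <- sqrt(rowSums(xyz^2)) - 1
  out[rec$missing] <- 0
  out
}

#' Saturate a signal to a symmetric range
#'
#' @param signal numeric vector in g.
#' @param limit clip limit in g (default 2): values are saturated to
#'   `[-limit, limit]`.
#' @return clipped numeric vector.
#' @export
clip_signal <- function(signal, limit = 2) {
  if (limit <= 0) stopf("clip limit must be positive")
  pmin(pmax(signal, -limit), limit)
}

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, so peak
#' positions are not shifted), with odd-symmetric signal extension at both
#' ends to suppress boundary transients. DC gain is 1.
#'
#' @param signal numeric vector.
#' @param sample_rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 5); must be below Nyquist.
#' @param order filter order (default 4).
#' @return filtered numeric vector, same length as input.
#' @export
lowpass_signal <- function(signal, sample_rate, cutoff = 5, order = 4) {
  if (cutoff >= sample_rate / 2)
    stopf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cutoff, sample_rate / 2)
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "low")
  b <- bf$b; a <- bf$a
  n <- length(signal)
  pad <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L),
                         ceiling(3 * sample_rate / cutoff)))
  if (pad < 1L) return(signal)
  ext <- c(2 * signal[1] - signal[(pad + 1L):2L],
           signal,
           2 * signal[n] - signal[(n - 1L):(n - pad)])
  # run each pass from a flushed filter state: a constant warm-up prefix long
  # enough for the slowest pole's transient to decay below 1e-12
  r <- max(Mod(polyroot(rev(a))))
  warm <- ceiling(log(1e-12) / log(min(max(r, 1e-6), 1 - 1e-9)))
  run <- function(x) {
    y <- signal::filter(b, a, c(rep(x[1], warm), x))
    as.numeric(y[-seq_len(warm)])
  }
  fwd <- run(ext)
  bwd <- rev(run(rev(fwd)))
  bwd[(pad + 1L):(pad + n)]
}

#' Condition a recording for peak detection
#'
#' The fixed pipeline: gravity-removed magnitude ([enmo_signal()]), clipped
#' to `[-clip_limit, clip_limit]` ([clip_signal()]), then zero-phase
#' low-passed at `cutoff` Hz ([lowpass_signal()]).
#'
#' @param rec a [raw_recording].
#' @param clip_limit clip limit in g (default 2).
#' @param cutoff low-pass cutoff in Hz (default 5).
#' @return an object of class `conditioned_signal`: list with `values`,
#'   `sample_rate`, `clip_limit`, `cutoff`.
#' @export
condition_signal <- function(rec, clip_limit = 2, cutoff = 5) {
  v <- lowpass_signal(clip_signal(enmo_signal(rec), clip_limit),
                      rec$sample_rate, cutoff)
  structure(list(values = v, sample_rate = rec$sample_rate,
                 clip_limit = clip_limit, cutoff = cutoff),
            class = "conditioned_signal")
}

#' @export
print.conditioned_signal <- function(x, ...) {
  cat(sprintf("<conditioned_signal> %d samples at %g Hz (clip %g g, low-pass %g Hz)\n",
              length(x$values), x$sample_rate, x$clip_limit, x$cutoff))
  invisible(x)
}
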