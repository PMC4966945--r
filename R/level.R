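#' Dominant movement frequency of a trace
#'
#' Power spectrum (mean-removed movement axis, rectangular window, plain
#' FFT) restricted to the movement band; at 105 s the frequency resolution
#' is about 0.0095 Hz, so no zero-padding is needed. For bouncing the
#' movement axis is the vertical axis; for clapping the resultant magnitude.
#' The peak must stand above the noise floor (power at least
#' \code{floor_factor} times the band's median power), otherwise the
#' frequency is indeterminate (\code{NA}). The default factor of 30 is set
#' well above the peak-to-median ratio a white-noise periodogram reaches by
#' chance (about \code{log(n_bins)/log(2)}, roughly 9 for a 105 s window),
#' while a genuine periodic movement concentrates orders of magnitude more
#' power in its peak bin.
#'
#' @param trace an [accel_trace()] covering at least \code{min_window_s}
#'   seconds.
#' @param band_hz frequency band searched, Hz.
#' @param axis movement axis; autodetected for bouncing and replaced by the
#'   resultant magnitude for clapping when \code{NULL}.
#' @param min_window_s minimum window length for usable resolution.
#' @param floor_factor peak-to-median power ratio below which no dominant
#'   peak is declared.
#' @param harmonic_frac fundamental correction: impact-like movements
#'   (clapping) put comparable power into several harmonics of the movement
#'   rate, so the raw spectral maximum can land on a harmonic. If a
#'   subharmonic \code{f_peak / k} (k = 4, 3, 2) carries at least this
#'   fraction of the peak power, the lowest such subharmonic is reported as
#'   the movement frequency. Set to \code{Inf} to disable.
#' @return frequency in Hz, or \code{NA_real_} when indeterminate.
#' @export
dominant_frequency <- function(trace, band_hz = c(0.2, 4), axis = NULL,
                               min_window_s = 30, floor_factor = 30,
                               harmonic_frac = 0.15) {
  stopifnot(inherits(trace, "accel_trace"))
  rate <- trace_rate(trace)
  if (trace_duration(trace) < min_window_s) {
    stop(sprintf("analysis window shorter than %g s; frequency resolution too coarse",
                 min_window_s))
  }
  x <- if (!is.null(axis)) {
    trace[[axis]]
  } else if (identical(attr(trace, "movement_type"), "clap")) {
    resultant_magnitude(trace)
  } else {
    trace[[detect_vertical_axis(trace)]]
  }
  x <- x - mean(x)
  n <- length(x)
  pw <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  if (!any(keep)) stop("band contains no frequency bins")
  pband <- pw[keep]
  fband <- freqs[keep]
  i <- which.max(pband)
  if (pband[i] < floor_factor * stats::median(pband)) return(NA_real_)
  f_peak <- fband[i]
  p_peak <- pband[i]
  # fundamental correction: prefer the lowest subharmonic that carries a
  # substantial share of the peak power (harmonics of a transient train)
  if (is.finite(harmonic_frac)) {
    for (k in c(4L, 3L, 2L)) {
      fc <- f_peak / k
      if (fc < band_hz[1]) next
      halfwin <- max(2 * rate / n, 0.02 * fc)
      sub <- which(abs(fband - fc) <= halfwin)
      if (length(sub) && max(pband[sub]) >= harmonic_frac * p_peak) {
        return(fband[sub][which.max(pband[sub])])
      }
    }
  }
  f_peak
}

#' Classify the produced metrical level from the dominant frequency
#'
#' Movement at the beat frequency is beat level (L = 1), at half the beat
#' frequency the two-beat level (L = 2, every second beat), at a quarter the
#' four-beat level (L = 4). A level is assigned when the dominant frequency
#' is within \code{tolerance} (relative) of \code{beat_freq / L}; the
#' smallest qualifying L wins. Otherwise the trial is off-tempo: produced at
#' a rate that corresponds to no metrical level.
#'
#' @param dominant_freq_hz dominant movement frequency, Hz (possibly
#'   \code{NA}).
#' @param stimulus a [stimulus_spec()].
#' @param tolerance relative frequency tolerance (default 0.10).
#' @return a list of class \code{metrical_level_result}: \code{level}
#'   (\code{"beat"}, \code{"two_beat"}, \code{"four_beat"},
#'   \code{"off_tempo"} or \code{"indeterminate"}), \code{L} (1/2/4 or
#'   \code{NA}), \code{dominant_freq_hz}, \code{beat_freq_hz},
#'   \code{relative_deviation}.
#' @export
classify_level <- function(dominant_freq_hz, stimulus, tolerance = 0.10) {
  stopifnot(inherits(stimulus, "stimulus_spec"))
  f_beat <- stimulus$tempo_bpm / 60
  res <- list(level = "indeterminate", L = NA_real_,
              dominant_freq_hz = dominant_freq_hz, beat_freq_hz = f_beat,
              relative_deviation = NA_real_)
  class(res) <- "metrical_level_result"
  if (is.na(dominant_freq_hz)) return(res)
  labels <- c("beat", "two_beat", "four_beat")
  Ls <- c(1, 2, 4)
  dev <- abs(dominant_freq_hz - f_beat / Ls) / (f_beat / Ls)
  hit <- which(dev <= tolerance)
  if (length(hit)) {
    j <- hit[1]  # smallest L wins on (extreme-tolerance) ties
    res$level <- labels[j]
    res$L <- Ls[j]
    res$relative_deviation <- dev[j]
  } else {
    res$level <- "off_tempo"
    res$relative_deviation <- min(dev)
  }
  res
}

#' @export
print.metrical_level_result <- function(x, ...) {
  cat(sprintf("<metrical_level> %s (L = %s), f = %s Hz vs beat %.3f Hz\n",
              x$level, format(x$L), format(x$dominant_freq_hz),
              x$beat_freq_hz))
  invisible(x)
}

#' Metrical level with a within-trial stability check
#'
#' The level is estimated separately on the two halves of the analysis
#' window; if the halves disagree the produced level was not constant
#' throughout the trial and the result is \code{"unstable"} (such trials are
#' excluded, like off-tempo ones). Otherwise the common result is returned,
#' with the dominant frequency re-estimated on the full window.
#'
#' @inheritParams classify_level
#' @param trace an [accel_trace()] whose analysis window is at least 60 s.
#' @param ... passed to [dominant_frequency()].
#' @return a \code{metrical_level_result}; \code{level} may additionally be
#'   \code{"unstable"}.
#' @export
check_level_stability <- function(trace, stimulus, tolerance = 0.10, ...) {
  stopifnot(inherits(trace, "accel_trace"))
  if (trace_duration(trace) < 60) {
    stop("stability check needs at least 60 s of trace")
  }
  mid <- (min(trace$time_s) + max(trace$time_s)) / 2
  halves <- list(trace[trace$time_s < mid, , drop = FALSE],
                 trace[trace$time_s >= mid, , drop = FALSE])
  res <- lapply(halves, function(h) {
    for (a in c("sample_rate_hz", "participant_id", "movement_type",
                "stimulus_name")) attr(h, a) <- attr(trace, a)
    class(h) <- c("accel_trace", "data.frame")
    classify_level(dominant_frequency(h, ...), stimulus, tolerance)
  })
  if (!identical(res[[1]]$level, res[[2]]$level)) {
    out <- list(level = "unstable", L = NA_real_,
                dominant_freq_hz = NA_real_,
                beat_freq_hz = stimulus$tempo_bpm / 60,
                relative_deviation = NA_real_)
    class(out) <- "metrical_level_result"
    return(out)
  }
  classify_level(dominant_frequency(trace, ...), stimulus, tolerance)
}
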