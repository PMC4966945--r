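#' An ordered series of movement events
#'
#' @param event_times strictly increasing event times, seconds.
#' @param movement_type \code{"bounce"} or \code{"clap"}.
#' @param source id of the trace the events came from.
#' @return a list of class \code{response_series} with \code{event_times},
#'   \code{movement_type}, \code{source} and derived \code{iris}
#'   (inter-response intervals, ms; length \code{n - 1}).
#' @export
response_series <- function(event_times, movement_type = NA_character_,
                            source = NA_character_) {
  event_times <- as.numeric(event_times)
  if (length(event_times) >= 2 &&
      is.unsorted(event_times, strictly = TRUE)) {
    stop("event times must be strictly increasing")
  }
  structure(
    list(event_times = event_times,
         movement_type = movement_type,
         source = source,
         iris = if (length(event_times) >= 2) diff(event_times) * 1000 else numeric(0)),
    class = "response_series"
  )
}

#' @export
print.response_series <- function(x, ...) {
  cat(sprintf("<response_series> %d events (%s), mean IRI %.1f ms\n",
              length(x$event_times), x$movement_type,
              if (length(x$iris)) mean(x$iris) else NA))
  invisible(x)
}

#' Drop the lead-in of a trace
#'
#' The opening seconds of a trial, during which the participant is still
#' finding the beat, are discarded; the study used a 10 s lead on 115 s
#' stimuli, leaving 105 s for analysis. Timestamps are preserved, not
#' re-zeroed.
#'
#' @param trace an [accel_trace()].
#' @param lead_s seconds to discard from the start.
#' @return the restricted [accel_trace()].
#' @export
discard_lead <- function(trace, lead_s = 10) {
  stopifnot(inherits(trace, "accel_trace"))
  if (lead_s < 0) stop("`lead_s` must be non-negative")
  if (lead_s == 0) return(trace)
  if (max(trace$time_s) <= lead_s) {
    stop("trace is shorter than the lead to discard")
  }
  out <- trace[trace$time_s >= lead_s, , drop = FALSE]
  for (a in c("sample_rate_hz", "participant_id", "movement_type",
              "stimulus_name")) {
    attr(out, a) <- attr(trace, a)
  }
  class(out) <- c("accel_trace", "data.frame")
  out
}

# axis with maximal low-frequency variance = the movement (vertical) axis
detect_vertical_axis <- function(trace, cutoff_hz = 5) {
  rate <- trace_rate(trace)
  lp <- signal::butter(2, min(cutoff_hz / (rate / 2), 0.99), type = "low")
  v <- vapply(c("ax", "ay", "az"), function(a) {
    stats::var(signal::filtfilt(lp, trace[[a]] - mean(trace[[a]])))
  }, numeric(1))
  names(v)[which.max(v)]
}

resultant_magnitude <- function(trace) {
  sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
}

# local minima with minimum separation and prominence floor; greedy from the
# deepest minimum outwards
find_minima <- function(x, min_sep_samples, min_prominence) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] < x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  # prominence proxy: depth below the lower of the two neighbouring maxima
  # within one separation window
  prom <- vapply(cand, function(i) {
    lo <- max(1L, i - min_sep_samples)
    hi <- min(n, i + min_sep_samples)
    min(max(x[lo:i]), max(x[i:hi])) - x[i]
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand])]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) || all(abs(keep - i) >= min_sep_samples)) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

#' Extract movement-event times from an acceleration trace
#'
#' Bouncing: the vertical axis (maximal low-frequency variance, overridable)
#' is band-passed to the movement band (0.3-5 Hz) and events are local
#' minima — maximal knee flexion is the lowest trunk point, where vertical
#' acceleration bottoms out — subject to a minimum separation of
#' \code{0.4 * expected period} and a prominence of at least
#' \code{0.5 * sd} of the filtered signal. Clapping: the resultant magnitude
#' is high-passed above 10 Hz, rectified, and threshold crossings at
#' \code{4 * robust noise sd} (MAD) are taken as impacts with a 150 ms
#' refractory window; the event time is the rectified peak within each
#' burst. Events are detected on the whole trace, then restricted to
#' \code{t >= window_start_s}.
#'
#' @param trace an [accel_trace()].
#' @param expected_period_s expected inter-event period; if \code{NULL} the
#'   dominant spectral period of the movement axis is used.
#' @param window_start_s analysis-window start (the lead discard), seconds.
#' @param vertical_axis force the bounce movement axis
#'   (\code{"ax"/"ay"/"az"}); autodetected when \code{NULL}.
#' @param min_events minimum usable event count (default 8); fewer is an
#'   error because the trial cannot be scored.
#' @param config constants of the detector, see [event_config()].
#' @return a [response_series()].
#' @export
extract_events <- function(trace, expected_period_s = NULL,
                           window_start_s = 10, vertical_axis = NULL,
                           min_events = 8, config = event_config()) {
  stopifnot(inherits(trace, "accel_trace"))
  mv <- attr(trace, "movement_type")
  if (is.na(mv)) stop("trace has no movement_type metadata")
  rate <- trace_rate(trace)
  flatness <- stats::sd(c(trace$ax, trace$ay, trace$az))
  if (!is.finite(flatness) || flatness < 1e-9) {
    stop("trace is flat; no events to extract")
  }

  if (mv == "bounce") {
    axis <- vertical_axis %||% detect_vertical_axis(trace)
    x <- trace[[axis]] - mean(trace[[axis]])
    bp <- signal::butter(2, c(config$bounce_band_hz[1],
                              min(config$bounce_band_hz[2], rate / 2 * 0.99)) /
                           (rate / 2), type = "pass")
    xf <- signal::filtfilt(bp, x)
    if (is.null(expected_period_s)) {
      f <- dominant_frequency(trace, axis = axis)
      if (is.na(f)) stop("no dominant movement frequency; cannot set separation")
      expected_period_s <- 1 / f
    }
    sep <- max(2L, round(config$bounce_min_sep_frac * expected_period_s * rate))
    idx <- find_minima(xf, sep, config$bounce_prominence_frac * stats::sd(xf))
    times <- trace$time_s[idx]
  } else {
    mag <- resultant_magnitude(trace)
    hp <- signal::butter(2, config$clap_highpass_hz / (rate / 2), type = "high")
    hx <- signal::filtfilt(hp, mag - mean(mag))
    r <- abs(hx)
    # robust noise sd from the signed signal (transients are sparse, so the
    # MAD estimates the sensor-noise sd); floored at a small fraction of the
    # largest transient so a noiseless trace does not admit filter ringing
    thr <- max(config$clap_threshold_mads * stats::mad(hx),
               config$clap_floor_frac * max(r))
    # blank the filter-settling edges of the trace
    guard <- round(config$clap_edge_guard_s * rate)
    if (guard > 0 && length(r) > 2 * guard) {
      r[c(seq_len(guard), length(r) - seq_len(guard) + 1L)] <- 0
    }
    above <- r > thr
    if (!any(above)) stop("no clap transients above threshold")
    refr <- round(config$clap_refractory_ms / 1000 * rate)
    idx <- integer(0)
    i <- 1L
    n <- length(r)
    while (i <= n) {
      if (above[i]) {
        j <- min(n, i + refr)
        pk <- i - 1L + which.max(r[i:j])
        idx <- c(idx, pk)
        i <- pk + refr
      } else i <- i + 1L
    }
    times <- trace$time_s[idx]
  }

  times <- times[times >= window_start_s]
  if (length(times) < min_events) {
    stop(sprintf("too few events (%d < %d); trial unusable",
                 length(times), min_events))
  }
  response_series(times, movement_type = mv,
                  source = attr(trace, "stimulus_name"))
}

#' Detector constants
#'
#' All event-detection constants in one place: the bounce band-pass edges,
#' the minimum-separation fraction of the expected period, the prominence
#' floor as a fraction of the filtered-signal sd, the clap high-pass edge,
#' the threshold in robust noise sds, and the clap refractory window.
#'
#' @param bounce_band_hz band-pass edges for bouncing, Hz.
#' @param bounce_min_sep_frac minimum event separation as a fraction of the
#'   expected period.
#' @param bounce_prominence_frac prominence floor as a fraction of sd.
#' @param clap_highpass_hz high-pass edge for clapping, Hz.
#' @param clap_threshold_mads impact threshold in MADs of the rectified
#'   high-passed signal.
#' @param clap_floor_frac absolute threshold floor as a fraction of the
#'   largest rectified transient (keeps noiseless traces usable).
#' @param clap_refractory_ms refractory window after each impact, ms.
#' @param clap_edge_guard_s trace edges ignored for clap detection (filter
#'   settling), seconds.
#' @return a list of constants.
#' @export
event_config <- function(bounce_band_hz = c(0.3, 5),
                         bounce_min_sep_frac = 0.4,
                         bounce_prominence_frac = 0.5,
                         clap_highpass_hz = 10,
                         clap_threshold_mads = 4,
                         clap_floor_frac = 0.02,
                         clap_refractory_ms = 150,
                         clap_edge_guard_s = 0.25) {
  list(bounce_band_hz = bounce_band_hz,
       bounce_min_sep_frac = bounce_min_sep_frac,
       bounce_prominence_frac = bounce_prominence_frac,
       clap_highpass_hz = clap_highpass_hz,
       clap_threshold_mads = clap_threshold_mads,
       clap_floor_frac = clap_floor_frac,
       clap_refractory_ms = clap_refractory_ms,
       clap_edge_guard_s = clap_edge_guard_s)
}

#' Inter-response intervals of a series
#'
#' @param series a [response_series()] or numeric vector of event times.
#' @return successive differences in milliseconds (length n - 1).
#' @export
compute_iris <- function(series) {
  t <- if (inherits(series, "response_series")) series$event_times else series
  if (length(t) < 2) stop("need at least 2 events to form an interval")
  diff(t) * 1000
}
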