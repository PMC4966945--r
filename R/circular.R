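#' Convert response times to angles on the beat circle
#'
#' Period-matching is scored on the circle whose circumference is one
#' produced cycle: one stimulus inter-beat interval for beat-level trials,
#' two IBIs for two-beat-level trials. Each response time is mapped to
#' \code{theta = 2*pi * (t mod (L*IBI)) / (L*IBI)} using the unrounded IBI,
#' so a response series whose period equals L*IBI lands on a single
#' direction regardless of its phase relative to the beat (phase is not
#' scored).
#'
#' @param events a [response_series()] or numeric vector of event times in
#'   seconds.
#' @param ibi_ms stimulus inter-beat interval, ms (unrounded preferred).
#' @param L level multiplier (1 or 2; IBIs per circle).
#' @return a list of class \code{angle_series}: \code{angles} (radians in
#'   \code{[0, 2*pi)}) and \code{circle_span_ms}.
#' @export
events_to_angles <- function(events, ibi_ms, L = 1) {
  t <- if (inherits(events, "response_series")) events$event_times else events
  if (!length(t)) stop("no events to convert")
  if (ibi_ms <= 0) stop("`ibi_ms` must be positive")
  span <- L * ibi_ms
  theta <- 2 * pi * ((t * 1000) %% span) / span
  theta <- theta %% (2 * pi)
  structure(list(angles = theta, circle_span_ms = span),
            class = "angle_series")
}

as_angles <- function(x) {
  if (inherits(x, "angle_series")) x$angles else as.numeric(x)
}

#' Resultant length of a set of angles
#'
#' The length of the mean unit vector: 1 for perfectly concentrated angles,
#' 0 for balanced dispersion.
#'
#' @param angles an \code{angle_series} or numeric vector of radians.
#' @return R in \code{[0, 1]}.
#' @export
resultant_length <- function(angles) {
  a <- as_angles(angles)
  if (!length(a)) stop("no angles")
  min(1, sqrt(mean(cos(a))^2 + mean(sin(a))^2))
}

#' Circular variance
#'
#' \code{V = 1 - R}: the standard angular-dispersion measure, 0 for
#' perfectly regular period-matching, 1 for balanced dispersion.
#'
#' @inheritParams resultant_length
#' @return V in \code{[0, 1]}.
#' @export
circular_variance <- function(angles) 1 - resultant_length(angles)

#' Rayleigh test of circular uniformity
#'
#' Null hypothesis: the angles are uniformly distributed around the circle
#' (no period matching). The statistic is \code{z = n * R^2}; the p-value
#' uses the standard small-sample exponential approximation
#' \code{p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))}, capped into
#' \code{(0, 1]}.
#'
#' @inheritParams resultant_length
#' @param min_n minimum sample size (default 4; below that the
#'   approximation is unreliable and the segment is unusable).
#' @return a list of class \code{rayleigh_result}: \code{n}, \code{R},
#'   \code{z}, \code{p}.
#' @export
rayleigh_test <- function(angles, min_n = 4) {
  a <- as_angles(angles)
  n <- length(a)
  if (n < min_n) {
    stop(sprintf("too few responses for a Rayleigh test (%d < %d)", n, min_n))
  }
  R <- resultant_length(a)
  z <- n * R^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * R)^2)) - (1 + 2 * n))
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(n = n, R = R, z = z, p = p), class = "rayleigh_result")
}

#' @export
print.rayleigh_result <- function(x, ...) {
  cat(sprintf("<rayleigh> n = %d, R = %.4f, z = %.3f, p = %.4g\n",
              x$n, x$R, x$z, x$p))
  invisible(x)
}

#' Split an angle series into consecutive equal-count segments
#'
#' Beat-level trials are split into four consecutive segments, two-beat
#' trials into two, so that each segment has (as near as possible) the same
#' number of responses; with remainder r, the first r segments receive one
#' extra response. Segment-wise testing catches trials in which the beat was
#' lost partway through, or found only late.
#'
#' @param angles an \code{angle_series} or numeric vector (order-preserving:
#'   angles must be in response order).
#' @param L level multiplier; 1 gives 4 segments, 2 gives 2.
#' @param min_per_segment minimum responses per segment (Rayleigh minimum).
#' @return list of numeric angle vectors.
#' @export
segment_angles <- function(angles, L = 1, min_per_segment = 4) {
  a <- as_angles(angles)
  k <- if (L == 1) 4L else 2L
  n <- length(a)
  if (n < k * min_per_segment) {
    stop(sprintf("too few responses to segment (%d < %d); trial unusable",
                 n, k * min_per_segment))
  }
  base <- n %/% k
  r <- n %% k
  sizes <- rep(base, k) + c(rep(1L, r), rep(0L, k - r))
  split(a, rep(seq_len(k), times = sizes))
}

#' Detect a bimodal response-angle distribution
#'
#' Some trials show two preferred directions (e.g. responses alternating
#' between two phases); such trials cannot be scored for period matching
#' and are excluded. The axial-doubling diagnostic is used: with two
#' antipodal-ish lobes, the resultant length of the doubled angles
#' \code{2*theta} (\code{R2}) is large while the plain resultant \code{R} is
#' small. The trial is flagged bimodal when the Rayleigh test on the doubled
#' angles is significant and \code{R2 - R >= margin}.
#'
#' @inheritParams resultant_length
#' @param alpha significance level for the doubled-angle Rayleigh test.
#' @param margin required excess concentration of the axial statistic.
#' @param min_n below this the flag is undetermined (returned FALSE with
#'   \code{determined = FALSE}).
#' @return list: \code{bimodal} flag, \code{determined}, \code{R},
#'   \code{R2}, \code{p_axial}.
#' @export
detect_bimodality <- function(angles, alpha = 0.05, margin = 0.2, min_n = 8) {
  a <- as_angles(angles)
  if (length(a) < min_n) {
    return(list(bimodal = FALSE, determined = FALSE,
                R = NA_real_, R2 = NA_real_, p_axial = NA_real_))
  }
  R <- resultant_length(a)
  ax <- rayleigh_test((2 * a) %% (2 * pi))
  list(bimodal = (ax$p < alpha) && (ax$R - R >= margin),
       determined = TRUE, R = R, R2 = ax$R, p_axial = ax$p)
}
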