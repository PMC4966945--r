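#' Self-paced production statistics
#'
#' Produced tempo and regularity of unpaced movement: the mean
#' inter-response interval of the first 30 events (29 intervals) gives the
#' produced period (the referent period), and the coefficient of variation
#' (sample sd of those IRIs / mean IRI) gives regularity. Because the CV is
#' bounded by zero its distribution is log-normal, so a normalized score
#' \code{-log10(max(cv, floor))} is also returned (higher = more regular).
#'
#' @param series a [response_series()] or numeric event times in seconds.
#' @param n_events number of initial events used (default 30). If fewer are
#'   available the statistics are computed on what exists, with a warning.
#' @param floor floor inside the log of the normalized CV.
#' @return list of class \code{self_paced_stats}: \code{mean_iri_ms},
#'   \code{cv}, \code{sd_iri_ms}, \code{normalized_cv},
#'   \code{n_events_used}.
#' @export
self_paced_stats <- function(series, n_events = 30, floor = 1e-6) {
  t <- if (inherits(series, "response_series")) series$event_times else series
  if (length(t) < 2) stop("need at least 2 events")
  if (length(t) < n_events) {
    warning(sprintf("only %d events available (< %d); using all of them",
                    length(t), n_events))
  }
  used <- utils::head(t, n_events)
  iris <- diff(used) * 1000
  m <- mean(iris)
  s <- stats::sd(iris)
  cv <- s / m
  structure(
    list(mean_iri_ms = m, cv = cv, sd_iri_ms = s,
         normalized_cv = -log10(max(cv, floor)),
         n_events_used = length(used)),
    class = "self_paced_stats"
  )
}

#' Normative cut-off from a reference group
#'
#' Two-sd cut-off around a reference (Normal Synchronizer) distribution:
#' \code{mean + 2*sd} for abnormally high values (e.g. an extremely slow
#' produced period) or \code{mean - 2*sd} for abnormally low ones (e.g. low
#' regularity, or a low perceptual test score). For integer-scored tests the
#' cut-off is rounded to the nearest integer.
#'
#' @param reference numeric reference values (>= 3).
#' @param direction \code{"upper"} or \code{"lower"}.
#' @param integer round the cut-off to the nearest integer.
#' @return the cut-off value.
#' @export
normative_cutoff <- function(reference, direction = c("upper", "lower"),
                             integer = FALSE) {
  direction <- match.arg(direction)
  if (length(reference) < 3) stop("need at least 3 reference values")
  m <- mean(reference)
  s <- stats::sd(reference)
  if (s == 0) {
    warning("degenerate reference (sd = 0); cut-off equals the mean")
    cut <- m
  } else {
    cut <- m + if (direction == "upper") 2 * s else -2 * s
  }
  if (integer) round(cut) else cut
}

#' Cut-off directly from printed reference moments
#'
#' @param mean,sd reference mean and sd.
#' @inheritParams normative_cutoff
#' @return the cut-off value.
#' @export
cutoff_from_moments <- function(mean, sd, direction = c("upper", "lower"),
                                integer = FALSE) {
  direction <- match.arg(direction)
  cut <- mean + if (direction == "upper") 2 * sd else -2 * sd
  if (integer) round(cut) else cut
}

#' Flag values beyond a cut-off
#'
#' @param values named numeric vector (names are ids).
#' @param cutoff the cut-off value.
#' @param direction \code{"upper"} flags values above the cut-off,
#'   \code{"lower"} values below it.
#' @return character vector of flagged ids.
#' @export
flag_outliers <- function(values, cutoff, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  hit <- if (direction == "upper") values > cutoff else values < cutoff
  nm <- names(values) %||% as.character(seq_along(values))
  nm[hit]
}
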