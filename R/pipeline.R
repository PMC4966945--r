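#' Analyze one synchronization trial end to end
#'
#' Runs the full per-trial procedure: discard the lead-in, determine the
#' produced metrical level with the two-half stability check, and — when the
#' level is beat or two-beat — extract movement events, convert them to
#' angles on the beat circle, flag bimodality, split into consecutive
#' segments (four at beat level, two at two-beat level), Rayleigh-test each
#' segment, and classify the trial. Four-beat, off-tempo, unstable and
#' indeterminate trials are level-excluded; trials with too few events are
#' unusable.
#'
#' @param trace an [accel_trace()] of the full recording.
#' @param stimulus a [stimulus_spec()].
#' @param config a [sync_config()].
#' @return a list of class \code{trial_result}: \code{level}, \code{L},
#'   \code{trial_class} (\code{normal/poor/bimodal/level_excluded/unusable}),
#'   \code{n_events}, \code{segments} (list of [rayleigh_test()] results),
#'   \code{segment_p}, \code{bimodal}, \code{V} (whole-trial circular
#'   variance), \code{sr} (regularity, normal trials only),
#'   \code{dominant_freq_hz}.
#' @export
analyze_trial <- function(trace, stimulus, config = sync_config()) {
  win <- discard_lead(trace, config$lead_s)
  lev <- check_level_stability(win, stimulus,
                               tolerance = config$level_tolerance)
  out <- list(level = lev$level, L = lev$L,
              dominant_freq_hz = lev$dominant_freq_hz,
              trial_class = "level_excluded", n_events = NA_integer_,
              segments = list(), segment_p = numeric(0),
              bimodal = FALSE, V = NA_real_, sr = NA_real_)
  class(out) <- "trial_result"
  if (!lev$level %in% c("beat", "two_beat")) return(out)

  events <- tryCatch(
    extract_events(trace, expected_period_s = 1 / lev$dominant_freq_hz,
                   window_start_s = config$lead_s),
    error = function(e) e
  )
  if (inherits(events, "error")) {
    out$trial_class <- "unusable"
    return(out)
  }
  out$n_events <- length(events$event_times)

  ibi_ms <- bpm_to_ibi(stimulus$tempo_bpm, round = FALSE)
  ang <- events_to_angles(events, ibi_ms, L = lev$L)
  bim <- detect_bimodality(ang, alpha = config$alpha,
                           margin = config$bimodal_margin)
  out$bimodal <- isTRUE(bim$bimodal)

  segs <- tryCatch(segment_angles(ang, L = lev$L), error = function(e) e)
  if (inherits(segs, "error")) {
    out$trial_class <- "unusable"
    return(out)
  }
  out$segments <- lapply(segs, rayleigh_test)
  out$segment_p <- vapply(out$segments, `[[`, numeric(1), "p")
  out$V <- circular_variance(ang)
  out$trial_class <- classify_trial(out$segments, out$bimodal, config$alpha)
  if (out$trial_class == "normal") {
    out$sr <- synchronization_regularity(out$V, config$sr_floor)
  }
  out
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s | level %s (L=%s), n=%s, V=%s, seg p: %s\n",
              x$trial_class, x$level, format(x$L), format(x$n_events),
              format(round(x$V, 4)),
              paste(signif(x$segment_p, 3), collapse = " ")))
  invisible(x)
}

#' Analyze a simulated cohort end to end
#'
#' Regenerates each trial of a [simulate_cohort()] plan, analyzes it with
#' [analyze_trial()], and assembles the per-trial table, per-participant
#' groups, the cohort trial accounting and condition-wise success profiles.
#' Traces are realized one at a time, so memory stays flat for large
#' cohorts.
#'
#' @param cohort a list from [simulate_cohort()] (the \code{plan} +
#'   \code{stimuli}).
#' @param config a [sync_config()].
#' @param progress print a dot every 50 trials.
#' @return list: \code{trials} (data.frame of per-trial outcomes incl.
#'   ground truth), \code{participants} (data.frame: id, group,
#'   exclusion_reason, ground truth), \code{accounting} (per movement type),
#'   \code{profiles} (success proportions).
#' @export
analyze_cohort <- function(cohort, config = sync_config(), progress = FALSE) {
  plan <- cohort$plan
  stimuli <- cohort$stimuli
  is_metro <- stats::setNames(stimuli$is_metronome, stimuli$name)
  specs <- lapply(seq_len(nrow(stimuli)), function(i) {
    as_stimulus_spec(stimuli[i, ])
  })
  names(specs) <- stimuli$name

  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    tr <- if (!is.null(cohort$traces)) {
      cohort$traces[[plan$trial_id[i]]]
    } else {
      realize_trial(plan[i, ], stimuli)
    }
    res <- analyze_trial(tr, specs[[plan$stimulus_name[i]]], config)
    rows[[i]] <- data.frame(
      trial_id = plan$trial_id[i],
      participant_id = plan$participant_id[i],
      movement_type = plan$movement_type[i],
      stimulus_name = plan$stimulus_name[i],
      is_metronome = unname(is_metro[plan$stimulus_name[i]]),
      group_truth = plan$group_truth[i],
      trial_mode = plan$trial_mode[i],
      level = res$level, L = res$L,
      trial_class = res$trial_class,
      n_events = res$n_events, V = res$V, sr = res$sr,
      stringsAsFactors = FALSE)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  trials <- do.call(rbind, rows)

  parts <- do.call(rbind, lapply(split(trials, trials$participant_id),
                                 function(g) {
    cls <- classify_participant(g, config)
    data.frame(participant_id = g$participant_id[1],
               group = cls$group,
               exclusion_reason = cls$exclusion_reason,
               n_poor_bounce = cls$n_poor[["bounce"]],
               n_poor_clap = cls$n_poor[["clap"]],
               group_truth = g$group_truth[1],
               stringsAsFactors = FALSE)
  }))
  rownames(parts) <- NULL

  acc <- do.call(rbind, lapply(c("bounce", "clap"), function(mv) {
    g <- trials[trials$movement_type == mv, ]
    cbind(movement_type = mv,
          trial_accounting(
            total = nrow(g),
            level_excluded = sum(g$trial_class %in% c("level_excluded", "unusable")),
            bimodal = sum(g$trial_class == "bimodal"),
            poor = sum(g$trial_class == "poor")))
  }))

  list(trials = trials, participants = parts, accounting = acc,
       profiles = success_profiles(trials))
}
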