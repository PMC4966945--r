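#' Analysis configuration
#'
#' All decision thresholds of the pipeline in one flat structure.
#'
#' @param alpha Rayleigh significance level for period matching.
#' @param level_tolerance relative tolerance of metrical-level matching.
#' @param bimodal_margin required \code{R2 - R} excess for a bimodal flag.
#' @param sr_floor floor on circular variance inside the log of the
#'   regularity score.
#' @param lead_s lead-in discard, seconds.
#' @param poor_trial_threshold poor music trials (out of 6, per movement
#'   type) that make a participant a Poor Synchronizer.
#' @param bimodal_trial_threshold bimodal trials (out of 8, per movement
#'   type) that exclude a participant for too much missing data.
#' @param four_beat_prop proportion of level-determined trials at the
#'   four-beat level above which the participant is excluded as a four-beat
#'   mover.
#' @return a list of class \code{sync_config}.
#' @export
sync_config <- function(alpha = 0.05, level_tolerance = 0.10,
                        bimodal_margin = 0.2, sr_floor = 1e-6,
                        lead_s = 10, poor_trial_threshold = 3,
                        bimodal_trial_threshold = 3,
                        four_beat_prop = 0.5) {
  structure(list(alpha = alpha, level_tolerance = level_tolerance,
                 bimodal_margin = bimodal_margin, sr_floor = sr_floor,
                 lead_s = lead_s,
                 poor_trial_threshold = poor_trial_threshold,
                 bimodal_trial_threshold = bimodal_trial_threshold,
                 four_beat_prop = four_beat_prop),
            class = "sync_config")
}

#' Classify a single trial from its segment tests
#'
#' A trial is normal synchronization only if every segment's Rayleigh test
#' is significant; if any one segment fails, the trial is poor
#' synchronization. Bimodal trials are excluded from period-matching scoring
#' altogether.
#'
#' @param segments list of [rayleigh_test()] results (or numeric p-values).
#' @param bimodal logical bimodality flag.
#' @param alpha significance level.
#' @return \code{"normal"}, \code{"poor"} or \code{"bimodal"}.
#' @export
classify_trial <- function(segments, bimodal = FALSE, alpha = 0.05) {
  if (isTRUE(bimodal)) return("bimodal")
  if (!length(segments)) stop("no segments to classify")
  p <- vapply(segments, function(s) {
    if (inherits(s, "rayleigh_result")) s$p else as.numeric(s)
  }, numeric(1))
  if (all(p < alpha)) "normal" else "poor"
}

#' Synchronization regularity from circular variance
#'
#' The circular variance of period-matched trials is log-normally
#' distributed, so regularity is scored as \code{SR = -log10(max(V,
#' floor))}: higher means more regular, 0 at V = 1 (balanced dispersion),
#' capped at 6 by the floor.
#'
#' @param V circular variance in \code{[0, 1]}.
#' @param floor positive floor inside the log.
#' @return SR score(s).
#' @export
synchronization_regularity <- function(V, floor = 1e-6) {
  if (any(!is.finite(V)) || any(V < 0) || any(V > 1)) {
    stop("circular variance must lie in [0, 1]")
  }
  -log10(pmax(V, floor))
}

#' Classify a participant from their trial classes
#'
#' Rules, applied in order: (1) a participant whose produced level is
#' predominantly four-beat (tempo-matched, but at a level not comparable to
#' the rest of the cohort) is excluded as a four-beat mover; (2) a
#' participant with at least \code{bimodal_trial_threshold} bimodal trials
#' out of the 8 of either movement type is excluded for too much missing
#' data; (3) a participant with at least \code{poor_trial_threshold} poor
#' trials out of the 6 music trials of either movement type is a Poor
#' Synchronizer — off-tempo and unstable-level trials count as poor here
#' (failing to match tempo at any level is the severest period-matching
#' failure); (4) otherwise a Normal Synchronizer.
#'
#' @param trials data.frame with one row per trial and columns
#'   \code{movement_type}, \code{is_metronome} (logical),
#'   \code{trial_class} (\code{normal/poor/bimodal/level_excluded/unusable})
#'   and \code{level} (\code{beat/two_beat/four_beat/off_tempo/unstable/...}).
#' @param config a [sync_config()].
#' @return list: \code{group} (\code{"normal_synchronizer"},
#'   \code{"poor_synchronizer"} or \code{"excluded"}),
#'   \code{exclusion_reason} (\code{"four_beat_mover"},
#'   \code{"bimodal_overload"} or \code{"none"}), and per-movement poor
#'   counts.
#' @export
classify_participant <- function(trials, config = sync_config()) {
  needed <- c("movement_type", "is_metronome", "trial_class", "level")
  if (!all(needed %in% names(trials))) {
    stop("`trials` must have columns ", paste(needed, collapse = ", "))
  }
  if (!all(c("bounce", "clap") %in% trials$movement_type)) {
    stop("incomplete profile: need trials for both movement types")
  }

  determined <- trials$level %in% c("beat", "two_beat", "four_beat")
  if (sum(determined) > 0 &&
      mean(trials$level[determined] == "four_beat") >= config$four_beat_prop) {
    return(list(group = "excluded", exclusion_reason = "four_beat_mover",
                n_poor = c(bounce = NA_integer_, clap = NA_integer_)))
  }

  for (mv in c("bounce", "clap")) {
    nb <- sum(trials$trial_class == "bimodal" & trials$movement_type == mv)
    if (nb >= config$bimodal_trial_threshold) {
      return(list(group = "excluded", exclusion_reason = "bimodal_overload",
                  n_poor = c(bounce = NA_integer_, clap = NA_integer_)))
    }
  }

  poor_like <- trials$trial_class == "poor" |
    (trials$trial_class %in% c("level_excluded", "unusable") &
       trials$level %in% c("off_tempo", "unstable"))
  n_poor <- vapply(c(bounce = "bounce", clap = "clap"), function(mv) {
    sum(poor_like & trials$movement_type == mv & !trials$is_metronome)
  }, integer(1))

  group <- if (any(n_poor >= config$poor_trial_threshold)) {
    "poor_synchronizer"
  } else {
    "normal_synchronizer"
  }
  list(group = group, exclusion_reason = "none", n_poor = n_poor)
}

#' Cohort-level trial accounting
#'
#' Per movement type: total trials, level-excluded (off-tempo, unstable or
#' four-beat), bimodal, poor and normal counts, and the poor percentage
#' computed over scoreable trials,
#' \code{poor / (total - level_excluded - bimodal) * 100}, rounded to one
#' decimal.
#'
#' @param total,level_excluded,bimodal,poor counts (scalars or vectors of
#'   equal length, e.g. one per movement type).
#' @return data.frame with the counts, \code{normal}, and \code{poor_pct}.
#' @export
trial_accounting <- function(total, level_excluded, bimodal, poor) {
  scoreable <- total - level_excluded - bimodal
  if (any(scoreable < poor)) stop("more poor trials than scoreable trials")
  data.frame(
    total = total, level_excluded = level_excluded, bimodal = bimodal,
    poor = poor, normal = scoreable - poor,
    poor_pct = round(poor / scoreable * 100, 1)
  )
}
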