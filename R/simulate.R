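#' Parameters of the synthetic movement-timing model
#'
#' The generator produces event times (bounces or claps) locked to a
#' stimulus beat grid through a simple period model: the nominal produced
#' period is \code{L * IBI * (1 + rho)}, where \code{L} is the metrical level
#' multiplier (1 = every beat, 2 = every second beat, 4 = every fourth beat)
#' and \code{rho} a relative tempo mismatch. The realized period wanders by a
#' Gaussian random walk (\code{drift_sd} per step), each event additionally
#' receives independent Gaussian timing jitter (\code{phase_noise_sd}), and
#' with probability \code{bimodal_mix} an event is displaced by a fixed
#' circular offset, producing a second phase lobe (e.g. alternating between
#' two phases).
#'
#' @param movement_type \code{"bounce"} or \code{"clap"}.
#' @param level_multiplier metrical level multiplier L, one of 1, 2, 4.
#' @param tempo_mismatch relative period mismatch rho (0 = on tempo).
#' @param phase_noise_sd sd of per-event timing jitter, milliseconds.
#' @param drift_sd sd of the random-walk period increment, milliseconds.
#' @param bimodal_offset circular offset of the second lobe, radians
#'   (\code{NA} disables).
#' @param bimodal_mix probability an event is displaced to the second lobe.
#' @param amplitude movement acceleration amplitude, m/s^2.
#' @param noise_sd additive sensor-noise sd, m/s^2.
#' @return a list of class \code{sim_params}.
#' @export
sim_params <- function(movement_type = c("bounce", "clap"),
                       level_multiplier = 1,
                       tempo_mismatch = 0,
                       phase_noise_sd = 0,
                       drift_sd = 0,
                       bimodal_offset = NA_real_,
                       bimodal_mix = 0,
                       amplitude = 5,
                       noise_sd = 0.2) {
  movement_type <- match.arg(movement_type)
  if (!level_multiplier %in% c(1, 2, 4)) {
    stop("`level_multiplier` must be 1, 2 or 4")
  }
  if (phase_noise_sd < 0 || drift_sd < 0) {
    stop("noise sds must be non-negative")
  }
  if (bimodal_mix < 0 || bimodal_mix > 1) stop("`bimodal_mix` must be in [0, 1]")
  structure(
    list(movement_type = movement_type,
         level_multiplier = level_multiplier,
         tempo_mismatch = tempo_mismatch,
         phase_noise_sd = phase_noise_sd,
         drift_sd = drift_sd,
         bimodal_offset = bimodal_offset,
         bimodal_mix = bimodal_mix,
         amplitude = amplitude,
         noise_sd = noise_sd),
    class = "sim_params"
  )
}

#' Simulate movement-event times for one trial
#'
#' Event times follow \code{t[1] = offset}, then
#' \code{t[i+1] = t[i] + L*IBI*(1+rho) + cumdrift[i]}, with independent
#' Gaussian jitter \code{N(0, phase_noise_sd)} added to each event time
#' afterwards (so successive inter-event intervals have sd
#' \code{sqrt(2) * phase_noise_sd} when the drift is zero). Bimodal
#' displacement, if enabled, moves selected events by
#' \code{bimodal_offset * L*IBI / (2*pi)}. Times outside \code{[0, duration]}
#' are dropped.
#'
#' @param stimulus a [stimulus_spec()], or \code{NULL} for self-paced
#'   production (then \code{referent_period_ms} must be given).
#' @param params a [sim_params()].
#' @param seed integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @param offset_s time of the first event, seconds.
#' @param duration_s trial duration; defaults to the stimulus duration, or
#'   120 s for self-paced production.
#' @param referent_period_ms self-paced target period, milliseconds.
#' @param on_nonmonotone what to do if jitter makes times non-increasing:
#'   \code{"resort"} (warn and sort) or \code{"error"}.
#' @return an object of class \code{response_series} (see
#'   [response_series()]).
#' @export
simulate_event_times <- function(stimulus = NULL, params = sim_params(),
                                 seed = 1L, offset_s = 0,
                                 duration_s = NULL,
                                 referent_period_ms = NULL,
                                 on_nonmonotone = c("resort", "error")) {
  on_nonmonotone <- match.arg(on_nonmonotone)
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(stimulus)) {
    stopifnot(inherits(stimulus, "stimulus_spec"))
    base_ms <- bpm_to_ibi(stimulus$tempo_bpm, round = FALSE)
    if (is.null(duration_s)) duration_s <- stimulus$duration_s
  } else {
    if (is.null(referent_period_ms) || referent_period_ms <= 0) {
      stop("self-paced simulation needs a positive `referent_period_ms`")
    }
    base_ms <- referent_period_ms / params$level_multiplier
    if (is.null(duration_s)) duration_s <- 120
  }
  period_s <- params$level_multiplier * base_ms / 1000 *
    (1 + params$tempo_mismatch)

  n_max <- max(2L, ceiling((duration_s - offset_s) / max(period_s, 1e-6)) + 2L)
  t <- withr::with_seed(seed, {
    drift <- if (params$drift_sd > 0) {
      cumsum(stats::rnorm(n_max - 1, 0, params$drift_sd / 1000))
    } else {
      numeric(n_max - 1)
    }
    nominal <- offset_s + c(0, cumsum(period_s + drift))
    jitter <- if (params$phase_noise_sd > 0) {
      stats::rnorm(n_max, 0, params$phase_noise_sd / 1000)
    } else {
      numeric(n_max)
    }
    tt <- nominal + jitter
    if (params$bimodal_mix > 0 && is.finite(params$bimodal_offset)) {
      span_s <- params$level_multiplier * base_ms / 1000
      hit <- stats::runif(n_max) < params$bimodal_mix
      tt[hit] <- tt[hit] + params$bimodal_offset * span_s / (2 * pi)
    }
    tt
  })
  t <- t[t >= 0 & t <= duration_s]
  if (is.unsorted(t, strictly = TRUE)) {
    if (on_nonmonotone == "error") {
      stop("jitter produced non-increasing event times")
    }
    warning("jitter produced non-increasing event times; re-sorting")
    t <- sort(t)
    t <- t[c(TRUE, diff(t) > 0)]
  }
  response_series(t, movement_type = params$movement_type)
}

#' A 3-axis acceleration trace
#'
#' @param time_s sample times, seconds.
#' @param ax,ay,az acceleration, m/s^2 (gravity-removed, zero baseline).
#' @param sample_rate_hz sampling rate.
#' @param participant_id,movement_type,stimulus_name trial metadata.
#' @return a data.frame of class \code{accel_trace} with columns
#'   \code{time_s, ax, ay, az} and metadata attributes.
#' @export
accel_trace <- function(time_s, ax, ay, az, sample_rate_hz = 100,
                        participant_id = NA_character_,
                        movement_type = NA_character_,
                        stimulus_name = NA_character_) {
  stopifnot(length(time_s) == length(ax), length(ax) == length(ay),
            length(ay) == length(az))
  if (any(!is.finite(c(ax, ay, az)))) stop("trace contains non-finite values")
  out <- data.frame(time_s = time_s, ax = ax, ay = ay, az = az)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "participant_id") <- participant_id
  attr(out, "movement_type") <- movement_type
  attr(out, "stimulus_name") <- stimulus_name
  class(out) <- c("accel_trace", "data.frame")
  out
}

trace_rate <- function(trace) attr(trace, "sample_rate_hz")
trace_duration <- function(trace) {
  if (nrow(trace) == 0) return(0)
  max(trace$time_s) - min(trace$time_s) + 1 / trace_rate(trace)
}

#' Render an acceleration trace from event times
#'
#' Bouncing is rendered as a continuous raised-cosine oscillation on the
#' vertical axis whose minima (maximal knee flexion, the lowest trunk point)
#' coincide with the event times; clapping as a biexponential impact
#' transient (1 ms rise, 30 ms decay by default) whose peak sits at each
#' event time, carried on one hand axis so that the resultant magnitude
#' shows the impacts. Gravity is not modelled: acceleration oscillates about
#' a zero baseline, which is all the downstream analysis needs. Independent
#' Gaussian sensor noise of sd \code{noise_sd} is added to every axis; the
#' two non-movement axes carry only low-amplitude noise.
#'
#' @param events a [response_series()] of event times.
#' @param params a [sim_params()] (movement type, amplitude, noise).
#' @param sample_rate_hz sampling rate; must be >= 50 Hz for clapping so the
#'   impact transient is resolved.
#' @param duration_s trace duration, seconds.
#' @param seed seed for the sensor noise.
#' @param clap_rise_ms,clap_decay_ms transient time constants.
#' @param ... metadata passed to [accel_trace()].
#' @return an [accel_trace()]; the movement axis is \code{az} (vertical) for
#'   bouncing and \code{ax} for clapping.
#' @export
render_trace <- function(events, params, sample_rate_hz = 100,
                         duration_s = 115, seed = 1L,
                         clap_rise_ms = 1, clap_decay_ms = 30, ...) {
  stopifnot(inherits(params, "sim_params"))
  t_ev <- if (inherits(events, "response_series")) events$event_times else events
  n <- round(sample_rate_hz * duration_s)
  tt <- (seq_len(n) - 1) / sample_rate_hz
  sig <- numeric(n)

  if (params$movement_type == "bounce") {
    if (length(t_ev) >= 2 && params$amplitude > 0) {
      # piecewise-linear phase: integer at each event; -cos() puts continuous
      # minima exactly at event times
      phase <- stats::approx(t_ev, seq_along(t_ev), xout = tt, rule = 2)$y
      sig <- -params$amplitude * cos(2 * pi * phase)
      # flatten outside the event span so no movement is invented there
      sig[tt < t_ev[1] | tt > t_ev[length(t_ev)]] <-
        -params$amplitude
      sig <- sig - mean(sig)
    }
  } else {
    if (sample_rate_hz < 50) {
      stop("sample rate below 50 Hz cannot resolve clap transients")
    }
    if (length(t_ev) >= 1 && params$amplitude > 0) {
      tau_r <- clap_rise_ms / 1000
      tau_d <- clap_decay_ms / 1000
      # shift kernel so its maximum lands on the event time
      t_peak <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
      kpeak <- exp(-t_peak / tau_d) - exp(-t_peak / tau_r)
      for (e in t_ev) {
        lo <- e - t_peak
        idx <- which(tt >= lo & tt <= lo + 8 * tau_d)
        if (length(idx)) {
          u <- tt[idx] - lo
          sig[idx] <- sig[idx] +
            params$amplitude * (exp(-u / tau_d) - exp(-u / tau_r)) / kpeak
        }
      }
    }
  }

  noise <- withr::with_seed(seed, {
    matrix(stats::rnorm(3 * n, 0, params$noise_sd), ncol = 3)
  })
  # non-movement axes: low-amplitude noise only
  off_scale <- 0.5
  if (params$movement_type == "bounce") {
    ax <- off_scale * noise[, 1]
    ay <- off_scale * noise[, 2]
    az <- sig + noise[, 3]
  } else {
    ax <- sig + noise[, 1]
    ay <- off_scale * noise[, 2]
    az <- off_scale * noise[, 3]
  }
  accel_trace(tt, ax, ay, az, sample_rate_hz = sample_rate_hz,
              movement_type = params$movement_type, ...)
}

#' Write / read a trace as columnar text
#'
#' The on-disk format is plain text: a `#`-prefixed key-value metadata
#' header (participant, movement, stimulus, rate), then a header line
#' `time_s ax ay az` and one row per sample.
#'
#' @param trace an [accel_trace()].
#' @param path file path.
#' @return \code{write_trace} returns \code{path} invisibly;
#'   \code{read_trace} returns an [accel_trace()].
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(participant = attr(trace, "participant_id"),
            movement = attr(trace, "movement_type"),
            stimulus = attr(trace, "stimulus_name"),
            rate_hz = format(trace_rate(trace)))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  writeLines("time_s ax ay az", con)
  writeLines(sprintf("%.4f %.6g %.6g %.6g",
                     trace$time_s, trace$ax, trace$ay, trace$az), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE)
  accel_trace(body$time_s, body$ax, body$ay, body$az,
              sample_rate_hz = as.numeric(meta$rate_hz %||% 100),
              participant_id = meta$participant %||% NA_character_,
              movement_type = meta$movement %||% NA_character_,
              stimulus_name = meta$stimulus %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## --- cohort simulation ------------------------------------------------

# Condition-wise generating parameters for each poor-synchronizer archetype.
# "fail" means a period-matching failure is generated (tempo mismatch); the
# paper gives no quantitative timing model for its poor synchronizers, so
# these are free design choices documented in the methods vignette.
poor_archetypes <- function() {
  list(
    global_failure = list(bounce_music = "fail", clap_music = "fail",
                          bounce_metro = "fail", clap_metro = "fail"),
    music_only_failure = list(bounce_music = "fail", clap_music = "fail",
                              bounce_metro = "ok", clap_metro = "ok"),
    graded_failure = list(bounce_music = "fail", clap_music = "partial",
                          bounce_metro = "partial", clap_metro = "ok"),
    bounce_only_failure = list(bounce_music = "fail", clap_music = "ok",
                               bounce_metro = "fail", clap_metro = "ok")
  )
}

# share of trials produced at the beat (vs two-beat) level: people mostly
# clap on every beat but often bounce on every second beat
beat_level_prob <- function(movement_type) {
  if (movement_type == "clap") 0.85 else 0.58
}

normal_trial_params <- function(movement_type, ibi_ms, L = NULL) {
  # clean synchronizer: on tempo, with timing jitter tighter for claps than
  # bounces (discrete impacts are timed more precisely than continuous
  # whole-body oscillation); no period drift — a synchronized mover corrects
  # drift against the stimulus, and an uncorrected random walk in the period
  # integrates into unbounded phase wander over a 105 s trial
  jit <- if (movement_type == "clap") 0.010 else 0.030
  sim_params(movement_type = movement_type,
             level_multiplier = L %||% if (movement_type == "bounce") 2 else 1,
             tempo_mismatch = 0,
             phase_noise_sd = jit * ibi_ms,
             drift_sd = 0)
}

failing_trial_params <- function(movement_type, ibi_ms, L = NULL) {
  # off the stimulus period: 6% tempo mismatch sweeps the response phase
  # around the circle within a segment, defeating the Rayleigh test while
  # staying inside the +/-10% level-classification tolerance
  sim_params(movement_type = movement_type,
             level_multiplier = L %||% if (movement_type == "bounce") 2 else 1,
             tempo_mismatch = 0.06,
             phase_noise_sd = 0.05 * ibi_ms,
             drift_sd = 0.005 * ibi_ms)
}

#' Simulate a labelled synthetic cohort
#'
#' Builds the full study design in silico: every participant performs 8
#' stimulus trials (6 music + 2 metronome) in each of the two movement
#' types. Normal synchronizers are generated on tempo with small timing
#' jitter; poor synchronizers cycle through four archetypes (global failure;
#' music-only failure; graded failure, bouncing worse than clapping and
#' music worse than metronome; bounce-only failure). Every trial is tagged
#' with its generating profile, so downstream classification can be scored
#' against ground truth.
#'
#' @param n_normal,n_poor participant counts (their sum must be positive).
#' @param stimuli a stimulus table as returned by [study_stimuli()].
#' @param seed master seed; all per-trial seeds derive from it.
#' @param return \code{"plan"} (default) returns the trial table only;
#'   \code{"traces"} also materializes every [accel_trace()] (memory-heavy
#'   for large cohorts — each trace is ~11,500 samples).
#' @return a list with \code{plan} (data.frame, one row per trial: ids,
#'   condition, generating mode, produced level \code{level_gen} (1 = beat,
#'   2 = two-beat, drawn per trial with clapping favouring the beat level),
#'   per-trial seed, ground-truth labels)
#'   and, when requested, \code{traces} (list of [accel_trace()] keyed by
#'   \code{trial_id}). Use [realize_trial()] to regenerate any single trace
#'   from its plan row.
#' @export
simulate_cohort <- function(n_normal, n_poor, stimuli = study_stimuli(),
                            seed = 1L, return = c("plan", "traces")) {
  return <- match.arg(return)
  if (n_normal + n_poor <= 0) stop("cohort must contain at least one participant")
  archs <- poor_archetypes()
  groups <- c(rep("normal", n_normal), rep("poor", n_poor))
  arch_of <- c(rep(NA_character_, n_normal),
               names(archs)[((seq_len(n_poor) - 1) %% length(archs)) + 1])

  rows <- list()
  k <- 0L
  for (p in seq_along(groups)) {
    pid <- sprintf("P%03d", p)
    for (mv in c("bounce", "clap")) {
      for (s in seq_len(nrow(stimuli))) {
        k <- k + 1L
        st <- stimuli[s, ]
        cond <- paste0(mv, "_", if (st$is_metronome) "metro" else "music")
        mode <- if (groups[p] == "normal") "ok" else {
          m <- archs[[arch_of[p]]][[cond]]
          if (m == "partial") {
            # graded archetype: alternate fail/ok within the condition
            if (s %% 2 == 0) "fail" else "ok"
          } else m
        }
        rows[[k]] <- data.frame(
          trial_id = sprintf("%s_%s_%s", pid, mv, st$name),
          participant_id = pid, movement_type = mv,
          stimulus_name = st$name, condition = cond,
          group_truth = groups[p], archetype = arch_of[p],
          trial_mode = mode, stringsAsFactors = FALSE)
      }
    }
  }
  plan <- do.call(rbind, rows)
  draws <- withr::with_seed(seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, nrow(plan)),
         u = stats::runif(nrow(plan)))
  })
  plan$trial_seed <- draws$seeds
  # per-trial produced metrical level (beat vs two-beat)
  plan$level_gen <- ifelse(
    draws$u < vapply(plan$movement_type, beat_level_prob, numeric(1)), 1L, 2L)
  out <- list(plan = plan, stimuli = stimuli)
  if (return == "traces") {
    out$traces <- lapply(seq_len(nrow(plan)), function(i) {
      realize_trial(plan[i, ], stimuli)
    })
    names(out$traces) <- plan$trial_id
  }
  out
}

#' Regenerate one trial's trace from its cohort-plan row
#'
#' @param plan_row one row of the \code{plan} returned by
#'   [simulate_cohort()].
#' @param stimuli the stimulus table the plan was built from.
#' @return an [accel_trace()]; deterministic given the row's stored seed.
#' @export
realize_trial <- function(plan_row, stimuli = study_stimuli()) {
  st <- stimuli[stimuli$name == plan_row$stimulus_name, , drop = FALSE]
  if (nrow(st) != 1) stop("unknown stimulus: ", plan_row$stimulus_name)
  spec <- as_stimulus_spec(st[1, ])
  ibi <- bpm_to_ibi(spec$tempo_bpm, round = FALSE)
  L <- if ("level_gen" %in% names(plan_row)) plan_row$level_gen else NULL
  pars <- if (plan_row$trial_mode == "ok") {
    normal_trial_params(plan_row$movement_type, ibi, L)
  } else {
    failing_trial_params(plan_row$movement_type, ibi, L)
  }
  ev <- simulate_event_times(spec, pars, seed = plan_row$trial_seed,
                             offset_s = 0.3)
  render_trace(ev, pars, duration_s = spec$duration_s,
               seed = plan_row$trial_seed + 1L,
               participant_id = plan_row$participant_id,
               stimulus_name = plan_row$stimulus_name)
}

#' Simulate a self-paced production trial
#'
#' Two minutes of unpaced bouncing or clapping at an individual referent
#' period with Gaussian timing jitter.
#'
#' @param referent_period_ms target inter-movement period, ms.
#' @param movement_type \code{"bounce"} or \code{"clap"}.
#' @param cv relative timing jitter (sd of jitter / period).
#' @param seed integer seed.
#' @param duration_s production duration (default 120 s).
#' @return an [accel_trace()].
#' @export
simulate_self_paced <- function(referent_period_ms, movement_type = "bounce",
                                cv = 0.04, seed = 1L, duration_s = 120) {
  pars <- sim_params(movement_type = movement_type, level_multiplier = 1,
                     phase_noise_sd = cv * referent_period_ms / sqrt(2))
  ev <- simulate_event_times(NULL, pars, seed = seed, offset_s = 0.3,
                             duration_s = duration_s,
                             referent_period_ms = referent_period_ms)
  render_trace(ev, pars, duration_s = duration_s, seed = seed + 1L)
}
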