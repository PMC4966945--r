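# shared fixtures, all built in code

metronome_125 <- function(duration_s = 115) {
  stimulus_spec("Metronome_125", "metronome", 125, duration_s,
                beat_saliency_z = 1.14)
}

# clean synthetic trial: returns list(trace, events, stimulus, params)
make_trial <- function(movement_type = "bounce", L = 2, tempo_bpm = 125,
                       rho = 0, phase_noise_sd = 0, noise_sd = 0,
                       duration_s = 115, seed = 1L, offset_s = 0.3, ...) {
  st <- stimulus_spec("stim", "metronome", tempo_bpm, duration_s)
  pars <- sim_params(movement_type = movement_type, level_multiplier = L,
                     tempo_mismatch = rho, phase_noise_sd = phase_noise_sd,
                     noise_sd = noise_sd, ...)
  ev <- simulate_event_times(st, pars, seed = seed, offset_s = offset_s)
  tr <- render_trace(ev, pars, duration_s = duration_s, seed = seed + 1L)
  list(trace = tr, events = ev, stimulus = st, params = pars)
}

# brute-force circular oracles, independent of the package implementation:
# explicit unit-vector accumulation in a loop
oracle_resultant <- function(angles) {
  cx <- 0; sx <- 0
  for (a in angles) { cx <- cx + cos(a); sx <- sx + sin(a) }
  sqrt((cx / length(angles))^2 + (sx / length(angles))^2)
}

# O(n^2) rank-sum oracle: count pairs a < b, half credit for ties
oracle_rank_sum_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x < y) + 0.5 * (x == y)
  u
}

# 4 planted success-profile archetypes with Gaussian jitter
planted_profiles <- function(n_per = 5, noise_sd = 0.03, seed = 16) {
  arch <- rbind(c(0.05, 0.05, 0.05, 0.05),   # global failure
                c(0.15, 0.35, 1.00, 1.00),   # music-only failure
                c(0.30, 0.85, 0.70, 1.00),   # graded failure
                c(0.10, 0.85, 0.30, 1.00))   # bounce-only failure
  m <- withr::with_seed(seed, {
    mm <- arch[rep(1:4, each = n_per), ] +
      matrix(rnorm(4 * n_per * 4, 0, noise_sd), ncol = 4)
    pmin(pmax(mm, 0), 1)
  })
  colnames(m) <- c("bounce_music", "clap_music", "bounce_metro", "clap_metro")
  rownames(m) <- sprintf("P%02d", seq_len(nrow(m)))
  list(m = m, truth = rep(1:4, each = n_per))
}

# event-recovery scores against the full ground truth, tolerance in seconds;
# recall is judged on events safely inside the analysis window (a true event
# a hair before window_start can legitimately be detected a sample later)
match_events <- function(recovered, truth_all, tol_s, window_start = 10) {
  in_win <- truth_all[truth_all >= window_start + tol_s]
  hits <- vapply(in_win, function(t) any(abs(recovered - t) <= tol_s),
                 logical(1))
  spurious <- vapply(recovered, function(t) all(abs(truth_all - t) > tol_s),
                     logical(1))
  list(recall = mean(hits), n_spurious = sum(spurious),
       precision = 1 - mean(spurious))
}
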