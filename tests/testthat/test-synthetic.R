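test_that("noise-free event times sit exactly on the beat grid", {
  st <- metronome_125()
  for (L in c(1, 2, 4)) {
    pars <- sim_params("bounce", level_multiplier = L, noise_sd = 0)
    ev <- simulate_event_times(st, pars, seed = 3, offset_s = 0)
    grid <- make_beat_grid(st)
    expect_equal(ev$event_times, grid[seq(1, length(grid), by = L)],
                 tolerance = 1e-12)
  }
})

test_that("a pure tempo mismatch stretches every interval exactly", {
  st <- metronome_125()
  pars <- sim_params("clap", level_multiplier = 1, tempo_mismatch = 0.05)
  ev <- simulate_event_times(st, pars, seed = 3, offset_s = 0)
  expect_equal(unique(round(ev$iris, 9)), 1.05 * 480)
})

test_that("generators are pure functions of seed and parameters", {
  st <- metronome_125()
  pars <- sim_params("clap", phase_noise_sd = 20, drift_sd = 2)
  e1 <- simulate_event_times(st, pars, seed = 99)
  e2 <- simulate_event_times(st, pars, seed = 99)
  expect_identical(e1$event_times, e2$event_times)
  e3 <- simulate_event_times(st, pars, seed = 100)
  expect_false(identical(e1$event_times, e3$event_times))

  t1 <- render_trace(e1, pars, duration_s = 20, seed = 5)
  t2 <- render_trace(e1, pars, duration_s = 20, seed = 5)
  expect_identical(t1$ax, t2$ax)

  f1 <- tempfile(); f2 <- tempfile()
  write_trace(t1, f1); write_trace(t2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical files
  rt <- read_trace(f1)
  expect_equal(rt$ax, t1$ax, tolerance = 1e-4)
  expect_equal(attr(rt, "movement_type"), "clap")
  unlink(c(f1, f2))
})

test_that("inter-event interval sd converges to sqrt(2) * phase noise sd", {
  pars <- sim_params("clap", phase_noise_sd = 20)
  # long self-paced run at a 500 ms period: ~4000 intervals
  ev <- simulate_event_times(NULL, pars, seed = 17, duration_s = 2000,
                             referent_period_ms = 500)
  expect_gt(length(ev$iris), 3000)
  expect_equal(sd(ev$iris), sqrt(2) * 20, tolerance = 0.05)
})

test_that("bimodal displacement moves the stated share of events", {
  st <- metronome_125()
  pars <- sim_params("clap", bimodal_offset = pi, bimodal_mix = 0.5)
  ev <- simulate_event_times(st, pars, seed = 21, offset_s = 0)
  ang <- events_to_angles(ev, 480, L = 1)$angles
  near0 <- mean(pmin(ang, 2 * pi - ang) < 0.1)
  nearpi <- mean(abs(ang - pi) < 0.1)
  expect_equal(near0 + nearpi, 1)
  expect_gt(nearpi, 0.35)
  expect_lt(nearpi, 0.65)
})

test_that("rendered claps put transient peaks at the event times", {
  pars <- sim_params("clap", noise_sd = 0)
  tr <- render_trace(c(1.0, 1.5), pars, sample_rate_hz = 100, duration_s = 3)
  mag <- sqrt(tr$ax^2 + tr$ay^2 + tr$az^2)
  thr <- 0.5 * max(mag)
  bursts <- split(which(mag > thr), cumsum(c(1, diff(which(mag > thr)) > 5)))
  expect_length(bursts, 2)
  peaks <- vapply(bursts, function(i) tr$time_s[i[which.max(mag[i])]], numeric(1))
  expect_equal(unname(peaks), c(1.0, 1.5), tolerance = 0.0101)
})

test_that("rendered bounce carries its fundamental at the event rate", {
  tri <- make_trial("bounce", L = 2, tempo_bpm = 125, noise_sd = 0)
  f <- dominant_frequency(discard_lead(tri$trace), axis = "az")
  expect_equal(f, 125 / 60 / 2, tolerance = 0.01)  # 1.0417 Hz
})

test_that("degenerate rendering yields a flat trace and low rates error", {
  pars <- sim_params("bounce", amplitude = 0, noise_sd = 0)
  tr <- render_trace(c(1, 2, 3), pars, duration_s = 5)
  expect_equal(sd(c(tr$ax, tr$ay, tr$az)), 0)
  expect_error(render_trace(c(1, 2), sim_params("clap"), sample_rate_hz = 40,
                            duration_s = 5),
               "50 Hz")
})

test_that("cohort plans have the full study design and honest labels", {
  co <- simulate_cohort(5, 0, seed = 2)
  expect_equal(nrow(co$plan), 5 * 8 * 2)  # 8 stimuli x 2 movements each
  expect_true(all(co$plan$group_truth == "normal"))
  expect_true(all(co$plan$trial_mode == "ok"))

  co2 <- simulate_cohort(0, 4, seed = 2)
  boa <- co2$plan[co2$plan$archetype == "bounce_only_failure", ]
  expect_true(all(boa$trial_mode[boa$movement_type == "clap"] == "ok"))
  expect_true(all(boa$trial_mode[boa$movement_type == "bounce"] == "fail"))

  expect_error(simulate_cohort(0, 0), "at least one")

  # same seed -> identical realized traces
  p1 <- realize_trial(co$plan[1, ], co$stimuli)
  p2 <- realize_trial(co$plan[1, ], co$stimuli)
  expect_identical(p1$az, p2$az)
})
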