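test_that("a trial is normal only when every segment is significant", {
  expect_equal(classify_trial(c(.01, .001, .02, .03)), "normal")
  expect_equal(classify_trial(c(.01, .20, .001, .001)), "poor")
  expect_equal(classify_trial(c(.01, .001), bimodal = TRUE), "bimodal")
  expect_error(classify_trial(list()), "no segments")
  # works on rayleigh_result objects too
  segs <- lapply(1:4, function(i) rayleigh_test(rep(0.3, 20) + i * 1e-3))
  expect_equal(classify_trial(segs), "normal")
})

test_that("lowering alpha can only move trials from normal to poor", {
  set.seed(11)
  for (i in 1:30) {
    p <- runif(4, 0, 0.2)
    cls <- vapply(c(0.1, 0.05, 0.01), function(al) classify_trial(p, alpha = al),
                  character(1))
    # once poor at some alpha, poor at every smaller alpha
    poor_at <- cls == "poor"
    expect_true(all(poor_at == cummax(poor_at)))
  }
})

make_profile <- function(poor_bounce_music = 0, poor_clap_music = 0,
                         bimodal_bounce = 0, n_four_beat = 0) {
  trials <- expand.grid(movement_type = c("bounce", "clap"),
                        stim = 1:8, stringsAsFactors = FALSE)
  trials$is_metronome <- trials$stim >= 7
  trials$trial_class <- "normal"
  trials$level <- "beat"
  flip <- function(df, mv, k, class, metro = FALSE) {
    i <- which(df$movement_type == mv & df$is_metronome == metro &
                 df$trial_class == "normal")[seq_len(k)]
    df$trial_class[i] <- class
    df
  }
  trials <- flip(trials, "bounce", poor_bounce_music, "poor")
  trials <- flip(trials, "clap", poor_clap_music, "poor")
  trials <- flip(trials, "bounce", bimodal_bounce, "bimodal")
  if (n_four_beat > 0) {
    trials$level[seq_len(n_four_beat)] <- "four_beat"
  }
  trials
}

test_that("participant rules follow the 3-of-6 and 3-of-8 thresholds", {
  r <- classify_participant(make_profile(poor_bounce_music = 3))
  expect_equal(r$group, "poor_synchronizer")
  expect_equal(unname(r$n_poor), c(3L, 0L))

  # two poor music trials per movement type stays normal (threshold is 3)
  r2 <- classify_participant(make_profile(poor_bounce_music = 2,
                                          poor_clap_music = 2))
  expect_equal(r2$group, "normal_synchronizer")

  r3 <- classify_participant(make_profile(bimodal_bounce = 3))
  expect_equal(r3$group, "excluded")
  expect_equal(r3$exclusion_reason, "bimodal_overload")

  # predominantly four-beat mover is excluded before anything else
  r4 <- classify_participant(make_profile(n_four_beat = 16))
  expect_equal(r4$exclusion_reason, "four_beat_mover")

  # off-tempo music trials count toward the poor rule
  tr <- make_profile()
  i <- which(tr$movement_type == "clap" & !tr$is_metronome)[1:3]
  tr$trial_class[i] <- "level_excluded"
  tr$level[i] <- "off_tempo"
  expect_equal(classify_participant(tr)$group, "poor_synchronizer")

  # bimodal music trials do NOT count as poor
  tr2 <- make_profile(bimodal_bounce = 2)
  expect_equal(classify_participant(tr2)$group, "normal_synchronizer")

  only_bounce <- make_profile()[make_profile()$movement_type == "bounce", ]
  expect_error(classify_participant(only_bounce), "incomplete")
})

test_that("regularity is the sign-flipped log of circular variance", {
  expect_equal(synchronization_regularity(1), 0)
  expect_equal(synchronization_regularity(0.1), 1)
  expect_equal(synchronization_regularity(0), 6)  # floored at 1e-6
  v <- seq(1e-5, 1, length.out = 50)
  expect_true(all(diff(synchronization_regularity(v)) < 0))  # strictly decreasing
  expect_error(synchronization_regularity(1.2), "\\[0, 1\\]")
  expect_error(synchronization_regularity(-0.1), "\\[0, 1\\]")
})

test_that("regularity falls as injected timing noise rises", {
  st <- metronome_125()
  noise <- c(5, 15, 30, 60, 100)
  sr <- vapply(seq_along(noise), function(i) {
    pars <- sim_params("clap", phase_noise_sd = noise[i])
    ev <- simulate_event_times(st, pars, seed = 100 + i)
    V <- circular_variance(events_to_angles(ev, 480, L = 1))
    synchronization_regularity(V)
  }, numeric(1))
  expect_lt(cor(noise, sr, method = "spearman"), 0)
  expect_true(all(diff(sr) < 0))
})

test_that("trial accounting reproduces the cohort percentages", {
  a <- trial_accounting(776, 37, 20, 53)
  expect_equal(a$poor_pct, 7.4)
  expect_equal(a$normal, 776 - 37 - 20 - 53)
  b <- trial_accounting(776, 14, 15, 23)
  expect_equal(b$poor_pct, 3.1)
  expect_equal(trial_accounting(100, 5, 5, 0)$poor_pct, 0)
  expect_error(trial_accounting(10, 5, 5, 1), "more poor")
})
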