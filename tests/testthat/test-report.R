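test_that("level-table medians reproduce the printed cohort medians", {
  # per-stimulus participant counts at each level, both movement types
  clap_beat <- c(95, 89, 85, 90, 78, 75, 65, 56)
  bounce_beat <- c(55, 57, 68, 61, 52, 52, 49, 44)
  clap_two <- c(2, 7, 11, 4, 16, 19, 28, 38)
  bounce_two <- c(39, 38, 25, 27, 38, 38, 44, 47)
  expect_equal(median_half_even(clap_beat), 82)    # raw 81.5
  expect_equal(median_half_even(bounce_beat), 54)  # raw 53.5
  expect_equal(median_half_even(clap_two), 14)     # raw 13.5
  expect_equal(median_half_even(bounce_two), 38)   # raw 38.5
  expect_equal(median_half_even(rep(7, 8)), 7)

  # the table builder aggregates trial rows into the same counts
  trials <- do.call(rbind, lapply(1:8, function(s) {
    n <- clap_beat[s] + clap_two[s]
    data.frame(stimulus_name = paste0("S", s),
               movement_type = "clap",
               level = rep(c("beat", "two_beat"), c(clap_beat[s], clap_two[s])))
  }))
  tab <- level_distribution_table(trials)
  expect_equal(tab$counts$clap_beat, clap_beat)
  expect_equal(tab$counts$clap_two_beat, clap_two)
  expect_equal(unname(tab$medians["clap_beat"]), 82)
})

test_that("success profiles are per-condition proportions over classifiable trials", {
  grid <- expand.grid(participant_id = "P1",
                      movement_type = c("bounce", "clap"),
                      stim = 1:8, stringsAsFactors = FALSE)
  grid$is_metronome <- grid$stim >= 7
  grid$trial_class <- "normal"
  p <- success_profiles(grid)
  expect_equal(unlist(p[1, -1], use.names = FALSE), c(1, 1, 1, 1))

  grid$trial_class[grid$movement_type == "bounce"] <- "poor"
  p2 <- success_profiles(grid)
  expect_equal(unlist(p2[1, -1], use.names = FALSE), c(0, 1, 0, 1))

  # excluded trials leave the denominator; empty conditions are NA not 0
  grid$trial_class[grid$movement_type == "clap" & !grid$is_metronome] <- "bimodal"
  grid$trial_class[grid$movement_type == "clap" & grid$is_metronome] <- "level_excluded"
  p3 <- success_profiles(grid)
  expect_true(is.na(p3$clap_music) && is.na(p3$clap_metro))

  # invariant to trial ordering
  shuf <- grid[sample(nrow(grid)), ]
  expect_equal(success_profiles(shuf), success_profiles(grid))
})

test_that("well-separated archetype profiles are recovered exactly at k = 4", {
  pp <- planted_profiles()
  res <- cluster_profiles(pp$m, k_range = 2:6, seed = 1)
  expect_equal(res$k, 4)
  # exact partition recovery up to label permutation
  expect_equal(unname(table(res$assignments, pp$truth) > 0) |> rowSums(),
               rep(1, 4))
  expect_true(all(table(res$assignments) == 5))
  # k-means fixed point: each centroid equals the mean of its members
  for (g in 1:4) {
    expect_equal(unname(res$centroids[g, ]),
                 unname(colMeans(pp$m[res$assignments == g, , drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("clustering handles forced and degenerate cases", {
  pp <- planted_profiles()
  one <- cluster_profiles(pp$m, k = 1)
  expect_equal(unname(one$centroids[1, ]), unname(colMeans(pp$m)))

  dup <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 7), nrow = 7)
  colnames(dup) <- colnames(pp$m)
  dd <- cluster_profiles(dup, k_range = 2:4)
  expect_equal(dd$k, 1)

  expect_error(cluster_profiles(pp$m[1:2, ], k_range = 3:4), "fewer profiles")
})

test_that("the rank-sum U matches the pair-count oracle and wilcox", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(10, 11, 12))$U, 9)   # full separation
  expect_equal(rank_sum_test(c(10, 11, 12), c(1, 2, 3))$U, 0)
  expect_equal(rank_sum_test(1:4, 1:4)$U, 8)                    # symmetry: n1 n2 / 2

  set.seed(17)
  for (i in 1:25) {
    n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
    a <- sample(1:8, n1, replace = TRUE)  # ties likely
    b <- sample(1:8, n2, replace = TRUE)
    r <- rank_sum_test(a, b)
    expect_equal(r$U, oracle_rank_sum_U(a, b))
    w <- suppressWarnings(wilcox.test(b, a, exact = FALSE, correct = FALSE))
    expect_equal(r$U, unname(w$statistic))
    expect_equal(r$p, w$p.value, tolerance = 1e-9)
  }
})

test_that("condition summaries weight regularity by response count", {
  sr <- data.frame(
    participant_id = rep(c("P1", "P2"), each = 4),
    movement_type = rep(c("bounce", "clap"), 4),
    stimulus_name = rep(c("S1", "S2"), each = 2, times = 2),
    sr = c(1, 2, 1.5, 2.5, 0.5, 1.5, 1.0, 2.0),
    n = c(100, 200, 100, 200, 100, 200, 100, 200))
  cs <- condition_summary(sr)
  # equal weights reduce to the plain mean
  sr_eq <- sr; sr_eq$n <- 50
  cs_eq <- condition_summary(sr_eq)
  expect_equal(unname(cs_eq$by_movement["bounce"]),
               mean(sr$sr[sr$movement_type == "bounce"]))
  # weighted means follow sum(w x)/sum(w)
  bo <- sr[sr$movement_type == "bounce", ]
  expect_equal(unname(cs$by_movement["bounce"]),
               sum(bo$sr * bo$n) / sum(bo$n))
  expect_equal(unname(cs$clap_minus_bounce["P1"]), 2.25 - 1.25)

  # generator check: tighter clap timing shows up as higher clap regularity
  st <- metronome_125()
  srs <- lapply(1:6, function(i) {
    out <- lapply(c(bounce = 35, clap = 12), function(ns) {
      pars <- sim_params("clap", phase_noise_sd = ns)
      ev <- simulate_event_times(st, pars, seed = 500 + i)
      V <- circular_variance(events_to_angles(ev, 480, L = 1))
      synchronization_regularity(V)
    })
    data.frame(participant_id = paste0("P", i),
               movement_type = c("bounce", "clap"),
               stimulus_name = "M125", sr = unlist(out), n = c(239, 239))
  })
  cs2 <- condition_summary(do.call(rbind, srs))
  expect_gt(cs2$by_movement[["clap"]], cs2$by_movement[["bounce"]])
  expect_true(all(cs2$clap_minus_bounce > 0))
})
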