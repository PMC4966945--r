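test_that("response times map onto the beat circle by modular arithmetic", {
  ibi <- 480
  expect_equal(events_to_angles(c(0.48, 0.96, 4.80), ibi, L = 1)$angles,
               rep(0, 3), tolerance = 1e-9)
  expect_equal(events_to_angles(0.24, ibi, L = 1)$angles, pi)

  # independent mod-and-scale oracle on an arbitrary series
  set.seed(5)
  t <- sort(runif(15, 0, 60))
  for (L in 1:2) {
    span <- L * ibi
    want <- 2 * pi * ((t * 1000) %% span) / span
    got <- events_to_angles(t, ibi, L = L)
    expect_equal(got$angles, want, tolerance = 1e-12)
    expect_equal(got$circle_span_ms, span)
    expect_true(all(got$angles >= 0 & got$angles < 2 * pi))
  }
  expect_error(events_to_angles(numeric(0), ibi), "no events")
  expect_error(events_to_angles(1, 0), "positive")
})

test_that("translating events by whole circles leaves angles unchanged", {
  set.seed(6)
  t <- sort(runif(12, 0, 30))
  for (L in 1:2) {
    a0 <- events_to_angles(t, 483.871, L = L)$angles   # unrounded 124 BPM IBI
    a1 <- events_to_angles(t + 7 * L * 0.483871, 483.871, L = L)$angles
    expect_equal(a1, a0, tolerance = 1e-8)
  }
})

test_that("resultant length and circular variance match the vector-sum oracle", {
  expect_equal(resultant_length(rep(1.3, 9)), 1)
  expect_equal(resultant_length(c(0, pi / 2, pi, 3 * pi / 2)), 0,
               tolerance = 1e-12)
  expect_equal(resultant_length(c(0, pi / 2)), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, pi / 2)), 1 - sqrt(2) / 2,
               tolerance = 1e-12)
  expect_equal(circular_variance(rep(0.2, 5)), 0)
  expect_equal(circular_variance(c(0, pi / 2, pi, 3 * pi / 2)), 1,
               tolerance = 1e-12)

  set.seed(7)
  for (i in 1:20) {
    a <- runif(sample(4:200, 1), 0, 2 * pi)
    expect_equal(resultant_length(a), oracle_resultant(a), tolerance = 1e-12)
    expect_equal(circular_variance(a), 1 - oracle_resultant(a),
                 tolerance = 1e-12)
  }
  expect_error(resultant_length(numeric(0)), "no angles")
})

test_that("the Rayleigh statistic and p follow the stated formula", {
  r <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(r$R, 0, tolerance = 1e-12)
  expect_equal(r$z, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)  # exp(sqrt(81) - 9) at n = 4, R = 0

  r2 <- rayleigh_test(rep(0.7, 20))
  expect_equal(r2$R, 1)
  expect_equal(r2$z, 20)
  expect_equal(r2$p, exp(-32), tolerance = 1e-10)

  # z = n R^2 identity on random inputs
  set.seed(8)
  for (i in 1:10) {
    a <- runif(sample(4:60, 1), 0, 2 * pi)
    rr <- rayleigh_test(a)
    expect_equal(rr$z, rr$n * rr$R^2, tolerance = 1e-12)
    expect_true(rr$p > 0 && rr$p <= 1)
  }
  expect_error(rayleigh_test(c(0, 1, 2)), "too few")
})

test_that("all circular statistics are rotation invariant", {
  set.seed(9)
  for (i in 1:10) {
    a <- runif(30, 0, 2 * pi)
    rot <- runif(1, 0, 2 * pi)
    b <- (a + rot) %% (2 * pi)
    expect_equal(resultant_length(b), resultant_length(a), tolerance = 1e-12)
    expect_equal(circular_variance(b), circular_variance(a), tolerance = 1e-12)
    ra <- rayleigh_test(a); rb <- rayleigh_test(b)
    expect_equal(rb$z, ra$z, tolerance = 1e-10)
    expect_equal(rb$p, ra$p, tolerance = 1e-10)
  }
})

test_that("segmentation is consecutive with the remainder up front", {
  segs <- segment_angles(seq_len(40) / 40, L = 1)
  expect_equal(lengths(segs), c(`1` = 10, `2` = 10, `3` = 10, `4` = 10))
  segs <- segment_angles(seq_len(42) / 42, L = 1)
  expect_equal(unname(lengths(segs)), c(11, 11, 10, 10))
  segs <- segment_angles(seq_len(21) / 21, L = 2)
  expect_equal(unname(lengths(segs)), c(11, 10))
  expect_equal(unlist(segs, use.names = FALSE), seq_len(21) / 21)  # order kept
  expect_error(segment_angles(runif(7), L = 1), "too few")
})

test_that("axial doubling flags two-lobe distributions and only those", {
  set.seed(10)
  two <- c(rnorm(25, 0, 0.1), rnorm(25, pi, 0.1)) %% (2 * pi)
  d <- detect_bimodality(two)
  expect_true(d$bimodal)
  expect_lt(d$R, 0.3)
  expect_gt(d$R2, 0.9)

  one <- rnorm(50, 1, 0.1) %% (2 * pi)
  expect_false(detect_bimodality(one)$bimodal)

  expect_false(detect_bimodality(runif(6))$determined)  # n too small

  # false-flag rate on uniform angles stays near alpha
  flags <- vapply(1:400, function(i) {
    detect_bimodality(runif(30, 0, 2 * pi))$bimodal
  }, logical(1))
  expect_lte(mean(flags), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 400))
})
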