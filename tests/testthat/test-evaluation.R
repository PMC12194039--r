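test_that("binning sums rate mass and spike counts per bin", {
  # block sums of rate * dt
  ts <- time_series(c(1, 1, 1, 1, 2, 2, 2, 2), dt = 1)
  expect_equal(bin_downsample(ts, 4), c(4, 8))
  expect_equal(bin_downsample(ts, 1), ts$values)
  # brute-force binning oracle for spikes on the 10 ms grid, factor 4
  tr <- spike_train(c(0.005, 0.012, 0.095), duration = 0.12)
  expect_equal(bin_downsample(tr, 4, native_dt = 0.01), c(2, 0, 1))
  # trailing partial bin is dropped with a warning
  expect_warning(out <- bin_downsample(time_series(rep(1, 10), dt = 1), 4),
                 "partial bin")
  expect_equal(out, c(4, 4))
  expect_error(bin_downsample(ts, 0), "positive integer")
})

test_that("binning conserves total spike count up to the dropped tail", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(5:50, 1)
      times <- sort(runif(n, 0, 2))
      tr <- spike_train(times, duration = 2)
      counts <- bin_downsample(tr, 4, native_dt = 0.01)
      expect_equal(sum(counts), n)
    }
  })
})

test_that("pearson matches hand computation and affine invariance", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  # hand-computed: centered cross product -2.25 over variance 2.75
  expect_equal(pearson(c(1, 0, 2, 0), c(0, 1, 0, 2)), -9 / 11,
               tolerance = 1e-12)
  withr::with_seed(13, {
    a <- rnorm(40)
    b <- rnorm(40)
    for (lambda in c(0.5, 3)) {
      expect_equal(pearson(a, lambda * b + 2), pearson(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson(1, 1), "at least 2")
})

test_that("Victor-Purpura distance has unit move cost per native timestep", {
  cfg <- metric_config()
  a <- spike_train(0.100, duration = 1)
  b <- spike_train(0.110, duration = 1)
  expect_equal(victor_purpura(a, b, cfg), 1, tolerance = 1e-12)
  expect_equal(victor_purpura(a, a, cfg), 0)
  expect_equal(victor_purpura(spike_train(), spike_train(c(0.1, 0.2, 0.3)),
                              cfg), 3)
})

test_that("Victor-Purpura matches the exhaustive matching oracle", {
  cfg <- metric_config()
  q <- cfg$vp_shift_cost_per_step / cfg$native_dt
  grid <- seq(0, 0.09, by = 0.01)
  withr::with_seed(41, {
    for (i in 1:40) {
      a <- sort(sample(grid, sample(0:5, 1)))
      b <- sort(sample(grid, sample(1:5, 1)))
      d <- victor_purpura(a, b, cfg)
      expect_equal(d, vp_oracle(a, b, q), tolerance = 1e-12)
      # metric axioms
      expect_equal(d, victor_purpura(b, a, cfg), tolerance = 1e-12)
      expect_lte(d, length(a) + length(b) + 1e-12)
      cc <- sort(sample(grid, sample(0:5, 1)))
      expect_lte(d, victor_purpura(a, cc, cfg) +
                   victor_purpura(cc, b, cfg) + 1e-9)
    }
  })
})

test_that("rate traces convert to spike trains by per-bin rounding", {
  cfg <- metric_config()
  expect_equal(length(rates_to_spikes(time_series(rep(0, 40), dt = 0.01),
                                      cfg)), 0)
  # one 40 ms bin carrying mass 0.96 emits one spike at the bin center
  s <- time_series(c(24, 24, 24, 24), dt = 0.01)  # 0.96 expected spikes
  st <- rates_to_spikes(s, cfg)
  expect_equal(st$times, 0.02)
  # the drive of a known train round-trips exactly
  tr <- spike_train(c(0.015, 0.055, 0.056, 0.091), duration = 0.12)
  drv <- spikes_to_drive(tr, dt = 0.01, duration = 0.12)
  back <- rates_to_spikes(drv, cfg)
  expect_equal(length(back), length(tr))
  expect_equal(spike_counts(back, 0.04, 3), spike_counts(tr, 0.04, 3))
})

test_that("score summaries report per-group and pooled dispersion", {
  out <- summarize_scores(c(0.5, 0.5), c("d1", "d1"))
  expect_equal(out$sd[out$group == "d1"], 0)
  out2 <- summarize_scores(c(1, 3, 5, 7), c("a", "a", "b", "b"))
  expect_equal(out2$sd[out2$group == "a"], sqrt(2))
  expect_equal(out2$sd[out2$group == "b"], sqrt(2))
  expect_equal(out2$sd[out2$group == "all"], sd(c(1, 3, 5, 7)))
  expect_equal(out2$mean[out2$group == "all"], 4)
  out3 <- summarize_scores(0.4, "solo")
  expect_true(out3$degenerate[out3$group == "solo"])
  expect_equal(out3$sd[out3$group == "solo"], 0)
})
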