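test_that("perfect tracking with zero input yields a near-zero solution", {
  p <- gcamp_cell(alpha = 50)
  cfg <- mpc_config()
  state0 <- c(x = 2, z = 5)
  path <- crn_simulate(p, function(t) 0, state0, seq(0, 0.07, 0.01),
                       method = "rk4", substeps = 2)
  sol <- solve_horizon(p, state0, path$z, s_prev = 0, cfg)
  expect_lt(max(sol$s), 1e-4)
  expect_lt(sol$cost, 1e-8)
})

test_that("constant drive is recovered within 5% and beats a grid oracle", {
  p <- gcamp_cell(alpha = 50)
  cfg <- mpc_config()
  c_true <- 3
  ss <- crn_steady_state(p, c_true)
  path <- crn_simulate(p, function(t) c_true, ss, seq(0, 0.07, 0.01),
                       method = "rk4", substeps = 2)
  meas <- path$z[1:7]
  sol <- solve_horizon(p, ss, meas, s_prev = c_true, cfg)
  expect_true(all(abs(sol$s - c_true) / c_true < 0.05))
  # independent oracle: dense grid over constant rate sequences, cost
  # evaluated by a plain-R rollout of the same objective
  grid <- seq(0, 10, by = 0.05)
  oc <- vapply(grid, function(s0)
    horizon_cost_oracle(p, rep(s0, 6), ss, meas, c_true, cfg), numeric(1))
  expect_equal(grid[which.min(oc)], c_true, tolerance = 0.05)
  expect_lte(sol$cost, min(oc) + 1e-12)
})

test_that("compiled horizon cost agrees with the plain-R oracle", {
  p <- gcamp_cell(alpha = 20)
  cfg <- mpc_config()
  withr::with_seed(5, {
    for (i in 1:10) {
      s_seq <- runif(6, 0, 8)
      state0 <- c(x = runif(1, 0, 3), z = runif(1, 0, 10))
      meas <- runif(7, 0, 10)
      sp <- runif(1, 0, 5)
      got <- spikempc:::mpc_horizon_cost_cpp(
        s_seq, state0[["x"]], state0[["z"]], meas, sp,
        spikempc:::flatten_params(p), unclass(cfg))
      want <- horizon_cost_oracle(p, s_seq, state0, meas, sp, cfg)
      expect_equal(got$cost, want, tolerance = 1e-10)
    }
  })
})

test_that("a large smoothness weight forces a near-constant solution", {
  p <- gcamp_cell(alpha = 50)
  cfg <- mpc_config(r = 1e6)
  state0 <- crn_steady_state(p, 2)
  meas <- state0[["z"]] + c(0, 1, -1, 2, 0.5, -0.5, 1)
  sol <- solve_horizon(p, state0, meas, s_prev = 0, cfg)
  expect_lt(max(sol$s) - min(sol$s), 1e-3)
})

test_that("reported horizon cost never exceeds the zero-input candidate", {
  p <- gcamp_cell(alpha = 50)
  cfg <- mpc_config()
  withr::with_seed(9, {
    for (i in 1:10) {
      state0 <- c(x = runif(1, 0, 5), z = runif(1, 0, 12))
      meas <- runif(7, 0, 12)
      sp <- runif(1, 0, 3)
      sol <- solve_horizon(p, state0, meas, s_prev = sp, cfg)
      zero_cost <- horizon_cost_oracle(p, rep(0, 6), state0, meas, sp, cfg)
      expect_lte(sol$cost, zero_cost + 1e-9)
    }
  })
})

test_that("a flat measurement at the zero equilibrium infers silence", {
  p <- gcamp_cell(alpha = 50)
  meas <- time_series(rep(0, 200), dt = 0.01)
  res <- infer_rates(meas, p, mpc_config())
  expect_lt(max(res$s_hat$values), 1e-3)
  expect_true(all(res$s_hat$values >= 0))
})

test_that("a step change in the drive is localized within the horizon", {
  p <- gcamp_cell(alpha = 50)
  cfg <- mpc_config()
  times <- seq(0, 3, 0.01)
  c_after <- 5
  rate <- function(t) ifelse(t >= 1, c_after, 0)
  tr <- crn_simulate(p, rate, c(x = 0, z = 0), times, method = "rk4",
                     substeps = 10)
  res <- infer_rates(time_series(tr$z, dt = 0.01), p, cfg,
                     init = c(x = 0, z = 0))
  k_true <- which(times >= 1)[1]
  k_hat <- which(res$s_hat$values > c_after / 2)[1]
  expect_lte(abs(k_hat - k_true), cfg$n)
  # and the post-transition plateau is accurate
  plateau <- res$s_hat$values[times > 1.5 & times < 2.9]
  expect_lt(mean(abs(plateau - c_after)) / c_after, 0.05)
})

test_that("inference is causal: emitted rates never change with later data", {
  p <- gcamp_cell(alpha = 50)
  cfg <- mpc_config()
  withr::with_seed(21, {
    spec <- synthetic_spec(duration = 3, mean_rate = 2, noise_sigma = 1,
                           seed = 77)
  })
  train <- generate_spike_train(spec)
  rec <- synth_recording(gcamp_cell(alpha = 50), train, spec)
  full <- rec$noisy
  short <- time_series(full$values[1:260], dt = full$dt)
  res_full <- infer_rates(full, p, cfg)
  res_short <- infer_rates(short, p, cfg)
  keep <- seq_len(260 - cfg$n)
  expect_identical(res_full$s_hat$values[keep],
                   res_short$s_hat$values[keep])
})

test_that("rates stay nonnegative on noisy data", {
  p <- gcamp_cell(alpha = 50)
  spec <- synthetic_spec(duration = 5, mean_rate = 2, noise_sigma = 2,
                         seed = 3)
  train <- generate_spike_train(spec)
  rec <- synth_recording(p, train, spec)
  res <- infer_rates(rec$noisy, p, mpc_config())
  expect_true(all(res$s_hat$values >= 0))
  expect_equal(length(res$s_hat$values), length(rec$noisy$values))
})

test_that("tracking a feasible reference drives the model onto it", {
  p <- gcamp_cell(alpha = 50)
  rate <- function(t) 2 + 1.5 * sin(t)
  tr <- crn_simulate(p, rate, crn_steady_state(p, 2), seq(0, 4, 0.01),
                     method = "rk4", substeps = 10)
  desired <- time_series(tr$z, dt = 0.01)
  res <- track_reference(desired, p, mpc_config(),
                         init = crn_steady_state(p, 2))
  err <- abs(res$ci_sim$values - desired$values)
  expect_lt(mean(tail(err, 200)), 0.02 * mean(desired$values))
  expect_false(res$diagnostics$infeasible_reference)
})

test_that("an unattainable reference above L is flagged and z stays below L", {
  p <- gcamp_cell(alpha = 50)
  desired <- time_series(rep(40, 150), dt = 0.01)  # L = 30
  res <- track_reference(desired, p, mpc_config())
  expect_true(res$diagnostics$infeasible_reference)
  expect_lt(max(res$ci_sim$values), 30)
})

test_that("a square-wave reference elicits rate pulses at rising edges", {
  p <- gcamp_cell(alpha = 50)
  z_lo <- crn_steady_state(p, 1)[["z"]]
  z_hi <- crn_steady_state(p, 6)[["z"]]
  desired <- time_series(rep(c(z_lo, z_hi), each = 100, times = 2),
                         dt = 0.01)
  res <- track_reference(desired, p, mpc_config(),
                         init = crn_steady_state(p, 1))
  s <- res$s_hat$values
  # rate right after each rising edge far exceeds the plateau that follows
  for (edge in c(100, 300)) {
    pulse <- max(s[edge:(edge + 20)])
    plateau <- mean(s[(edge + 60):(edge + 95)])
    expect_gt(pulse, 2 * plateau)
  }
})
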