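test_that("the worked-example drive has the advertised frequency and range", {
  spec <- drive_spec(A = 10, omega = 0.5, c = 11)
  tt <- seq(0, 200, by = 0.01)
  s <- drive_signal(spec, tt)
  expect_equal(min(s), 1, tolerance = 1e-6)
  expect_equal(max(s), 21, tolerance = 1e-6)
  # dominant frequency from the periodogram
  sp <- Mod(fft(s - mean(s)))[2:(length(s) %/% 2)]
  f_grid <- (seq_along(sp)) / (length(s) * 0.01)
  f_hat <- f_grid[which.max(sp)]
  # agreement up to the periodogram's frequency resolution
  expect_lt(abs(f_hat - 1 / (4 * pi)), 1.5 / 200)
  # A = 0 collapses to the offset
  expect_equal(drive_signal(drive_spec(A = 0, omega = 1, c = 3), tt),
               rep(3, length(tt)))
  expect_warning(drive_signal(drive_spec(A = 20, omega = 0.5, c = 1), 0:5),
                 "clipping")
})

test_that("quasi-static amplitude ratio matches the steady-state map", {
  p <- gcamp_cell(alpha = 50)
  spec <- drive_spec(A = 3, omega = 0.05, c = 11)
  res <- amplitude_ratio(p, spec)
  zs <- function(s) crn_steady_state(p, s)[["z"]]
  xs <- function(s) crn_steady_state(p, s)[["x"]]
  qs_z <- (zs(14) - zs(8)) / 6
  qs_x <- (xs(14) - xs(8)) / 6
  expect_equal(res$ratio_z, qs_z, tolerance = 0.05)
  expect_equal(res$ratio_x, qs_x, tolerance = 0.05)
  expect_true(res$settled)
})

test_that("settled oscillations run at the drive frequency", {
  p <- gcamp_cell(alpha = 50)
  omega <- 2
  period <- 2 * pi / omega
  drive <- function(t) 3 * sin(omega * t) + 11
  times <- seq(0, 80, by = period / 128)
  tr <- crn_simulate(p, drive, crn_steady_state(p, 11), times)
  tail_z <- tr$z[tr$time > 60]
  sp <- Mod(fft(tail_z - mean(tail_z)))[2:(length(tail_z) %/% 2)]
  dt_out <- period / 128
  f_grid <- seq_along(sp) / (length(tail_z) * dt_out)
  f_hat <- f_grid[which.max(sp)]
  expect_equal(f_hat, omega / (2 * pi), tolerance = f_grid[1] * 1.5)
})

test_that("GCaMP6s indicator response falls off with drive frequency", {
  p <- gcamp_cell(alpha = 50)
  sweep <- frequency_sweep(p, drive_spec(A = 3, c = 11),
                           omega_grid = exp(c(-2, 0, 2)))
  expect_equal(nrow(sweep), 3)
  expect_true(all(diff(sweep$ratio_z) < 0))
  expect_true(all(sweep$settled))
  # single-point sweep equals a direct amplitude_ratio call
  one <- frequency_sweep(p, drive_spec(A = 3, c = 11), omega_grid = 1)
  direct <- amplitude_ratio(p, drive_spec(A = 3, omega = 1, c = 11))
  expect_equal(one$ratio_z, direct$ratio_z, tolerance = 1e-12)
})

test_that("indicator comparison reports affinities and antisymmetric differences", {
  hyp <- indicator_params(0.01, 10, 30)
  grid <- exp(c(0, 1))
  cmp <- compare_indicators(gcamp6s(), hyp, alpha = 50, gamma = 1,
                            omega_grid = grid)
  expect_equal(unname(cmp$k_d["candidate"]), 0.001, tolerance = 1e-12)
  expect_equal(unname(cmp$k_d["base"]), 0.0514 / 7.6, tolerance = 1e-12)
  # identical indicators differ nowhere
  same <- compare_indicators(gcamp6s(), gcamp6s(), alpha = 50, gamma = 1,
                             omega_grid = grid)
  expect_equal(max(abs(same$difference$d_ratio_z)), 0, tolerance = 1e-9)
  # swapping the roles negates the difference table
  swp <- compare_indicators(hyp, gcamp6s(), alpha = 50, gamma = 1,
                            omega_grid = grid)
  expect_equal(swp$difference$d_ratio_z, -cmp$difference$d_ratio_z,
               tolerance = 1e-9)
})

test_that("equal binding affinity does not imply equal dynamics", {
  base <- indicator_params(0.0514, 7.6, 30)
  slow <- indicator_params(0.00514, 0.76, 30)  # same k_d, 10x slower
  grid <- exp(c(0, 1))
  a <- frequency_sweep(cell_params(base, 50, 1), drive_spec(A = 3, c = 11),
                       grid)
  b <- frequency_sweep(cell_params(slow, 50, 1), drive_spec(A = 3, c = 11),
                       grid)
  expect_gt(max(abs(a$ratio_z - b$ratio_z)), 0.01)
})
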