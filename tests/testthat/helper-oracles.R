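# Shared fixtures and independent oracles used across the suite.

gcamp_cell <- function(alpha = 1, gamma = 1) {
  cell_params(gcamp6s(), alpha = alpha, gamma = gamma)
}

# Independent fixed-step RK4 integrator, written directly against the model
# equations in plain R (no package internals). Returns the state at t_end.
rk4_oracle <- function(params, rate, init, t_end, h) {
  k_f <- params$indicator$k_f; k_r <- params$indicator$k_r
  L <- params$indicator$L; al <- params$alpha; ga <- params$gamma
  f <- function(t, u) {
    s <- rate(t)
    bind <- k_f * u[1] * (L - u[2])
    c(al * s - ga * u[1] + k_r * u[2] - bind, bind - k_r * u[2])
  }
  u <- c(init[["x"]], init[["z"]])
  t <- 0
  n <- round(t_end / h)
  for (i in seq_len(n)) {
    k1 <- f(t, u)
    k2 <- f(t + h / 2, u + h / 2 * k1)
    k3 <- f(t + h / 2, u + h / 2 * k2)
    k4 <- f(t + h, u + h * k3)
    u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  c(x = u[1], z = u[2])
}

# R-side evaluation of the finite-horizon cost: forward-simulates the
# discretized dynamics with its own RK4 and sums the stage, smoothness and
# terminal terms. Independent of the compiled implementation.
horizon_cost_oracle <- function(params, s_seq, state0, meas, s_prev, cfg) {
  u <- c(state0[["x"]], state0[["z"]])
  k_f <- params$indicator$k_f; k_r <- params$indicator$k_r
  L <- params$indicator$L; al <- params$alpha; ga <- params$gamma
  h <- cfg$dt / cfg$substeps
  n <- length(s_seq)
  cost <- (u[2] - meas[1])^2
  prev <- s_prev
  for (k in seq_len(n)) {
    f <- function(u) {
      bind <- k_f * u[1] * (L - u[2])
      c(al * s_seq[k] - ga * u[1] + k_r * u[2] - bind, bind - k_r * u[2])
    }
    for (m in seq_len(cfg$substeps)) {
      k1 <- f(u); k2 <- f(u + h / 2 * k1)
      k3 <- f(u + h / 2 * k2); k4 <- f(u + h * k3)
      u <- u + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    w <- if (k == n) cfg$terminal_weight else 1
    cost <- cost + w * (u[2] - meas[k + 1])^2 + cfg$r * (s_seq[k] - prev)^2
    prev <- s_seq[k]
  }
  cost
}

# Exhaustive Victor-Purpura oracle: minimum over all order-preserving
# matchings (equal-size subsets of each train paired in time order) of
# q * sum |dt| plus unit cost per unmatched spike. Feasible for <= 5 spikes.
vp_oracle <- function(a, b, q) {
  la <- length(a); lb <- length(b)
  best <- la + lb
  for (k in seq_len(min(la, lb))) {
    sa <- utils::combn(la, k, simplify = FALSE)
    sb <- utils::combn(lb, k, simplify = FALSE)
    for (i in sa) for (j in sb) {
      cost <- q * sum(abs(a[i] - b[j])) + (la - k) + (lb - k)
      if (cost < best) best <- cost
    }
  }
  best
}

# Piecewise-constant rate helper
piecewise_rate <- function(breaks, levels) {
  function(t) levels[pmax(findInterval(t, breaks), 1L)]
}
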