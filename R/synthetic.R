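#' Synthetic recording specification
#'
#' Conditions under which ground-truth fixtures are generated: a Poisson
#' spike train drawn from a rate profile, a forward simulation of the
#' calcium/indicator ODE driven by those spikes, and additive Gaussian
#' measurement noise. Every stochastic draw is governed by the mandatory
#' seed.
#'
#' @param duration recording length in seconds (default 60).
#' @param dt sampling interval in seconds (default 0.010).
#' @param rate_profile `"constant"`, `"piecewise"` or `"sinusoidal"`.
#' @param mean_rate mean firing rate in Hz (default 1, a typical sparse
#'   cortical rate).
#' @param noise_sigma standard deviation of the additive Gaussian
#'   measurement noise, in bound-indicator concentration units (default
#'   0.05, about a quarter of the single-spike response at unit gain).
#' @param seed integer seed (mandatory).
#' @param rate_breaks,rate_levels for `"piecewise"`: segment start times
#'   (first must be 0) and the rate on each segment.
#' @param amplitude,omega for `"sinusoidal"`: `s(t) = amplitude *
#'   sin(omega * t) + mean_rate`, clipped at 0.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(duration = 60, dt = 0.010,
                           rate_profile = c("constant", "piecewise",
                                            "sinusoidal"),
                           mean_rate = 1, noise_sigma = 0.05, seed,
                           rate_breaks = NULL, rate_levels = NULL,
                           amplitude = NULL, omega = NULL) {
  rate_profile <- match.arg(rate_profile)
  stopifnot(is.numeric(duration), duration > 0, is.numeric(dt), dt > 0,
            is.numeric(mean_rate), mean_rate >= 0,
            is.numeric(noise_sigma), noise_sigma >= 0)
  if (missing(seed)) stop("`seed` is mandatory for any stochastic draw")
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (rate_profile == "piecewise") {
    if (is.null(rate_breaks) || is.null(rate_levels) ||
        length(rate_breaks) != length(rate_levels))
      stop("piecewise profile needs matching `rate_breaks` and `rate_levels`")
    if (rate_breaks[1L] != 0 || is.unsorted(rate_breaks, strictly = TRUE))
      stop("`rate_breaks` must start at 0 and increase")
    if (any(rate_levels < 0)) stop("`rate_levels` must be nonnegative")
  }
  if (rate_profile == "sinusoidal") {
    if (is.null(amplitude) || is.null(omega))
      stop("sinusoidal profile needs `amplitude` and `omega`")
  }
  structure(list(duration = duration, dt = dt, rate_profile = rate_profile,
                 mean_rate = mean_rate, noise_sigma = noise_sigma,
                 seed = as.integer(seed), rate_breaks = rate_breaks,
                 rate_levels = rate_levels, amplitude = amplitude,
                 omega = omega),
            class = "synthetic_spec")
}

rate_profile_fn <- function(spec) {
  switch(spec$rate_profile,
    constant = function(t) rep(spec$mean_rate, length(t)),
    piecewise = function(t) {
      idx <- findInterval(t, spec$rate_breaks)
      idx[idx < 1L] <- 1L
      spec$rate_levels[idx]
    },
    sinusoidal = function(t)
      pmax(spec$amplitude * sin(spec$omega * t) + spec$mean_rate, 0))
}

#' Generate a Poisson spike train
#'
#' Inhomogeneous Poisson draw on the sampling grid: the count in each step
#' is Poisson with mean `rate(t) * dt`; multiple spikes in a step are
#' spread uniformly inside it to keep times ordered. Deterministic given
#' the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A [spike_train()] of duration `spec$duration`.
#' @export
generate_spike_train <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- floor(spec$duration / spec$dt + 1e-9)
  t_steps <- (seq_len(n) - 1L) * spec$dt
  lam <- rate_profile_fn(spec)(t_steps) * spec$dt
  counts <- withr::with_seed(spec$seed, stats::rpois(n, lam))
  times <- unlist(lapply(which(counts > 0L), function(i) {
    k <- counts[i]
    t_steps[i] + (seq_len(k) - 0.5) / k * spec$dt
  }))
  if (is.null(times)) times <- numeric()
  spike_train(times, duration = spec$duration)
}

#' Spike train to firing-rate drive
#'
#' Zero-order-hold rate signal: each step carries `count / dt` Hz, so the
#' integral of `s * dt` over any window equals the spike count in that
#' window. A single spike in a 10 ms step reads as 100 Hz for that step.
#'
#' @param train a [spike_train()].
#' @param dt grid interval in seconds.
#' @param duration signal length in seconds; defaults to the train's
#'   duration.
#' @return A [time_series()] of rates.
#' @export
spikes_to_drive <- function(train, dt = 0.010, duration = NULL) {
  stopifnot(inherits(train, "spike_train"), dt > 0)
  if (is.null(duration)) duration <- train$duration
  n <- max(1L, floor(duration / dt + 1e-9))
  counts <- spike_counts(train, bin_width = dt, n_bins = n)
  time_series(counts / dt, dt = dt)
}

#' Synthesize a recording from a spike train
#'
#' Forward-simulates the calcium/indicator ODE from the zero equilibrium
#' under the spike-train drive (fixed-step RK4, 1 ms substeps) and adds iid
#' Gaussian measurement noise to the bound-indicator trajectory. Both the
#' clean and noisy traces are returned so tests can use the clean one as an
#' oracle. The noise draw uses `spec$seed + 1` so it is independent of the
#' spike draw but still fully determined by the spec.
#'
#' @param params a [cell_params()] object.
#' @param train a [spike_train()] (typically from
#'   [generate_spike_train()]).
#' @param spec a [synthetic_spec()].
#' @return A list with `clean` and `noisy` [time_series()] of the bound
#'   indicator, plus the `drive` [time_series()].
#' @export
synth_recording <- function(params, train, spec) {
  stopifnot(inherits(params, "cell_params"), inherits(train, "spike_train"),
            inherits(spec, "synthetic_spec"))
  drive <- spikes_to_drive(train, dt = spec$dt, duration = spec$duration)
  n <- length(drive$values)
  path <- crn_rk4_path_cpp(drive$values, 0, 0, spec$dt, 10L,
                           flatten_params(params))
  clean <- time_series(as.numeric(path$z)[seq_len(n)], dt = spec$dt)
  noisy_values <- if (spec$noise_sigma > 0) {
    clean$values + withr::with_seed(
      spec$seed + 1L, stats::rnorm(n, 0, spec$noise_sigma))
  } else clean$values
  list(clean = clean, noisy = time_series(noisy_values, dt = spec$dt),
       drive = drive)
}
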