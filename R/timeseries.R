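#' Uniformly sampled time series
#'
#' Lightweight container for a real-valued signal sampled on a uniform grid:
#' fluorescence traces, simulated bound indicator, or firing rates.
#'
#' @param values numeric vector of samples. Must be finite (NaN padding from
#'   raw files is stripped by the readers before construction).
#' @param dt sampling interval in seconds (default 0.010 s, the native
#'   spikefinder acquisition interval).
#' @param t0 time of the first sample in seconds.
#' @return Object of class `time_series`.
#' @export
time_series <- function(values, dt = 0.010, t0 = 0) {
  stopifnot(is.numeric(values), is.numeric(dt), length(dt) == 1L,
            is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (!is.finite(dt) || dt <= 0) stop("`dt` must be positive")
  if (length(values) && !all(is.finite(values)))
    stop("`values` must be finite (strip NaN padding before construction)")
  structure(list(values = as.numeric(values), dt = dt, t0 = t0),
            class = "time_series")
}

#' Sample times of a time series
#' @param x a [time_series()].
#' @return Numeric vector of times in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "time_series"))
  x$t0 + (seq_along(x$values) - 1L) * x$dt
}

#' @export
length.time_series <- function(x) length(x$values)

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples, dt = %g s, t0 = %g s\n",
              length(x$values), x$dt, x$t0))
  invisible(x)
}

#' @export
as.data.frame.time_series <- function(x, ...) {
  data.frame(time = ts_times(x), value = x$values)
}

#' Spike train
#'
#' Ordered spike times in seconds, with an optional recording duration used
#' when binning.
#'
#' @param times numeric vector of spike times (seconds), nondecreasing.
#' @param duration recording duration in seconds; defaults to the last spike
#'   time (0 for an empty train).
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times = numeric(), duration = NULL) {
  stopifnot(is.numeric(times))
  if (length(times) && any(!is.finite(times))) stop("spike times must be finite")
  if (is.unsorted(times)) stop("spike times must be ordered")
  if (length(times) && times[1L] < 0) stop("spike times must be nonnegative")
  if (is.null(duration)) duration <- if (length(times)) max(times) else 0
  if (length(times) && duration < max(times))
    stop("`duration` must cover all spike times")
  structure(list(times = as.numeric(times), duration = duration),
            class = "spike_train")
}

#' @export
length.spike_train <- function(x) length(x$times)

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s\n",
              length(x$times), x$duration))
  invisible(x)
}

#' Per-bin spike counts of a spike train
#'
#' @param train a [spike_train()].
#' @param bin_width bin width in seconds.
#' @param n_bins number of bins; defaults to `ceiling(duration / bin_width)`.
#' @return Integer vector of counts; spikes at exactly `t = k * bin_width`
#'   fall in bin `k + 1` (left-closed bins).
#' @export
spike_counts <- function(train, bin_width, n_bins = NULL) {
  stopifnot(inherits(train, "spike_train"), bin_width > 0)
  if (is.null(n_bins)) n_bins <- max(1L, ceiling(train$duration / bin_width))
  idx <- floor(train$times / bin_width) + 1L
  keep <- idx >= 1L & idx <= n_bins
  if (any(!keep))
    warning(sum(!keep), " spike(s) beyond the binned range were dropped")
  tabulate(idx[keep], nbins = n_bins)
}
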