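#' Measurement filter configuration
#'
#' Settings for mapping raw fluorescence to the measured bound-indicator
#' signal: the shifted sigmoid, its fallback shift, the saturation detector,
#' and the pre-filter normalization.
#'
#' @param h vertical shift of the sigmoid filter (default 0.15).
#' @param h_fallback aggressive shift applied on a saturation restart
#'   (default 0.25). Must satisfy `0 < h < h_fallback < 1`.
#' @param saturation_level fraction of the filter ceiling `1 - h` above
#'   which a sample counts as saturated (default 0.95).
#' @param saturation_run number of consecutive saturated samples that
#'   defines a stuck trace (default 25, i.e. 250 ms at 10 ms sampling).
#' @param normalization raw-trace standardization applied before the
#'   sigmoid: `"zscore"` (default), `"minmax"`, or `"none"`. The sigmoid is
#'   centered at -1, which presumes roughly standardized input.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(h = 0.15, h_fallback = 0.25,
                          saturation_level = 0.95, saturation_run = 25L,
                          normalization = c("zscore", "minmax", "none")) {
  stopifnot(is.numeric(h), is.numeric(h_fallback),
            is.numeric(saturation_level), saturation_run >= 1L)
  if (!(h > 0 && h < h_fallback && h_fallback < 1))
    stop("need 0 < h < h_fallback < 1")
  if (saturation_level <= 0 || saturation_level > 1)
    stop("`saturation_level` must be in (0, 1]")
  structure(list(h = h, h_fallback = h_fallback,
                 saturation_level = saturation_level,
                 saturation_run = as.integer(saturation_run),
                 normalization = match.arg(normalization)),
            class = "filter_config")
}

#' Shifted sigmoid filter
#'
#' Elementwise map \eqn{\sigma(x) = 1/(1 + e^{-(x+1)}) - h}. Strictly
#' increasing, with asymptotes `-h` and `1 - h`; extreme samples are
#' compressed toward the asymptotes while mid-range samples pass through an
#' approximately linear regime.
#'
#' @param trace a [time_series()] or numeric vector of finite samples.
#' @param h vertical shift.
#' @return Same type as `trace`, filtered.
#' @export
#' @examples
#' sigmoid_filter(c(-1, 0, 1), h = 0.15)
sigmoid_filter <- function(trace, h = 0.15) {
  stopifnot(is.numeric(h), length(h) == 1L, is.finite(h))
  if (inherits(trace, "time_series")) {
    out <- trace
    out$values <- 1 / (1 + exp(-(trace$values + 1))) - h
    return(out)
  }
  stopifnot(is.numeric(trace))
  1 / (1 + exp(-(trace + 1))) - h
}

#' Detect filter saturation in a simulated trace
#'
#' A simulated bound-indicator trace counts as saturated when at least
#' `saturation_run` consecutive samples exceed
#' `saturation_level * ceiling`.
#'
#' @param sim_trace a [time_series()] or numeric vector (simulated CI*).
#' @param cfg a [filter_config()].
#' @param ceiling the attainable maximum of the filtered signal; for a trace
#'   filtered with shift `h` this is `1 - h`.
#' @return Logical scalar.
#' @export
detect_saturation <- function(sim_trace, cfg = filter_config(), ceiling = 1) {
  v <- if (inherits(sim_trace, "time_series")) sim_trace$values else sim_trace
  stopifnot(is.numeric(v))
  if (!length(v)) return(FALSE)
  above <- v > cfg$saturation_level * ceiling
  r <- rle(above)
  any(r$values & r$lengths >= cfg$saturation_run)
}

#' Prepare a raw fluorescence trace for inference
#'
#' Standardizes the raw trace (per the configured normalization) and applies
#' the shifted sigmoid filter. Inference starts from `h = cfg$h`; when the
#' downstream receding-horizon loop reports saturation of the simulated
#' indicator, the caller re-invokes this function once with
#' `h = cfg$h_fallback` and restarts (see [spike_inference()], which
#' implements that restart contract).
#'
#' @param raw a [time_series()] with NaN padding already stripped.
#' @param cfg a [filter_config()].
#' @param h shift to apply; defaults to `cfg$h`.
#' @return A list with `series` (filtered [time_series()]), `h_used`, and
#'   `normalization`.
#' @export
prepare_measurement <- function(raw, cfg = filter_config(), h = cfg$h) {
  stopifnot(inherits(raw, "time_series"))
  if (!length(raw$values)) stop("empty trace")
  v <- raw$values
  v <- switch(cfg$normalization,
    zscore = {
      s <- stats::sd(v)
      if (s > 0) (v - mean(v)) / s else v - mean(v)
    },
    minmax = {
      rng <- range(v)
      if (diff(rng) > 0) (v - rng[1L]) / diff(rng) else v - rng[1L]
    },
    none = v)
  list(series = sigmoid_filter(time_series(v, raw$dt, raw$t0), h = h),
       h_used = h, normalization = cfg$normalization)
}
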