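#' Calibration specification
#'
#' Which model parameters to fit, over what bounds, and against which
#' objective. The headline use is fitting the firing gain `alpha` on one to
#' three cells with simultaneous fluorescence and ground-truth spikes while
#' holding the indicator kinetics and extrusion rate fixed.
#'
#' @param free_params character subset of
#'   `c("alpha", "gamma", "k_f", "k_r", "L")` (default `"alpha"`).
#' @param bounds named list of positive `c(lower, upper)` search bounds per
#'   free parameter; defaults to `c(1, 1000)` for `alpha` and two decades
#'   around typical values otherwise.
#' @param objective `"pearson"` (binned Pearson correlation, default) or
#'   `"vp"` (negated Victor-Purpura distance, so larger is still better).
#' @param bin_factor binning factor for the objective (default 4, 40 ms
#'   bins).
#' @param grid_points points of the coarse log-spaced search grid
#'   (default 16).
#' @return Object of class `calibration_spec`.
#' @export
calibration_spec <- function(free_params = "alpha", bounds = NULL,
                             objective = c("pearson", "vp"),
                             bin_factor = 4L, grid_points = 16L) {
  allowed <- c("alpha", "gamma", "k_f", "k_r", "L")
  if (!length(free_params) || !all(free_params %in% allowed))
    stop("`free_params` must be a non-empty subset of: ",
         paste(allowed, collapse = ", "))
  defaults <- list(alpha = c(1, 1000), gamma = c(0.1, 10),
                   k_f = c(0.005, 0.5), k_r = c(0.76, 76), L = c(3, 300))
  if (is.null(bounds)) bounds <- defaults[free_params]
  for (p in free_params) {
    if (is.null(bounds[[p]])) bounds[[p]] <- defaults[[p]]
    b <- bounds[[p]]
    if (length(b) != 2L || any(b <= 0) || b[1L] >= b[2L])
      stop("bounds for `", p, "` must be positive c(lower, upper)")
  }
  structure(list(free_params = free_params, bounds = bounds[free_params],
                 objective = match.arg(objective),
                 bin_factor = as.integer(bin_factor),
                 grid_points = as.integer(grid_points)),
            class = "calibration_spec")
}

set_free_param <- function(base, name, value) {
  if (name == "alpha") base$alpha <- value
  else if (name == "gamma") base$gamma <- value
  else base$indicator[[name]] <- value
  base
}

calibration_objective <- function(recording, params, spec, mpc_cfg) {
  truth <- recording$spikes
  res <- infer_rates(recording$trace, params, mpc_cfg)
  a <- bin_downsample(res$s_hat, spec$bin_factor,
                      native_dt = recording$trace$dt)
  b <- bin_downsample(truth, spec$bin_factor,
                      native_dt = recording$trace$dt)
  m <- min(length(a), length(b))
  a <- a[seq_len(m)]; b <- b[seq_len(m)]
  if (spec$objective == "pearson") {
    if (stats::sd(b) == 0)
      stop("calibration failure: ground truth has zero variance ",
           "(no spikes?)")
    if (stats::sd(a) == 0) return(NA_real_)
    return(stats::cor(a, b))
  }
  cfg <- metric_config(bin_factor = spec$bin_factor,
                       native_dt = recording$trace$dt)
  -victor_purpura(rates_to_spikes(res$s_hat, cfg), truth, cfg)
}

mean_objective <- function(recordings, params, spec, mpc_cfg) {
  mean(vapply(recordings, calibration_objective, numeric(1L),
              params = params, spec = spec, mpc_cfg = mpc_cfg))
}

# Local quadratic refinement: fit a parabola in log-parameter space through
# the grid points around the argmax and take its vertex, clamped to that
# neighborhood. Uses no extra objective evaluations and is robust to the
# small-scale roughness the binned objective inherits from spike
# discreteness (a line-search refinement would chase those wiggles).
parabolic_refine <- function(log_grid, obj, i) {
  lo <- max(1L, i - 2L)
  hi <- min(length(log_grid), i + 2L)
  lg <- log_grid[lo:hi]
  ob <- obj[lo:hi]
  keep <- is.finite(ob)
  if (sum(keep) < 3L) return(log_grid[i])
  fit <- stats::lm(ob ~ lg + I(lg^2), subset = keep)
  b <- stats::coef(fit)
  if (!is.finite(b[[3L]]) || b[[3L]] >= 0) return(log_grid[i])
  min(max(-b[[2L]] / (2 * b[[3L]]), lg[1L]), lg[length(lg)])
}

#' Auto-calibrate model parameters from paired recordings
#'
#' Fits the free parameters (by default the firing gain `alpha`) so that
#' rates inferred from the fluorescence traces best match the ground-truth
#' spikes under the binned-Pearson objective, averaged over the 1-3
#' calibration cells. The search is a coarse log-spaced grid followed by a
#' local quadratic (parabolic-vertex) refinement around the best grid
#' point; it is fully deterministic given the inputs.
#'
#' Traces are consumed as given: pass [prepare_measurement()] output for
#' real fluorescence, or model-scale traces for synthetic recordings (the
#' per-trace standardization in the sigmoid pipeline removes the amplitude
#' information that identifies `alpha`, so synthetic parameter-recovery
#' studies calibrate on unfiltered noisy traces).
#'
#' @param recordings list of 1-3 recordings, each a list with `trace` (a
#'   [time_series()] aligned to the grid) and `spikes` (a
#'   [spike_train()]).
#' @param base a [cell_params()] object supplying every fixed parameter.
#' @param spec a [calibration_spec()].
#' @param mpc_cfg an [mpc_config()] used for every inference run.
#' @return A [cell_params()] object with the free parameters replaced by
#'   their calibrated values; attribute `"calibration"` carries the search
#'   trace (grids and objective values).
#' @export
calibrate <- function(recordings, base, spec = calibration_spec(),
                      mpc_cfg = mpc_config()) {
  stopifnot(inherits(base, "cell_params"),
            inherits(spec, "calibration_spec"),
            inherits(mpc_cfg, "mpc_config"))
  if (!length(recordings)) stop("need at least one recording")
  for (rec in recordings) {
    if (!inherits(rec$trace, "time_series") ||
        !inherits(rec$spikes, "spike_train"))
      stop("each recording needs a `trace` time_series and a `spikes` ",
           "spike_train")
    if (!length(rec$spikes$times))
      stop("calibration failure: ground truth has no spikes ",
           "(zero-variance target)")
  }
  params <- base
  trace_log <- list()
  for (p in spec$free_params) {
    b <- spec$bounds[[p]]
    grid <- exp(seq(log(b[1L]), log(b[2L]),
                    length.out = spec$grid_points))
    obj <- vapply(grid, function(v) {
      mean_objective(recordings, set_free_param(params, p, v), spec,
                     mpc_cfg)
    }, numeric(1L))
    if (all(!is.finite(obj))) {
      stop("calibration failure: objective non-finite on every grid ",
           "candidate for `", p, "`; grid: ",
           paste(signif(grid, 3), collapse = ", "))
    }
    i <- which.max(obj)
    best <- exp(parabolic_refine(log(grid), obj, i))
    params <- set_free_param(params, p, best)
    trace_log[[p]] <- list(grid = grid, objective = obj, value = best)
  }
  attr(params, "calibration") <- trace_log
  params
}
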