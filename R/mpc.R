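#' Receding-horizon controller configuration
#'
#' Settings of the finite-horizon subproblem solved at every measurement
#' step: over a lookahead of `n` samples, minimize the squared tracking
#' error between simulated and measured bound indicator plus a smoothness
#' penalty (weight `r`) on step-to-step rate increments, with a terminal
#' tracking penalty at the horizon end, subject to the model dynamics and
#' `s_min <= s <= s_max`.
#'
#' @param n horizon length in steps (default 6; a 60 ms lookahead at 10 ms
#'   sampling).
#' @param r smoothness weight on rate increments (default 0.01).
#' @param dt control/measurement interval in seconds (default 0.010).
#' @param s_min lower rate bound in Hz (0: rates are nonnegative).
#' @param s_max upper rate bound in Hz (default 1000; effectively
#'   unconstrained but keeps the solver bounded).
#' @param terminal_weight scale of the horizon-end tracking penalty
#'   (default 1).
#' @param solver_tol convergence tolerance on the projected gradient norm of
#'   the horizon subproblem (default 1e-6).
#' @param max_iter Gauss-Newton iteration cap per horizon (default 50).
#' @param substeps RK4 substeps per control interval in the internal
#'   discretization (default 2, i.e. 5 ms steps).
#' @param discretization transcription of the dynamics inside the horizon
#'   subproblem; `"rk4"` single shooting with exact sensitivities is the
#'   implemented scheme.
#' @param reset_state if `TRUE`, the simulated bound-indicator state is
#'   reset to the current measurement before each solve instead of being
#'   propagated open loop (default `FALSE`).
#' @return Object of class `mpc_config`.
#' @export
mpc_config <- function(n = 6L, r = 0.01, dt = 0.010, s_min = 0,
                       s_max = 1000, terminal_weight = 1,
                       solver_tol = 1e-6, max_iter = 50L, substeps = 2L,
                       discretization = "rk4", reset_state = FALSE) {
  stopifnot(is.numeric(n), n >= 2L, is.numeric(r), r >= 0,
            is.numeric(dt), dt > 0, is.numeric(s_min), s_min >= 0,
            is.numeric(s_max), s_max > s_min,
            is.numeric(terminal_weight), terminal_weight >= 0,
            solver_tol > 0, max_iter >= 1L, substeps >= 1L,
            is.logical(reset_state))
  discretization <- match.arg(discretization, "rk4")
  structure(list(n = as.integer(n), r = r, dt = dt, s_min = s_min,
                 s_max = s_max, terminal_weight = terminal_weight,
                 solver_tol = solver_tol, max_iter = as.integer(max_iter),
                 substeps = as.integer(substeps),
                 discretization = discretization,
                 reset_state = reset_state),
            class = "mpc_config")
}

cfg_for_cpp <- function(cfg) unclass(cfg)

auto_init_state <- function(measurement, params) {
  # assume binding equilibrium at recording start: place z at the first
  # measurement sample and x on the z-nullcline. z is kept below 0.95 L —
  # the nullcline x diverges as z -> L, and a first sample at or above L
  # (an infeasible reference, say) would otherwise blow up the initial
  # free-calcium estimate.
  L <- params$indicator$L
  z0 <- min(max(measurement$values[1L], 1e-9 * L), 0.95 * L)
  x0 <- params$indicator$k_r * z0 / (params$indicator$k_f * (L - z0))
  c(x = x0, z = z0)
}

#' Solve one finite-horizon subproblem
#'
#' Minimizes the horizon cost from a given model state against a window of
#' measurements. Used internally by [infer_rates()] at every step; exposed
#' for inspection and testing.
#'
#' @param params a [cell_params()] object.
#' @param state0 current model state `c(x = , z = )`.
#' @param meas_window numeric vector or [time_series()] of at least `n`
#'   measurement samples starting at the current step (sample 1 aligns with
#'   `state0`). When `n + 1` samples are supplied the last one anchors the
#'   terminal penalty; with exactly `n` the final sample is reused.
#' @param s_prev rate applied on the previous step (the `s_{-1}` of the
#'   smoothness penalty).
#' @param cfg an [mpc_config()].
#' @param warm_start optional length-`n` starting sequence (default zeros).
#' @return A list with `s` (optimal nonnegative rate sequence, length `n`),
#'   `states` (data.frame of predicted `x`, `z` over the horizon), `cost`,
#'   `iterations` and `converged`.
#' @export
solve_horizon <- function(params, state0, meas_window, s_prev = 0,
                          cfg = mpc_config(), warm_start = NULL) {
  stopifnot(inherits(params, "cell_params"), inherits(cfg, "mpc_config"))
  m <- if (inherits(meas_window, "time_series")) meas_window$values
       else as.numeric(meas_window)
  if (!all(is.finite(m))) stop("`meas_window` must be finite")
  n <- cfg$n
  if (length(m) < n) stop("`meas_window` must hold at least n samples")
  m <- m[seq_len(min(length(m), n + 1L))]
  if (length(m) == n) m <- c(m, m[n])
  st <- model_state(state0[["x"]], state0[["z"]], L = params$indicator$L)
  if (!is.finite(s_prev) || s_prev < 0) stop("`s_prev` must be nonnegative")
  warm <- if (is.null(warm_start)) rep(cfg$s_min, n) else as.numeric(warm_start)
  if (length(warm) != n) stop("`warm_start` must have length n")
  out <- mpc_solve_horizon_cpp(warm, st[["x"]], st[["z"]], m, s_prev,
                               flatten_params(params), cfg_for_cpp(cfg))
  list(s = as.numeric(out$s),
       states = data.frame(x = as.numeric(out$x_pred),
                           z = as.numeric(out$z_pred)),
       cost = out$cost, iterations = out$iterations,
       converged = out$converged)
}

new_inference_result <- function(s_hat, ci_sim, states, diagnostics) {
  structure(list(s_hat = s_hat, ci_sim = ci_sim, states = states,
                 diagnostics = diagnostics),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf(
    "<inference_result> %d steps, dt = %g s; mean rate %.3g Hz; %s\n",
    length(x$s_hat$values), x$s_hat$dt, mean(x$s_hat$values),
    if (isTRUE(x$diagnostics$saturated)) "saturated" else "no saturation"))
  invisible(x)
}

#' Infer firing rates from a measured indicator trace
#'
#' The receding-horizon loop: at each measurement step a finite-horizon
#' subproblem is solved ([solve_horizon()]), only the first computed rate is
#' applied, the model is advanced one step, and the window shifts forward.
#' Controls are emitted causally and never revised — `s_hat[k]` depends only
#' on samples up to `k + n - 1` (an effective lag of `n * dt`, 60 ms at the
#' defaults). The final `n - 1` samples reuse the last solved horizon.
#'
#' @param measurement a [time_series()] of the measured bound indicator
#'   (typically the output of [prepare_measurement()]), at least `n` samples.
#' @param params a [cell_params()] object.
#' @param cfg an [mpc_config()].
#' @param init initial model state `c(x = , z = )`, or `"auto"` to assume
#'   binding equilibrium at the first measurement sample.
#' @return An `inference_result`: `s_hat` (inferred rate, Hz, same length
#'   and grid as the measurement), `ci_sim` (simulated bound indicator),
#'   `states` (data.frame with `x`, `z`), and per-step `diagnostics`
#'   (`cost`, `iterations`, `converged`).
#' @seealso [spike_inference()] for the full pipeline including the sigmoid
#'   filter and its saturation restart.
#' @export
infer_rates <- function(measurement, params, cfg = mpc_config(),
                        init = "auto") {
  stopifnot(inherits(measurement, "time_series"),
            inherits(params, "cell_params"), inherits(cfg, "mpc_config"))
  if (length(measurement$values) < cfg$n)
    stop("measurement shorter than the horizon length n")
  if (abs(measurement$dt - cfg$dt) > 1e-12)
    warning("measurement dt (", measurement$dt,
            ") differs from cfg$dt (", cfg$dt, "); using cfg$dt")
  st <- if (identical(init, "auto")) auto_init_state(measurement, params)
        else model_state(init[["x"]], init[["z"]], L = params$indicator$L)
  out <- mpc_infer_cpp(measurement$values, st[["x"]], st[["z"]],
                       flatten_params(params), cfg_for_cpp(cfg))
  s_hat <- time_series(pmax(as.numeric(out$s_hat), 0), measurement$dt,
                       measurement$t0)
  ci_sim <- time_series(as.numeric(out$z_sim), measurement$dt,
                        measurement$t0)
  states <- data.frame(x = as.numeric(out$x_sim), z = as.numeric(out$z_sim))
  diagnostics <- list(cost = as.numeric(out$cost),
                      iterations = as.numeric(out$iterations),
                      converged = as.logical(out$converged),
                      init_state = st)
  new_inference_result(s_hat, ci_sim, states, diagnostics)
}

#' Track a desired indicator trajectory
#'
#' Closed-loop stimulation use case: identical contract to [infer_rates()]
#' with a desired reference trajectory substituted for the measurement. The
#' returned rate sequence is the stimulation schedule that drives the model
#' along the reference. References above the total indicator concentration
#' `L` are unattainable (`z <= L` by conservation) and are flagged in the
#' diagnostics.
#'
#' @param desired a [time_series()] reference for the bound indicator.
#' @inheritParams infer_rates
#' @return An `inference_result`; `diagnostics$infeasible_reference` is
#'   `TRUE` when the reference exceeds `L` anywhere.
#' @export
track_reference <- function(desired, params, cfg = mpc_config(),
                            init = "auto") {
  res <- infer_rates(desired, params, cfg, init)
  res$diagnostics$infeasible_reference <-
    any(desired$values >= params$indicator$L)
  res
}

#' Full inference pipeline with saturation restart
#'
#' Applies the shifted sigmoid filter to the raw fluorescence trace
#' (`h = cfg$h`), runs [infer_rates()], and — if the simulated indicator
#' gets stuck near the filter ceiling — restarts once with the aggressive
#' shift `h = cfg$h_fallback`. Exactly one fallback pass is ever taken.
#'
#' @param raw a [time_series()] of raw fluorescence (NaN padding stripped).
#' @param params a [cell_params()] object.
#' @param mpc_cfg an [mpc_config()].
#' @param filter_cfg a [filter_config()].
#' @param init initial state passed to [infer_rates()].
#' @return An `inference_result` with `diagnostics$h_used` and
#'   `diagnostics$saturated` (saturation state of the returned pass).
#' @export
spike_inference <- function(raw, params, mpc_cfg = mpc_config(),
                            filter_cfg = filter_config(), init = "auto") {
  prep <- prepare_measurement(raw, filter_cfg, h = filter_cfg$h)
  res <- infer_rates(prep$series, params, mpc_cfg, init)
  sat <- detect_saturation(res$ci_sim, filter_cfg,
                           ceiling = 1 - prep$h_used)
  if (sat) {
    prep <- prepare_measurement(raw, filter_cfg, h = filter_cfg$h_fallback)
    res <- infer_rates(prep$series, params, mpc_cfg, init)
    sat <- detect_saturation(res$ci_sim, filter_cfg,
                             ceiling = 1 - prep$h_used)
  }
  res$diagnostics$h_used <- prep$h_used
  res$diagnostics$saturated <- sat
  res
}
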