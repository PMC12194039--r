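#' Time derivatives of the calcium/indicator ODE
#'
#' Evaluates the right-hand side of the governing system
#' \deqn{\dot x = \alpha s - \gamma x + k_r z - k_f x (L - z)}
#' \deqn{\dot z = k_f x (L - z) - k_r z}
#' With the drive term \eqn{\alpha s} and the extrusion term \eqn{\gamma x}
#' removed this reduces to the closed binding reaction alone.
#'
#' @param state named numeric `c(x = , z = )`; must lie in the admissible
#'   set `x >= 0`, `0 <= z <= L` (see [model_state()]).
#' @param s instantaneous firing rate in Hz, nonnegative.
#' @param params a [cell_params()] object.
#' @return Named numeric `c(dx = , dz = )`.
#' @export
#' @examples
#' p <- cell_params(gcamp6s(), alpha = 1, gamma = 1)
#' crn_derivatives(c(x = 1, z = 0), s = 0, p)
crn_derivatives <- function(state, s, params) {
  stopifnot(inherits(params, "cell_params"), is.numeric(s), length(s) == 1L)
  if (!is.finite(s) || s < 0) stop("`s` must be a finite nonnegative rate")
  st <- model_state(state[["x"]], state[["z"]], L = params$indicator$L)
  k_f <- params$indicator$k_f; k_r <- params$indicator$k_r
  L <- params$indicator$L
  bind <- k_f * st[["x"]] * (L - st[["z"]])
  c(dx = params$alpha * s - params$gamma * st[["x"]] + k_r * st[["z"]] - bind,
    dz = bind - k_r * st[["z"]])
}

#' Steady state under constant drive
#'
#' Closed-form equilibrium of the governing ODE for a constant firing rate:
#' `x* = alpha * s / gamma` and `z* = L k_f x* / (k_r + k_f x*)`. `z*`
#' approaches `L` only in the limit of infinite drive (binding saturation).
#'
#' @inheritParams crn_derivatives
#' @param s_const constant firing rate in Hz, nonnegative.
#' @return Named numeric `c(x = , z = )`.
#' @export
crn_steady_state <- function(params, s_const) {
  stopifnot(inherits(params, "cell_params"),
            is.numeric(s_const), length(s_const) == 1L)
  if (!is.finite(s_const) || s_const < 0)
    stop("`s_const` must be a finite nonnegative rate")
  k_f <- params$indicator$k_f; k_r <- params$indicator$k_r
  L <- params$indicator$L
  x_star <- params$alpha * s_const / params$gamma
  z_star <- L * k_f * x_star / (k_r + k_f * x_star)
  c(x = x_star, z = z_star)
}

#' Simulate the calcium/indicator ODE
#'
#' Integrates the governing system under an arbitrary nonnegative firing-rate
#' drive. Two integrators are available: an adaptive solver
#' (`deSolve::lsoda`, relative tolerance `1e-8`) for smooth drives, and a
#' fixed-step RK4 path (compiled) that treats the drive as piecewise constant
#' on the sampling grid — the natural choice for spike-train drives sampled
#' at 10 ms, where it lands substeps exactly on the rate discontinuities.
#'
#' @inheritParams crn_derivatives
#' @param rate_fn drive: either a function of time returning a nonnegative
#'   rate (Hz), or a [time_series()] interpreted with zero-order hold.
#' @param init initial state `c(x = , z = )` inside the admissible set.
#' @param times strictly increasing numeric vector of output times
#'   (seconds). For `method = "rk4"` the grid must be uniform.
#' @param method `"lsoda"` (adaptive, default) or `"rk4"` (fixed step,
#'   zero-order-hold drive).
#' @param rtol,atol tolerances for the adaptive solver.
#' @param substeps RK4 substeps per grid interval for `method = "rk4"`.
#' @return A data.frame with columns `time`, `x`, `z`, `s` (the drive that
#'   was applied on each interval).
#' @export
crn_simulate <- function(params, rate_fn, init, times,
                         method = c("lsoda", "rk4"),
                         rtol = 1e-8, atol = 1e-10, substeps = 10L) {
  stopifnot(inherits(params, "cell_params"), is.numeric(times),
            length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  method <- match.arg(method)
  init <- model_state(init[["x"]], init[["z"]], L = params$indicator$L)

  if (inherits(rate_fn, "time_series")) {
    ts <- rate_fn
    tt <- ts_times(ts)
    rate <- stats::approxfun(tt, ts$values, method = "constant",
                             yleft = ts$values[1L],
                             yright = ts$values[length(ts$values)])
  } else if (is.function(rate_fn)) {
    rate <- rate_fn
  } else stop("`rate_fn` must be a function or a time_series")

  if (method == "rk4") {
    dts <- diff(times)
    if (max(abs(dts - dts[1L])) > 1e-9 * dts[1L])
      stop("method = \"rk4\" requires a uniform time grid")
    s_steps <- vapply(times[-length(times)], rate, numeric(1L))
    if (any(!is.finite(s_steps) | s_steps < 0))
      stop("drive must be finite and nonnegative")
    path <- crn_rk4_path_cpp(s_steps, init[["x"]], init[["z"]],
                             dts[1L], as.integer(substeps),
                             flatten_params(params))
    return(data.frame(time = times, x = path$x, z = path$z,
                      s = c(s_steps, s_steps[length(s_steps)])))
  }

  pv <- flatten_params(params)
  rhs <- function(t, y, parms) {
    st <- max(rate(t), 0)
    bind <- pv$k_f * y[1L] * (pv$L - y[2L])
    list(c(pv$alpha * st - pv$gamma * y[1L] + pv$k_r * y[2L] - bind,
           bind - pv$k_r * y[2L]))
  }
  # hmax capped at the output spacing so short drive transients are not
  # stepped over by the adaptive solver
  out <- deSolve::lsoda(y = c(x = init[["x"]], z = init[["z"]]),
                        times = times, func = rhs, parms = NULL,
                        rtol = rtol, atol = atol,
                        hmax = min(diff(times)))
  if (attr(out, "istate")[1L] < 0)
    stop("integration failed; last valid time ",
         max(out[stats::complete.cases(out), "time"]))
  data.frame(time = out[, "time"], x = out[, "x"], z = out[, "z"],
             s = vapply(out[, "time"], function(t) max(rate(t), 0),
                        numeric(1L)))
}

#' Local stability at a steady state
#'
#' Jacobian eigenvalues of the governing ODE at the steady state reached
#' under a constant drive. For any positive parameters the equilibrium is
#' asymptotically stable: the Jacobian trace is
#' \eqn{-(\gamma + k_f(L - z^*) + k_r + k_f x^*) < 0} and its determinant is
#' \eqn{\gamma (k_r + k_f x^*) > 0}, so both eigenvalues have negative real
#' part for every achievable drive.
#'
#' @inheritParams crn_steady_state
#' @return A list with `steady_state`, the 2x2 `jacobian`, complex
#'   `eigenvalues`, and logical `stable` (all real parts negative).
#' @export
stability_report <- function(params, s_const) {
  if (!inherits(params, "cell_params")) stop("`params` must be cell_params")
  if (params$gamma <= 0)
    stop("unbounded equilibrium: gamma <= 0 gives no finite steady state ",
         "for positive drive")
  ss <- crn_steady_state(params, s_const)
  k_f <- params$indicator$k_f; k_r <- params$indicator$k_r
  L <- params$indicator$L
  x <- ss[["x"]]; z <- ss[["z"]]
  J <- matrix(c(-params$gamma - k_f * (L - z), k_r + k_f * x,
                k_f * (L - z), -(k_r + k_f * x)),
              nrow = 2L, byrow = TRUE,
              dimnames = list(c("dx", "dz"), c("x", "z")))
  ev <- eigen(J, only.values = TRUE)$values
  list(steady_state = ss, jacobian = J, eigenvalues = ev,
       stable = all(Re(ev) < 0))
}
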