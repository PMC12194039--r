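#' Indicator binding kinetics
#'
#' Parameters of the mass-action binding reaction Ca2+ + CI <-> CI* for one
#' fluorescent calcium indicator. Concentrations are in the model's
#' normalized units; time is in seconds.
#'
#' @param k_f forward (binding) rate constant, 1/(concentration * s). Must be
#'   positive.
#' @param k_r reverse (unbinding) rate constant, 1/s. Must be positive.
#' @param L total indicator concentration (bound + unbound), conserved over
#'   time. Must be positive.
#'
#' @return An object of class `indicator_params` with fields `k_f`, `k_r`,
#'   `L`.
#' @seealso [gcamp6s()], [binding_affinity()], [cell_params()]
#' @export
#' @examples
#' ind <- indicator_params(k_f = 0.0514, k_r = 7.6, L = 30)
#' binding_affinity(ind)
indicator_params <- function(k_f, k_r, L) {
  stopifnot(is.numeric(k_f), length(k_f) == 1L, is.finite(k_f),
            is.numeric(k_r), length(k_r) == 1L, is.finite(k_r),
            is.numeric(L), length(L) == 1L, is.finite(L))
  if (k_f <= 0) stop("`k_f` must be positive")
  if (k_r <= 0) stop("`k_r` must be positive")
  if (L <= 0) stop("`L` must be positive")
  structure(list(k_f = k_f, k_r = k_r, L = L), class = "indicator_params")
}

#' GCaMP6s indicator preset
#'
#' Binding kinetics of the widely used GCaMP6s indicator in the model's
#' normalized units: `k_f = 0.0514`, `k_r = 7.6`, `L = 30`.
#'
#' @return An [indicator_params()] object.
#' @export
gcamp6s <- function() indicator_params(k_f = 0.0514, k_r = 7.6, L = 30)

#' Binding affinity of an indicator
#'
#' The one-number kinetic summary `k_d = k_f / k_r` used when comparing or
#' designing indicators.
#'
#' @param indicator an [indicator_params()] object.
#' @return Positive scalar `k_f / k_r`.
#' @export
binding_affinity <- function(indicator) {
  stopifnot(inherits(indicator, "indicator_params"))
  indicator$k_f / indicator$k_r
}

#' Full cell model parameters
#'
#' Parameters of the governing ODE system
#' \deqn{\dot x = \alpha s - \gamma x + k_r z - k_f x (L - z)}
#' \deqn{\dot z = k_f x (L - z) - k_r z}
#' where `x` is free calcium, `z` is bound indicator and `s(t)` is the
#' (nonnegative) firing rate driving calcium influx.
#'
#' @param indicator an [indicator_params()] object.
#' @param alpha firing-rate-to-calcium gain (concentration per Hz per
#'   second). Must be positive.
#' @param gamma calcium extrusion rate, 1/s. Must be positive.
#'
#' @return An object of class `cell_params`.
#' @export
#' @examples
#' cell_params(gcamp6s(), alpha = 1, gamma = 1)
cell_params <- function(indicator, alpha, gamma) {
  stopifnot(inherits(indicator, "indicator_params"),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
  if (alpha <= 0) stop("`alpha` must be positive")
  if (gamma <= 0) {
    stop("`gamma` must be positive: with gamma <= 0 and alpha*s > 0 the ",
         "calcium equilibrium x* = alpha*s/gamma is unbounded")
  }
  structure(list(indicator = indicator, alpha = alpha, gamma = gamma),
            class = "cell_params")
}

#' @export
print.indicator_params <- function(x, ...) {
  cat(sprintf("<indicator_params> k_f = %g, k_r = %g, L = %g (k_d = %g)\n",
              x$k_f, x$k_r, x$L, x$k_f / x$k_r))
  invisible(x)
}

#' @export
print.cell_params <- function(x, ...) {
  cat(sprintf(
    "<cell_params> alpha = %g, gamma = %g; k_f = %g, k_r = %g, L = %g\n",
    x$alpha, x$gamma, x$indicator$k_f, x$indicator$k_r, x$indicator$L))
  invisible(x)
}

# flatten for the compiled routines
flatten_params <- function(params) {
  stopifnot(inherits(params, "cell_params"))
  list(k_f = params$indicator$k_f, k_r = params$indicator$k_r,
       L = params$indicator$L, alpha = params$alpha, gamma = params$gamma)
}

#' Model state
#'
#' A point `(x, z)` in the state space of the calcium/indicator ODE: `x` is
#' the free calcium concentration, `z` the bound-indicator concentration.
#' The admissible set is `x >= 0`, `0 <= z <= L`; the unbound indicator is
#' implicit as `y = L - z`.
#'
#' @param x free calcium concentration (nonnegative).
#' @param z bound indicator concentration.
#' @param L optional total indicator concentration; when given, `z` is
#'   checked against `[0, L]`.
#' @return Named numeric vector `c(x = , z = )`.
#' @export
model_state <- function(x, z, L = NULL) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x),
            is.numeric(z), length(z) == 1L, is.finite(z))
  if (x < 0) stop("state out of range: `x` must be nonnegative")
  if (z < 0) stop("state out of range: `z` must be nonnegative")
  if (!is.null(L) && z > L) stop("state out of range: `z` must not exceed L")
  c(x = x, z = z)
}
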