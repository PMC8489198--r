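# Pure algebraic kernels shared by every model variant.

#' Hill function
#'
#' `x^n / (x^n + K^n)`: the saturating activation used for every
#' calcium-dependent release rate and flux in the model. Vectorized over `x`.
#'
#' @param x nonnegative scalar or vector (e.g. a Ca2+ concentration, uM).
#' @param K positive half-saturation constant (same units as `x`).
#' @param n positive Hill exponent.
#' @return Fraction(s) in `[0, 1)`; exactly 0 at `x = 0`, 0.5 at `x = K`.
#' @export
#' @examples
#' hill(50, 50, 4)    # 0.5
#' hill(100, 50, 4)   # 16/17
hill <- function(x, K, n) {
  if (any(x < 0)) stop("hill(): x must be nonnegative")
  if (K <= 0) stop("hill(): K must be strictly positive")
  if (n <= 0) stop("hill(): n must be strictly positive")
  xn <- x^n
  xn / (xn + K^n)
}

#' Boltzmann (logistic) gating function
#'
#' `B(x, vshift, vscale) = 1 / (1 + exp(-(x - vshift)/vscale))`: the
#' steady-state activation/inactivation curve of every voltage-gated channel.
#' The sign of `vscale` sets the direction (positive: activation). Evaluation
#' is overflow-safe at extreme arguments. Vectorized over `x`.
#'
#' @param x scalar or vector (mV for gating; any consistent units otherwise).
#' @param vshift midpoint (value of `x` where the output is 0.5).
#' @param vscale nonzero slope factor.
#' @return Fraction(s) in `(0, 1)` (saturating to 0/1 at extremes).
#' @export
#' @examples
#' boltzmann(-30, -50, 10)   # 1/(1 + exp(-2))
boltzmann <- function(x, vshift, vscale) {
  if (any(vscale == 0)) stop("boltzmann(): vscale must be nonzero")
  z <- -(x - vshift) / vscale
  z <- pmin(pmax(z, -700), 700)
  1 / (1 + exp(z))
}

#' Gate specification
#'
#' Bundles the constants of one voltage-gated activation or inactivation gate:
#' the Boltzmann steady-state curve (midpoint, slope) and the bell-shaped
#' voltage-dependent time constant (peak, baseline, midpoint, slope).
#'
#' @param midpoint Boltzmann midpoint (mV).
#' @param slope Boltzmann slope (mV, nonzero; negative for inactivation).
#' @param tau_peak bell time-constant amplitude (ms, >= 0); the maximum of the
#'   bell is `tau_peak/2 + tau_base`.
#' @param tau_base additive baseline time constant (ms, >= 0).
#' @param tau_midpoint voltage of the bell maximum (mV).
#' @param tau_slope bell width parameter (mV, nonzero).
#' @param activation logical flag (informational).
#' @return A `gate_spec` list.
#' @export
gate_spec <- function(midpoint, slope, tau_peak, tau_base, tau_midpoint,
                      tau_slope, activation = TRUE) {
  if (slope == 0) stop("gate_spec(): slope must be nonzero")
  if (tau_peak < 0 || tau_base < 0) stop("gate_spec(): time constants must be >= 0")
  if (tau_slope == 0) stop("gate_spec(): tau_slope must be nonzero")
  structure(list(midpoint = midpoint, slope = slope, tau_peak = tau_peak,
                 tau_base = tau_base, tau_midpoint = tau_midpoint,
                 tau_slope = tau_slope, activation = isTRUE(activation)),
            class = "gate_spec")
}

# extract the gate_spec for one of the named Table-driven gates
.gate_from_params <- function(p, which = c("m_CL", "h_CL", "m_CT", "h_CT", "m_CN", "h_CN")) {
  which <- match.arg(which)
  g <- sub("^[mh]_", "", which)
  mh <- sub("_C[LTN]$", "", which)
  gate_spec(
    midpoint = p[[paste0("V_", mh, "_", g)]],
    slope = p[[paste0("S_", mh, "_", g)]],
    tau_peak = p[[paste0("tau_", mh, "_V_", g)]],
    tau_base = p[[paste0("tau_", mh, "0_V_", g)]],
    tau_midpoint = p[[paste0("V_tau_", mh, "_", g)]],
    tau_slope = p[[paste0("S_tau_", mh, "_", g)]],
    activation = mh == "m"
  )
}

#' Bell-shaped voltage-dependent time constant
#'
#' `tau(v) = tau_peak / (exp(-(v - Vt)/St) + exp((v - Vt)/St)) + tau_base`.
#' Symmetric about `tau_midpoint`, with maximum `tau_peak/2 + tau_base` there
#' and decaying to `tau_base` at extreme voltages. Vectorized over `v`.
#'
#' @param v membrane potential (mV).
#' @param g a [gate_spec()].
#' @return Time constant(s) in ms.
#' @export
#' @examples
#' # L-type activation gate peaks at 1/2 + 0.05 ms at v = -23 mV
#' p <- default_parameters()
#' bell_tau(-23, gate_spec(p$V_m_CL, p$S_m_CL, 1, 0.05, -23, 20))
bell_tau <- function(v, g) {
  stopifnot(inherits(g, "gate_spec"))
  u <- (v - g$tau_midpoint) / g$tau_slope
  u <- pmin(pmax(u, -700), 700)
  g$tau_peak / (exp(-u) + exp(u)) + g$tau_base
}

#' First-order gate relaxation rate
#'
#' `d y / dt = (y_inf - y) / tau`: the relaxation of every gating variable
#' toward its voltage-dependent steady state.
#'
#' @param y current gate value (fraction).
#' @param y_inf steady-state value (fraction).
#' @param tau relaxation time constant (ms, > 0).
#' @return Rate in ms^-1.
#' @export
gate_rhs <- function(y, y_inf, tau) {
  if (any(tau <= 0)) stop("gate_rhs(): tau must be strictly positive")
  (y_inf - y) / tau
}

# steady state + tau for a Table-driven gate at voltage v
.gate_inf_tau <- function(v, p, which) {
  g <- .gate_from_params(p, which)
  list(inf = boltzmann(v, g$midpoint, g$slope), tau = bell_tau(v, g))
}
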