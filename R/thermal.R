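# Temperature extension: Q10-style rate scaling of the Hodgkin-Huxley gates,
# temperature-dependent peak conductances, and the thermal neuron membrane
# equation with optional TRPM8 current.

#' Temperature scaling factors for the Hodgkin-Huxley gate rates
#'
#' `phi_mK = 4.3518 * 2.7^((T-20)/10)`, `phi_mNa = 4.4288 * 3^((T-20)/10)`,
#' `phi_hNa = 3.8923 * 2.3^((T-20)/10)`. Each multiplies the opening and
#' closing rates of its gate (equivalently scales `1/tau`, leaving the
#' steady-state curves unchanged).
#'
#' @param T temperature in degC; vectorized.
#' @param p parameter set.
#' @return Named list `phi_mK`, `phi_mNa`, `phi_hNa` (all > 0).
#' @export
#' @examples
#' phi_factors(20)$phi_mK   # 4.3518
phi_factors <- function(T, p = default_parameters()) {
  if (any(!is.finite(T))) stop("T must be finite")
  list(phi_mK = p$phi_mK_a * p$phi_mK_q^((T - 20) / 10),
       phi_mNa = p$phi_mNa_a * p$phi_mNa_q^((T - 20) / 10),
       phi_hNa = p$phi_hNa_a * p$phi_hNa_q^((T - 20) / 10))
}

#' Temperature-dependent peak conductances (printed Gaussian forms)
#'
#' `g_K_max(T) = 1.60 exp(-((T - 27.88)/12.85)^2)` and
#' `g_Na_max(T) = 0.42 exp(-((T - 31.83)/31.62)^2)`, as printed. In the
#' simulation engine these Gaussians are used as relative factors on the
#' reference peaks `g_K_bar`, `g_Na_bar` (normalized so the
#' temperature-independent model is recovered at each Gaussian maximum);
#' `sim_options(literal_gmax = TRUE)` uses the raw printed magnitudes instead.
#'
#' @param T temperature in degC; vectorized.
#' @param p parameter set.
#' @return Named list `g_K_max`, `g_Na_max` (printed magnitudes).
#' @export
#' @examples
#' peak_conductances(27.88)$g_K_max   # 1.60
peak_conductances <- function(T, p = default_parameters()) {
  if (any(!is.finite(T))) stop("T must be finite")
  list(g_K_max = p$gK_max_amp * exp(-((T - p$gK_max_mid) / p$gK_max_sig)^2),
       g_Na_max = p$gNa_max_amp * exp(-((T - p$gNa_max_mid) / p$gNa_max_sig)^2))
}

#' Thermal neuron right-hand side
#'
#' The neuron derivative with temperature effects: HH gate rates multiplied by
#' the [phi_factors()], peak Na/K conductances scaled by the
#' [peak_conductances()] Gaussians, and (when enabled in the thermal
#' configuration) the TRPM8 current driving the membrane toward its ~0 mV
#' reversal potential. With `thermal$mode == "off"` this is exactly
#' [neuron_rhs()].
#'
#' @param s named neuron state.
#' @param t time (ms).
#' @param p parameter set.
#' @param proto stimulus protocol (its own thermal config is replaced by
#'   `thermal` if supplied).
#' @param thermal a [thermal_config()]; defaults to the protocol's.
#' @param opts options ([sim_options()]).
#' @return Named derivative vector (per ms).
#' @export
thermal_neuron_rhs <- function(s, t = 0, p = default_parameters(),
                               proto = stimulus_protocol(),
                               thermal = NULL, opts = sim_options()) {
  if (!is.null(thermal)) {
    stopifnot(inherits(thermal, "thermal_config"))
    proto <- stimulus_protocol(
      pulses = if (nrow(proto$pulses)) proto$pulses else NULL,
      v_ind = if (nrow(proto$v_ind)) proto$v_ind else NULL,
      thermal = thermal)
  }
  neuron_rhs(s, t, p, proto, opts)
}
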