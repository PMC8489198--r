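# Neuron variant: modified Hodgkin-Huxley membrane with L/T-type Ca2+
# channels, four-compartment Ca2+ mass balance, and the neuronal exosomal
# release rate.

#' Neuron model right-hand side
#'
#' Time derivative of the full neuron state: membrane potential (HH conductances
#' `g_K_bar m_K^4`, `g_Na_bar m_Na^3 h_Na`, leak, induced current), first-order
#' gate relaxation for the Na/K and L/T-type calcium gates, and the
#' four-compartment calcium mass balance (open L-type microdomain, submembrane,
#' bulk cytosol, endoplasmic reticulum). The default uses the mass-conserving
#' sign convention for the microdomain and ER exchange terms; set
#' `opts = sim_options(literal_signs = TRUE)` for the printed (self-amplifying)
#' forms.
#'
#' @param s named neuron state (see [neuron_initial_state()]).
#' @param t time (ms).
#' @param p parameter set.
#' @param proto stimulus protocol supplying `I_ind(t)` (and temperature for the
#'   thermal variant).
#' @param opts integrator/model options ([sim_options()]).
#' @return Named derivative vector (per ms).
#' @export
neuron_rhs <- function(s, t = 0, p = default_parameters(),
                       proto = stimulus_protocol(), opts = sim_options()) {
  s <- .check_state(s, "neuron")
  d <- cpp_rhs(1L, t, unname(s), .param_vector(p), .build_drive(proto, opts = opts))
  setNames(d, names(s))
}

#' Exosomal release rates
#'
#' Hill-function release rates from the local calcium concentrations:
#' `R_CL` weights the open/closed L-type microdomain branches by the channel
#' open probability `m_CL^2 h_CL` (closed-channel microdomain concentration
#' equals the submembrane concentration `C_m`); `R_Cm` is the submembrane
#' Hill term; `R_CN` (astrocytes only) weights the N-type branches by
#' `m_CN^2 h_CN`. The collective rate is their sum.
#'
#' @param s named state vector of the appropriate variant.
#' @param p parameter set.
#' @return A `release_rates` list: `R_CL`, `R_Cm`, `R_CN`, `total`.
#' @export
neuron_release <- function(s, p = default_parameters()) {
  s <- .check_state(s, "neuron")
  w <- s[["m_CL"]]^2 * s[["h_CL"]]
  R_CL <- w * hill(max(s[["C_L"]], 0), p$K_L, p$n_L) +
    (1 - w) * hill(max(s[["C_m"]], 0), p$K_L, p$n_L)
  R_Cm <- hill(max(s[["C_m"]], 0), p$K_m, p$n_m)
  structure(list(R_CL = unname(R_CL), R_Cm = unname(R_Cm), R_CN = 0,
                 total = unname(R_CL + R_Cm)), class = "release_rates")
}

#' Relaxed resting state of the unstimulated neuron
#'
#' Integrates the unstimulated system for `t_relax` ms (adaptive integrator),
#' then refines the slow calcium compartments algebraically (their equilibrium
#' is linear once the membrane has settled), and verifies that the residual
#' derivative norm is below `tol`.
#'
#' @param p parameter set.
#' @param t_relax relaxation time (ms, >= 2000).
#' @param tol maximum absolute residual derivative accepted (per ms).
#' @return Named neuron state at equilibrium.
#' @export
resting_state <- function(p = default_parameters(), t_relax = 4000, tol = 1e-8) {
  if (t_relax < 2000) stop("t_relax must be >= 2000 ms")
  opts <- sim_options(t_max = t_relax, method = "adaptive", out_dt = t_relax,
                      rtol = 1e-10, atol = 1e-12, max_step = 0.25)
  res <- integrate_model("neuron", neuron_initial_state(p),
                         stimulus_protocol(), p, opts)
  s <- res$states[nrow(res$states), ]
  s <- setNames(as.numeric(s), colnames(res$states))

  # algebraic refinement of the slow compartments (valid when pumps active):
  # at rest C_c = C_m, C_r = (1 + k_SERCA/p_leak) C_c, C_L = C_m + dL with
  # dL = -alpha i_CL / (lambda_ud B_ud), and C_m balances the T-type influx
  # and microdomain exchange against the PMCA pump.
  if (p$k_PMCA > 0) {
    v <- s[["v_m"]]
    iCL <- microdomain_current("L", v, p)
    ICT <- p$g_CT * s[["m_CT"]] * (s[["h_CTf"]] + 0.04 * s[["h_CTs"]]) * (v - p$V_C)
    dL <- -(p$alpha / p$lambda_ud) * iCL / p$B_ud
    w <- s[["m_CL"]]^2 * s[["h_CL"]]
    kex <- p$N_L * p$lambda_ud * p$B_ud / p$lambda_m
    Cm <- (-(p$alpha / p$lambda_m) * ICT + kex * w * dL) /
      ((p$lambda_c / p$lambda_m) * p$k_PMCA)
    if (is.finite(Cm) && Cm > 0) {
      s[["C_m"]] <- Cm
      s[["C_c"]] <- Cm
      s[["C_r"]] <- (1 + p$k_SERCA / p$p_leak) * Cm
      s[["C_L"]] <- Cm + dL
    }
  }
  resid <- max(abs(neuron_rhs(s, t = 0, p = p)))
  if (resid > tol) {
    stop(sprintf("resting_state() did not converge: residual %.3g > %.3g",
                 resid, tol))
  }
  s
}
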