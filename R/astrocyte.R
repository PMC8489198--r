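# Electrically silent astrocyte driven by a depolarization step v_ind:
# IP3 production, Li-Rinzel ER calcium dynamics, L/N-type microdomains, and
# the astrocytic exosomal release rate.

#' IP3 production rate
#'
#' `dP/dt = (P0 - P)/tau_P + r_P * gate(t)`, where `gate(t)` is 1 while the
#' `v_ind` stimulus is active and 0 otherwise (optionally scaled linearly with
#' the step amplitude via `sim_options(rp_scale = TRUE)`). `P0` is the resting
#' IP3 concentration and `r_P` the stimulated production rate.
#'
#' @param P IP3 concentration (uM, >= 0).
#' @param t time (ms).
#' @param p parameter set.
#' @param proto stimulus protocol (its `v_ind` steps gate the production term).
#' @param opts options (only `rp_scale` is consulted).
#' @return dP/dt in uM/ms.
#' @export
ip3_rhs <- function(P, t = 0, p = default_parameters(),
                    proto = stimulus_protocol(), opts = sim_options()) {
  if (P < 0) stop("P must be >= 0")
  vi <- v_ind_at(proto, t)
  gate <- as.numeric(vi != 0)
  if (opts$rp_scale && gate > 0) gate <- vi / 20
  (p$IP3_0 - P) / p$tau_P + (p$r_P * 1e-3) * gate
}

#' Astrocyte model right-hand side
#'
#' Time derivative of the astrocyte state at effective membrane potential
#' `V_m + v_ind(t)`: IP3 production, Li-Rinzel IP3-receptor gating (`h_P`) and
#' bulk cytosolic Ca2+ with ER concentration `(c0 - C_c)/c1`, the L- and N-type
#' microdomain concentrations fed by per-channel currents, and the submembrane
#' compartment exchanging with both microdomain pools.
#'
#' @param s named astrocyte state ([astrocyte_initial_state()]).
#' @inheritParams neuron_rhs
#' @return Named derivative vector (per ms).
#' @export
astrocyte_rhs <- function(s, t = 0, p = default_parameters(),
                          proto = stimulus_protocol(), opts = sim_options()) {
  s <- .check_state(s, "astrocyte")
  d <- cpp_rhs(2L, t, unname(s), .param_vector(p), .build_drive(proto, opts = opts))
  setNames(d, names(s))
}

#' @rdname neuron_release
#' @export
astrocyte_release <- function(s, p = default_parameters()) {
  s <- .check_state(s, "astrocyte")
  wL <- s[["m_CL"]]^2 * s[["h_CL"]]
  wN <- s[["m_CN"]]^2 * s[["h_CN"]]
  R_CL <- wL * hill(max(s[["C_L"]], 0), p$K_L, p$n_L) +
    (1 - wL) * hill(max(s[["C_m"]], 0), p$K_L, p$n_L)
  R_Cm <- hill(max(s[["C_m"]], 0), p$K_m, p$n_m)
  R_CN <- wN * hill(max(s[["C_N"]], 0), p$K_N, p$n_N) +
    (1 - wN) * hill(max(s[["C_m"]], 0), p$K_N, p$n_N)
  structure(list(R_CL = unname(R_CL), R_Cm = unname(R_Cm), R_CN = unname(R_CN),
                 total = unname(R_CL + R_Cm + R_CN)), class = "release_rates")
}
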