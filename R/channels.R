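# Channel-level currents and rate functions: Hodgkin-Huxley Na+/K+ rates, the
# four voltage-gated Ca2+ channel (VGCC) current types, per-channel microdomain
# currents, and the TRPM8 thermodynamic gate.

# linear-over-exponential HH alpha form a*u/(1 - exp(-u/s)), with the removable
# singularity at u = 0 evaluated by its limit a*s.
.lin_exp <- function(a, u, s) {
  out <- ifelse(abs(u) < 1e-7, a * s, a * u / (1 - exp(-pmin(pmax(u / s, -700), 700))))
  out
}

#' Hodgkin-Huxley rate constants
#'
#' The six voltage-dependent opening/closing rates of the Na+ activation (m),
#' Na+ inactivation (h) and K+ activation (n-type m) gates, in ms^-1. By
#' default the classic forms are used (resting potential -65 mV convention);
#' `literal = TRUE` switches to the source table's printed shorthand (logistic
#' substituted for the linear-over-exponential forms; K+ closing rate with
#' denominator 18 rather than 80), kept for comparison only -- the literal
#' strings do not support repetitive spiking.
#'
#' @param v_m membrane potential (mV), scalar or vector.
#' @param literal use the printed-table rate strings instead of the classic forms.
#' @return Named list of vectors `alpha_m_Na`, `beta_m_Na`, `alpha_h_Na`,
#'   `beta_h_Na`, `alpha_m_K`, `beta_m_K` (ms^-1, all >= 0).
#' @export
#' @examples
#' hh_rates(-55)$alpha_m_K   # 0.1 (limit value at the removable singularity)
hh_rates <- function(v_m, literal = FALSE) {
  if (any(!is.finite(v_m))) stop("hh_rates(): v_m must be finite")
  if (literal) {
    list(
      alpha_m_Na = 0.1 * (v_m + 40) * boltzmann(v_m, -40, 10),
      beta_m_Na  = 4 * exp(-(v_m + 65) / 18),
      alpha_h_Na = 0.07 * exp(-(v_m + 65) / 20),
      beta_h_Na  = boltzmann(v_m, -35, 10),
      alpha_m_K  = 0.01 * (v_m + 55) * boltzmann(v_m, -55, 10),
      beta_m_K   = 0.125 * exp(-(v_m + 65) / 18)
    )
  } else {
    list(
      alpha_m_Na = .lin_exp(0.1, v_m + 40, 10),
      beta_m_Na  = 4 * exp(-(v_m + 65) / 18),
      alpha_h_Na = 0.07 * exp(-(v_m + 65) / 20),
      beta_h_Na  = boltzmann(v_m, -35, 10),
      alpha_m_K  = .lin_exp(0.01, v_m + 55, 10),
      beta_m_K   = 0.125 * exp(-(v_m + 65) / 80)
    )
  }
}

# Table-2 VGCC steady states and time constants for the amyloid-beta flux
# network (single-channel conductances in pS). Midpoints are interpreted as
# the negatives of the printed shorthand values; inactivation slopes negative.
.vgcc2_inf <- function(kind, v) {
  switch(kind,
    m_T  = boltzmann(v, -63.5, 1.5),
    h_T  = boltzmann(v, -76.2, -3),   # shared by fast and slow inactivation
    m_L  = boltzmann(v, -50, 3),
    m_N  = boltzmann(v, -45, 7),
    m_R  = boltzmann(v, -10, 10),
    h_R  = boltzmann(v, -48, -5),
    stop("unknown gate: ", kind)
  )
}

.vgcc2_tau <- function(kind, v) {
  switch(kind,
    m_T  = 65 * exp(-((v + 68) / 6)^2) + 12,
    h_Tf = 50 * exp(-((v + 72) / 10)^2) + 10,
    h_Ts = 400 * exp(-((v + 100) / 10)^2) + 400,
    m_L  = 18 * exp(-((v + 45) / 20)^2) + 1.5,
    m_N  = 18 * exp(-((v + 70) / 25)^2) + 0.3,
    m_R  = 0.1 * exp(-((v + 62) / 13)^2) + 0.05,
    h_R  = 0.5 * exp(-((v + 55.6) / 18)^2) + 0.5,
    stop("unknown gate: ", kind)
  )
}

# calcium-dependent (algebraic) inactivation of the L- and N-type channels;
# C_c in uM, divided by 1000 as printed (uM -> mM).
.h_L_ca <- function(C_c) 0.00045 / (0.00045 + C_c / 1000)
.h_N_ca <- function(C_c) 0.0001 / (0.0001 + C_c / 1000)

#' Voltage-gated calcium channel current (amyloid-beta flux network form)
#'
#' The four VGCC currents of the astrocytic flux network, in the simplified
#' conductance-times-gates form `g m h (v_m - V_C)` with single-channel
#' conductances in pS (current in fA for v in mV):
#' T-type `g_T m_T (h_Tf + 0.04 h_Ts)`, L-type `g_L m_L h_L(C_c)`,
#' N-type `g_N m_N h_N(C_c)`, R-type `g_R m_R h_R`. The L/N inactivation terms
#' are algebraic functions of cytosolic Ca2+.
#'
#' @param kind one of `"T"`, `"L"`, `"N"`, `"R"`.
#' @param v_m membrane potential (mV).
#' @param gates named list of the kind's gate states: T needs `m_T`, `h_Tf`,
#'   `h_Ts`; L needs `m_L`; N needs `m_N`; R needs `m_R`, `h_R`.
#' @param C_c cytosolic Ca2+ (uM), used by the L/N inactivation terms.
#' @param p parameter set.
#' @return Current in fA (pS x mV).
#' @export
vgcc_current <- function(kind, v_m, gates, C_c, p = default_parameters()) {
  if (C_c < 0) stop("vgcc_current(): C_c must be nonnegative")
  drive <- v_m - p$V_C
  switch(kind,
    T = p$g_T_bar * gates$m_T * (gates$h_Tf + 0.04 * gates$h_Ts) * drive,
    L = p$g_L_bar * gates$m_L * .h_L_ca(C_c) * drive,
    N = p$g_N_bar * gates$m_N * .h_N_ca(C_c) * drive,
    R = p$g_R_bar * gates$m_R * gates$h_R * drive,
    stop("unknown VGCC kind '", kind, "' (use T, L, N or R)")
  )
}

#' Per-channel microdomain current
#'
#' Single-channel current feeding one open L- or N-type microdomain:
#' `i = g_Cx (v_m - V_C) / N_x` (nS x mV / count = pA), where `v_m` already
#' includes any astrocytic depolarization `v_ind`.
#'
#' @param kind `"L"` or `"N"`.
#' @param v_m effective membrane potential (mV).
#' @param p parameter set.
#' @return Per-channel current in pA.
#' @export
#' @examples
#' microdomain_current("N", -70 + 0)   # 0.6 * (-135) / 200
microdomain_current <- function(kind, v_m, p = default_parameters()) {
  if (any(!is.finite(v_m))) stop("microdomain_current(): v_m must be finite")
  switch(kind,
    L = p$g_CL * (v_m - p$V_C) / p$N_L,
    N = p$g_CN * (v_m - p$V_C) / p$N_N,
    stop("unknown microdomain kind '", kind, "' (use L or N)")
  )
}

#' TRPM8 open probability (two-state thermodynamic gating)
#'
#' `a_m8 = B((T + 273.15) DS, DH - z F v_m, R (T + 273.15))`: the equilibrium
#' open probability of a two-state channel with enthalpy difference `DH`
#' (J/mol), entropy difference `DS` (J/(mol K)) and gating charge `z` between
#' closed and open states. With the default (negative) `DH` and `DS` the gate
#' opens on cooling and on depolarization. Voltage is converted to volts inside
#' the energy term. Vectorized over `T` or `v_m`.
#'
#' @param T temperature in degrees Celsius (> -273.15).
#' @param v_m membrane potential (mV).
#' @param p parameter set (uses `DeltaH`, `DeltaS`, `z_gate`, `F`, `R_gas`).
#' @return Open probability in (0, 1).
#' @export
#' @examples
#' trpm8_open_probability(25, 0)   # ~0.038
trpm8_open_probability <- function(T, v_m, p = default_parameters()) {
  if (any(T <= -273.15)) stop("trpm8_open_probability(): T must exceed absolute zero")
  TK <- T + 273.15
  boltzmann(TK * p$DeltaS,
            p$DeltaH - p$z_gate * p$F * (v_m * 1e-3),
            p$R_gas * TK)
}

#' TRPM8 current
#'
#' `I_m8 = g_m8 a_m8 (v_m - V_m8)` in the conventional outward-positive form
#' (uA/cm2 for g_m8 in mS/cm2 and v in mV). In the membrane equation the
#' channel enters as `g_m8 a_m8 (V_m8 - v_m)`, driving the potential toward its
#' ~0 mV reversal, so the cold-opened channel depolarizes a resting neuron.
#'
#' @inheritParams trpm8_open_probability
#' @param g_m8 maximal conductance override (defaults to `p$g_m8`).
#' @return Current in uA/cm2; zero at `v_m = V_m8` and for `g_m8 = 0`.
#' @export
trpm8_current <- function(T, v_m, p = default_parameters(), g_m8 = p$g_m8) {
  if (g_m8 < 0) stop("trpm8_current(): g_m8 must be >= 0")
  g_m8 * trpm8_open_probability(T, v_m, p) * (v_m - p$V_m8)
}
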