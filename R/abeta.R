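# Amyloid-beta modulated astrocytic Ca2+ flux network, the astrocyte-to-neuron
# feedback current, and the coupled neuron-astrocyte network derivative.

# Hill ratio tolerating a zero half-saturation argument (x constant, K = state)
.hill_ratio <- function(x, K, n) {
  xn <- x^n
  xn / (xn + K^n)
}

#' Amyloid-beta calcium fluxes
#'
#' The named flux set of the astrocytic network (all in uM/s, printed units):
#' VGCC influx (T/L/N/R currents converted by `-I/(z_Ca F lambda_ast)`, with
#' the L-type current scaled by `(1 + A_VL l)`), IP3-receptor CICR, SERCA
#' uptake, ryanodine-receptor release with Abeta-sensitized half-saturation
#' `k_d + A_RyR l`, passive ER leak, membrane leak-in
#' `a1 + a2_in P_c + A_in l^n5`, plasma-membrane extrusion, and PLC-catalyzed
#' IP3 production scaled by `(1 + A_m l)`.
#'
#' @param s named abeta state (at least `C_c`, `C_r`, `P_c` and the VGCC gates;
#'   see [abeta_initial_state()]).
#' @param cfg an [abeta_config()].
#' @param p parameter set.
#' @param v_m driving membrane potential (mV).
#' @return Named list: `J_VGCC`, `J_CICR`, `J_SERCA`, `J_RyR`, `J_r`, `J_in`,
#'   `J_pm`, `J_PLC` (uM/s).
#' @export
abeta_fluxes <- function(s, cfg = abeta_config(), p = default_parameters(),
                         v_m = -70) {
  Cc <- s[["C_c"]]; Cr <- s[["C_r"]]; Pc <- s[["P_c"]]
  if (any(c(Cc, Cr, Pc) < 0)) stop("concentrations must be >= 0")
  gates <- list(m_T = s[["m_T"]], h_Tf = s[["h_Tf"]], h_Ts = s[["h_Ts"]],
                m_L = s[["m_L"]], m_N = s[["m_N"]], m_R = s[["m_R"]],
                h_R = s[["h_R"]])
  I_T <- vgcc_current("T", v_m, gates, Cc, p)
  I_L <- vgcc_current("L", v_m, gates, Cc, p)
  I_N <- vgcc_current("N", v_m, gates, Cc, p)
  I_R <- vgcc_current("R", v_m, gates, Cc, p)
  # currents in fA; 1e-15 A * 1e6 uM/M / (z F lambda_ast L) -> uM/s
  jfac <- 1e-9 / (p$z_Ca * p$F * p$lambda_ast)
  J_VGCC <- -(I_T + (1 + cfg$A_VL * cfg$l) * I_L + I_N + I_R) * jfac

  J_CICR <- 4 * p$M_CICR * .hill_ratio(p$P_CA, Cc, p$n1) *
    .hill_ratio(Cc, p$P_CI, p$n1) * .hill_ratio(Pc, p$P_IP3, p$n2) * (Cr - Cc)
  J_SERCA <- p$M_SERCA * .hill_ratio(Cc, p$P_SERCA, p$n4)
  J_RyR <- (p$k1 + p$k2 * .hill_ratio(Cc, p$k_d + cfg$A_RyR * cfg$l, p$n3)) * (Cr - Cc)
  J_r <- p$P_f * (Cr - Cc)
  J_in <- p$a1 + p$a2_in * Pc + cfg$A_in * cfg$l^p$n5
  J_pm <- p$lambda_PM * .hill_ratio(Cc, p$K_pm, p$n4)
  J_PLC <- (1 + cfg$A_m * cfg$l) * p$M_PLC * .hill_ratio(Cc, p$P_PC, p$n4)
  list(J_VGCC = J_VGCC, J_CICR = J_CICR, J_SERCA = J_SERCA, J_RyR = J_RyR,
       J_r = J_r, J_in = J_in, J_pm = J_pm, J_PLC = J_PLC)
}

#' Amyloid-beta astrocyte right-hand side
#'
#' Derivative of the flux-network state: cytosolic and ER Ca2+ balances, IP3
#' (`P_c`) production/degradation, and first-order VGCC gate relaxation at the
#' driving potential (clamped at `opts$vm_clamp` plus any `v_ind` step for the
#' autonomous variant).
#'
#' @param s named abeta state.
#' @param cfg an [abeta_config()].
#' @inheritParams neuron_rhs
#' @return Named derivative vector (per ms).
#' @export
abeta_rhs <- function(s, t = 0, cfg = abeta_config(), p = default_parameters(),
                      proto = stimulus_protocol(), opts = sim_options()) {
  s <- .check_state(s, "abeta")
  p2 <- .apply_cfg_params(p, cfg)
  d <- cpp_rhs(3L, t, unname(s), .param_vector(p2), .build_drive(proto, cfg, opts))
  setNames(d, names(s))
}

#' Astrocyte-to-neuron feedback current
#'
#' Depolarizing current injected into the neuron by astrocytic glutamate
#' release, as a function of the astrocytic cytosolic Ca2+:
#' `I_astro = A_astro ln(y)` for `y = 1000 C_c - 196.69 > 1`, and 0 otherwise
#' (continuous at the threshold). The printed hard-Heaviside gate (`y > 0`,
#' negative currents for y < 1) is available via
#' `sim_options(literal_heaviside = TRUE)` in the engine.
#'
#' @param C_c astrocytic cytosolic Ca2+ (uM, >= 0); vectorized.
#' @param p parameter set.
#' @param literal use the printed Heaviside form.
#' @return Current in uA/cm2.
#' @export
#' @examples
#' astro_feedback_current(0.2)   # 2.11 * log(3.31)
astro_feedback_current <- function(C_c, p = default_parameters(), literal = FALSE) {
  if (any(C_c < 0)) stop("C_c must be >= 0")
  y <- 1000 * C_c - 196.69
  thr <- if (literal) 0 else 1
  ifelse(y > thr, p$A_astro * log(pmax(y, 1e-300)), 0)
}

#' Coupled neuron-astrocyte right-hand side
#'
#' Joint derivative of the network model: the neuronal membrane equation with
#' the additional astrocytic feedback current `I_astro(C_c)`, the amyloid-beta
#' astrocyte driven by the shared membrane potential, and the astrocytic
#' release microdomains (L/N-type plus submembrane) exchanging with the
#' flux-network cytosol.
#'
#' @param neuron named neuron state.
#' @param astro named abeta state (the `ast_` block) concatenated with the
#'   microdomain block, or a full 17-element vector in
#'   `state_names("abeta_release")` order.
#' @param cfg an [abeta_config()].
#' @inheritParams neuron_rhs
#' @return Named derivative of the full coupled state
#'   (`state_names("coupled")`).
#' @export
coupled_rhs <- function(neuron, astro, t = 0, cfg = abeta_config(),
                        p = default_parameters(), proto = stimulus_protocol(),
                        opts = sim_options()) {
  neuron <- .check_state(neuron, "neuron")
  astro <- .check_state(astro, "abeta_release")
  s <- c(unname(neuron), unname(astro))
  p2 <- .apply_cfg_params(p, cfg)
  d <- cpp_rhs(5L, t, s, .param_vector(p2), .build_drive(proto, cfg, opts))
  setNames(d, state_names("coupled"))
}
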