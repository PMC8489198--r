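# Model variants, state packing (stable, versioned), and state constructors.

.variants <- c(neuron = 1L, astrocyte = 2L, abeta = 3L,
               abeta_release = 4L, coupled = 5L)

.state_names <- local({
  neuron <- c("v_m", "m_Na", "h_Na", "m_K", "m_CL", "h_CL", "m_CT",
              "h_CTf", "h_CTs", "C_L", "C_m", "C_c", "C_r")
  astro <- c("P", "h_P", "m_CL", "h_CL", "m_CN", "h_CN",
             "C_L", "C_N", "C_m", "C_c")
  abeta <- c("C_c", "C_r", "P_c", "m_T", "h_Tf", "h_Ts",
             "m_L", "m_N", "m_R", "h_R")
  micro <- c("md_m_CL", "md_h_CL", "md_m_CN", "md_h_CN",
             "md_C_L", "md_C_N", "md_C_m")
  list(neuron = neuron,
       astrocyte = astro,
       abeta = abeta,
       abeta_release = c(abeta, micro),
       coupled = c(neuron, paste0("ast_", abeta), micro))
})

.variant_id <- function(variant) {
  if (is.numeric(variant)) variant <- names(.variants)[match(variant, .variants)]
  id <- .variants[match(variant, names(.variants))]
  if (is.na(id)) stop("unknown model variant '", variant, "'; valid: ",
                      paste(names(.variants), collapse = ", "))
  id
}

#' State vector field names of a model variant
#' @param variant one of `"neuron"`, `"astrocyte"`, `"abeta"`,
#'   `"abeta_release"`, `"coupled"`.
#' @return Character vector of state names in packing order.
#' @export
state_names <- function(variant) {
  .state_names[[names(.variants)[.variant_id(variant)]]]
}

.check_state <- function(s, variant) {
  nm <- state_names(variant)
  if (length(s) != length(nm)) {
    stop("state for variant '", variant, "' needs ", length(nm),
         " elements (", paste(nm, collapse = ", "), ")")
  }
  if (any(!is.finite(s))) stop("non-finite state rejected")
  setNames(as.numeric(s), nm)
}

# steady-state value of a Table-1 gate at voltage v
.ss <- function(v, p, which) .gate_inf_tau(v, p, which)$inf

#' Initial neuron state
#'
#' Gates at their steady-state curves at `v`, calcium compartments at nominal
#' starting concentrations (uM). Use [resting_state()] for the relaxed
#' equilibrium.
#'
#' @param p parameter set.
#' @param v initial membrane potential (mV).
#' @param C_L,C_m,C_c,C_r initial compartment Ca2+ (uM).
#' @return Named state vector (see `state_names("neuron")`).
#' @export
neuron_initial_state <- function(p = default_parameters(), v = -65,
                                 C_L = 0.1, C_m = 0.1, C_c = 0.1, C_r = 1.5) {
  r <- hh_rates(v)
  c(v_m = v,
    m_Na = r$alpha_m_Na / (r$alpha_m_Na + r$beta_m_Na),
    h_Na = r$alpha_h_Na / (r$alpha_h_Na + r$beta_h_Na),
    m_K = r$alpha_m_K / (r$alpha_m_K + r$beta_m_K),
    m_CL = .ss(v, p, "m_CL"), h_CL = .ss(v, p, "h_CL"),
    m_CT = .ss(v, p, "m_CT"), h_CTf = .ss(v, p, "h_CT"), h_CTs = .ss(v, p, "h_CT"),
    C_L = C_L, C_m = C_m, C_c = C_c, C_r = C_r)
}

#' Initial astrocyte state
#' @param p parameter set.
#' @param v_ind initial depolarization added to the resting potential (mV).
#' @return Named state vector (see `state_names("astrocyte")`).
#' @export
astrocyte_initial_state <- function(p = default_parameters(), v_ind = 0) {
  v <- p$V_m_ast + v_ind
  P0 <- p$IP3_0
  Cc <- 0.1
  Q <- p$d2 * (P0 + p$d1) / (P0 + p$d3)
  c(P = P0, h_P = Q / (Q + Cc),
    m_CL = .ss(v, p, "m_CL"), h_CL = .ss(v, p, "h_CL"),
    m_CN = .ss(v, p, "m_CN"), h_CN = .ss(v, p, "h_CN"),
    C_L = 0.1, C_N = 0.1, C_m = 0.1, C_c = Cc)
}

#' Initial amyloid-beta astrocyte state
#'
#' Printed initial condition `(C_c, P_c, C_r) = (0.1, 0.1, 1.5)` uM with VGCC
#' gates at their steady states at the driving potential.
#'
#' @param p parameter set.
#' @param v driving membrane potential (mV).
#' @return Named state vector (see `state_names("abeta")`).
#' @export
abeta_initial_state <- function(p = default_parameters(), v = -70) {
  Cc <- 0.1
  c(C_c = Cc, C_r = 1.5, P_c = 0.1,
    m_T = boltzmann(v, -63.5, 1.5), h_Tf = boltzmann(v, -76.2, -3),
    h_Ts = boltzmann(v, -76.2, -3), m_L = boltzmann(v, -50, 3),
    m_N = boltzmann(v, -45, 7), m_R = boltzmann(v, -10, 10),
    h_R = boltzmann(v, -48, -5))
}

.micro_initial <- function(p, v) {
  c(md_m_CL = .ss(v, p, "m_CL"), md_h_CL = .ss(v, p, "h_CL"),
    md_m_CN = .ss(v, p, "m_CN"), md_h_CN = .ss(v, p, "h_CN"),
    md_C_L = 0.1, md_C_N = 0.1, md_C_m = 0.1)
}

#' Initial state for the release-tracking amyloid-beta astrocyte
#' @inheritParams abeta_initial_state
#' @return Named state vector (see `state_names("abeta_release")`).
#' @export
abeta_release_initial_state <- function(p = default_parameters(), v = -70) {
  c(abeta_initial_state(p, v), .micro_initial(p, v))
}

#' Initial state for the coupled neuron-astrocyte network
#'
#' Neuron at its relaxed resting state, amyloid-beta astrocyte at the printed
#' initial condition, astrocytic release microdomains at nominal values.
#'
#' @param p parameter set.
#' @param neuron optional pre-computed neuron state (e.g. [resting_state()]);
#'   computed if NULL.
#' @return Named state vector (see `state_names("coupled")`).
#' @export
coupled_initial_state <- function(p = default_parameters(), neuron = NULL) {
  if (is.null(neuron)) neuron <- resting_state(p)
  v <- neuron[["v_m"]]
  ab <- abeta_initial_state(p, v)
  names(ab) <- paste0("ast_", names(ab))
  c(neuron, ab, .micro_initial(p, v))
}
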