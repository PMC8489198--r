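# Deterministic ODE integration of any model variant under a protocol, with
# reproducible run metadata.

#' Integrator and model options
#'
#' @param t_max end of the integration window (ms, >= 0; starts at 0).
#' @param dt fixed step for the RK4 integrator (ms); also the initial step of
#'   the adaptive integrator.
#' @param out_dt output grid spacing (ms); must be an integer multiple of `dt`
#'   for the fixed-step method (it is rounded to one internally).
#' @param method `"rk4"` (fixed-step, bit-reproducible) or `"adaptive"`
#'   (Cash-Karp 4(5) with error control, for the slow IP3/amyloid scenarios).
#' @param rtol,atol adaptive relative/absolute error tolerances.
#' @param max_step adaptive maximum step (ms); keep at or below ~2x the fastest
#'   gate time constant (explicit method).
#' @param literal_rates use the printed HH rate strings (no spiking; comparison
#'   only).
#' @param literal_signs use the printed (non-conserving) microdomain/ER signs.
#' @param literal_heaviside use the printed Heaviside gate for I_astro.
#' @param literal_gmax use the raw printed thermal peak-conductance magnitudes.
#' @param vm_clamp driving membrane potential for the clamped abeta variants (mV).
#' @param rp_scale scale the stimulated IP3 production rate linearly with the
#'   v_ind amplitude (reference 20 mV); default off.
#' @param seed recorded in metadata; the model is fully deterministic and the
#'   value is never consumed.
#' @return A `sim_options` list.
#' @export
sim_options <- function(t_max = 600, dt = 0.01, out_dt = 0.05,
                        method = c("rk4", "adaptive"),
                        rtol = 1e-8, atol = 1e-10, max_step = 0.25,
                        literal_rates = FALSE, literal_signs = FALSE,
                        literal_heaviside = FALSE, literal_gmax = FALSE,
                        vm_clamp = -70, rp_scale = FALSE, seed = NULL) {
  method <- match.arg(method)
  if (t_max < 0) stop("t_max must be >= 0")
  if (dt <= 0 || out_dt <= 0) stop("dt and out_dt must be > 0")
  if (rtol <= 0 || atol <= 0) stop("tolerances must be > 0")
  structure(list(t_max = t_max, dt = dt, out_dt = out_dt, method = method,
                 rtol = rtol, atol = atol, max_step = max_step,
                 literal_rates = isTRUE(literal_rates),
                 literal_signs = isTRUE(literal_signs),
                 literal_heaviside = isTRUE(literal_heaviside),
                 literal_gmax = isTRUE(literal_gmax),
                 vm_clamp = vm_clamp, rp_scale = isTRUE(rp_scale),
                 seed = seed),
            class = "sim_options")
}

# default initial state for a variant
.default_initial <- function(variant, p, opts) {
  switch(names(.variants)[.variant_id(variant)],
         neuron = resting_state(p),
         astrocyte = astrocyte_initial_state(p),
         abeta = abeta_initial_state(p, v = opts$vm_clamp),
         abeta_release = abeta_release_initial_state(p, v = opts$vm_clamp),
         coupled = coupled_initial_state(p))
}

# per-variant release-rate traces from a state matrix
.release_traces <- function(variant, st, p) {
  vname <- names(.variants)[.variant_id(variant)]
  h <- function(x, K, n) hill(pmax(x, 0), K, n)
  if (vname == "neuron") {
    w <- st[, "m_CL"]^2 * st[, "h_CL"]
    R_CL <- w * h(st[, "C_L"], p$K_L, p$n_L) + (1 - w) * h(st[, "C_m"], p$K_L, p$n_L)
    R_Cm <- h(st[, "C_m"], p$K_m, p$n_m)
    return(cbind(R_CL = R_CL, R_Cm = R_Cm, R_CN = 0, R_total = R_CL + R_Cm))
  }
  if (vname == "astrocyte") {
    wL <- st[, "m_CL"]^2 * st[, "h_CL"]
    wN <- st[, "m_CN"]^2 * st[, "h_CN"]
    R_CL <- wL * h(st[, "C_L"], p$K_L, p$n_L) + (1 - wL) * h(st[, "C_m"], p$K_L, p$n_L)
    R_Cm <- h(st[, "C_m"], p$K_m, p$n_m)
    R_CN <- wN * h(st[, "C_N"], p$K_N, p$n_N) + (1 - wN) * h(st[, "C_m"], p$K_N, p$n_N)
    return(cbind(R_CL = R_CL, R_Cm = R_Cm, R_CN = R_CN,
                 R_total = R_CL + R_Cm + R_CN))
  }
  if (vname %in% c("abeta_release", "coupled")) {
    wL <- st[, "md_m_CL"]^2 * st[, "md_h_CL"]
    wN <- st[, "md_m_CN"]^2 * st[, "md_h_CN"]
    R_CL <- wL * h(st[, "md_C_L"], p$K_L, p$n_L) +
      (1 - wL) * h(st[, "md_C_m"], p$K_L, p$n_L)
    R_Cm <- h(st[, "md_C_m"], p$K_m, p$n_m)
    R_CN <- wN * h(st[, "md_C_N"], p$K_N, p$n_N) +
      (1 - wN) * h(st[, "md_C_m"], p$K_N, p$n_N)
    return(cbind(R_CL = R_CL, R_Cm = R_Cm, R_CN = R_CN,
                 R_total = R_CL + R_Cm + R_CN))
  }
  NULL # autonomous abeta variant carries no release microdomains
}

#' Integrate a model variant
#'
#' Runs the selected variant under a stimulus protocol from `t = 0` to
#' `opts$t_max`, returning state traces on the output grid, per-step release
#' rates (where the variant carries release microdomains), and reproducible
#' run metadata. Stimulus discontinuities are aligned to integration step
#' boundaries (fixed-step) or used as mandatory step endpoints (adaptive).
#' Identical inputs with the fixed-step method give bit-identical traces.
#'
#' @param variant `"neuron"`, `"astrocyte"`, `"abeta"`, `"abeta_release"` or
#'   `"coupled"`.
#' @param s0 named initial state; NULL for the variant's default.
#' @param proto a [stimulus_protocol()].
#' @param p parameter set.
#' @param opts a [sim_options()].
#' @param cfg an [abeta_config()] (consulted by the abeta/coupled variants).
#' @return A `sim_result`: list with `time` (ms), `states` (matrix, one named
#'   column per state variable), `release` (matrix or NULL), `variant`,
#'   `proto`, `metadata`.
#' @export
#' @examples
#' \donttest{
#' res <- integrate_model("neuron", proto = stimulus_protocol(cbind(50, 100, 15)),
#'                        opts = sim_options(t_max = 200))
#' max(res$states[, "v_m"])
#' }
integrate_model <- function(variant, s0 = NULL, proto = stimulus_protocol(),
                            p = default_parameters(), opts = sim_options(),
                            cfg = abeta_config()) {
  id <- .variant_id(variant)
  vname <- names(.variants)[id]
  stopifnot(inherits(proto, "stimulus_protocol"), inherits(opts, "sim_options"),
            inherits(cfg, "abeta_config"))
  if (is.null(s0)) s0 <- .default_initial(vname, p, opts)
  s0 <- .check_state(s0, vname)
  p2 <- if (vname %in% c("abeta", "abeta_release", "coupled")) {
    .apply_cfg_params(p, cfg)
  } else p
  drive <- .build_drive(proto, cfg, opts)
  raw <- cpp_integrate(id, unname(s0), 0, opts$t_max, opts$dt, opts$out_dt,
                       opts$method, opts$rtol, opts$atol, opts$max_step,
                       .param_vector(p2), drive)
  st <- raw$states
  colnames(st) <- state_names(vname)
  rel <- .release_traces(vname, st, p2)
  meta <- list(
    variant = vname,
    parameter_hash = .param_hash(p2),
    integrator = list(method = opts$method, dt = opts$dt, out_dt = opts$out_dt,
                      rtol = opts$rtol, atol = opts$atol,
                      max_step = opts$max_step),
    flags = opts[c("literal_rates", "literal_signs", "literal_heaviside",
                   "literal_gmax", "rp_scale")],
    abeta = unclass(cfg),
    vm_clamp = opts$vm_clamp,
    seed = opts$seed,
    assumptions = c(
      attr(p, "assumed"),
      "table2-boltzmann-midpoints-negated",
      "spike-criterion-threshold-crossing",
      "release-concentration-as-rate-integral"
    ),
    package_version = as.character(utils::packageVersion("exosim"))
  )
  structure(list(time = raw$time, states = st, release = rel,
                 variant = vname, proto = proto, metadata = meta),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> variant '%s': %d time points over %.6g ms, %d state variables\n",
              x$variant, length(x$time), max(x$time), ncol(x$states)))
  if (!is.null(x$release)) {
    tot <- .trapz(x$time, x$release[, "R_total"])
    cat(sprintf("  cumulative release integral: %.4g (rate x ms)\n", tot))
  }
  cat(sprintf("  parameter hash %s; integrator %s\n",
              x$metadata$parameter_hash, x$metadata$integrator$method))
  invisible(x)
}

# trapezoidal integral
.trapz <- function(t, y) sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
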