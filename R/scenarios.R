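# Registry of canonical simulation scenarios. Each entry is a fully specified
# runnable configuration (variant, initial state, protocol, parameters,
# integrator options); amplitudes / abeta level / TRPM8 conductance are
# exposed as arguments so the reference sweeps are one-liners.

.scenario_registry <- function() {
  list(
    fig2_neuron_pulse = function(amplitude = 20, p = default_parameters()) {
      list(variant = "neuron", s0 = NULL,
           proto = stimulus_protocol(pulses = cbind(50, 500, amplitude)),
           p = p, cfg = abeta_config(),
           opts = sim_options(t_max = 600, dt = 0.01, out_dt = 0.05),
           description = "depolarized neuron, 500 ms current pulse (10-20 uA/cm2 sweepable)")
    },
    fig2_astrocyte = function(amplitude = 20, p = default_parameters()) {
      list(variant = "astrocyte", s0 = NULL,
           proto = stimulus_protocol(v_ind = cbind(50, 500, amplitude)),
           p = p, cfg = abeta_config(),
           opts = sim_options(t_max = 1000, dt = 0.01, out_dt = 0.5),
           description = "electrically silent astrocyte, 500 ms v_ind step (10-30 mV sweepable)")
    },
    fig4_abeta_autonomous = function(l = 0.4, p = default_parameters()) {
      list(variant = "abeta", s0 = NULL,
           proto = stimulus_protocol(),
           p = p, cfg = abeta_config(l = l),
           opts = sim_options(t_max = 6e5, method = "adaptive", out_dt = 100,
                              rtol = 1e-6, atol = 1e-9, max_step = 0.25),
           description = "autonomous abeta astrocyte Ca2+ oscillations, v_m clamped at -70 mV")
    },
    fig6_abeta_release = function(l = 0.4, p = default_parameters()) {
      list(variant = "abeta_release", s0 = NULL,
           proto = stimulus_protocol(),
           p = p, cfg = abeta_config(l = l),
           opts = sim_options(t_max = 6e5, method = "adaptive", out_dt = 100,
                              rtol = 1e-6, atol = 1e-9, max_step = 0.25),
           description = "abeta astrocyte exosomal release without induced current")
    },
    fig7_abeta_driven = function(l = 0.4, amplitude = 20, p = default_parameters()) {
      list(variant = "coupled", s0 = NULL,
           proto = stimulus_protocol(pulses = cbind(50, 59950, amplitude)),
           p = p, cfg = abeta_config(l = l),
           opts = sim_options(t_max = 6e4, dt = 0.01, out_dt = 0.25),
           description = "abeta astrocyte release driven by a constant induced current")
    },
    fig8_coupled = function(l = 0.4, amplitude = 20, p = default_parameters()) {
      list(variant = "coupled", s0 = NULL,
           proto = stimulus_protocol(pulses = cbind(50, 59950, amplitude)),
           p = p, cfg = abeta_config(l = l),
           opts = sim_options(t_max = 6e4, dt = 0.01, out_dt = 0.25),
           description = "coupled neuron-astrocyte network with I_astro feedback")
    },
    fig9_thermal_pulse = function(T = 25, amplitude = 20, p = default_parameters()) {
      list(variant = "neuron", s0 = NULL,
           proto = stimulus_protocol(pulses = cbind(50, 500, amplitude),
                                     thermal = thermal_config("constant", T = T)),
           p = p, cfg = abeta_config(),
           opts = sim_options(t_max = 600, dt = 0.005, out_dt = 0.05),
           description = "thermal neuron (phi factors + Gaussian peak conductances) under a 500 ms pulse")
    },
    fig11_trpm8_const_T = function(T = 10, g_m8 = 3, amplitude = 20,
                                   p = default_parameters()) {
      list(variant = "neuron", s0 = NULL,
           proto = stimulus_protocol(pulses = cbind(50, 500, amplitude),
                                     thermal = thermal_config("constant", T = T,
                                                              g_m8 = g_m8,
                                                              trpm8 = TRUE)),
           p = p, cfg = abeta_config(),
           opts = sim_options(t_max = 600, dt = 0.005, out_dt = 0.05),
           description = "cold-sensing neuron with TRPM8 at constant temperature")
    },
    fig12_trpm8_ramp = function(g_m8 = 3, p = default_parameters()) {
      list(variant = "neuron", s0 = NULL,
           proto = stimulus_protocol(
             thermal = thermal_config("ramp", ramp = c(30, 5, 2000, 2),
                                      g_m8 = g_m8, trpm8 = TRUE)),
           p = p, cfg = abeta_config(),
           opts = sim_options(t_max = 4000, dt = 0.005, out_dt = 0.05),
           description = "TRPM8 neuron under a down-up temperature ramp (30 -> 5 -> 30 degC), no induced current")
    },
    fig13_thermal_abeta = function(l = 0.4, T = 25, amplitude = 20,
                                   p = default_parameters()) {
      list(variant = "coupled", s0 = NULL,
           proto = stimulus_protocol(pulses = cbind(50, 29950, amplitude),
                                     thermal = thermal_config("constant", T = T)),
           p = p, cfg = abeta_config(l = l),
           opts = sim_options(t_max = 3e4, dt = 0.005, out_dt = 1),
           description = "thermal coupled neuron-abeta astrocyte under constant current")
    },
    fig14_trpm8_abeta = function(l = 0.4, T = 10, g_m8 = 3, amplitude = 20,
                                 p = default_parameters()) {
      list(variant = "coupled", s0 = NULL,
           proto = stimulus_protocol(pulses = cbind(50, 29950, amplitude),
                                     thermal = thermal_config("constant", T = T,
                                                              g_m8 = g_m8,
                                                              trpm8 = TRUE)),
           p = p, cfg = abeta_config(l = l),
           opts = sim_options(t_max = 3e4, dt = 0.01, out_dt = 1),
           description = "TRPM8 + abeta coupled model at constant cold temperature")
    }
  )
}

#' List registered scenario names
#' @return Character vector of valid scenario names.
#' @export
scenario_names <- function() names(.scenario_registry())

#' Retrieve a runnable scenario configuration
#'
#' Returns the fully specified configuration (variant, initial state, stimulus
#' protocol, parameters, abeta config, integrator options) for one of the
#' registered simulation experiments. Scenario-specific knobs (pulse
#' `amplitude`, abeta level `l`, temperature `T`, TRPM8 conductance `g_m8`)
#' are passed through `...`.
#'
#' @param name a scenario name (see [scenario_names()]).
#' @param ... scenario-specific overrides.
#' @return A list with elements `variant`, `s0`, `proto`, `p`, `cfg`, `opts`,
#'   `description`, `name`.
#' @export
#' @examples
#' sc <- scenario("fig2_neuron_pulse", amplitude = 15)
#' sc$variant
scenario <- function(name, ...) {
  reg <- .scenario_registry()
  if (!name %in% names(reg)) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(reg), collapse = ", "))
  }
  sc <- reg[[name]](...)
  sc$name <- name
  sc
}

#' Run a registered scenario
#' @inheritParams scenario
#' @param opts optional [sim_options()] replacing the scenario default.
#' @return A `sim_result`.
#' @export
run_scenario <- function(name, ..., opts = NULL) {
  sc <- scenario(name, ...)
  if (!is.null(opts)) sc$opts <- opts
  integrate_model(sc$variant, sc$s0, sc$proto, sc$p, sc$opts, sc$cfg)
}

#' Parameter sweep over a scenario
#'
#' Runs one scenario once per value of a swept quantity. `param_path` is
#' either one of the scenario's own knobs (`"amplitude"`, `"l"`, `"T"`,
#' `"g_m8"`) or the name of a [default_parameters()] field. Execution is
#' deterministic; a summary table (spike count on the voltage trace where one
#' exists, cumulative release where tracked) accompanies the results.
#'
#' @param name scenario name.
#' @param param_path swept quantity (see above).
#' @param values numeric vector of values (may be empty).
#' @param ... fixed scenario overrides.
#' @return List with `results` (list of `sim_result`) and `summary`
#'   (data.frame: value, spike count, cumulative release).
#' @export
#' @examples
#' \donttest{
#' sw <- sweep_scenario("fig2_neuron_pulse", "amplitude", c(10, 15, 20))
#' sw$summary
#' }
sweep_scenario <- function(name, param_path, values, ...) {
  if (!is.character(param_path) || length(param_path) != 1L) {
    stop("param_path must be a single string (note: pass scenario overrides ",
         "like 'p' by their full name to avoid partial matching)")
  }
  reg <- .scenario_registry()
  if (!name %in% names(reg)) stop("unknown scenario '", name, "'")
  fixed <- list(...)
  knobs <- names(formals(reg[[name]]))
  results <- vector("list", length(values))
  for (i in seq_along(values)) {
    args <- fixed
    if (param_path %in% knobs) {
      args[[param_path]] <- values[i]
      sc <- do.call(scenario, c(list(name = name), args))
    } else if (param_path %in% names(default_parameters())) {
      base_p <- if ("p" %in% names(fixed)) fixed$p else default_parameters()
      args$p <- load_overrides(setNames(list(values[i]), param_path), base = base_p)
      sc <- do.call(scenario, c(list(name = name), args))
    } else {
      stop("unresolvable parameter path '", param_path, "'")
    }
    results[[i]] <- integrate_model(sc$variant, sc$s0, sc$proto, sc$p,
                                    sc$opts, sc$cfg)
  }
  summ <- data.frame(value = values,
                     spikes = rep(NA_real_, length(values)),
                     cumulative_release = rep(NA_real_, length(values)))
  for (i in seq_along(results)) {
    r <- results[[i]]
    vcol <- intersect(c("v_m"), colnames(r$states))
    if (length(vcol)) {
      summ$spikes[i] <- detect_spikes(r$time, r$states[, "v_m"])$count
    }
    if (!is.null(r$release)) {
      summ$cumulative_release[i] <- .trapz(r$time, r$release[, "R_total"])
    }
  }
  list(results = results, summary = summ)
}
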