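# Stimulus protocols: current pulse trains, astrocytic depolarization steps,
# and temperature schedules.

#' Thermal configuration
#'
#' Temperature handling for the thermal model variants. `mode = "off"` (the
#' default) reproduces the temperature-independent model exactly; `"constant"`
#' holds `T` fixed; `"ramp"` runs a piecewise-linear ramp `T_start -> T_end`
#' over `leg_ms` milliseconds, and back up for `legs = 2` (the down-up cold
#' sweep). `trpm8 = TRUE` adds the TRPM8 current with maximal conductance
#' `g_m8` (mS/cm2).
#'
#' @param mode one of `"off"`, `"constant"`, `"ramp"`.
#' @param T temperature in degrees Celsius (constant mode).
#' @param ramp numeric `c(T_start, T_end, leg_ms, legs)`; `legs` 1 (one-way)
#'   or 2 (down then up).
#' @param g_m8 TRPM8 maximal conductance (mS/cm2, >= 0).
#' @param trpm8 enable the TRPM8 current.
#' @return A `thermal_config` list.
#' @export
thermal_config <- function(mode = c("off", "constant", "ramp"), T = 25,
                           ramp = c(30, 5, 2000, 2), g_m8 = 0, trpm8 = FALSE) {
  mode <- match.arg(mode)
  if (mode == "constant" && T <= -273.15) stop("T must exceed absolute zero")
  if (mode == "ramp") {
    if (length(ramp) != 4) stop("ramp must be c(T_start, T_end, leg_ms, legs)")
    if (ramp[3] <= 0) stop("ramp leg duration must be > 0")
    if (any(ramp[1:2] <= -273.15)) stop("ramp temperatures must exceed absolute zero")
    if (!ramp[4] %in% c(1, 2)) stop("ramp legs must be 1 or 2")
  }
  if (g_m8 < 0) stop("g_m8 must be >= 0")
  structure(list(mode = mode, T = T, ramp = ramp, g_m8 = g_m8,
                 trpm8 = isTRUE(trpm8)), class = "thermal_config")
}

#' Temperature at time t under a thermal configuration
#' @param th a [thermal_config()].
#' @param t time (ms), vectorized.
#' @return Temperature(s) in degC (`NA` for mode "off").
#' @export
temperature_at <- function(th, t) {
  stopifnot(inherits(th, "thermal_config"))
  if (th$mode == "off") return(rep(NA_real_, length(t)))
  if (th$mode == "constant") return(rep(th$T, length(t)))
  leg <- th$ramp[3]
  if (th$ramp[4] <= 1) {
    u <- pmin(pmax(t / leg, 0), 1)
    return(th$ramp[1] + (th$ramp[2] - th$ramp[1]) * u)
  }
  tt <- pmin(pmax(t, 0), 2 * leg)
  ifelse(tt <= leg,
         th$ramp[1] + (th$ramp[2] - th$ramp[1]) * tt / leg,
         th$ramp[2] + (th$ramp[1] - th$ramp[2]) * (tt - leg) / leg)
}

.check_pulse_table <- function(x, what) {
  if (is.null(x)) return(matrix(numeric(0), 0, 3))
  x <- as.matrix(x)
  if (ncol(x) != 3) stop(what, " must have columns (start, duration, amplitude)")
  if (any(x[, 2] <= 0)) stop(what, " durations must be > 0")
  if (nrow(x) > 1) {
    o <- order(x[, 1])
    s <- x[o, 1]; e <- x[o, 1] + x[o, 2]
    if (any(s[-1] < e[-nrow(x)])) stop(what, " intervals must be non-overlapping")
  }
  unname(x)
}

#' Stimulus protocol
#'
#' Time-dependent drive for a simulation: induced current pulses `I_ind`
#' (applied to the neuronal membrane), astrocytic depolarization steps `v_ind`
#' (added to the resting astrocytic potential, and gating IP3 production), and
#' a temperature schedule.
#'
#' @param pulses matrix/data.frame with columns (start ms, duration ms,
#'   amplitude uA/cm2), or NULL.
#' @param v_ind matrix/data.frame with columns (start ms, duration ms,
#'   amplitude mV), or NULL.
#' @param thermal a [thermal_config()].
#' @return A `stimulus_protocol` list.
#' @export
#' @examples
#' stimulus_protocol(pulses = cbind(50, 500, 20))
stimulus_protocol <- function(pulses = NULL, v_ind = NULL,
                              thermal = thermal_config("off")) {
  stopifnot(inherits(thermal, "thermal_config"))
  structure(list(pulses = .check_pulse_table(pulses, "pulses"),
                 v_ind = .check_pulse_table(v_ind, "v_ind"),
                 thermal = thermal),
            class = "stimulus_protocol")
}

#' Induced current at time t
#' @param proto a [stimulus_protocol()].
#' @param t time (ms), vectorized.
#' @return I_ind in uA/cm2.
#' @export
i_ind_at <- function(proto, t) {
  out <- numeric(length(t))
  pl <- proto$pulses
  if (nrow(pl)) for (i in seq_len(nrow(pl)))
    out <- out + ifelse(t >= pl[i, 1] & t < pl[i, 1] + pl[i, 2], pl[i, 3], 0)
  out
}

#' Astrocytic depolarization at time t
#' @inheritParams i_ind_at
#' @return v_ind in mV.
#' @export
v_ind_at <- function(proto, t) {
  out <- numeric(length(t))
  vi <- proto$v_ind
  if (nrow(vi)) for (i in seq_len(nrow(vi)))
    out <- out + ifelse(t >= vi[i, 1] & t < vi[i, 1] + vi[i, 2], vi[i, 3], 0)
  out
}

#' Amyloid-beta configuration
#'
#' The scalar amyloid-beta burden `l` (dimensionless) and the four pathway
#' weights it scales: L-type VGCC (`A_VL`), ryanodine-receptor sensitization
#' (`A_RyR`), mGluR5/PLC (`A_m`), and membrane leak (`A_in`).
#'
#' @param l amyloid-beta level (>= 0); the reference runs use 0, 0.4 and 1.
#' @param A_VL,A_RyR,A_m,A_in pathway weights (>= 0, default 1).
#' @return An `abeta_config` list.
#' @export
abeta_config <- function(l = 0, A_VL = 1, A_RyR = 1, A_m = 1, A_in = 1) {
  if (l < 0) stop("l must be >= 0")
  if (any(c(A_VL, A_RyR, A_m, A_in) < 0)) stop("pathway weights must be >= 0")
  structure(list(l = l, A_VL = A_VL, A_RyR = A_RyR, A_m = A_m, A_in = A_in),
            class = "abeta_config")
}

# assemble the drive list consumed by the C++ engine
.build_drive <- function(proto, cfg = abeta_config(), opts = sim_options()) {
  th <- proto$thermal
  list(
    pulse_start = proto$pulses[, 1], pulse_dur = proto$pulses[, 2],
    pulse_amp = proto$pulses[, 3],
    vind_start = proto$v_ind[, 1], vind_dur = proto$v_ind[, 2],
    vind_amp = proto$v_ind[, 3],
    thermal_mode = match(th$mode, c("off", "constant", "ramp")) - 1L,
    T_const = th$T,
    T_start = th$ramp[1], T_end = th$ramp[2],
    ramp_dur = th$ramp[3], ramp_legs = as.integer(th$ramp[4]),
    trpm8 = as.integer(th$trpm8), g_m8 = th$g_m8,
    literal_rates = as.integer(opts$literal_rates),
    literal_signs = as.integer(opts$literal_signs),
    literal_heaviside = as.integer(opts$literal_heaviside),
    literal_gmax = as.integer(opts$literal_gmax),
    l = cfg$l, vm_clamp = opts$vm_clamp,
    rp_scale = as.integer(opts$rp_scale)
  )
}

# pathway weights live in the parameter set; an abeta_config overrides them
.apply_cfg_params <- function(p, cfg) {
  load_overrides(list(A_VL = cfg$A_VL, A_RyR = cfg$A_RyR,
                      A_m = cfg$A_m, A_in = cfg$A_in), base = p)
}
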