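#' @useDynLib exosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Single source of truth for every model constant: value, unit (as printed),
# provenance (table cell or section), and whether positivity is enforced.
# Values are stored in their printed units; rate constants printed per second
# are converted to the millisecond time base by canonical_units() (the
# simulation engine applies the same conversions internally).
.param_table <- function() {
  # entry helper: value, unit, provenance, positive?
  e <- function(value, unit, prov, pos = FALSE) {
    list(value = value, unit = unit, provenance = prov, positive = pos)
  }
  list(
    ## -- membrane / Hodgkin-Huxley --------------------------------------
    V_K      = e(-70,   "mV",        "core constant table"),
    V_Na     = e(50,    "mV",        "core constant table"),
    V_L      = e(-54.4, "mV",        "core constant table"),
    V_C      = e(65,    "mV",        "core constant table (listed twice, stored once)"),
    g_K_bar  = e(36,    "mS/cm3",    "core constant table", TRUE),
    g_Na_bar = e(120,   "mS/cm3",    "core constant table", TRUE),
    g_L      = e(0.3,   "mS/cm3",    "core constant table", TRUE),
    c_m      = e(1,     "uF/cm2",    "core constant table", TRUE),

    ## -- neuron calcium compartments --------------------------------------
    f         = e(0.01,     "1",     "core constant table", TRUE),
    alpha     = e(5e-15,    "umol.pm/(A.s)", "core constant table (consumed as uM/ms per pA after /lambda); 0 allowed (membrane exchange off)"),
    lambda_ud = e(2.62e-19, "L",     "core constant table", TRUE),
    lambda_m  = e(5e-14,    "L",     "core constant table", TRUE),
    lambda_c  = e(5.7e-13,  "L",     "core constant table", TRUE),
    lambda_r  = e(5.7e-13 / 31, "L", "derived: lambda_c / (printed ratio lambda_c/lambda_r = 31)", TRUE),
    B_ud      = e(264,      "ms^-1", "core constant table", TRUE),
    B_m       = e(0.128,    "ms^-1", "core constant table", TRUE),
    k_PMCA    = e(0.300,    "ms^-1", "core constant table; 0 allowed (pump off)"),
    k_SERCA   = e(0.100,    "ms^-1", "core constant table", TRUE),
    p_leak    = e(3e-4,     "ms^-1", "core constant table", TRUE),
    N_L       = e(200,      "count", "core constant table", TRUE),
    N_N       = e(200,      "count", "core constant table", TRUE),
    g_CT      = e(0.4,      "nS",    "core constant table", TRUE),
    g_CL      = e(0.7,      "nS",    "core constant table", TRUE),
    g_CN      = e(0.6,      "nS",    "core constant table", TRUE),
    K_L       = e(50,       "uM",    "core constant table", TRUE),
    K_m       = e(2,        "uM",    "core constant table", TRUE),
    K_N       = e(2,        "uM",    "core constant table", TRUE),
    n_L       = e(4,        "1",     "core constant table", TRUE),
    n_m       = e(4,        "1",     "core constant table", TRUE),
    n_N       = e(4,        "1",     "core constant table", TRUE),

    ## -- L-type gate (Boltzmann / bell time constants) ---------------------
    V_m_CL     = e(-30,  "mV", "core constant table"),
    S_m_CL     = e(10,   "mV", "core constant table"),
    V_h_CL     = e(-33,  "mV", "core constant table"),
    S_h_CL     = e(-5,   "mV", "core constant table"),
    tau_m_V_CL = e(1,    "ms", "core constant table", TRUE),
    tau_m0_V_CL = e(0.05, "ms", "core constant table"),
    V_tau_m_CL = e(-23,  "mV", "core constant table"),
    S_tau_m_CL = e(20,   "mV", "core constant table"),
    tau_h_V_CL = e(60,   "ms", "core constant table", TRUE),
    tau_h0_V_CL = e(51,  "ms", "core constant table"),
    V_tau_h_CL = e(0,    "mV", "core constant table"),
    S_tau_h_CL = e(20,   "mV", "core constant table"),

    ## -- T-type gate ------------------------------------------------------
    V_m_CT     = e(-49,  "mV", "core constant table"),
    S_m_CT     = e(4,    "mV", "core constant table"),
    V_h_CT     = e(-52,  "mV", "core constant table"),
    S_h_CT     = e(-5,   "mV", "core constant table"),
    tau_m_V_CT = e(15,   "ms", "core constant table", TRUE),
    tau_m0_V_CT = e(0,   "ms", "core constant table"),
    V_tau_m_CT = e(-50,  "mV", "core constant table"),
    S_tau_m_CT = e(12,   "mV", "core constant table"),
    tau_h_V_CT = e(20,   "ms", "core constant table", TRUE),
    tau_h0_V_CT = e(5,   "ms", "core constant table"),
    V_tau_h_CT = e(-50,  "mV", "core constant table"),
    S_tau_h_CT = e(15,   "mV", "core constant table"),

    ## -- N-type gate ------------------------------------------------------
    V_m_CN     = e(-5,   "mV", "core constant table"),
    S_m_CN     = e(10,   "mV", "core constant table"),
    V_h_CN     = e(33,   "mV", "core constant table (printed +33)"),
    S_h_CN     = e(-5,   "mV", "core constant table"),
    tau_m_V_CN = e(1,    "ms", "core constant table", TRUE),
    tau_m0_V_CN = e(0.05, "ms", "core constant table"),
    V_tau_m_CN = e(-23,  "mV", "core constant table"),
    S_tau_m_CN = e(20,   "mV", "core constant table"),
    tau_h_V_CN = e(60,   "ms", "core constant table", TRUE),
    tau_h0_V_CN = e(51,  "ms", "core constant table"),
    V_tau_h_CN = e(0,    "mV", "core constant table"),
    S_tau_h_CN = e(20,   "mV", "core constant table"),

    ## -- astrocyte IP3 / Li-Rinzel -----------------------------------------
    IP3_0    = e(0.160,    "uM",      "core constant table (also used as the IP3 production baseline P0; assumed identity)", TRUE),
    r_P      = e(0.04,     "uM/s",    "core constant table", TRUE),
    tau_P    = e(1 / 0.000140, "ms",  "core constant table (printed 1/0.000140 ms)", TRUE),
    V_m_ast  = e(-70,      "mV",      "astrocyte model (resting membrane potential)"),
    c0       = e(2,        "uM",      "core constant table", TRUE),
    c1       = e(0.185,    "1",       "core constant table", TRUE),
    v1       = e(6,        "s^-1",    "core constant table", TRUE),
    v2       = e(0.11,     "s^-1",    "core constant table", TRUE),
    v3       = e(0.9,      "uM/s",    "core constant table", TRUE),
    k3       = e(0.1,      "uM",      "core constant table", TRUE),
    d1       = e(0.13,     "uM",      "core constant table", TRUE),
    d2       = e(1.049,    "uM",      "core constant table", TRUE),
    d3       = e(0.943,    "uM",      "core constant table", TRUE),
    d5       = e(0.082,    "uM",      "core constant table", TRUE),
    d6       = e(1,        "1",       "astrocyte model (IP3R gating Hill exponent)", TRUE),
    a2_ip3r  = e(0.5,      "1/(uM.s)", "core constant table ('a_2' row with unit 1/(uM s); IP3R inactivation rate)", TRUE),
    A_astro  = e(2.11,     "uA/cm2",  "astrocyte feedback current", TRUE),

    ## -- amyloid-beta flux network (rates printed per second) --------------
    A_VL      = e(1,      "1",     "core constant table"),
    A_RyR     = e(1,      "1",     "core constant table"),
    A_m       = e(1,      "1",     "core constant table"),
    A_in      = e(1,      "1",     "core constant table"),
    k1        = e(0.013,  "s^-1",  "core constant table", TRUE),
    k2        = e(0.18,   "s^-1",  "core constant table", TRUE),
    k_d       = e(0.13,   "uM",    "core constant table", TRUE),
    n1        = e(2.02,   "1",     "core constant table", TRUE),
    n2        = e(2.2,    "1",     "core constant table", TRUE),
    n3        = e(3,      "1",     "core constant table", TRUE),
    n4        = e(2,      "1",     "core constant table", TRUE),
    n5        = e(3.5,    "1",     "core constant table", TRUE),
    a1        = e(0.003,  "uM/s",  "core constant table", TRUE),
    a2_in     = e(0.02,   "s^-1",  "core constant table ('a_2' row with value 0.02; membrane-leak slope)", TRUE),
    lambda_PM = e(4.2,    "uM/s",  "core constant table", TRUE),
    lambda_ast = e(3.49e-13, "L",  "core constant table", TRUE),
    M_SERCA   = e(15,     "uM/s",  "core constant table", TRUE),
    M_CICR    = e(10,     "s^-1",  "core constant table", TRUE),
    M_PLC     = e(0.05,   "uM/s",  "core constant table (listed twice, stored once)", TRUE),
    P_SERCA   = e(0.1,    "uM",    "core constant table (printed uM/s; Hill constant, stored as uM)", TRUE),
    P_PC      = e(0.3,    "uM",    "core constant table (printed uM/s; Hill constant, stored as uM)", TRUE),
    P_CA      = e(0.15,   "uM",    "core constant table (printed uM/s; Hill constant, stored as uM)", TRUE),
    P_CI      = e(0.15,   "uM",    "core constant table", TRUE),
    P_IP3     = e(0.1,    "uM",    "core constant table", TRUE),
    P_deg     = e(0.08,   "s^-1",  "core constant table", TRUE),
    P_f       = e(0.01,   "s^-1",  "core constant table", TRUE),
    K_pm      = e(1.3329, "uM",    "assumed: no printed value; calibrated so the l=0 flux network rests at the printed C_c = 0.1 uM (v = -70 mV)", TRUE),
    g_T_bar   = e(0.0600, "pS",    "core constant table", TRUE),
    g_L_bar   = e(3.5000, "pS",    "core constant table", TRUE),
    g_N_bar   = e(0.3900, "pS",    "core constant table", TRUE),
    g_R_bar   = e(0.2225, "pS",    "core constant table", TRUE),

    ## -- TRPM8 / thermodynamics --------------------------------------------
    DeltaH   = e(-156000, "J/mol",     "core constant table (-156 kJ/mol)"),
    DeltaS   = e(-550,    "J/(mol.K)", "core constant table"),
    z_gate   = e(0.87,    "e",         "core constant table ('z'; TRPM8 gating charge)", TRUE),
    z_Ca     = e(2,       "1",         "calcium valence (current-to-flux conversion)", TRUE),
    R_gas    = e(8.3144,  "J/(mol.K)", "core constant table", TRUE),
    F        = e(96485,   "C/mol",     "core constant table", TRUE),
    g_m8     = e(0,       "mS/cm2",    "TRPM8 scenarios (0 = channel absent; reference runs use 3, 5, 10)"),
    V_m8     = e(0,       "mV",        "TRPM8 model (reversal potential near 0 mV)"),
    T_ref    = e(10,      "degC",      "core constant table ('T')"),

    ## -- temperature-dependent peak conductances / phi factors -------------
    gK_max_amp  = e(1.60,  "1 (relative)", "thermal peak-conductance formula", TRUE),
    gK_max_mid  = e(27.88, "degC",         "thermal peak-conductance formula"),
    gK_max_sig  = e(12.85, "degC",         "thermal peak-conductance formula", TRUE),
    gNa_max_amp = e(0.42,  "1 (relative)", "thermal peak-conductance formula", TRUE),
    gNa_max_mid = e(31.83, "degC",         "thermal peak-conductance formula"),
    gNa_max_sig = e(31.62, "degC",         "thermal peak-conductance formula", TRUE),
    phi_mK_a    = e(4.3518, "1", "gate-rate temperature scaling", TRUE),
    phi_mK_q    = e(2.7,    "1", "gate-rate temperature scaling", TRUE),
    phi_mNa_a   = e(4.4288, "1", "gate-rate temperature scaling", TRUE),
    phi_mNa_q   = e(3,      "1", "gate-rate temperature scaling", TRUE),
    phi_hNa_a   = e(3.8923, "1", "gate-rate temperature scaling", TRUE),
    phi_hNa_q   = e(2.3,    "1", "gate-rate temperature scaling", TRUE)
  )
}

# fields whose printed unit is per second (or uM per second); canonical_units()
# rescales them to the millisecond time base.
.per_second_fields <- c(
  "r_P", "v1", "v2", "v3", "a2_ip3r", "k1", "k2", "a1", "a2_in",
  "lambda_PM", "M_SERCA", "M_CICR", "M_PLC", "P_deg", "P_f"
)

#' Default parameter set
#'
#' Returns the full named constant registry for every model variant: membrane
#' and Hodgkin-Huxley constants, the four-compartment neuronal calcium
#' parameters, voltage-gated calcium channel gating constants, Li-Rinzel
#' IP3-receptor constants, the amyloid-beta flux-network constants, and the
#' TRPM8/temperature constants. Each field carries a unit tag and a provenance
#' string; values are stored in their printed units (rates mixing per-second
#' and per-millisecond bases; see [canonical_units()]).
#'
#' Two constants named "a_2" in the source table are stored as distinct fields
#' `a2_in` (membrane-leak slope, per second) and `a2_ip3r` (IP3-receptor
#' inactivation rate, per micromolar-second); overriding a bare `a2` is
#' rejected as ambiguous. `lambda_r` is derived from `lambda_c` and the printed
#' ratio `lambda_c/lambda_r = 31`. `K_pm` has no printed value and defaults to
#' 0.1 uM, flagged as assumed.
#'
#' @return A `parameter_set` object: named list of numeric values with
#'   attributes `units`, `provenance`, `positive` and `assumed`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$K_L                       # 50 (uM)
#' p$lambda_c / p$lambda_r     # 31
default_parameters <- function() {
  tab <- .param_table()
  values <- lapply(tab, `[[`, "value")
  structure(
    values,
    units = vapply(tab, `[[`, "", "unit"),
    provenance = vapply(tab, `[[`, "", "provenance"),
    positive = vapply(tab, `[[`, TRUE, "positive"),
    assumed = c("K_pm", "IP3_0-as-P0", "alpha-per-ms", "z_Ca"),
    time_base = "printed",
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %d constants (time base: %s)\n",
              length(x), attr(x, "time_base")))
  cat("assumed fields:", paste(attr(x, "assumed"), collapse = ", "), "\n")
  invisible(x)
}

.validate_params <- function(p) {
  pos <- attr(p, "positive")
  vals <- unlist(p)
  if (any(!is.finite(vals))) {
    stop("non-finite parameter value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  bad <- names(vals)[pos[names(vals)] & vals <= 0]
  # g_m8 = 0 disables the channel and is allowed; tau baselines may be 0
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  }
  invisible(p)
}

#' Override parameters from a config document or named list
#'
#' Applies overrides to the default registry. `source` is either a named list
#' / named numeric vector, or a path to a flat text config of `key: value`
#' lines (a YAML-style mapping subset; `#` comments and blank lines ignored).
#' Unknown keys are rejected by name; the ambiguous bare name `a2` is rejected
#' (use `a2_in` or `a2_ip3r`); positivity-constrained fields reject
#' non-positive values. Units are not re-interpreted: overrides are taken in
#' the same printed units as the defaults.
#'
#' @param source named list/vector of overrides, or path to a config file.
#' @param base parameter set to start from (defaults to [default_parameters()]).
#' @return A `parameter_set` with the listed fields replaced.
#' @export
#' @examples
#' p <- load_overrides(list(g_m8 = 5))
#' p$g_m8
load_overrides <- function(source, base = default_parameters()) {
  ov <- if (is.character(source) && length(source) == 1L) {
    .parse_config_file(source)
  } else if (is.list(source) || (is.numeric(source) && !is.null(names(source)))) {
    as.list(source)
  } else {
    stop("`source` must be a named list/vector or a config file path")
  }
  if (!length(ov)) return(base)
  if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
    stop("all overrides must be named")
  }
  if ("a2" %in% names(ov)) {
    stop("ambiguous parameter name 'a2': use 'a2_in' (membrane-leak slope) ",
         "or 'a2_ip3r' (IP3R inactivation rate)")
  }
  unknown <- setdiff(names(ov), names(base))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  pos <- attr(base, "positive")
  for (k in names(ov)) {
    v <- suppressWarnings(as.numeric(ov[[k]]))
    if (length(v) != 1L || !is.finite(v)) stop("parameter '", k, "' must be a finite scalar")
    if (pos[[k]] && v <= 0) {
      stop("parameter '", k, "' must be strictly positive (got ", v, ")")
    }
    base[[k]] <- v
  }
  .validate_params(base)
  attr(base, "overridden") <- union(attr(base, "overridden"), names(ov))
  base
}

# flat "key: value" / "key = value" parser (no external yaml dependency)
.parse_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=[:space:]]+)[[:space:]]*[:=][[:space:]]*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
    out[[m[2]]] <- m[3]
  }
  out
}

#' Convert a parameter set to the canonical millisecond time base
#'
#' The source tables mix per-millisecond rates (neuronal compartments) with
#' per-second rates (Li-Rinzel and amyloid-beta fluxes). This converts every
#' per-second field to the millisecond base (x 1e-3) and records the factors in
#' the `conversions` attribute, so reporting back in original units
#' ([original_units()]) is an exact identity.
#'
#' @param p a `parameter_set` in printed units.
#' @return The parameter set on the ms time base (`time_base = "ms"`).
#' @export
canonical_units <- function(p) {
  if (identical(attr(p, "time_base"), "ms")) return(p)
  conv <- setNames(rep(1, length(p)), names(p))
  for (k in .per_second_fields) {
    p[[k]] <- p[[k]] * 1e-3
    conv[[k]] <- 1e-3
  }
  u <- attr(p, "units")
  u[.per_second_fields] <- sub("s\\^-1", "ms^-1", u[.per_second_fields])
  u[.per_second_fields] <- sub("/s$", "/ms", u[.per_second_fields])
  u[.per_second_fields] <- sub("\\.s\\)", ".ms)", u[.per_second_fields])
  attr(p, "units") <- u
  attr(p, "conversions") <- conv
  attr(p, "time_base") <- "ms"
  p
}

#' Report a canonical parameter set back in its original printed units
#'
#' Exact inverse of [canonical_units()].
#' @param p a `parameter_set` on the ms time base.
#' @return The parameter set in printed units.
#' @export
original_units <- function(p) {
  if (!identical(attr(p, "time_base"), "ms")) return(p)
  conv <- attr(p, "conversions")
  for (k in names(conv)) p[[k]] <- p[[k]] / conv[[k]]
  tab <- .param_table()
  attr(p, "units") <- vapply(tab, `[[`, "", "unit")
  attr(p, "conversions") <- NULL
  attr(p, "time_base") <- "printed"
  p
}

# flatten for the C++ engine (printed units; C++ converts internally)
.param_vector <- function(p) {
  stopifnot(inherits(p, "parameter_set"))
  if (identical(attr(p, "time_base"), "ms")) p <- original_units(p)
  unlist(p)
}

# short deterministic fingerprint for run metadata
.param_hash <- function(p) {
  v <- .param_vector(p)
  s <- paste(names(v), format(v, digits = 17), sep = "=", collapse = ";")
  # cheap multiplicative hash, avoids a digest dependency
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
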