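# Independent term-by-term oracles for every model right-hand side, coded
# directly from the governing equations with plain R arithmetic. These share
# no code with the package implementation (own logistic/Hill/tau helpers) and
# exist solely to cross-check the compiled engine.

o_boltz <- function(x, shift, scale) 1 / (1 + exp(-(x - shift) / scale))
o_hill <- function(x, K, n) x^n / (x^n + K^n)
o_bell <- function(v, tauV, Vt, St, tau0) {
  tauV / (exp(-(v - Vt) / St) + exp((v - Vt) / St)) + tau0
}

# Table-1 gate steady states / taus (neuron + astrocyte microdomains)
o_gates1 <- function(v) {
  list(
    m_CL = list(inf = o_boltz(v, -30, 10),  tau = o_bell(v, 1, -23, 20, 0.05)),
    h_CL = list(inf = o_boltz(v, -33, -5),  tau = o_bell(v, 60, 0, 20, 51)),
    m_CT = list(inf = o_boltz(v, -49, 4),   tau = max(o_bell(v, 15, -50, 12, 0), 1e-3)),
    h_CTf = list(inf = o_boltz(v, -52, -5), tau = o_bell(v, 20, -50, 15, 5)),
    h_CTs = list(inf = o_boltz(v, -52, -5), tau = 400 * exp(-((v + 100) / 10)^2) + 400),
    m_CN = list(inf = o_boltz(v, -5, 10),   tau = o_bell(v, 1, -23, 20, 0.05)),
    h_CN = list(inf = o_boltz(v, 33, -5),   tau = o_bell(v, 60, 0, 20, 51))
  )
}

# classic HH rates (ms^-1)
o_hh <- function(v) {
  linexp <- function(a, u, s) if (abs(u) < 1e-7) a * s else a * u / (1 - exp(-u / s))
  list(am_Na = linexp(0.1, v + 40, 10),
       bm_Na = 4 * exp(-(v + 65) / 18),
       ah_Na = 0.07 * exp(-(v + 65) / 20),
       bh_Na = o_boltz(v, -35, 10),
       am_K = linexp(0.01, v + 55, 10),
       bm_K = 0.125 * exp(-(v + 65) / 80))
}

# neuron RHS (conserving signs), I_extra adds to the membrane current
oracle_neuron_rhs <- function(s, t, p, I_ind = 0, I_extra = 0) {
  v <- s[["v_m"]]
  r <- o_hh(v)
  g <- o_gates1(v)
  d <- numeric(13)
  names(d) <- names(s)
  d["m_Na"] <- r$am_Na * (1 - s[["m_Na"]]) - r$bm_Na * s[["m_Na"]]
  d["h_Na"] <- r$ah_Na * (1 - s[["h_Na"]]) - r$bh_Na * s[["h_Na"]]
  d["m_K"] <- r$am_K * (1 - s[["m_K"]]) - r$bm_K * s[["m_K"]]
  for (k in c("m_CL", "h_CL", "m_CT", "h_CTf", "h_CTs")) {
    d[k] <- (g[[k]]$inf - s[[k]]) / g[[k]]$tau
  }
  iCL <- p$g_CL * (v - p$V_C) / p$N_L
  ICT <- p$g_CT * s[["m_CT"]] * (s[["h_CTf"]] + 0.04 * s[["h_CTs"]]) * (v - p$V_C)
  w <- s[["m_CL"]]^2 * s[["h_CL"]]
  CL <- s[["C_L"]]; Cm <- s[["C_m"]]; Cc <- s[["C_c"]]; Cr <- s[["C_r"]]
  d["C_L"] <- -p$f * (p$alpha / p$lambda_ud * iCL + p$B_ud * (CL - Cm))
  d["C_m"] <- p$f / p$lambda_m *
    (-p$alpha * ICT + p$N_L * p$lambda_ud * p$B_ud * w * (CL - Cm) -
       p$lambda_c * p$k_PMCA * Cm - p$lambda_c * p$B_m * (Cm - Cc))
  d["C_c"] <- p$f * (p$B_m * (Cm - Cc) + p$p_leak * (Cr - Cc) - p$k_SERCA * Cc)
  d["C_r"] <- -p$f * (p$lambda_c / p$lambda_r) *
    (p$p_leak * (Cr - Cc) - p$k_SERCA * Cc)
  gK <- p$g_K_bar * s[["m_K"]]^4
  gNa <- p$g_Na_bar * s[["m_Na"]]^3 * s[["h_Na"]]
  d["v_m"] <- (gK * (p$V_K - v) + gNa * (p$V_Na - v) + p$g_L * (p$V_L - v) +
                 I_ind + I_extra) / p$c_m
  d
}

# astrocyte RHS at effective potential V_m + v_ind
oracle_astro_rhs <- function(s, t, p, v_ind = 0, stim_on = (v_ind != 0)) {
  v <- p$V_m_ast + v_ind
  g <- o_gates1(v)
  d <- numeric(10)
  names(d) <- names(s)
  P <- s[["P"]]; Cc <- s[["C_c"]]
  d["P"] <- (p$IP3_0 - P) / p$tau_P + (p$r_P / 1000) * as.numeric(stim_on)
  Q <- p$d2 * (P + p$d1) / (P + p$d3)
  hPinf <- Q / (Q + Cc)
  tau_hP <- 1000 / (p$a2_ip3r * (Q + Cc))
  d["h_P"] <- (hPinf - s[["h_P"]]) / tau_hP
  mPinf <- (P / (P + p$d1)) * (Cc / (Cc + p$d5))
  er <- (p$c0 - Cc) / p$c1
  d["C_c"] <- 1e-3 * (-p$c1 * p$v1 * mPinf^3 * s[["h_P"]]^3 * (Cc - er) -
                        p$c1 * p$v2 * (Cc - er) -
                        p$v3 * o_hill(Cc, p$k3, p$n4))
  for (k in c("m_CL", "h_CL", "m_CN", "h_CN")) {
    d[k] <- (g[[k]]$inf - s[[k]]) / g[[k]]$tau
  }
  iCL <- p$g_CL * (v - p$V_C) / p$N_L
  iCN <- p$g_CN * (v - p$V_C) / p$N_N
  CL <- s[["C_L"]]; CN <- s[["C_N"]]; Cm <- s[["C_m"]]
  d["C_L"] <- -p$f * (p$alpha / p$lambda_ud * iCL + p$B_ud * (CL - Cm))
  d["C_N"] <- -p$f * (p$alpha / p$lambda_ud * iCN + p$B_ud * (CN - Cm))
  wL <- s[["m_CL"]]^2 * s[["h_CL"]]
  wN <- s[["m_CN"]] * s[["h_CN"]]
  d["C_m"] <- p$f / p$lambda_m *
    (p$N_L * p$lambda_ud * p$B_ud * wL * (CL - Cm) +
       p$N_N * p$lambda_ud * p$B_ud * wN * (CN - Cm) -
       p$lambda_c * p$k_PMCA * Cm - p$lambda_c * p$B_m * (Cm - Cc))
  d
}

# Table-2 VGCC gate curves for the amyloid network
o_gates2 <- function(v) {
  list(
    m_T = list(inf = o_boltz(v, -63.5, 1.5), tau = 65 * exp(-((v + 68) / 6)^2) + 12),
    h_Tf = list(inf = o_boltz(v, -76.2, -3), tau = 50 * exp(-((v + 72) / 10)^2) + 10),
    h_Ts = list(inf = o_boltz(v, -76.2, -3), tau = 400 * exp(-((v + 100) / 10)^2) + 400),
    m_L = list(inf = o_boltz(v, -50, 3), tau = 18 * exp(-((v + 45) / 20)^2) + 1.5),
    m_N = list(inf = o_boltz(v, -45, 7), tau = 18 * exp(-((v + 70) / 25)^2) + 0.3),
    m_R = list(inf = o_boltz(v, -10, 10), tau = 0.1 * exp(-((v + 62) / 13)^2) + 0.05),
    h_R = list(inf = o_boltz(v, -48, -5), tau = 0.5 * exp(-((v + 55.6) / 18)^2) + 0.5)
  )
}

# amyloid-beta astrocyte RHS at driving potential v (10 states)
oracle_abeta_rhs <- function(s, v, p, l = 0,
                             A_VL = 1, A_RyR = 1, A_m = 1, A_in = 1) {
  d <- numeric(10)
  names(d) <- names(s)
  g <- o_gates2(v)
  for (k in c("m_T", "h_Tf", "h_Ts", "m_L", "m_N", "m_R", "h_R")) {
    d[k] <- (g[[k]]$inf - s[[k]]) / g[[k]]$tau
  }
  Cc <- s[["C_c"]]; Cr <- s[["C_r"]]; Pc <- s[["P_c"]]
  hL <- 0.00045 / (0.00045 + Cc / 1000)
  hN <- 0.0001 / (0.0001 + Cc / 1000)
  drv <- v - p$V_C
  IT <- p$g_T_bar * s[["m_T"]] * (s[["h_Tf"]] + 0.04 * s[["h_Ts"]]) * drv
  IL <- p$g_L_bar * s[["m_L"]] * hL * drv
  IN <- p$g_N_bar * s[["m_N"]] * hN * drv
  IR <- p$g_R_bar * s[["m_R"]] * s[["h_R"]] * drv
  JV <- -(IT + (1 + A_VL * l) * IL + IN + IR) * 1e-9 / (p$z_Ca * p$F * p$lambda_ast)
  Jc <- 4 * p$M_CICR * (p$P_CA^p$n1 / (p$P_CA^p$n1 + Cc^p$n1)) *
    o_hill(Cc, p$P_CI, p$n1) * o_hill(Pc, p$P_IP3, p$n2) * (Cr - Cc)
  Js <- p$M_SERCA * o_hill(Cc, p$P_SERCA, p$n4)
  Jry <- (p$k1 + p$k2 * o_hill(Cc, p$k_d + A_RyR * l, p$n3)) * (Cr - Cc)
  Jr <- p$P_f * (Cr - Cc)
  Jin <- p$a1 + p$a2_in * Pc + A_in * l^p$n5
  Jpm <- p$lambda_PM * o_hill(Cc, p$K_pm, p$n4)
  Jplc <- (1 + A_m * l) * p$M_PLC * o_hill(Cc, p$P_PC, p$n4)
  d["C_c"] <- 1e-3 * (JV + Jin + Jry + Jc + Jr - Js - Jpm)
  d["C_r"] <- 1e-3 * (Js - Jc - Jry - Jr)
  d["P_c"] <- 1e-3 * (Jplc - p$P_deg * Pc)
  d
}

# astrocytic microdomain release block at driving potential v, bulk Cc supplied
oracle_micro_rhs <- function(s, v, p, Cc_bulk) {
  d <- numeric(7)
  names(d) <- names(s)
  g <- o_gates1(v)
  map <- c(md_m_CL = "m_CL", md_h_CL = "h_CL", md_m_CN = "m_CN", md_h_CN = "h_CN")
  for (k in names(map)) d[k] <- (g[[map[k]]]$inf - s[[k]]) / g[[map[k]]]$tau
  iCL <- p$g_CL * (v - p$V_C) / p$N_L
  iCN <- p$g_CN * (v - p$V_C) / p$N_N
  CL <- s[["md_C_L"]]; CN <- s[["md_C_N"]]; Cm <- s[["md_C_m"]]
  d["md_C_L"] <- -p$f * (p$alpha / p$lambda_ud * iCL + p$B_ud * (CL - Cm))
  d["md_C_N"] <- -p$f * (p$alpha / p$lambda_ud * iCN + p$B_ud * (CN - Cm))
  wL <- s[["md_m_CL"]]^2 * s[["md_h_CL"]]
  wN <- s[["md_m_CN"]] * s[["md_h_CN"]]
  d["md_C_m"] <- p$f / p$lambda_m *
    (p$N_L * p$lambda_ud * p$B_ud * wL * (CL - Cm) +
       p$N_N * p$lambda_ud * p$B_ud * wN * (CN - Cm) -
       p$lambda_c * p$k_PMCA * Cm - p$lambda_c * p$B_m * (Cm - Cc_bulk))
  d
}

# full coupled RHS: neuron + I_astro, abeta block at the neuron's v, microblock
oracle_coupled_rhs <- function(s, t, p, l, I_ind = 0) {
  sn <- s[1:13]
  sa <- s[14:23]
  names(sa) <- sub("^ast_", "", names(sa))
  sm <- s[24:30]
  Cc <- sa[["C_c"]]
  y <- 1000 * Cc - 196.69
  Ia <- if (y > 1) p$A_astro * log(y) else 0
  dn <- oracle_neuron_rhs(sn, t, p, I_ind = I_ind, I_extra = Ia)
  da <- oracle_abeta_rhs(sa, sn[["v_m"]], p, l = l)
  dm <- oracle_micro_rhs(sm, sn[["v_m"]], p, Cc_bulk = Cc)
  out <- c(dn, da, dm)
  names(out) <- names(s)
  out
}

# random-but-valid states for property loops
random_neuron_state <- function(p) {
  v <- runif(1, -80, 30)
  s <- neuron_initial_state(p, v = v,
                            C_L = runif(1, 0, 40), C_m = runif(1, 0, 2),
                            C_c = runif(1, 0, 1), C_r = runif(1, 0.5, 20))
  gates <- c("m_Na", "h_Na", "m_K", "m_CL", "h_CL", "m_CT", "h_CTf", "h_CTs")
  s[gates] <- runif(length(gates))
  s
}
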