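p <- default_parameters()

test_that("HH rate functions: removable singularities and fixed values", {
  r <- hh_rates(-55)
  expect_equal(r$alpha_m_K, 0.1)        # limit of 0.01(v+55)/(1-exp(-(v+55)/10))
  r <- hh_rates(-65)
  expect_equal(r$beta_m_Na, 4)          # exponent vanishes
  expect_equal(r$alpha_h_Na, 0.07)
  r <- hh_rates(-40)
  expect_equal(r$alpha_m_Na, 0.1 * 10)  # limit at v = -40
  # classic rates nonnegative over a wide range (the literal table strings
  # go negative below -40 mV, one of the reasons they are non-default)
  rr <- hh_rates(seq(-120, 60, by = 0.5))
  expect_true(all(unlist(rr) >= 0))
  expect_lt(hh_rates(-60, literal = TRUE)$alpha_m_Na, 0)
  # the literal table strings differ from the classic forms (beta_m_K /18)
  expect_gt(hh_rates(-100, literal = TRUE)$beta_m_K,
            hh_rates(-100, literal = FALSE)$beta_m_K)
  expect_error(hh_rates(NaN), "finite")
})

test_that("VGCC currents: zero driving force, Ca-dependent inactivation", {
  gates <- list(m_T = 0.5, h_Tf = 0.5, h_Ts = 0.5, m_L = 0.5, m_N = 0.5,
                m_R = 0.5, h_R = 0.5)
  for (k in c("T", "L", "N", "R")) {
    expect_identical(vgcc_current(k, p$V_C, gates, 0.1, p), 0)
  }
  # h_L at C_c = 0.45 uM: 0.00045/(0.00045 + 0.00045) = 0.5
  expect_equal(exosim:::.h_L_ca(0.45), 0.5)
  expect_equal(exosim:::.h_N_ca(0.1), 0.5)
  # L current halves when C_c moves from 0 to 0.45
  i0 <- vgcc_current("L", -20, gates, 0, p)
  i1 <- vgcc_current("L", -20, gates, 0.45, p)
  expect_equal(i1 / i0, 0.5)
  expect_error(vgcc_current("X", -20, gates, 0.1, p), "unknown")
  expect_error(vgcc_current("L", -20, gates, -1, p), "nonnegative")
  # steady-state R-type activation midpoint under the sign convention
  expect_equal(exosim:::.vgcc2_inf("m_R", -10), 0.5)
  expect_equal(exosim:::.vgcc2_inf("m_T", -63.5), 0.5)
})

test_that("microdomain per-channel currents scale as g (v - V_C) / N", {
  expect_equal(microdomain_current("N", -70, p), 0.6 * (-135) / 200)
  expect_identical(microdomain_current("L", p$V_C, p), 0)
  p2 <- load_overrides(list(N_N = 400), base = p)
  expect_equal(microdomain_current("N", -70, p2),
               microdomain_current("N", -70, p) / 2)
  expect_error(microdomain_current("T", -70, p), "unknown")
})

test_that("TRPM8 gate: midpoint, printed value, monotonicity, energy scaling", {
  # exact thermodynamic midpoint: (T+273.15) DS = DH - zF v
  vm <- -65
  TK <- (p$DeltaH - p$z_gate * p$F * vm * 1e-3) / p$DeltaS
  Tmid <- TK - 273.15
  expect_equal(trpm8_open_probability(Tmid, vm, p), 0.5)
  # direct evaluation at 25 degC, 0 mV (independent calculator value)
  expect_equal(trpm8_open_probability(25, 0, p), 0.0384, tolerance = 0.01)
  # strictly decreasing in T at fixed v; increasing in v at fixed T
  a <- trpm8_open_probability(seq(0, 40, by = 0.5), -65, p)
  expect_true(all(diff(a) < 0))
  b <- trpm8_open_probability(10, seq(-90, 40, by = 1), p)
  expect_true(all(diff(b) > 0))
  expect_gt(trpm8_open_probability(5, -65, p), trpm8_open_probability(15, -65, p))
  # invariance under common rescaling of all energy terms (DH, DS, R, and the
  # electrical work term via F): only energy ratios matter
  p2 <- load_overrides(list(DeltaH = p$DeltaH * 7, DeltaS = p$DeltaS * 7,
                            R_gas = p$R_gas * 7, F = p$F * 7), base = p)
  Ts <- c(2, 11, 23, 37)
  expect_equal(trpm8_open_probability(Ts, -50, p2),
               trpm8_open_probability(Ts, -50, p))
  # at v = 0 the electrical term vanishes, so DH/DS/R rescaling alone suffices
  p3 <- load_overrides(list(DeltaH = p$DeltaH * 3, DeltaS = p$DeltaS * 3,
                            R_gas = p$R_gas * 3), base = p)
  expect_equal(trpm8_open_probability(Ts, 0, p3),
               trpm8_open_probability(Ts, 0, p))
  expect_error(trpm8_open_probability(-300, 0, p), "absolute zero")
})

test_that("TRPM8 current: product form, disabled channel, sign", {
  expect_identical(trpm8_current(10, 0, p, g_m8 = 3), 0)   # V_m8 = 0
  expect_identical(trpm8_current(10, -65, p, g_m8 = 0), 0)
  for (v in c(-80, -20, 15)) {
    expect_equal(sign(trpm8_current(10, v, p, g_m8 = 5)), sign(v))
  }
  expect_error(trpm8_current(10, -65, p, g_m8 = -1), ">= 0")
})
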