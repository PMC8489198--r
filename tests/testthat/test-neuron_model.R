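p <- default_parameters()

test_that("neuron_rhs matches the independent term-by-term oracle", {
  # reference state: resting potential, gates at steady state,
  # nominal concentrations
  s <- neuron_initial_state(p, v = -65, C_L = 0.1, C_m = 0.1, C_c = 0.1, C_r = 1.5)
  expect_equal(neuron_rhs(s, 0, p), oracle_neuron_rhs(s, 0, p), tolerance = 1e-12)
  # under a live pulse
  proto <- stimulus_protocol(pulses = cbind(0, 100, 17))
  expect_equal(neuron_rhs(s, 50, p, proto),
               oracle_neuron_rhs(s, 50, p, I_ind = 17), tolerance = 1e-12)
  # property loop over random valid states
  set.seed(42)
  for (i in 1:25) {
    s <- random_neuron_state(p)
    expect_equal(neuron_rhs(s, 0, p), oracle_neuron_rhs(s, 0, p),
                 tolerance = 1e-10)
  }
  expect_error(neuron_rhs(c(s[-1], NA), 0, p))
})

test_that("microdomain exchange terms vanish when C_L equals C_m", {
  s <- neuron_initial_state(p, v = -60, C_L = 0.37, C_m = 0.37)
  d <- neuron_rhs(s, 0, p)
  # with C_L = C_m, dC_L/dt reduces to the pure current-influx term
  iCL <- microdomain_current("L", -60, p)
  expect_equal(unname(d["C_L"]), -p$f * (p$alpha / p$lambda_ud) * iCL)
  # and the exchange contribution to C_m is zero: compare against a state
  # with the exchange weight zeroed
  s2 <- s; s2[["m_CL"]] <- 0
  d2 <- neuron_rhs(s2, 0, p)
  expect_equal(unname(d["C_m"]), unname(d2["C_m"]))
})

test_that("cytosol balance: dC_c/dt = 0 at the algebraic balance point", {
  # B_m (C_m - C_c) + p_leak (C_r - C_c) = k_SERCA C_c
  Cc <- 0.2
  Cr <- 5
  Cm <- (p$k_SERCA * Cc - p$p_leak * (Cr - Cc)) / p$B_m + Cc
  s <- neuron_initial_state(p, v = -65, C_m = Cm, C_c = Cc, C_r = Cr)
  expect_equal(unname(neuron_rhs(s, 0, p)["C_c"]), 0, tolerance = 1e-15)
})

test_that("neuron_release: Hill branches, midpoint, bounds", {
  s <- neuron_initial_state(p, v = -65, C_L = 30, C_m = 2)
  s[["m_CL"]] <- 0
  r <- neuron_release(s, p)
  expect_equal(r$R_CL, hill(2, p$K_L, p$n_L))   # closed branch only
  expect_equal(r$R_Cm, 0.5)                     # C_m = K_m
  expect_identical(r$R_CN, 0)
  expect_equal(r$total, r$R_CL + r$R_Cm)
  set.seed(7)
  for (i in 1:20) {
    s <- random_neuron_state(p)
    r <- neuron_release(s, p)
    expect_gte(r$R_CL, 0); expect_lte(r$R_CL, 1)
    expect_gte(r$R_Cm, 0); expect_lte(r$R_Cm, 1)
    expect_lte(r$total, 2)
  }
})

test_that("resting_state is a fixed point with physiological potential", {
  rs <- resting_state(p)
  expect_lt(max(abs(neuron_rhs(rs, 0, p))), 1e-8)
  expect_gt(rs[["v_m"]], -75)
  expect_lt(rs[["v_m"]], -55)
  # gates sit on their steady-state curves
  v <- rs[["v_m"]]
  for (k in c("m_CL", "h_CL", "m_CT")) {
    expect_equal(rs[[k]], exosim:::.ss(v, p, sub("CTf", "CT", k)),
                 tolerance = 1e-6)
  }
  r <- hh_rates(v)
  expect_equal(rs[["m_Na"]], r$alpha_m_Na / (r$alpha_m_Na + r$beta_m_Na),
               tolerance = 1e-6)
  # unstimulated run from rest produces no spikes
  res <- integrate_model("neuron", rs, stimulus_protocol(), p,
                         sim_options(t_max = 500))
  expect_identical(detect_spikes(res$time, res$states[, "v_m"])$count, 0L)
  expect_lt(diff(range(res$states[, "v_m"])), 0.01)
})

test_that("cumulative release is non-decreasing in time", {
  res <- integrate_model("neuron", NULL,
                         stimulus_protocol(pulses = cbind(20, 150, 15)), p,
                         sim_options(t_max = 250))
  cumrel <- cumsum(res$release[, "R_total"])
  expect_true(all(diff(cumrel) >= 0))
})
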