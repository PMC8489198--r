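p <- default_parameters()

test_that("phi factors: printed prefactors at 20 degC, Q10 decades, positivity", {
  ph <- phi_factors(20, p)
  expect_equal(ph$phi_mK, 4.3518)
  expect_equal(ph$phi_mNa, 4.4288)
  expect_equal(ph$phi_hNa, 3.8923)
  expect_equal(phi_factors(30, p)$phi_mNa, 4.4288 * 3)
  expect_equal(phi_factors(10, p)$phi_mK, 4.3518 / 2.7)
  Ts <- seq(-5, 45, by = 2.5)
  for (f in phi_factors(Ts, p)) {
    expect_true(all(f > 0))
    expect_true(all(diff(f) > 0))
  }
})

test_that("peak conductances: Gaussian maxima and one-sigma point", {
  expect_equal(peak_conductances(27.88, p)$g_K_max, 1.60)
  expect_equal(peak_conductances(31.83, p)$g_Na_max, 0.42)
  expect_equal(peak_conductances(27.88 + 12.85, p)$g_K_max, 1.60 / exp(1))
  expect_equal(peak_conductances(31.83 + 31.62, p)$g_Na_max, 0.42 / exp(1))
})

test_that("degenerate thermal configuration reproduces neuron_rhs exactly", {
  # phi prefactors forced to 1 and Gaussian midpoints moved to T = 20 make the
  # thermal model at 20 degC algebraically identical to the reference model
  p1 <- load_overrides(list(phi_mK_a = 1, phi_mNa_a = 1, phi_hNa_a = 1,
                            gK_max_mid = 20, gNa_max_mid = 20), base = p)
  th <- thermal_config("constant", T = 20)
  proto <- stimulus_protocol(pulses = cbind(0, 100, 12), thermal = th)
  proto0 <- stimulus_protocol(pulses = cbind(0, 100, 12))
  set.seed(3)
  for (i in 1:10) {
    s <- random_neuron_state(p1)
    expect_equal(thermal_neuron_rhs(s, 5, p1, proto),
                 neuron_rhs(s, 5, p1, proto0), tolerance = 1e-14)
  }
})

test_that("g_m8 = 0 disables TRPM8 in the thermal membrane equation", {
  th_on <- thermal_config("constant", T = 10, g_m8 = 0, trpm8 = TRUE)
  th_off <- thermal_config("constant", T = 10)
  s <- neuron_initial_state(p)
  expect_equal(
    thermal_neuron_rhs(s, 0, p, stimulus_protocol(thermal = th_on)),
    thermal_neuron_rhs(s, 0, p, stimulus_protocol(thermal = th_off)),
    tolerance = 1e-14)
  # and a nonzero g_m8 only changes the membrane equation, by I_m8/c_m
  th3 <- thermal_config("constant", T = 10, g_m8 = 3, trpm8 = TRUE)
  d3 <- thermal_neuron_rhs(s, 0, p, stimulus_protocol(thermal = th3))
  d0 <- thermal_neuron_rhs(s, 0, p, stimulus_protocol(thermal = th_off))
  v <- s[["v_m"]]
  expect_equal(unname(d3["v_m"] - d0["v_m"]),
               -trpm8_current(10, v, p, g_m8 = 3) / p$c_m, tolerance = 1e-10)
  expect_equal(d3[-1], d0[-1], tolerance = 1e-14)
})

test_that("temperature schedules: constant and piecewise-linear down-up ramp", {
  th <- thermal_config("ramp", ramp = c(30, 5, 2000, 2))
  expect_equal(temperature_at(th, 0), 30)
  expect_equal(temperature_at(th, 1000), 17.5)
  expect_equal(temperature_at(th, 2000), 5)
  expect_equal(temperature_at(th, 3000), 17.5)
  expect_equal(temperature_at(th, 4000), 30)
  expect_equal(temperature_at(th, 9999), 30)  # held after the ramp
  th1 <- thermal_config("ramp", ramp = c(30, 5, 2000, 1))
  expect_equal(temperature_at(th1, 2000), 5)
  expect_equal(temperature_at(th1, 5000), 5)
  expect_error(thermal_config("ramp", ramp = c(30, 5, -1, 2)), "> 0")
  expect_error(thermal_config("constant", T = -280), "absolute zero")
})

test_that("thermal gating scales rates but not steady states", {
  # at any fixed voltage the HH gate fixed point is unchanged by temperature,
  # while the relaxation rate scales by phi
  p1 <- p
  v <- -55
  r <- hh_rates(v)
  minf <- r$alpha_m_K / (r$alpha_m_K + r$beta_m_K)
  s <- neuron_initial_state(p1, v = v)
  s[["m_K"]] <- minf
  for (T in c(5, 20, 35)) {
    proto <- stimulus_protocol(thermal = thermal_config("constant", T = T))
    d <- thermal_neuron_rhs(s, 0, p1, proto)
    expect_equal(unname(d["m_K"]), 0, tolerance = 1e-12)
  }
  s[["m_K"]] <- 0.1
  d20 <- thermal_neuron_rhs(s, 0, p1,
                            stimulus_protocol(thermal = thermal_config("constant", T = 20)))
  d30 <- thermal_neuron_rhs(s, 0, p1,
                            stimulus_protocol(thermal = thermal_config("constant", T = 30)))
  expect_equal(unname(d30["m_K"] / d20["m_K"]), 2.7, tolerance = 1e-9)
})

test_that("ramp response is asymmetric between descending and ascending legs", {
  res <- run_scenario("fig12_trpm8_ramp", g_m8 = 3)
  sp <- detect_spikes(res$time, res$states[, "v_m"])
  leg <- res$proto$thermal$ramp[3]
  down <- sum(sp$times <= leg)
  up <- sum(sp$times > leg & sp$times <= 2 * leg)
  expect_gt(down + up, 0)
  expect_false(down == up)
  # the ascending-leg activity outlasts the descending leg
  expect_gt(up, down)
})
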