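p <- default_parameters()

test_that("IP3 production: fixed points and monotone relaxation", {
  # stimulated steady state P* = P0 + tau_P r_P
  Pstar <- p$IP3_0 + p$tau_P * p$r_P * 1e-3
  expect_equal(Pstar, 0.4457, tolerance = 1e-3)
  proto_on <- stimulus_protocol(v_ind = cbind(0, 1000, 20))
  expect_equal(ip3_rhs(Pstar, 10, p, proto_on), 0, tolerance = 1e-15)
  # stimulus off, P = P0 is a fixed point
  expect_identical(ip3_rhs(p$IP3_0, 0, p), 0)
  # relaxation toward the active steady state is monotone (linear ODE)
  P <- 0.16
  dt <- 10
  vals <- numeric(200)
  for (i in 1:200) { P <- P + dt * ip3_rhs(P, 10, p, proto_on); vals[i] <- P }
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < Pstar))
  expect_error(ip3_rhs(-0.1, 0, p), ">= 0")
})

test_that("astrocyte_rhs matches the independent oracle", {
  s <- astrocyte_initial_state(p)
  s[["P"]] <- 0.16; s[["h_P"]] <- 0.8; s[["C_c"]] <- 0.1
  expect_equal(astrocyte_rhs(s, 0, p), oracle_astro_rhs(s, 0, p, v_ind = 0),
               tolerance = 1e-12)
  proto <- stimulus_protocol(v_ind = cbind(0, 500, 20))
  expect_equal(astrocyte_rhs(s, 100, p, proto),
               oracle_astro_rhs(s, 100, p, v_ind = 20), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    s2 <- astrocyte_initial_state(p)
    s2[1:6] <- c(runif(1, 0.05, 1), runif(5))
    s2[7:10] <- runif(4, 0, 5)
    names(s2) <- names(s)
    expect_equal(astrocyte_rhs(s2, 0, p), oracle_astro_rhs(s2, 0, p),
                 tolerance = 1e-10)
  }
})

test_that("Li-Rinzel structure: zero-gradient ER terms and h_P midpoint", {
  # when C_c equals the ER-equivalent concentration (c0 - C_c)/c1 the CICR and
  # leak terms vanish; the remaining cytosol derivative is the SERCA term
  Cc <- p$c0 / (1 + p$c1)
  s <- astrocyte_initial_state(p)
  s[["C_c"]] <- Cc
  d <- astrocyte_rhs(s, 0, p)
  expect_equal(unname(d["C_c"]), -1e-3 * p$v3 * hill(Cc, p$k3, p$n4),
               tolerance = 1e-12)
  # h_P steady state is 0.5 when C_c = Q (Hill midpoint, exponent d6 = 1)
  P <- 0.3
  Q <- p$d2 * (P + p$d1) / (P + p$d3)
  s[["P"]] <- P; s[["C_c"]] <- Q; s[["h_P"]] <- 0.5
  expect_equal(unname(astrocyte_rhs(s, 0, p)["h_P"]), 0, tolerance = 1e-12)
})

test_that("astrocyte_release: equal-concentration degeneracy and bounds", {
  s <- astrocyte_initial_state(p)
  s[["C_N"]] <- 1.3; s[["C_m"]] <- 1.3; s[["C_L"]] <- 1.3
  r <- astrocyte_release(s, p)
  expect_equal(r$R_CN, hill(1.3, p$K_N, p$n_N))  # gate-independent
  expect_lte(r$total, 3)
  expect_equal(r$total, r$R_CL + r$R_Cm + r$R_CN)
})

test_that("unstimulated astrocyte holds a constant release rate", {
  res <- integrate_model("astrocyte", NULL, stimulus_protocol(), p,
                         sim_options(t_max = 2000, dt = 0.01, out_dt = 1,
                                     method = "adaptive", max_step = 0.25))
  tot <- res$release[, "R_total"]
  late <- tot[res$time > 500]
  expect_lt(diff(range(late)), 1e-5)
})

test_that("astrocytic release varies slower than neuronal spiking", {
  # matched stimulation; compare dominant timescale via zero-crossing count of
  # the mean-removed release trace
  rn <- run_scenario("fig2_neuron_pulse", opts = sim_options(t_max = 300, dt = 0.01,
                                                             out_dt = 0.2))
  ra <- run_scenario("fig2_astrocyte", opts = sim_options(t_max = 300, dt = 0.01,
                                                          out_dt = 0.2))
  osc_count <- function(r) {
    x <- r$release[r$time >= 50, "R_total"]
    x <- x - mean(x)
    sum(diff(sign(x)) != 0)
  }
  expect_gt(osc_count(rn), 10 * max(osc_count(ra), 1))
})
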