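p <- default_parameters()

test_that("named fluxes: hand-computed values and structural zeros", {
  s <- abeta_initial_state(p, v = -70)
  cfg <- abeta_config(l = 0)
  # J_RyR vanishes at C_r = C_c
  s2 <- s; s2[["C_r"]] <- s2[["C_c"]]
  J <- abeta_fluxes(s2, cfg, p, v_m = -70)
  expect_identical(J$J_RyR, 0)
  expect_identical(J$J_r, 0)
  expect_identical(J$J_CICR, 0)
  # J_SERCA at C_c = P_SERCA -> half-max
  s3 <- s; s3[["C_c"]] <- p$P_SERCA
  expect_equal(abeta_fluxes(s3, cfg, p)$J_SERCA, p$M_SERCA * 0.5)
  # J_in at l = 0, P_c = 0.1: a1 + a2_in * 0.1
  expect_equal(J$J_in, 0.003 + 0.02 * 0.1)
  # l scales the pathways it should and only those
  J1 <- abeta_fluxes(s, abeta_config(l = 1), p, v_m = -70)
  J0 <- abeta_fluxes(s, cfg, p, v_m = -70)
  expect_gt(J1$J_in, J0$J_in)
  expect_gt(J1$J_PLC, J0$J_PLC)
  expect_equal(J1$J_SERCA, J0$J_SERCA)
  expect_equal(J1$J_pm, J0$J_pm)
  # invariant bounds
  expect_gte(J0$J_pm, 0); expect_gte(J0$J_SERCA, 0)
  expect_gte(J0$J_in, p$a1)
})

test_that("abeta_rhs matches the independent oracle and its ER identity", {
  s <- abeta_initial_state(p, v = -70)
  for (l in c(0, 0.4, 1)) {
    cfg <- abeta_config(l = l)
    d <- abeta_rhs(s, 0, cfg, p)
    expect_equal(d, oracle_abeta_rhs(s, -70, p, l = l), tolerance = 1e-12)
    # dC_c + dC_r + (J_pm - J_VGCC - J_in)/1000 = 0: ER exchange cancels
    J <- abeta_fluxes(s, cfg, p, v_m = -70)
    expect_equal(unname(d["C_c"] + d["C_r"]) +
                   1e-3 * (J$J_pm - J$J_VGCC - J$J_in), 0, tolerance = 1e-15)
  }
  set.seed(5)
  for (i in 1:15) {
    s2 <- abeta_initial_state(p, v = runif(1, -90, 20))
    s2[["C_c"]] <- runif(1, 0.01, 1.5)
    s2[["C_r"]] <- runif(1, 0.1, 20)
    s2[["P_c"]] <- runif(1, 0.01, 1)
    expect_equal(abeta_rhs(s2, 0, abeta_config(l = 0.4), p),
                 oracle_abeta_rhs(s2, -70, p, l = 0.4), tolerance = 1e-10)
  }
})

test_that("the autonomous l=0 network has a stationary point with C_c in (0,1)", {
  # short relaxation for a starting guess, then Newton on the slow subsystem
  # (C_c, C_r, P_c) with gates pinned to their steady states at v = -70
  res <- integrate_model("abeta", NULL, stimulus_protocol(), p,
                         sim_options(t_max = 1e5, method = "adaptive",
                                     out_dt = 1000, rtol = 1e-7, atol = 1e-10,
                                     max_step = 0.25),
                         cfg = abeta_config(l = 0))
  fin <- setNames(as.numeric(res$states[nrow(res$states), ]),
                  colnames(res$states))
  slow <- c("C_c", "C_r", "P_c")
  fun <- function(x) {
    s <- fin; s[slow] <- x
    abeta_rhs(s, 0, abeta_config(l = 0), p)[slow]
  }
  x <- fin[slow]
  for (it in 1:40) {
    fx <- fun(x)
    J <- matrix(0, 3, 3)
    for (j in 1:3) {
      h <- max(1e-7, 1e-6 * abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      J[, j] <- (fun(xp) - fx) / h
    }
    x <- x - solve(J, fx)
    if (max(abs(fx)) < 1e-14) break
  }
  root <- fin; root[slow] <- x
  d <- abeta_rhs(root, 0, abeta_config(l = 0), p)
  expect_lt(max(abs(d)), 1e-10)
  expect_gt(root[["C_c"]], 0)
  expect_lt(root[["C_c"]], 1)
})

test_that("astro_feedback_current: gate, continuity, printed value", {
  expect_identical(astro_feedback_current(0.1, p), 0)       # y < 0
  expect_identical(astro_feedback_current(0.19769, p), 0)   # y = 1 boundary
  expect_equal(astro_feedback_current(0.2, p), 2.11 * log(1000 * 0.2 - 196.69),
               tolerance = 1e-12)
  expect_equal(astro_feedback_current(0.2, p), 2.526, tolerance = 1e-3)
  # continuity at the threshold
  eps <- 1e-9
  expect_lt(astro_feedback_current(0.19769 + eps, p), 1e-5)
  # literal Heaviside form admits negative currents for 0 < y < 1
  expect_lt(astro_feedback_current(0.1975, p, literal = TRUE), 0)
  expect_error(astro_feedback_current(-0.1, p), ">= 0")
})

test_that("coupled_rhs composes the two oracles plus the coupling term", {
  neuron <- neuron_initial_state(p, v = -65, C_L = 0.1, C_m = 0.1,
                                 C_c = 0.1, C_r = 1.5)
  astro <- abeta_release_initial_state(p, v = -65)
  s <- c(neuron, setNames(astro[1:10], paste0("ast_", names(astro)[1:10])),
         astro[11:17])
  for (l in c(0, 0.4)) {
    d <- coupled_rhs(neuron, astro, 0, abeta_config(l = l), p)
    expect_equal(d, oracle_coupled_rhs(s, 0, p, l = l), tolerance = 1e-10)
  }
  # with astro C_c below threshold, I_astro = 0 and the neuron block reduces
  # exactly to the uncoupled neuron_rhs
  d <- coupled_rhs(neuron, astro, 0, abeta_config(l = 0.4), p)
  dn <- neuron_rhs(neuron, 0, p)
  expect_equal(d[1:13], dn, tolerance = 1e-12)
  # with astro C_c above threshold, only the membrane equation changes
  astro2 <- astro; astro2[["C_c"]] <- 0.5
  d2 <- coupled_rhs(neuron, astro2, 0, abeta_config(l = 0.4), p)
  expect_equal(unname(d2["v_m"] - d["v_m"]),
               astro_feedback_current(0.5, p) / p$c_m, tolerance = 1e-10)
  expect_equal(d2[2:13], d[2:13], tolerance = 1e-12)
})
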