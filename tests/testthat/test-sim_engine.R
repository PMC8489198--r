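p <- default_parameters()

test_that("t_max = 0 returns only the initial state", {
  s <- neuron_initial_state(p)
  res <- integrate_model("neuron", s, stimulus_protocol(), p,
                         sim_options(t_max = 0))
  expect_identical(nrow(res$states), 1L)
  expect_equal(unname(res$states[1, ]), unname(s))
})

test_that("fixed-step integration is bit-identical across repeated runs", {
  proto <- stimulus_protocol(pulses = cbind(10, 80, 15))
  opts <- sim_options(t_max = 120)
  r1 <- integrate_model("neuron", NULL, proto, p, opts)
  r2 <- integrate_model("neuron", NULL, proto, p, opts)
  expect_identical(r1$states, r2$states)
  expect_identical(r1$time, r2$time)
})

test_that("instability is reported with the failure time", {
  # the printed (literal) sign convention self-amplifies and blows up
  opts <- sim_options(t_max = 400, out_dt = 0.5, literal_signs = TRUE)
  expect_error(
    integrate_model("neuron", NULL, stimulus_protocol(), p, opts),
    "unstable")
})

test_that("scenario registry: all entries runnable metadata, unknown rejected", {
  nm <- scenario_names()
  expect_setequal(nm, c("fig2_neuron_pulse", "fig2_astrocyte",
                        "fig4_abeta_autonomous", "fig6_abeta_release",
                        "fig7_abeta_driven", "fig8_coupled",
                        "fig9_thermal_pulse", "fig11_trpm8_const_T",
                        "fig12_trpm8_ramp", "fig13_thermal_abeta",
                        "fig14_trpm8_abeta"))
  for (n in nm) {
    sc <- scenario(n)
    expect_true(sc$variant %in% c("neuron", "astrocyte", "abeta",
                                  "abeta_release", "coupled"))
    expect_s3_class(sc$proto, "stimulus_protocol")
    expect_s3_class(sc$opts, "sim_options")
  }
  expect_error(scenario("unknown"), "valid names")
  sc <- scenario("fig2_neuron_pulse", amplitude = 10)
  expect_equal(sc$proto$pulses[1, 3], 10)
  expect_error(stimulus_protocol(pulses = rbind(c(0, 100, 5), c(50, 100, 5))),
               "non-overlapping")
  expect_error(stimulus_protocol(pulses = cbind(0, -5, 5)), "> 0")
})

test_that("gate traces stay in [0,1] and concentrations nonnegative", {
  # cheap scenarios, shortened; the property is grid-wide
  cases <- list(
    list(name = "fig2_neuron_pulse", opts = sim_options(t_max = 200)),
    list(name = "fig2_astrocyte", opts = sim_options(t_max = 300, out_dt = 0.5)),
    list(name = "fig12_trpm8_ramp", opts = sim_options(t_max = 600, dt = 0.005))
  )
  gate_cols <- function(st) grep("^(md_)?(ast_)?[mh]_", colnames(st), value = TRUE)
  conc_cols <- function(st) grep("C_|^P", colnames(st), value = TRUE)
  for (cs in cases) {
    res <- run_scenario(cs$name, opts = cs$opts)
    st <- res$states
    g <- st[, gate_cols(st), drop = FALSE]
    expect_true(all(g >= -1e-9 & g <= 1 + 1e-9), label = cs$name)
    cc <- st[, setdiff(conc_cols(st), gate_cols(st)), drop = FALSE]
    expect_true(all(cc >= -1e-9), label = cs$name)
  }
})

test_that("sweep resolves scenario knobs and registry fields; empty sweep", {
  sw <- sweep_scenario("fig2_neuron_pulse", "amplitude", numeric(0))
  expect_length(sw$results, 0)
  # registry-field path: sweeping g_m8 changes the parameter set
  sw2 <- sweep_scenario("fig2_neuron_pulse", "g_m8", c(1, 2))
  expect_length(sw2$results, 2)
  expect_false(identical(sw2$results[[1]]$metadata$parameter_hash,
                         sw2$results[[2]]$metadata$parameter_hash))
  expect_error(sweep_scenario("fig2_neuron_pulse", list(1), 2), "single string")
  expect_error(sweep_scenario("fig2_neuron_pulse", "no_such_path", 1),
               "unresolvable")
})

test_that("run metadata pins parameters, flags and packing order", {
  res <- integrate_model("neuron", NULL, stimulus_protocol(), p,
                         sim_options(t_max = 1))
  md <- res$metadata
  expect_match(md$parameter_hash, "^[0-9a-f]{8}$")
  expect_identical(md$integrator$method, "rk4")
  expect_false(md$flags$literal_signs)
  expect_true(any(grepl("K_pm", md$assumptions)))
  expect_identical(colnames(res$states), state_names("neuron"))
  # hash is sensitive to any parameter change
  res2 <- integrate_model("neuron", NULL, stimulus_protocol(),
                          load_overrides(list(K_L = 51)), sim_options(t_max = 1))
  expect_false(identical(md$parameter_hash, res2$metadata$parameter_hash))
})
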