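test_that("default registry carries the printed values, units and provenance", {
  p <- default_parameters()
  expect_identical(p$K_L, 50)
  expect_identical(p$B_ud, 264)
  expect_equal(p$lambda_c / p$lambda_r, 31)
  expect_identical(p$g_Na_bar, 120)
  expect_identical(p$DeltaH, -156000)
  expect_identical(p$tau_P, 1 / 0.000140)
  u <- attr(p, "units")
  expect_identical(unname(u["K_L"]), "uM")
  expect_identical(unname(u["B_ud"]), "ms^-1")
  expect_match(attr(p, "provenance")[["K_L"]], "core constant table")
  # the two printed 'a_2' rows are distinct fields, duplicated rows stored once
  expect_identical(p$a2_in, 0.02)
  expect_identical(p$a2_ip3r, 0.5)
  expect_identical(p$M_PLC, 0.05)
  # assumed fields are flagged
  expect_true("K_pm" %in% attr(p, "assumed"))
})

test_that("overrides replace fields, reject unknown/ambiguous/non-positive", {
  p <- load_overrides(list(g_m8 = 5))
  expect_identical(p$g_m8, 5)
  expect_identical(p$K_L, 50)
  expect_error(load_overrides(list(a2 = 0.02)), "ambiguous")
  expect_error(load_overrides(list(K_L = -1)), "strictly positive")
  expect_error(load_overrides(list(not_a_param = 1)), "unknown parameter")
  expect_error(load_overrides(list(1, 2)), "named")
})

test_that("config files parse as flat key:value maps", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# overrides", "g_m8: 3", "K_L = 40", ""), f)
  p <- load_overrides(f)
  expect_identical(p$g_m8, 3)
  expect_identical(p$K_L, 40)
  f2 <- withr::local_tempfile(fileext = ".cfg")
  writeLines("what is this line", f2)
  expect_error(load_overrides(f2), "cannot parse")
  expect_error(load_overrides("/nonexistent/file.cfg"), "not found")
})

test_that("canonical_units rescales per-second rates to ms and round-trips", {
  p <- default_parameters()
  cp <- canonical_units(p)
  expect_equal(cp$r_P, 4e-5)          # 0.04 uM/s
  expect_equal(cp$M_CICR, 0.01)       # 10 s^-1
  expect_equal(cp$B_ud, 264)          # already canonical
  expect_equal(cp$k1, 1.3e-5)
  expect_identical(attr(cp, "time_base"), "ms")
  back <- original_units(cp)
  expect_identical(unlist(back), unlist(p))
  expect_identical(attr(back, "units"), attr(p, "units"))
  # canonicalizing twice is a no-op
  expect_identical(unlist(canonical_units(cp)), unlist(cp))
})

test_that("every engine symbol resolves to exactly one registry field", {
  # the compiled engine fetches parameters by name at integration time; a
  # missing or renamed field fails loudly rather than silently defaulting
  p <- default_parameters()
  v <- exosim:::.param_vector(p)
  expect_false(any(duplicated(names(v))))
  s <- neuron_initial_state(p)
  expect_silent(neuron_rhs(s, 0, p))
  # dropping any field consumed by the engine is an error
  v2 <- v[names(v) != "B_ud"]
  expect_error(
    exosim:::cpp_rhs(1L, 0, unname(s), v2,
                     exosim:::.build_drive(stimulus_protocol())),
    "B_ud")
})
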