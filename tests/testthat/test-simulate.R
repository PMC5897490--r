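test_that("activation-threshold curve has the stated plateaus and midpoint", {
  g <- default_params("WT-CHO")
  expect_equal(true_threshold(0, g), 127)
  expect_equal(true_threshold(1e9, g), 62, tolerance = 1e-3)
  # at ca = ec50 the curve sits exactly midway between the plateaus
  expect_equal(true_threshold(g$ec50, g), (127 + 62) / 2)
  # strictly decreasing
  ca <- c(0, 0.5, 1, 3, 9, 30, 100, 240)
  expect_true(all(diff(true_threshold(ca, g)) < 0))
})

test_that("far below threshold the time-dependent component vanishes", {
  g <- noiseless_params()
  rec <- simulate_sweep_set(g, permeation_spec(), fast_protocol(),
                            ca = 3, seed = 1)
  iv <- extract_amplitudes(rec)
  expect_lt(abs(iv$difference[iv$voltage == -100]), 2)
  expect_lt(abs(iv$difference[iv$voltage == 0]), 2)
})

test_that("baseline current sits at zero before the step (holding 0 mV)", {
  g <- default_params("WT-HEK")
  rec <- simulate_sweep_set(g, permeation_spec(), build_step_protocol(),
                            ca = 3, seed = 5)
  base_idx <- rec$time_ms < rec$protocol$baseline_ms
  base <- rec$sweeps[, base_idx]
  expect_lt(abs(mean(base)), 3 * g$noise_sd_pA / sqrt(length(base)) + 0.5)
})

test_that("noiseless relaxation refit recovers the generative tau to 1%", {
  g <- noiseless_params(tau_ms = 60)
  rec <- simulate_sweep_set(g, permeation_spec(), build_step_protocol(),
                            ca = 3, seed = 1)
  f <- fit_relaxation(rec, sweep = 14, segment = "activation")
  expect_true(f$ok)
  expect_equal(f$tau_ms, 60, tolerance = 0.01)
  ft <- fit_relaxation(rec, sweep = 14, segment = "tail")
  expect_equal(ft$tau_ms, 60, tolerance = 0.01)
})

test_that("default WT currents are strongly outward rectifying", {
  g <- default_params("WT-HEK")
  rec <- simulate_sweep_set(g, permeation_spec(), build_step_protocol(),
                            ca = 3, seed = 2)
  iv <- extract_amplitudes(rec, steady_window = c(280, 300))
  expect_gt(abs(iv$steady[iv$voltage == 180]),
            10 * abs(iv$steady[iv$voltage == -100]))
})

test_that("same seed reproduces populations bit-identically", {
  g <- default_params("WT-HEK")
  pop <- population_spec(g, 3, n = 3, base_seed = 11)
  a <- simulate_population(pop, fast_protocol())
  b <- simulate_population(pop, fast_protocol())
  expect_identical(lapply(a, `[[`, "sweeps"), lapply(b, `[[`, "sweeps"))
  # zero-variability population of one equals simulate_sweep_set
  g0 <- noiseless_params()
  pop1 <- population_spec(g0, 3, n = 1, base_seed = 4)
  one <- simulate_population(pop1, fast_protocol())[[1]]
  ref <- simulate_sweep_set(g0, permeation_spec(), fast_protocol(), 3,
                            seed = 5)
  expect_equal(unname(one$sweeps), unname(ref$sweeps))
})

test_that("controls are ohmic and trigger no threshold detection", {
  rc <- simulate_control(build_step_protocol(), seed = 3)
  th <- detect_threshold(extract_amplitudes(rc))
  expect_false(th$detected)
  # zero noise: exact ohmic trace during the step
  rc0 <- simulate_control(fast_protocol(), noise_sd_pA = 0, leak_nS = 1.5,
                          seed = 1)
  iv <- extract_amplitudes(rc0)
  expect_equal(iv$steady, 1.5 * iv$voltage, tolerance = 1e-6)
  # high-Ca variant: small endogenous component only at the top voltages
  rhi <- simulate_control(build_step_protocol(), seed = 8, ca = 240,
                          endogenous_conductance = 0.01)
  ivh <- extract_amplitudes(rhi)
  expect_true(all(ivh$difference[ivh$voltage <= 120] <
                    2 * ivh$noise_sd[ivh$voltage <= 120] |
                    ivh$difference[ivh$voltage <= 120] <= 0))
  expect_gt(ivh$difference[ivh$voltage == 180], 2 * ivh$noise_sd[15])
})

test_that("reversal-potential invariants hold for the permeation presets", {
  g <- noiseless_params(leak_nS = 0)
  tp <- build_tail_protocol()
  # nonselective (equal permeabilities): bath NaCl 140 -> 10 barely moves V_rev
  eq <- permeation_spec("equal_perm")
  r1 <- estimate_vrev(simulate_sweep_set(g, eq, tp, 100, seed = 1))
  r2 <- estimate_vrev(simulate_sweep_set(g, with_bath(eq, c(Na = 10, Cl = 10)),
                                         tp, 100, seed = 1))
  expect_lt(abs(r2$v_rev - r1$v_rev), 5)
  # anion-selective: the same substitution shifts V_rev by the Nernst amount
  an <- permeation_spec("anion_only")
  tpa <- build_tail_protocol(start_mV = -40, stop_mV = 80)
  a1 <- estimate_vrev(simulate_sweep_set(g, an, tpa, 100, seed = 1))
  a2 <- estimate_vrev(simulate_sweep_set(g, with_bath(an, c(Na = 10, Cl = 10)),
                                         tpa, 100, seed = 1))
  shift_pred <- nernst(-1, 136, 10) - nernst(-1, 136, 140)
  expect_equal(a2$v_rev - a1$v_rev, shift_pred, tolerance = 1)
  # symmetric single-ion spec reverses at 0 mV
  sym <- permeation_spec(data.frame(name = "Cl", valence = -1,
                                    internal_mM = 140, external_mM = 140,
                                    perm = 1))
  s <- estimate_vrev(simulate_sweep_set(g, sym, tp, 100, seed = 1))
  expect_lt(abs(s$v_rev), 0.5)
  # noiseless estimates match the analytic GHK zero-current potential
  expect_lt(abs(r1$v_rev - ghk_reversal(eq)), 0.5)
  expect_lt(abs(a1$v_rev - ghk_reversal(an)), 0.5)
})

test_that("detection-offset calibration is a fixed point within tolerance", {
  g <- default_params("T498I")
  proto <- build_step_protocol(stop_mV = 140)
  perm <- permeation_spec()
  # re-calibrating at the stored delta's anchor returns nearly the same value
  d0 <- detection_offset(g, 3)
  g2 <- g; g2$delta <- 0
  d1 <- calibrate_detection_offset(g2, perm, proto, 3, 59.6, n_mc = 120,
                                   seed = 99)
  expect_lt(abs(d1 - d0), 4)
})
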