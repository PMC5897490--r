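test_that("step protocol enumerates sweeps and validates its inputs", {
  p <- build_step_protocol()
  expect_equal(p$n_sweeps, 15L)              # -100..+180 by 20
  expect_equal(protocol_voltages(p)[1], -100)
  expect_equal(protocol_voltages(p)[15], 180)
  p2 <- build_step_protocol(stop_mV = 140)
  expect_equal(p2$n_sweeps, 13L)             # -100..+140 by 20
  expect_error(build_step_protocol(increment_mV = 0), "nonzero")
  expect_error(build_step_protocol(stop_mV = 171), "divide")
  expect_error(build_step_protocol(step_ms = -1), "positive")
})

test_that("command voltage is piecewise constant over baseline/step/tail", {
  p <- build_step_protocol()
  expect_equal(voltage_at(p, 0, 10), 0)       # baseline at holding
  expect_equal(voltage_at(p, 0, 200), -100)   # first step voltage
  expect_equal(voltage_at(p, 14, 200), 180)
  expect_equal(voltage_at(p, 0, 400), -80)    # tail pulse
  expect_error(voltage_at(p, 15, 10), "out of range")
  expect_error(voltage_at(p, 0, 1e4), "span")
  tp <- build_tail_protocol()
  expect_equal(voltage_at(tp, 0, 100), 140)   # prepulse
  expect_equal(voltage_at(tp, 0, 300), -50)   # tail step
})

test_that("recording container round trips bit-exactly", {
  g <- noiseless_params()
  g$noise_sd_pA <- 10
  rec <- simulate_sweep_set(g, permeation_spec(), fast_protocol(),
                            ca = 3, seed = 7)
  d <- withr::local_tempdir()
  write_recording(rec, file.path(d, "cell1"))
  back <- read_recording(file.path(d, "cell1"))
  expect_identical(back$sweeps, unname(rec$sweeps))
  expect_identical(back$time_ms, rec$time_ms)
  expect_equal(back$protocol, rec$protocol)
  expect_equal(back$meta$ca_uM, 3)
  expect_equal(back$meta$seed, 7)
})

test_that("malformed containers produce format errors naming the defect", {
  g <- noiseless_params()
  rec <- simulate_sweep_set(g, permeation_spec(), fast_protocol(),
                            ca = 3, seed = 1)
  d <- withr::local_tempdir()
  p <- file.path(d, "cell")
  write_recording(rec, p)
  # drop a sweep column
  tab <- read.csv(file.path(p, "sweeps.csv"), check.names = FALSE)
  write.csv(tab[, -2], file.path(p, "sweeps.csv"), row.names = FALSE)
  expect_error(read_recording(p), "sweep columns")
  unlink(file.path(p, "meta.json"))
  expect_error(read_recording(p), "meta.json")
})

test_that("recording construction enforces protocol/matrix consistency", {
  p <- fast_protocol()
  m <- matrix(0, p$n_sweeps - 1, length(time_base(p)))
  expect_error(recording(m, p), "sweep count")
  m2 <- matrix(0, p$n_sweeps, 10)
  expect_error(recording(m2, p), "sample count")
})

test_that("fluorescence container round trips and validates", {
  tr <- simulate_fluorescence(scrambling_params(), TRUE, seed = 3)
  d <- withr::local_tempdir()
  write_fluor(tr, file.path(d, "f1"))
  back <- read_fluor(file.path(d, "f1"))
  expect_identical(back$time_min, tr$time_min)
  expect_identical(back$f_raw, tr$f_raw)
  expect_error(fluor_trace(c(1, 1, 2), c(0, 0, 0)), "increasing")
})
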