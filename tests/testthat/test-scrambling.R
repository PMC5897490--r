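test_that("fluorescence traces are reproducible and controls stay flat", {
  p <- scrambling_params()
  a <- simulate_fluorescence(p, TRUE, seed = 5)
  b <- simulate_fluorescence(p, TRUE, seed = 5)
  expect_identical(a$f_raw, b$f_raw)
  # control cells never cross the detection criterion in 25 min
  cohort <- simulate_scrambling_cohort(p, n_transfected = 10, n_control = 4,
                                       base_seed = 2)
  ctrl <- cohort$onsets[!cohort$onsets$transfected, ]
  expect_true(all(is.na(ctrl$latency_detected)))
})

test_that("normalization fixes the transfected-cohort mean maximum at 1", {
  p <- scrambling_params()
  traces <- lapply(1:8, function(i)
    simulate_fluorescence(p, transfected = i <= 6, seed = 100 + i,
                          cell_id = i))
  normed <- delta_f_norm(traces)
  transf <- vapply(normed, function(x) isTRUE(x$meta$transfected), logical(1))
  maxima <- vapply(normed[transf], function(x) max(x$f_norm), numeric(1))
  expect_equal(mean(maxima), 1, tolerance = 1e-9)
  # F_norm starts at 0 by construction
  expect_true(all(vapply(normed, function(x) x$f_norm[1] == 0, logical(1))))
  # constant raw trace normalizes to identically zero
  const <- fluor_trace(0:25, rep(40, 26), meta = list(transfected = FALSE))
  one <- simulate_fluorescence(p, TRUE, seed = 1)
  nn <- delta_f_norm(list(one, const))
  expect_true(all(abs(nn[[2]]$f_norm) < 1e-12))
  # single transfected cell: its own maximum is exactly 1
  solo <- delta_f_norm(list(one))
  expect_equal(max(solo[[1]]$f_norm), 1, tolerance = 1e-12)
  expect_error(delta_f_norm(list(const)), "no transfected")
})

test_that("onset detection matches constructed latencies", {
  # noiseless step at t = 7 min detected at 7 min
  f <- c(rep(0, 7), rep(1, 19))
  tr <- fluor_trace(0:25, f, meta = list(transfected = TRUE))
  tr$f_norm <- f
  expect_equal(detect_onset(tr), 7)
  # flat noisy control: none
  set.seed(1)
  tr2 <- fluor_trace(0:25, rnorm(26, 0, 0.01))
  tr2$f_norm <- tr2$f_raw
  expect_true(is.na(detect_onset(tr2)))
  # noiseless generative trace with known latency, fine sampling: bias
  # below one sampling interval for any latency
  for (L in c(3.2, 5.0, 11.7)) {
    p <- scrambling_params(latency_mean = L, latency_sd = 0, noise_sd = 0,
                           drift = 0, latency_bounds = c(L, L),
                           interval_min = 0.1)
    tr3 <- simulate_fluorescence(p, TRUE, seed = 2)
    tr3 <- delta_f_norm(list(tr3))[[1]]
    expect_lt(abs(detect_onset(tr3, baseline_n = 5) - L), 0.1 + 1e-9)
  }
  expect_error(detect_onset(tr, baseline_n = 3), ">= 5")
})

test_that("default transfected cohort recovers the latency distribution", {
  res <- run_experiment(experiment_config("scrambling", base_seed = 42))
  det <- res$cells$latency_detected[res$cells$transfected]
  expect_gte(sum(is.finite(det)), 8)   # nearly all cells detected
  # detected onsets track the latent ones to within ~1 sampling interval
  lat <- res$cells$latency_true[res$cells$transfected]
  d <- det - lat
  expect_true(all(d[is.finite(d)] > -1))   # never early by over one interval
  expect_lt(mean(d[is.finite(d)]), 1.6)
  expect_equal(res$summary$n_controls_detected, 0)
})
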