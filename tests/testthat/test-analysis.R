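test_that("amplitude extraction matches the closed-form relaxation increment", {
  g <- noiseless_params(tau_ms = 60)
  proto <- build_step_protocol()
  rec <- simulate_sweep_set(g, permeation_spec(), proto, ca = 3, seed = 1)
  iv <- extract_amplitudes(rec)
  # closed form: I(t) = leak V + G phi p(t), p(t) = pinf + (p0-pinf) e^{-t/tau}
  ctr <- true_threshold(3, g) + g$delta
  p_inf <- function(v) 1 / (1 + exp(-(v - ctr) / g$slope))
  for (k in c(13, 15)) {
    v <- protocol_voltages(proto)[k]
    p0 <- p_inf(0)
    A <- g$conductance * ghk_current(permeation_spec(), v) * (p_inf(v) - p0)
    win_mean <- function(a, b) {
      tt <- rec$time_ms[rec$time_ms >= proto$baseline_ms + a &
                          rec$time_ms <= proto$baseline_ms + b] -
        proto$baseline_ms
      mean(1 - exp(-tt / g$tau_ms))
    }
    expected <- A * (win_mean(275, 300) - win_mean(5, 10))
    expect_equal(iv$difference[k], expected, tolerance = 0.01)
  }
  # ohmic sweep: difference ~ 0
  expect_lt(abs(iv$difference[1]), 1)
  expect_error(extract_amplitudes(rec, steady_window = c(290, 400)),
               "window")
})

test_that("threshold detection applies the 2x noise criterion in order", {
  iv <- data.frame(voltage = seq(-100, 180, 20),
                   instantaneous = 0, steady = 0,
                   difference = c(rep(0, 10), 25, 30, 40, 60, 90),
                   noise_sd = 10)
  class(iv) <- c("iv_curve", "data.frame")
  th <- detect_threshold(iv)
  expect_equal(th$v_threshold, 100)   # first difference > 2*10
  expect_false(th$left_censored)
  # monotone: adding a positive constant never raises the threshold
  iv2 <- iv; iv2$difference <- iv2$difference + 15
  expect_lte(detect_threshold(iv2)$v_threshold, th$v_threshold)
  # negative (inward) differences never trigger
  iv3 <- iv; iv3$difference <- -abs(iv3$difference) * 10
  expect_false(detect_threshold(iv3)$detected)
  # left-censoring flagged when the first sweep qualifies
  iv4 <- iv; iv4$difference <- 100
  expect_true(detect_threshold(iv4)$left_censored)
  expect_error(detect_threshold(iv[0, ]), "empty")
})

test_that("relaxation fit flags unidentifiable traces and ignores offsets", {
  rc <- simulate_control(build_step_protocol(), noise_sd_pA = 5, seed = 2)
  f <- fit_relaxation(rc, sweep = 14)
  expect_false(f$ok)
  g <- noiseless_params()
  rec <- simulate_sweep_set(g, permeation_spec(), build_step_protocol(),
                            ca = 3, seed = 1)
  rec2 <- rec
  rec2$sweeps <- rec2$sweeps + 500  # constant offset
  f1 <- fit_relaxation(rec, 14); f2 <- fit_relaxation(rec2, 14)
  expect_equal(f1$tau_ms, f2$tau_ms, tolerance = 1e-6)
})

test_that("V_rev estimation errors when no sign change exists", {
  g <- noiseless_params(leak_nS = 0)
  tp <- build_tail_protocol(start_mV = 10, stop_mV = 60, increment_mV = 10)
  rec <- simulate_sweep_set(g, permeation_spec(), tp, 100, seed = 1)
  expect_error(estimate_vrev(rec), "sign change|out of range")
})

test_that("Hill fit recovers exact parameters from noiseless points", {
  ca <- c(0, 1, 3, 9, 100, 240)
  y <- 62 + (127 - 62) / (1 + (ca / 2.9)^1.5)
  f <- fit_hill(ca, y)
  expect_true(f$converged)
  expect_equal(f$ec50, 2.9, tolerance = 1e-6)
  expect_equal(f$h, 1.5, tolerance = 1e-6)
  expect_equal(f$max, 127, tolerance = 1e-6)   # zero-Ca plateau, exact at ca=0
  expect_equal(f$base, 62, tolerance = 1e-6)
})

test_that("Hill fit matches a coarse global grid-search oracle", {
  set.seed(7)
  ca <- c(0, 1, 3, 9, 30, 100, 240)
  y <- 60 + 70 / (1 + (ca / 4)^1.2) + rnorm(length(ca), 0, 1.5)
  f <- fit_hill(ca, y)
  grid <- expand.grid(ec50 = exp(seq(log(0.5), log(30), length.out = 60)),
                      h = seq(0.4, 3, by = 0.05))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    pred_term <- ifelse(ca == 0, 0, (ca / grid$ec50[i])^grid$h[i])
    X <- cbind(1, 1 / (1 + pred_term))   # linear in (base, max-base)
    r <- stats::lm.fit(X, y)$residuals
    sum(r^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_equal(f$ec50, best$ec50, tolerance = 0.1)
  expect_equal(f$h, best$h, tolerance = 0.08)
})

test_that("Hill fit validates its inputs", {
  expect_error(fit_hill(c(0, 1, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_hill(c(0, 1, 3, 9), rep(5, 4)), "identical")
  expect_error(fit_hill(c(-1, 1, 3, 9), c(1, 2, 3, 4)), ">= 0")
})
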