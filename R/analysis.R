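#' Extract instantaneous and steady current amplitudes per sweep
#'
#' The instantaneous amplitude is the mean current in a window shortly after
#' step onset (default 5--10 ms, before appreciable relaxation); the steady
#' amplitude is the mean near the end of the step (default 275--300 ms).
#' Their difference isolates the time-dependent current component. The
#' end-of-pulse noise SD is the SD of linearly detrended samples in the
#' steady window, computed per sweep.
#'
#' @param rec A [recording()] made with a step protocol.
#' @param inst_window Instantaneous window, ms after step onset.
#' @param steady_window Steady window, ms after step onset.
#' @return Data.frame of class `iv_curve`: one row per sweep with columns
#'   `voltage`, `instantaneous`, `steady`, `difference`, `noise_sd` (all pA
#'   except voltage in mV).
#' @export
#' @examples
#' g <- gating_params(conductance = 0.1, delta = 85)
#' rec <- simulate_sweep_set(g, permeation_spec(), build_step_protocol(),
#'                           ca = 3, seed = 1)
#' extract_amplitudes(rec)
extract_amplitudes <- function(rec, inst_window = c(5, 10),
                               steady_window = c(275, 300)) {
  stopifnot(inherits(rec, "recording"))
  proto <- rec$protocol
  if (proto$kind != "step")
    stop("extract_amplitudes requires a step protocol")
  if (inst_window[1] < 0 || steady_window[2] > proto$step_ms)
    stop("analysis window outside the test step")
  onset <- proto$baseline_ms
  tb <- rec$time_ms
  idx_inst <- which(tb >= onset + inst_window[1] & tb <= onset + inst_window[2])
  idx_st <- which(tb >= onset + steady_window[1] &
                    tb <= onset + steady_window[2])
  if (length(idx_inst) < 2 || length(idx_st) < 4)
    stop("analysis window contains too few samples")
  v <- protocol_voltages(proto)
  t_st <- tb[idx_st]
  out <- data.frame(voltage = v, instantaneous = NA_real_, steady = NA_real_,
                    difference = NA_real_, noise_sd = NA_real_)
  for (i in seq_len(nrow(rec$sweeps))) {
    y <- rec$sweeps[i, ]
    inst <- mean(y[idx_inst])
    st <- mean(y[idx_st])
    res <- stats::lm.fit(cbind(1, t_st), y[idx_st])$residuals
    out$instantaneous[i] <- inst
    out$steady[i] <- st
    out$difference[i] <- st - inst
    out$noise_sd[i] <- stats::sd(res)
  }
  class(out) <- c("iv_curve", "data.frame")
  out
}

#' Detect the activation threshold potential
#'
#' V_threshold is the first step potential (ascending voltage order) at
#' which the time-dependent (steady minus instantaneous) current exceeds
#' the end-of-pulse noise SD by more than `multiplier` times; only positive
#' (outward) differences qualify. Returns an explicit "none detected"
#' (`NA`) when no sweep qualifies; if the first qualifying sweep is the
#' lowest voltage tested the result is flagged left-censored.
#'
#' @param iv An `iv_curve` from [extract_amplitudes()].
#' @param multiplier Noise criterion multiplier (default 2).
#' @return List of class `threshold_result`: `v_threshold` (mV or NA),
#'   `detected`, `left_censored`, `pass` (per-sweep logical),
#'   `multiplier`.
#' @export
detect_threshold <- function(iv, multiplier = 2) {
  if (!nrow(iv)) stop("empty IV curve")
  if (is.unsorted(iv$voltage, strictly = TRUE))
    stop("sweeps must be in ascending voltage order")
  pass <- iv$difference > multiplier * iv$noise_sd & iv$difference > 0
  first <- which(pass)[1]
  res <- list(v_threshold = if (is.na(first)) NA_real_ else iv$voltage[first],
              detected = !is.na(first),
              left_censored = isTRUE(first == 1L),
              pass = pass, multiplier = multiplier)
  class(res) <- "threshold_result"
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$detected)
    cat("V_threshold = ", x$v_threshold, " mV",
        if (x$left_censored) " (left-censored)", "\n", sep = "")
  else cat("V_threshold: none detected\n")
  invisible(x)
}

# Single-exponential least squares on (t, y): activation
# a*(1-exp(-t/tau)) + c, or decay a*exp(-t/tau) + c. Returns list with
# a, tau, c, rmse, ok. Self-starting from log-linearized residual decay.
.fit_exp <- function(t, y, mode = c("activation", "decay")) {
  mode <- match.arg(mode)
  t0 <- t - t[1]
  a0 <- y[length(y)] - y[1]
  span <- diff(range(t0))
  tau0 <- span / 3
  df <- data.frame(t = t0, y = y)
  form <- if (mode == "activation") y ~ a * (1 - exp(-t / tau)) + c
          else y ~ a * exp(-t / tau) + c
  start <- if (mode == "activation") list(a = a0, tau = tau0, c = y[1])
           else list(a = -a0, tau = tau0, c = y[length(y)])
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      lower = c(-Inf, span * 1e-4, -Inf),
                      upper = c(Inf, span * 1e3, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(a = NA_real_, tau = NA_real_, c = NA_real_, rmse = NA_real_,
                ok = FALSE, reason = "no convergence"))
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  at_bound <- cf[["tau"]] <= span * 2e-4 || cf[["tau"]] >= span * 0.99e3
  list(a = unname(cf[["a"]]), tau = unname(cf[["tau"]]),
       c = unname(cf[["c"]]), rmse = rmse, ok = !at_bound,
       reason = if (at_bound) "tau at bound" else "ok")
}

#' Fit a single-exponential relaxation to one sweep segment
#'
#' Least-squares fit of a*(1 - exp(-t/tau)) + c (activation segment) or
#' a*exp(-t/tau) + c (tail segment) after blanking the first `blank_ms` of
#' the segment (capacitative transient). Poor identifiability (relaxation
#' amplitude within the noise, tau at the search bound, or no convergence)
#' is reported via the `ok` flag, not an exception.
#'
#' @param rec A [recording()].
#' @param sweep 0-based sweep index.
#' @param segment `"activation"` (the test step / prepulse) or `"tail"`.
#' @param blank_ms Initial blanking, ms.
#' @return List of class `relaxation_fit`: `voltage`, `tau_ms`,
#'   `amplitude_pA`, `offset_pA`, `rmse_pA`, `ok`, `reason`.
#' @export
#' @examples
#' g <- gating_params(conductance = 0.1, delta = 85, noise_sd_pA = 0)
#' rec <- simulate_sweep_set(g, permeation_spec(), build_step_protocol(),
#'                           ca = 3, seed = 1)
#' fit_relaxation(rec, sweep = 14)$tau_ms   # recovers tau = 60 ms
fit_relaxation <- function(rec, sweep, segment = c("activation", "tail"),
                           blank_ms = 5) {
  segment <- match.arg(segment)
  stopifnot(inherits(rec, "recording"))
  proto <- rec$protocol
  if (sweep < 0 || sweep >= proto$n_sweeps) stop("sweep index out of range")
  seg <- .protocol_segments(proto)
  rng <- if (segment == "activation") c(seg[[1]], seg[[2]]) else
    c(seg[[2]], seg[[3]])
  idx <- which(rec$time_ms >= rng[1] + blank_ms & rec$time_ms <= rng[2])
  if (length(idx) < 20)
    stop("segment has fewer than 20 samples after blanking")
  t <- rec$time_ms[idx]
  y <- rec$sweeps[sweep + 1L, idx]
  mode <- if (segment == "activation") "activation" else "decay"
  f <- .fit_exp(t, y, mode)
  v <- if (segment == "activation" && proto$kind == "step")
    protocol_voltages(proto)[sweep + 1L]
  else if (segment == "activation") proto$prepulse_mV
  else if (proto$kind == "step") proto$tail_mV
  else protocol_voltages(proto)[sweep + 1L]
  # amplitude within noise -> tau unidentifiable
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (f$ok && is.finite(f$a) && abs(f$a) < 3 * noise / sqrt(length(y)) * 10) {
    f$ok <- FALSE
    f$reason <- "relaxation amplitude within noise"
  }
  structure(list(voltage = v, tau_ms = f$tau, amplitude_pA = f$a,
                 offset_pA = f$c, rmse_pA = f$rmse, ok = f$ok,
                 reason = f$reason),
            class = "relaxation_fit")
}

#' Estimate the reversal potential from tail currents
#'
#' For each tail step, the tail current is fitted to a single exponential
#' (after blanking the capacitative transient) and extrapolated back to the
#' tail onset, giving the instantaneous tail amplitude while the
#' conductance is still that of the activating prepulse. The reversal
#' potential is the zero crossing of amplitude versus voltage: a coarse
#' crossing is located from the sign change, then refined by a linear fit
#' restricted to a +-`window_mV` interval around it (two-pass).
#'
#' @param tail_rec A [recording()] made with a tail protocol
#'   ([build_tail_protocol()]).
#' @param blank_ms Blanking after the tail-step onset, ms.
#' @param window_mV Half-width of the linear-fit window, mV.
#' @return List of class `vrev_result`: `v_rev` (mV), `amplitudes`
#'   (data.frame voltage/amplitude), `slope` (pA/mV), `window` (mV range
#'   used).
#' @export
estimate_vrev <- function(tail_rec, blank_ms = 5, window_mV = 40) {
  stopifnot(inherits(tail_rec, "recording"))
  proto <- tail_rec$protocol
  if (proto$kind != "tail")
    stop("estimate_vrev requires a tail-protocol recording")
  v <- protocol_voltages(proto)
  if (length(v) < 5) stop("need >= 5 tail voltages")
  seg <- .protocol_segments(proto)
  amp <- vapply(seq_along(v), function(i) {
    idx <- which(tail_rec$time_ms >= seg[[2]] + blank_ms &
                   tail_rec$time_ms <= seg[[3]])
    t <- tail_rec$time_ms[idx]
    y <- tail_rec$sweeps[i, idx]
    f <- .fit_exp(t, y, "decay")
    if (!is.finite(f$a) || !is.finite(f$c)) return(NA_real_)
    # fit is y = a exp(-(t - t[1])/tau) + c; extrapolate back across the
    # blanked gap to the tail onset at seg[[2]]
    f$a * exp((t[1] - seg[[2]]) / f$tau) + f$c
  }, numeric(1))
  ok <- is.finite(amp)
  if (sum(ok) < 5) stop("tail-current fits failed on too many sweeps")
  v_ok <- v[ok]; a_ok <- amp[ok]
  s <- sign(a_ok)
  cross <- which(s[-1] * s[-length(s)] <= 0 & s[-1] != 0)[1]
  if (is.na(cross))
    stop("V_rev out of range: no sign change in extrapolated tail amplitudes")
  # coarse crossing by linear interpolation
  v0 <- v_ok[cross] - a_ok[cross] * (v_ok[cross + 1] - v_ok[cross]) /
    (a_ok[cross + 1] - a_ok[cross])
  # refined: linear fit within +-window_mV of the crossing; the window is
  # kept symmetric about the current estimate (clipped to available data)
  # so curvature of the I-V relation does not bias the zero crossing
  v_rev <- v0
  for (pass in 1:2) {
    half <- min(window_mV, v_rev - min(v_ok), max(v_ok) - v_rev)
    sel <- abs(v_ok - v_rev) <= half + 1e-9
    if (sum(sel) < 3) {
      sel <- rank(abs(v_ok - v_rev), ties.method = "first") <= 3
    }
    fit <- stats::lm(a_ok[sel] ~ v_ok[sel])
    co <- stats::coef(fit)
    v_rev <- -co[[1]] / co[[2]]
  }
  if (v_rev < min(v_ok[sel]) - 1e-6 || v_rev > max(v_ok[sel]) + 1e-6)
    stop("V_rev out of range of the linear-fit window")
  structure(list(v_rev = unname(v_rev),
                 amplitudes = data.frame(voltage = v_ok, amplitude = a_ok),
                 slope = unname(co[[2]]),
                 window = range(v_ok[sel])),
            class = "vrev_result")
}

#' Fit the modified Hill equation to a Ca2+ dependence
#'
#' y = base + (max - base) / (1 + (ca / ec50)^h). Zero concentration is
#' handled exactly (the concentration term vanishes and y -> max). For a
#' quantity that decreases with Ca2+ (such as the activation threshold),
#' `max` is the zero-Ca2+ plateau and `base` the saturating plateau.
#' Weighted least squares via Levenberg-Marquardt with bounded h; starting
#' values are taken from the data plateaus and the log-interpolated
#' midpoint.
#'
#' @param ca Concentrations, uM (>= 0), at least 4 distinct values.
#' @param y Observable (e.g., mean V_threshold, mV; or current).
#' @param weights Optional fit weights (e.g., 1/SEM^2).
#' @param h_bounds Bounds for the Hill coefficient.
#' @return List of class `hill_fit`: `base`, `max`, `ec50`, `h`,
#'   `residuals`, `converged`.
#' @export
#' @examples
#' ca <- c(0, 1, 3, 9, 100, 240)
#' y <- 62 + 65 / (1 + (ca / 2.9)^1.5)
#' fit_hill(ca, y)[c("ec50", "h")]
fit_hill <- function(ca, y, weights = NULL, h_bounds = c(0.1, 10)) {
  if (length(ca) != length(y)) stop("ca and y differ in length")
  keep <- is.finite(ca) & is.finite(y)
  ca <- ca[keep]; y <- y[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(unique(ca)) < 4)
    stop("need at least 4 distinct concentrations")
  if (length(unique(y)) < 2) stop("all observations identical")
  if (any(ca < 0)) stop("concentrations must be >= 0")
  hill_f <- function(ca, base, ymax, ec50, h) {
    term <- ifelse(ca == 0, 0, (ca / ec50)^h)
    base + (ymax - base) / (1 + term)
  }
  ord <- order(ca)
  y_lo_ca <- mean(y[ord][seq_len(min(2, length(y)))])
  y_hi_ca <- mean(y[rev(ord)][seq_len(min(2, length(y)))])
  # log-interpolated midpoint start
  mid_y <- (y_lo_ca + y_hi_ca) / 2
  pos <- ca > 0
  ec0 <- tryCatch({
    ap <- stats::approx(y[pos][order(ca[pos])], log(ca[pos][order(ca[pos])]),
                        xout = mid_y, rule = 2, ties = mean)$y
    exp(ap)
  }, error = function(e) stats::median(ca[pos]))
  if (!is.finite(ec0) || ec0 <= 0) ec0 <- stats::median(ca[pos])
  df <- data.frame(ca = ca, y = y)
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ hill_f(ca, base, ymax, ec50, h), data = df,
                      weights = w,
                      start = list(base = y_hi_ca, ymax = y_lo_ca,
                                   ec50 = ec0, h = 1),
                      lower = c(-Inf, -Inf, 1e-4, h_bounds[1]),
                      upper = c(Inf, Inf, 1e5, h_bounds[2]),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(base = NA_real_, max = NA_real_, ec50 = NA_real_,
                          h = NA_real_, residuals = rep(NA_real_, length(y)),
                          converged = FALSE),
                     class = "hill_fit"))
  cf <- stats::coef(fit)
  structure(list(base = unname(cf[["base"]]), max = unname(cf[["ymax"]]),
                 ec50 = unname(cf[["ec50"]]), h = unname(cf[["h"]]),
                 residuals = unname(stats::resid(fit)), converged = TRUE),
            class = "hill_fit")
}
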