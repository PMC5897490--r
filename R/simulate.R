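# Deterministic (noise-free, transient-free) current signal for one sweep:
# leak + conductance * GHK flux * relaxing open probability.
# Returns the sample vector; `center` is the Boltzmann center in mV.
.sweep_signal <- function(g, perm, protocol, sweep, center, cond_scale,
                          with_transient = TRUE) {
  tb <- time_base(protocol)
  seg <- .protocol_segments(protocol)
  p_inf <- function(v) 1 / (1 + exp(-(v - center) / g$slope))
  v_of_seg <- c(protocol$holding_mV,
                if (protocol$kind == "step")
                  protocol$start_mV + protocol$increment_mV * sweep
                else protocol$prepulse_mV,
                if (protocol$kind == "step") protocol$tail_mV
                else protocol$start_mV + protocol$increment_mV * sweep)
  starts <- c(0, seg[[1]], seg[[2]])
  ends <- c(seg[[1]], seg[[2]], seg[[3]])
  out <- numeric(length(tb))
  p0 <- p_inf(v_of_seg[1])  # equilibrated at holding
  for (s in 1:3) {
    idx <- tb >= starts[s] & tb < ends[s] + 1e-9
    t_rel <- tb[idx] - starts[s]
    v <- v_of_seg[s]
    pinf <- p_inf(v)
    p <- pinf + (p0 - pinf) * exp(-t_rel / g$tau_ms)
    out[idx] <- g$leak_nS * v +
      cond_scale * ghk_current(perm, v) * p
    if (with_transient && s > 1 && g$cap_amp_pA != 0) {
      dv <- v_of_seg[s] - v_of_seg[s - 1]
      out[idx] <- out[idx] +
        g$cap_amp_pA * (dv / 100) * exp(-t_rel / g$cap_tau_ms)
    }
    # state at segment end
    p0 <- pinf + (p0 - pinf) * exp(-(ends[s] - starts[s]) / g$tau_ms)
  }
  out
}

#' Simulate an episodic whole-cell recording
#'
#' Generates one cell's sweep set under the mechanistic model: per sweep,
#' I(t) = leak * V + noise + capacitative transient +
#' conductance * GHK(V) * p(t), where p relaxes single-exponentially towards
#' a Boltzmann p_inf centered on `true_threshold(ca) + delta + midpoint
#' offset`. Deterministic given `seed`.
#'
#' @param g A [gating_params()].
#' @param perm A [permeation_spec()].
#' @param protocol A `voltage_protocol`.
#' @param ca Free Ca2+, uM.
#' @param seed RNG seed (noise reproducibility).
#' @param midpoint_offset Per-cell shift of the activation midpoint, mV.
#' @param conductance_factor Per-cell multiplicative conductance factor.
#' @param with_transient Include the capacitative transient (default TRUE).
#' @param meta Extra metadata entries for the [recording()].
#' @return A [recording()]; metadata records ca, seed, label, offsets.
#' @export
#' @examples
#' g <- gating_params(conductance = 0.1, delta = 85)
#' rec <- simulate_sweep_set(g, permeation_spec(), build_step_protocol(),
#'                           ca = 3, seed = 1)
simulate_sweep_set <- function(g, perm, protocol, ca, seed,
                               midpoint_offset = 0, conductance_factor = 1,
                               with_transient = TRUE, meta = list()) {
  center <- true_threshold(ca, g) + detection_offset(g, ca) + midpoint_offset
  cond <- g$conductance * conductance_factor
  n_samp <- length(time_base(protocol))
  sw <- matrix(0, protocol$n_sweeps, n_samp)
  for (i in seq_len(protocol$n_sweeps)) {
    sw[i, ] <- .sweep_signal(g, perm, protocol, i - 1L, center, cond,
                             with_transient)
  }
  if (g$noise_sd_pA > 0) {
    noise <- withr::with_seed(seed, matrix(
      stats::rnorm(length(sw), 0, g$noise_sd_pA), nrow(sw), ncol(sw)))
    sw <- sw + noise
  }
  recording(sw, protocol,
            c(list(label = g$label, ca_uM = ca, seed = seed,
                   transfected = cond > 0,
                   midpoint_offset = midpoint_offset,
                   conductance_factor = conductance_factor), meta))
}

#' Simulate a cohort of cells
#'
#' Cell i draws its activation-midpoint offset ~ Normal(0, midpoint_sd) and
#' conductance factor ~ log-normal (unit mean, CV `conductance_cv`) under
#' seed `base_seed + i`, then its recording noise under the same seed.
#' Bit-reproducible for a fixed base seed.
#'
#' @param pop A [population_spec()].
#' @param protocol A `voltage_protocol`.
#' @return List of [recording()] objects, length `pop$n`.
#' @export
simulate_population <- function(pop, protocol) {
  stopifnot(inherits(pop, "population_spec"))
  sdlog <- sqrt(log(1 + pop$conductance_cv^2))
  lapply(seq_len(pop$n), function(i) {
    seed_i <- pop$base_seed + i
    draws <- withr::with_seed(seed_i, list(
      off = stats::rnorm(1, 0, pop$midpoint_sd),
      fac = stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)))
    if (pop$midpoint_sd == 0) draws$off <- 0
    if (pop$conductance_cv == 0) draws$fac <- 1
    simulate_sweep_set(pop$g, pop$perm, protocol, pop$ca, seed = seed_i,
                       midpoint_offset = draws$off,
                       conductance_factor = draws$fac,
                       meta = list(cell_id = i))
  })
}

#' Simulate a non-transfected control cell
#'
#' Leak plus noise only; with `endogenous_conductance > 0` a small
#' endogenous time-dependent outward component (Boltzmann center
#' `endogenous_center_mV`) appears at strongly depolarized potentials, as
#' background currents do at high intracellular Ca2+.
#'
#' @param protocol A `voltage_protocol`.
#' @param noise_sd_pA Noise SD, pA.
#' @param leak_nS Leak conductance, nS.
#' @param seed RNG seed.
#' @param ca Free Ca2+ recorded in metadata, uM.
#' @param endogenous_conductance Conductance scale of the endogenous
#'   component (0 = pure leak).
#' @param endogenous_center_mV Boltzmann center of the endogenous component.
#' @param perm Permeation spec for the endogenous component.
#' @return A [recording()].
#' @export
simulate_control <- function(protocol, noise_sd_pA = 10, leak_nS = 1, seed = 1,
                             ca = 0, endogenous_conductance = 0,
                             endogenous_center_mV = 185,
                             perm = permeation_spec()) {
  g <- gating_params(conductance = endogenous_conductance,
                     v_half_max = endogenous_center_mV, delta_v = 0,
                     slope = 12, leak_nS = leak_nS,
                     noise_sd_pA = noise_sd_pA, delta = 0,
                     label = "control")
  rec <- simulate_sweep_set(g, perm, protocol, ca = ca, seed = seed)
  rec$meta$transfected <- FALSE
  rec
}

#' Calibrate the detection offset delta
#'
#' Finds the offset delta (mV) between the nominal activation-threshold
#' curve and the Boltzmann gating center such that the population mean of
#' detected thresholds ([detect_threshold()] over simulated cells) equals
#' `target_mean`. Monotone bisection on delta with common random numbers;
#' the Monte-Carlo budget is `n_mc` cells per evaluation.
#'
#' @param g A [gating_params()] (its `delta` entry is ignored).
#' @param perm A [permeation_spec()].
#' @param protocol A `voltage_protocol`.
#' @param ca Free Ca2+, uM.
#' @param target_mean Requested population mean detected threshold, mV.
#' @param n_mc Monte-Carlo cells per evaluation.
#' @param seed RNG seed for the common random numbers.
#' @param multiplier Noise-criterion multiplier of [detect_threshold()].
#' @param bounds Search bounds for delta, mV.
#' @param tol Tolerance on the achieved mean, mV.
#' @return delta in mV.
#' @export
calibrate_detection_offset <- function(g, perm, protocol, ca, target_mean,
                                       n_mc = 200, seed = 1, multiplier = 2,
                                       bounds = c(0, 250), tol = 0.5) {
  g0 <- g
  mean_detected <- function(delta) {
    g0$delta <- delta
    pop <- population_spec(g0, ca, n_mc, base_seed = seed, perm = perm)
    recs <- simulate_population(pop, protocol)
    th <- vapply(recs, function(r) {
      res <- detect_threshold(extract_amplitudes(r), multiplier = multiplier)
      if (is.na(res$v_threshold)) NA_real_ else res$v_threshold
    }, numeric(1))
    if (all(is.na(th))) return(Inf)  # fully censored: above any target
    mean(th, na.rm = TRUE)
  }
  lo <- bounds[1]; hi <- bounds[2]
  f_lo <- mean_detected(lo) - target_mean
  f_hi <- mean_detected(hi) - target_mean
  if (is.nan(f_lo) || is.nan(f_hi) || sign(f_lo) == sign(f_hi))
    stop("calibration failed: target mean ", target_mean,
         " mV not bracketed by delta in [", lo, ", ", hi, "]")
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    f_mid <- mean_detected(mid) - target_mean
    if (abs(f_mid) < tol || (hi - lo) < 0.05) break
    if (sign(f_mid) == sign(f_lo)) { lo <- mid; f_lo <- f_mid } else hi <- mid
  }
  mid
}
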