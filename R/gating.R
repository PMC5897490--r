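#' Gating parameters of the Ca2+-shifted voltage activation model
#'
#' The generative model: channel open probability follows a Boltzmann
#' p_inf(V) = 1 / (1 + exp(-(V - center) / slope)) whose center tracks the
#' Ca2+-dependent activation-threshold curve [true_threshold()] plus a
#' detection offset delta (see [calibrate_detection_offset()]); relaxation
#' towards p_inf is single-exponential with time constant `tau_ms`.
#'
#' @param conductance Maximal conductance scale (pA per GHK flux unit).
#' @param v_half_max Activation threshold at zero Ca2+, mV.
#' @param delta_v Maximal Ca2+-induced threshold shift, mV.
#' @param slope Boltzmann slope factor, mV (> 0).
#' @param ec50 Half-maximal Ca2+ concentration, uM (> 0).
#' @param hill Hill coefficient (> 0).
#' @param tau_ms Relaxation time constant, ms (> 0); voltage-independent.
#' @param leak_nS Ohmic leak conductance, nS.
#' @param noise_sd_pA White Gaussian current noise SD, pA.
#' @param cap_amp_pA Capacitative transient amplitude per 100 mV jump, pA.
#' @param cap_tau_ms Capacitative transient time constant, ms.
#' @param delta Detection offset, mV: either a scalar or a data.frame with
#'   columns `ca` (uM) and `delta` (mV) produced by calibration; values at
#'   other Ca2+ are interpolated in log concentration.
#' @param midpoint_sd Inter-cell SD of the activation midpoint, mV
#'   (population default).
#' @param conductance_cv Inter-cell coefficient of variation of the
#'   conductance scale, log-normal (population default).
#' @param label Optional parameter-set label.
#' @return Object of class `gating_params`.
#' @export
gating_params <- function(conductance = 0.1, v_half_max = 125.2,
                          delta_v = 72.4, slope = 22, ec50 = 2.9,
                          hill = 1.5, tau_ms = 60, leak_nS = 1,
                          noise_sd_pA = 10, cap_amp_pA = 500,
                          cap_tau_ms = 0.5, delta = 0, midpoint_sd = 0,
                          conductance_cv = 0, label = NULL) {
  if (slope <= 0) stop("slope must be > 0")
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (hill <= 0) stop("hill must be > 0")
  if (tau_ms <= 0) stop("tau_ms must be > 0")
  if (noise_sd_pA < 0) stop("noise_sd_pA must be >= 0")
  structure(list(conductance = conductance, v_half_max = v_half_max,
                 delta_v = delta_v, slope = slope, ec50 = ec50, hill = hill,
                 tau_ms = tau_ms, leak_nS = leak_nS,
                 noise_sd_pA = noise_sd_pA, cap_amp_pA = cap_amp_pA,
                 cap_tau_ms = cap_tau_ms, delta = delta,
                 midpoint_sd = midpoint_sd, conductance_cv = conductance_cv,
                 label = label),
            class = "gating_params")
}

#' Activation threshold as a function of intracellular Ca2+
#'
#' V_thr(Ca) = (v_half_max - delta_v) + delta_v / (1 + (Ca/ec50)^hill):
#' the Hill-type curve through the zero-Ca2+ plateau `v_half_max` and the
#' saturating-Ca2+ plateau `v_half_max - delta_v`, strictly decreasing in
#' Ca2+.
#'
#' @param ca Free Ca2+ concentration(s), uM (>= 0).
#' @param g A [gating_params()].
#' @return Threshold potential(s), mV.
#' @export
#' @examples
#' g <- default_params("WT-CHO")
#' true_threshold(c(0, 2.9, 240), g)
true_threshold <- function(ca, g) {
  stopifnot(all(ca >= 0))
  (g$v_half_max - g$delta_v) + g$delta_v / (1 + (ca / g$ec50)^g$hill)
}

# Detection offset at a given Ca2+: scalar pass-through, or interpolation
# of a calibrated (ca, delta) table in log10(ca + 0.3 uM), flat beyond the
# calibrated range.
detection_offset <- function(g, ca) {
  d <- g$delta
  if (is.numeric(d) && length(d) == 1) return(d)
  d <- as.data.frame(d)
  if (!all(c("ca", "delta") %in% names(d)))
    stop("delta table must have columns ca, delta")
  hit <- which(abs(d$ca - ca) < 1e-9)
  if (length(hit)) return(d$delta[hit[1]])
  x <- log10(d$ca + 0.3)
  stats::approx(x, d$delta, xout = log10(ca + 0.3), rule = 2)$y
}

#' Named default parameter sets
#'
#' Loads the versioned parameter-set file bundled with the package
#' (`inst/extdata/parameter_sets.json`, written by
#' `scripts/calibrate_defaults.R`). Sets: `WT-HEK`, `WT-CHO`,
#' `WT-CHO-3uM` (per-concentration anchored), `WT-913` (reduced
#' conductance), `T498I` (gain-of-function, active at zero Ca2+),
#' `TMEM16B-like` (anion-selective), `control` (leak only).
#'
#' @param set Parameter-set name; `NULL` lists available names.
#' @param path Optional alternative JSON file.
#' @return A [gating_params()] (or character vector of names).
#' @export
#' @examples
#' default_params()
#' default_params("WT-HEK")
default_params <- function(set = NULL, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "parameter_sets.json", package = "anophys")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  sets <- cfg$parameter_sets
  if (is.null(set)) return(names(sets))
  if (!set %in% names(sets)) stop("unknown parameter set: ", set)
  s <- sets[[set]]
  delta <- if (!is.null(s$delta_table)) as.data.frame(s$delta_table)
           else if (!is.null(s$delta)) s$delta else 0
  gating_params(conductance = s$conductance, v_half_max = s$v_half_max,
                delta_v = s$delta_v, slope = s$slope, ec50 = s$ec50,
                hill = s$hill, tau_ms = s$tau_ms, leak_nS = s$leak_nS,
                noise_sd_pA = s$noise_sd_pA, cap_amp_pA = s$cap_amp_pA,
                cap_tau_ms = s$cap_tau_ms, delta = delta,
                midpoint_sd = s$midpoint_sd,
                conductance_cv = s$conductance_cv, label = set)
}

#' Population specification for simulated cell cohorts
#'
#' Cell i (1-based) uses seed `base_seed + i`, draws an activation-midpoint
#' offset ~ Normal(0, midpoint_sd) and a conductance factor ~ log-normal
#' with coefficient of variation `conductance_cv` (unit mean).
#'
#' @param g A [gating_params()].
#' @param ca Free Ca2+, uM.
#' @param n Number of cells (>= 1).
#' @param base_seed Base RNG seed.
#' @param perm A [permeation_spec()].
#' @param midpoint_sd,conductance_cv Override the population variability
#'   stored in `g` (default: take from `g`).
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(g, ca, n, base_seed, perm = permeation_spec(),
                            midpoint_sd = NULL, conductance_cv = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (is.null(midpoint_sd)) midpoint_sd <- g$midpoint_sd
  if (is.null(conductance_cv)) conductance_cv <- g$conductance_cv
  if (midpoint_sd < 0 || conductance_cv < 0)
    stop("variability parameters must be >= 0")
  structure(list(g = g, ca = ca, n = as.integer(n),
                 base_seed = as.integer(base_seed), perm = perm,
                 midpoint_sd = midpoint_sd, conductance_cv = conductance_cv),
            class = "population_spec")
}
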