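# shared fixtures: fast protocols and noiseless parameter sets

# coarse protocol for speed where sampling density is irrelevant
fast_protocol <- function(stop_mV = 180, rate_kHz = 2)
  build_step_protocol(stop_mV = stop_mV, rate_kHz = rate_kHz)

noiseless_params <- function(...) {
  gating_params(conductance = 0.075, delta = 72, noise_sd_pA = 0,
                cap_amp_pA = 0, midpoint_sd = 0, conductance_cv = 0, ...)
}

std_solution <- function(ca_mM = NULL) {
  tot <- c(CsCl = 130, HEPES = 10, HEDTA = 10)
  if (!is.null(ca_mM)) tot[["Ca"]] <- ca_mM
  solution_spec(tot, pH = 7.2, temperature_C = 22)
}

# 1-D bisection oracle for a single-ligand Ca-only equilibrium: solves the
# scalar mass balance  free + K' * free * Ltot / (alpha + K'*free) = total
# on the apparent-constant scale, independently of the package solver.
bisect_free_ca <- function(total_M, L_tot_M, K_app) {
  f <- function(x) x + K_app * x * L_tot_M / (1 + K_app * x) - total_M
  lo <- 0; hi <- total_M
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
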