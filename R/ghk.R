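#' Ion permeation specification for GHK open-channel currents
#'
#' @param ions data.frame with columns `name`, `valence` (-1, +1 or +2),
#'   `internal_mM`, `external_mM`, `perm` (relative permeability, >= 0).
#' @param temperature_C Temperature, degC; sets RT/F.
#' @return Object of class `permeation_spec`.
#' @export
#' @examples
#' permeation_spec()           # calibrated nonselective default
#' permeation_spec("anion_only")
permeation_spec <- function(ions = NULL, temperature_C = 22) {
  if (is.character(ions) || is.null(ions)) {
    preset <- if (is.null(ions)) "wt_default" else ions
    ions <- .perm_presets(preset)
  }
  req <- c("name", "valence", "internal_mM", "external_mM", "perm")
  if (!all(req %in% names(ions)))
    stop("ions must have columns: ", paste(req, collapse = ", "))
  if (!all(ions$valence %in% c(-1, 1, 2)))
    stop("valences must be in {-1, +1, +2}")
  if (any(ions$internal_mM < 0 | ions$external_mM < 0 | ions$perm < 0))
    stop("concentrations and permeabilities must be >= 0")
  if (all(ions$perm == 0)) stop("at least one permeant ion required")
  structure(list(ions = ions, temperature_C = temperature_C,
                 RT_F = 25.43 * (temperature_C + 273.15) / 295.15),
            class = "permeation_spec")
}

# Anion:cation permeability ratio of the default nonselective spec,
# calibrated (scripts/calibrate_defaults.R) so that reducing bath NaCl from
# 140 to 10 mM (sucrose-substituted) scales the +140 mV current by 0.69.
.PCL_DEFAULT <- 0.46842

# Built-in ion tables. Internal: 130 CsCl pipette (Cl- includes ~6 mM from
# CaCl2/HCl); external: 140 NaCl, 5 K-gluconate standard bath.
.perm_presets <- function(preset) {
  base <- data.frame(
    name        = c("Cs", "Na", "K", "Cl"),
    valence     = c(1, 1, 1, -1),
    internal_mM = c(130, 0, 0, 136),
    external_mM = c(0, 140, 5, 140),
    perm        = c(1, 1, 1, .PCL_DEFAULT))
  switch(preset,
    wt_default = base,
    equal_perm = transform(base, perm = 1),
    anion_only = transform(base, perm = c(0, 0, 0, 1)),
    cation_only = transform(base, perm = c(1, 1, 1, 0)),
    low_NaCl = transform(base, external_mM = c(0, 10, 5, 10)),
    stop("unknown permeation preset: ", preset)
  )
}

#' Substitute the bath (external) solution of a permeation spec
#'
#' @param perm A [permeation_spec()].
#' @param external_mM Named vector of new external concentrations (mM) by
#'   ion name; ions not named keep their concentration.
#' @export
#' @examples
#' with_bath(permeation_spec(), c(Na = 10, Cl = 10))  # low-NaCl, sucrose
with_bath <- function(perm, external_mM) {
  ions <- perm$ions
  for (nm in names(external_mM)) {
    i <- which(ions$name == nm)
    if (!length(i)) stop("ion not in spec: ", nm)
    ions$external_mM[i] <- external_mM[[nm]]
  }
  permeation_spec(ions, perm$temperature_C)
}

#' Goldman-Hodgkin-Katz open-channel current
#'
#' Sum of constant-field flux terms over the ions of `perm`, in pA per unit
#' conductance scale (arbitrary units proportional to permeability x mM x
#' mV). Continuous at V = 0 via the series expansion of the flux equation.
#'
#' @param perm A [permeation_spec()].
#' @param V_mV Membrane potential(s), mV (vectorized).
#' @return Open-channel current (positive = outward), same length as `V_mV`.
#' @export
#' @examples
#' ghk_current(permeation_spec(), c(-100, 0, 140, 180))
ghk_current <- function(perm, V_mV) {
  stopifnot(all(is.finite(V_mV)))
  out <- numeric(length(V_mV))
  for (i in seq_len(nrow(perm$ions))) {
    z <- perm$ions$valence[i]
    P <- perm$ions$perm[i]
    if (P == 0) next
    ci <- perm$ions$internal_mM[i]
    co <- perm$ions$external_mM[i]
    u <- z * V_mV / perm$RT_F
    small <- abs(u) < 1e-5
    flux <- numeric(length(u))
    # I_ion = P z^2 (F V / RT) (ci - co e^-u) / (1 - e^-u); u -> 0 limit:
    # P z^2 RT/F * [ (ci - co) + u (ci + co) / 2 ]
    flux[!small] <- z * V_mV[!small] *
      (ci - co * exp(-u[!small])) / (1 - exp(-u[!small]))
    flux[small] <- perm$RT_F *
      ((ci - co) + u[small] * (ci + co) / 2)
    out <- out + P * z * flux
  }
  out
}

#' Zero-current (reversal) potential of a permeation spec
#'
#' Root of [ghk_current()] in voltage, found numerically.
#'
#' @param perm A [permeation_spec()].
#' @param interval Search interval, mV.
#' @return Reversal potential, mV.
#' @export
ghk_reversal <- function(perm, interval = c(-150, 150)) {
  f <- function(v) ghk_current(perm, v)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (sign(lo) == sign(hi))
    stop("no zero crossing of GHK current in interval")
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Nernst equilibrium potential
#'
#' @param valence Ion valence.
#' @param internal_mM,external_mM Concentrations, mM.
#' @param temperature_C Temperature, degC.
#' @return Equilibrium potential, mV.
#' @export
nernst <- function(valence, internal_mM, external_mM, temperature_C = 22) {
  RT_F <- 25.43 * (temperature_C + 273.15) / 295.15
  RT_F / valence * log(external_mM / internal_mM)
}
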