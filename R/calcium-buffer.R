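#' Binding-constant tables for Ca2+ chelator equilibria
#'
#' Loads a table of absolute stepwise log10 association constants for
#' metal--ligand and proton--ligand complexes of the Ca2+ chelators used in
#' pipette-solution design (EGTA, HEDTA). Constants are stored as stepwise
#' association constants, e.g. `HL` is for H+ + L <-> HL, `H2L` for
#' H+ + HL <-> H2L, `CaL` for Ca2+ + L <-> CaL, `CaHL` for Ca2+ + HL <-> CaHL.
#' Each constant carries the reference temperature (degC) and ionic strength
#' (mol/L) at which it was determined; [apparent_constant()] and
#' [solve_equilibrium()] correct them to working conditions with the Davies
#' equation.
#'
#' The bundled default table (`inst/extdata/binding_constants.csv`) contains
#' literature values of the Martell & Smith type, the same family of
#' constants used by the classic free-Ca2+ calculator programs.
#'
#' @param path CSV file with columns `ligand, species, log10_K, T_ref_C,
#'   I_ref_M`. Defaults to the bundled table.
#' @return A data.frame of class `buffer_constants`.
#' @export
#' @examples
#' bc <- buffer_constants()
#' subset(bc, ligand == "HEDTA")
buffer_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "binding_constants.csv", package = "anophys")
  }
  tab <- utils::read.csv(path, comment.char = "#", strip.white = TRUE,
                         stringsAsFactors = FALSE)
  required <- c("ligand", "species", "log10_K", "T_ref_C", "I_ref_M")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("constants table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(tab$log10_K)))
    stop("all log10_K values must be finite")
  key <- paste(tab$ligand, tab$species)
  if (anyDuplicated(key))
    stop("duplicate (ligand, species) entries: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  for (lig in unique(tab$ligand)) {
    if (!any(tab$ligand == lig & tab$species == "HL"))
      stop("ligand ", lig, " has no proton association constant (HL)")
  }
  class(tab) <- c("buffer_constants", "data.frame")
  tab
}

#' Specify a buffered solution recipe
#'
#' @param totals Named numeric vector of total concentrations in mM. Metals
#'   are named `Ca`, `Mg`; chelators by ligand name (`EGTA`, `HEDTA`); any
#'   other names (e.g. `CsCl`, `HEPES`, `NaCl`) are treated as background
#'   electrolytes that only contribute to ionic strength.
#' @param pH Solution pH (fixed; the recipes are HEPES-buffered, so pH is an
#'   input, not a solved quantity).
#' @param temperature_C Working temperature in degC (0--40).
#' @param ionic_strength Ionic strength in mol/L, or `NA` to estimate it from
#'   the recipe (see [estimate_ionic_strength()]).
#' @return An object of class `solution_spec`.
#' @export
#' @examples
#' solution_spec(c(CsCl = 130, HEPES = 10, HEDTA = 10, Ca = 3.209), pH = 7.2)
solution_spec <- function(totals, pH, temperature_C = 22, ionic_strength = NA) {
  if (is.null(names(totals)) || any(!nzchar(names(totals))))
    stop("'totals' must be a fully named vector (mM)")
  if (any(totals < 0)) stop("total concentrations must be >= 0")
  if (!(pH > 0 && pH < 14)) stop("pH must lie in (0, 14)")
  if (temperature_C < 0 || temperature_C > 40)
    stop("temperature must lie in 0-40 degC")
  structure(list(totals = totals, pH = pH, temperature_C = temperature_C,
                 ionic_strength = ionic_strength),
            class = "solution_spec")
}

# Davies activity coefficient (log10 scale) for charge z at ionic strength I.
# A is the Debye-Hueckel slope, weakly temperature dependent.
davies_log_gamma <- function(z, I, temperature_C) {
  A <- 0.509 + 9e-4 * (temperature_C - 25)
  -A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I)
}

# Charge bookkeeping per ligand: fully deprotonated charge of the chelator
# anion. EGTA4-, HEDTA3-.
.ligand_charge <- c(EGTA = -4, HEDTA = -3)

# Delta(z^2) = sum z^2(reactants) - z^2(product) for a stepwise association
# of species `sp` of ligand `lig`; used to move a constant between ionic
# strengths with the Davies equation.
.delta_z2 <- function(lig, sp) {
  zL <- .ligand_charge[[lig]]
  step <- switch(sp,
    HL   = list(zs = c(1, zL),      zp = zL + 1),
    H2L  = list(zs = c(1, zL + 1),  zp = zL + 2),
    H3L  = list(zs = c(1, zL + 2),  zp = zL + 3),
    CaL  = list(zs = c(2, zL),      zp = zL + 2),
    CaHL = list(zs = c(2, zL + 1),  zp = zL + 3),
    MgL  = list(zs = c(2, zL),      zp = zL + 2),
    MgHL = list(zs = c(2, zL + 1),  zp = zL + 3),
    stop("unknown species code: ", sp)
  )
  sum(step$zs^2) - step$zp^2
}

# Correct a stepwise log10 K from its reference ionic strength to I.
.corrected_logK <- function(row, lig, I, temperature_C, davies = TRUE) {
  if (!davies) return(row$log10_K)
  f <- function(II) sqrt(II) / (1 + sqrt(II)) - 0.3 * II
  A <- 0.509 + 9e-4 * (temperature_C - 25)
  row$log10_K - A * .delta_z2(lig, row$species) * (f(I) - f(row$I_ref_M))
}

.get_row <- function(constants, lig, sp) {
  i <- which(constants$ligand == lig & constants$species == sp)
  if (!length(i)) return(NULL)
  constants[i, , drop = FALSE]
}

# Proton-competition factor alpha_H = 1 + K1[H] + K1 K2 [H]^2 + ... and the
# effective metal-binding coefficients of a ligand at fixed pH.
# pH is read as -log10 of the proton *activity*; [H+] = 10^-pH / gamma_H.
.ligand_coefficients <- function(constants, lig, pH, temperature_C, I,
                                 davies = TRUE) {
  logK <- function(sp) {
    row <- .get_row(constants, lig, sp)
    if (is.null(row)) return(NA_real_)
    .corrected_logK(row, lig, I, temperature_C, davies)
  }
  gH <- if (davies) 10^davies_log_gamma(1, I, temperature_C) else 1
  H <- 10^(-pH) / gH
  k1 <- logK("HL"); k2 <- logK("H2L"); k3 <- logK("H3L")
  if (is.na(k1)) stop("ligand ", lig, " has no proton constants")
  beta <- c(k1,
            if (!is.na(k2)) k1 + k2 else NA,
            if (!is.na(k2) && !is.na(k3)) k1 + k2 + k3 else NA)
  beta <- beta[!is.na(beta)]
  alpha_H <- 1 + sum(10^beta * H^seq_along(beta))
  coef_metal <- function(m) {
    kml <- logK(paste0(m, "L"))
    if (is.na(kml)) return(0)
    kmhl <- logK(paste0(m, "HL"))
    10^kml + if (!is.na(kmhl)) 10^(kmhl + k1) * H else 0
  }
  list(alpha_H = alpha_H, KCa = coef_metal("Ca"), KMg = coef_metal("Mg"),
       H = H)
}

#' Apparent (conditional) Ca2+-ligand association constant
#'
#' The pH-conditional association constant K' = K_abs / alpha_H, where
#' alpha_H = 1 + sum_i beta_Hi [H+]^i is the Schwarzenbach proton-competition
#' coefficient of the ligand. With the Davies correction enabled (default)
#' the absolute constants are first moved from their reference ionic strength
#' to the working one and [H+] is derived from pH as an activity.
#'
#' @param constants A [buffer_constants()] table.
#' @param ligand Ligand name present in `constants`.
#' @param pH Working pH.
#' @param temperature_C Working temperature (degC).
#' @param ionic_strength Working ionic strength (mol/L).
#' @param metal `"Ca"` (default) or `"Mg"`.
#' @param davies Apply Davies activity corrections (default `TRUE`).
#' @return Apparent association constant in 1/M.
#' @export
#' @examples
#' bc <- buffer_constants()
#' apparent_constant(bc, "EGTA", pH = 7.2)
apparent_constant <- function(constants, ligand, pH, temperature_C = 22,
                              ionic_strength = 0.16, metal = "Ca",
                              davies = TRUE) {
  if (!(pH > 0 && pH < 14)) stop("pH must lie in (0, 14)")
  if (!ligand %in% constants$ligand)
    stop("no constants available for ligand ", ligand)
  co <- .ligand_coefficients(constants, ligand, pH, temperature_C,
                             ionic_strength, davies)
  K <- switch(metal, Ca = co$KCa, Mg = co$KMg,
              stop("metal must be 'Ca' or 'Mg'"))
  if (K == 0) stop("no ", metal, " constants for ligand ", ligand)
  K / co$alpha_H
}

#' Estimate ionic strength of a recipe
#'
#' Ionic strength I = 1/2 sum c_i z_i^2 over the species actually listed in
#' the printed recipe: 1:1 background salts count once; each chelator is
#' counted at its dominant protonation state at the given pH (HL2- for HEDTA
#' and H2L2- for EGTA near neutral pH); metals added as chloride salts
#' contribute their chloride, with the metal itself assumed chelator-bound
#' when a chelator is present (free otherwise); HEPES contributes its
#' anionic fraction (pKa 7.5). Counterions introduced by titrating the
#' chelator and buffer to the stated pH are not part of the printed recipe
#' and are not modeled. This is a design-level estimate; the Davies
#' corrections it feeds are smooth in I.
#'
#' @inheritParams solve_equilibrium
#' @return Ionic strength in mol/L.
#' @export
estimate_ionic_strength <- function(solution, constants = buffer_constants()) {
  tot <- solution$totals / 1000  # mM -> M
  ligs <- intersect(names(tot), names(.ligand_charge))
  has_chelator <- length(ligs) > 0 && sum(unlist(tot[ligs])) > 0
  I <- 0
  for (nm in names(tot)) {
    c0 <- tot[[nm]]
    if (c0 == 0) next
    if (nm %in% names(.ligand_charge)) {
      zL <- .ligand_charge[[nm]]
      logK <- function(sp) {
        row <- .get_row(constants, nm, sp)
        if (is.null(row)) NA_real_ else row$log10_K
      }
      k1 <- logK("HL"); k2 <- logK("H2L")
      H <- 10^(-solution$pH)
      w <- c(1, 10^k1 * H, if (!is.na(k2)) 10^(k1 + k2) * H^2 else 0)
      w <- w / sum(w)
      z <- c(zL, zL + 1, zL + 2)[seq_along(w)]
      I <- I + 0.5 * c0 * sum(w * z^2)
    } else if (nm %in% c("Ca", "Mg")) {
      # chloride salt: 2 Cl- per metal; metal counted only if unchelated
      I <- I + c0 + if (has_chelator) 0 else 0.5 * c0 * 4
    } else if (nm == "HEPES") {
      frac <- 1 / (1 + 10^(7.5 - solution$pH))
      I <- I + 0.5 * c0 * frac
    } else {
      I <- I + c0                      # 1:1 monovalent salt
    }
  }
  unname(I)
}

#' Solve the multi-ligand Ca2+/Mg2+ buffering equilibrium
#'
#' Computes free metal concentrations in a recipe containing EGTA and/or
#' HEDTA at fixed pH, by damped fixed-point iteration on the free-metal
#' concentrations with analytic elimination of the free-ligand
#' concentrations (each ligand's mass balance is linear in its free form
#' once the free metals are fixed). Converges to a mass-balance residual
#' below `tol` or errors.
#'
#' @param solution A [solution_spec()].
#' @param constants A [buffer_constants()] table.
#' @param davies Apply Davies activity corrections (default `TRUE`).
#' @param tol Mass-balance tolerance in mol/L.
#' @param max_iter Iteration bound.
#' @return A list of class `equilibrium_result` with elements `free` (named
#'   free metal concentrations, M), `bound` (per-ligand bound metal, M),
#'   `ligand_free` (free fully-deprotonated ligand, M), `ionic_strength`,
#'   `residual` (worst mass-balance residual, M).
#' @export
#' @examples
#' sol <- solution_spec(c(CsCl = 130, HEPES = 10, HEDTA = 10, Ca = 3.209),
#'                      pH = 7.2)
#' solve_equilibrium(sol)$free[["Ca"]]
solve_equilibrium <- function(solution, constants = buffer_constants(),
                              davies = TRUE, tol = 1e-12, max_iter = 200) {
  stopifnot(inherits(solution, "solution_spec"))
  tot <- solution$totals / 1000  # M
  ligs <- intersect(names(tot), unique(constants$ligand))
  unknown <- setdiff(intersect(names(tot), names(.ligand_charge)), ligs)
  if (length(unknown))
    stop("no constants available for ligand ", paste(unknown, collapse = ", "))
  metals <- c("Ca", "Mg")
  M_tot <- vapply(metals, function(m) if (m %in% names(tot)) tot[[m]] else 0,
                  numeric(1))
  names(M_tot) <- metals

  I <- solution$ionic_strength
  if (is.na(I)) I <- estimate_ionic_strength(solution, constants)

  co <- lapply(ligs, function(l)
    .ligand_coefficients(constants, l, solution$pH, solution$temperature_C,
                         I, davies))
  names(co) <- ligs
  L_tot <- vapply(ligs, function(l) tot[[l]], numeric(1))

  # free ligand (fully deprotonated) given free metals
  lig_free <- function(M_free) {
    vapply(ligs, function(l) {
      L_tot[[l]] / (co[[l]]$alpha_H +
                      co[[l]]$KCa * M_free[["Ca"]] +
                      co[[l]]$KMg * M_free[["Mg"]])
    }, numeric(1))
  }

  M_free <- M_tot  # start from no binding
  if (length(ligs)) {
    active <- metals[M_tot > 0]
    # residual of the metal mass balances at free concentrations x (vector
    # over active metals); ligand mass balance is eliminated analytically
    resid_fun <- function(x) {
      M <- c(Ca = 0, Mg = 0)
      M[active] <- x
      Lf <- lig_free(M)
      vapply(active, function(m) {
        K <- vapply(ligs, function(l)
          if (m == "Ca") co[[l]]$KCa else co[[l]]$KMg, numeric(1))
        M[[m]] * (1 + sum(K * Lf)) - M_tot[[m]]
      }, numeric(1))
    }
    if (length(active)) {
      x <- M_tot[active]
      # damped Newton on log-free-concentrations, numerical Jacobian
      for (it in seq_len(max_iter)) {
        r <- resid_fun(x)
        resid <- max(abs(r))
        if (resid < tol) break
        J <- matrix(0, length(active), length(active))
        for (j in seq_along(active)) {
          h <- x[j] * 1e-7
          xp <- x; xp[j] <- x[j] + h
          J[, j] <- (resid_fun(xp) - r) / h
        }
        dx <- tryCatch(solve(J, -r), error = function(e) -r / diag(J))
        # limit multiplicative change per step (log-space damping)
        fac <- pmin(pmax(1 + dx / x, 0.2), 5)
        x <- x * fac
      }
      if (resid >= tol)
        stop("equilibrium solver did not converge; residual = ",
             format(resid), " M")
      M_free <- c(Ca = 0, Mg = 0)
      M_free[active] <- x
    } else {
      M_free <- c(Ca = 0, Mg = 0)
      resid <- 0
    }
    Lf <- lig_free(M_free)
    bound <- vapply(metals, function(m) {
      sum(vapply(ligs, function(l) {
        K <- if (m == "Ca") co[[l]]$KCa else co[[l]]$KMg
        K * M_free[[m]] * Lf[[l]]
      }, numeric(1)))
    }, numeric(1))
  } else {
    Lf <- numeric(0)
    bound <- c(Ca = 0, Mg = 0)
    resid <- 0
  }

  bound_per_ligand <- if (length(ligs)) {
    vapply(ligs, function(l)
      co[[l]]$KCa * M_free[["Ca"]] * Lf[[l]] +
        co[[l]]$KMg * M_free[["Mg"]] * Lf[[l]], numeric(1))
  } else numeric(0)

  structure(list(free = M_free, bound = bound_per_ligand,
                 ligand_free = Lf, ionic_strength = I, residual = resid),
            class = "equilibrium_result")
}

#' Total Ca2+ required for a target free concentration
#'
#' Inverts [solve_equilibrium()]: finds the total Ca (mM) such that the
#' recipe yields the requested free Ca2+. Solved by monotone bisection
#' (free Ca is strictly increasing in total Ca at fixed ligand).
#'
#' @param target_free_ca Target free Ca2+ in mol/L (> 0).
#' @param solution A [solution_spec()]; its `Ca` entry, if any, is ignored.
#' @param constants A [buffer_constants()] table.
#' @param davies Apply Davies corrections (default `TRUE`).
#' @param rel_tol Relative tolerance on the achieved free Ca2+.
#' @return Total Ca in mM.
#' @export
#' @examples
#' sol <- solution_spec(c(CsCl = 130, HEPES = 10, HEDTA = 10), pH = 7.2)
#' total_for_free(3e-6, sol)  # ~3.2 mM
total_for_free <- function(target_free_ca, solution,
                           constants = buffer_constants(), davies = TRUE,
                           rel_tol = 1e-3) {
  if (!(target_free_ca > 0)) stop("target_free_ca must be > 0")
  free_at <- function(total_mM) {
    tot <- solution$totals
    tot[["Ca"]] <- total_mM
    s <- solution_spec(tot, solution$pH, solution$temperature_C,
                       solution$ionic_strength)
    solve_equilibrium(s, constants, davies)$free[["Ca"]]
  }
  # bracket: free <= total, so lower bound is the target itself
  lo <- target_free_ca * 1000
  hi <- lo
  lig_cap <- sum(vapply(intersect(names(solution$totals),
                                  unique(constants$ligand)),
                        function(l) solution$totals[[l]], numeric(1)))
  hi <- lo + lig_cap + 1
  if (free_at(hi) < target_free_ca)
    stop("target free Ca2+ unreachable with this recipe")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    f <- free_at(mid)
    if (abs(f - target_free_ca) / target_free_ca < rel_tol * 0.1) break
    if (f < target_free_ca) lo <- mid else hi <- mid
  }
  achieved <- free_at(mid)
  if (abs(achieved - target_free_ca) / target_free_ca > rel_tol)
    stop("bisection failed to reach target free Ca2+")
  mid
}
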