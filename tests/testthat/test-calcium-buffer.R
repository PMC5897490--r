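test_that("apparent constant reduces to the absolute constant without proton competition", {
  tab <- buffer_constants()
  tab2 <- tab
  tab2$log10_K[tab2$species %in% c("HL", "H2L", "H3L")] <- -30  # no competition
  k_abs <- 10^tab$log10_K[tab$ligand == "HEDTA" & tab$species == "CaL"]
  k_app <- apparent_constant(tab2, "HEDTA", pH = 7.2, davies = FALSE)
  expect_equal(k_app, k_abs, tolerance = 1e-10)
})

test_that("apparent constant increases with pH (proton competition relaxes)", {
  tab <- buffer_constants()
  k72 <- apparent_constant(tab, "EGTA", pH = 7.2)
  k74 <- apparent_constant(tab, "EGTA", pH = 7.4)
  expect_lt(k72, k74)
  # brute-force alpha_H oracle at fixed ionic strength, no corrections
  for (lig in c("EGTA", "HEDTA")) {
    rows <- tab[tab$ligand == lig, ]
    logK <- function(sp) {
      v <- rows$log10_K[rows$species == sp]
      if (length(v)) v else NA_real_
    }
    H <- 10^-7.2
    beta <- cumsum(c(logK("HL"), logK("H2L"), logK("H3L")))
    beta <- beta[!is.na(beta)]
    alpha <- 1 + sum(10^beta * H^seq_along(beta))
    # conditional constant includes the protonated ternary complex CaHL
    k_eff <- 10^logK("CaL") +
      if (!is.na(logK("CaHL"))) 10^(logK("CaHL") + logK("HL")) * H else 0
    expect_equal(apparent_constant(tab, lig, 7.2, davies = FALSE),
                 k_eff / alpha, tolerance = 1e-9)
  }
})

test_that("solver satisfies mass balance and matches the bisection oracle", {
  tab <- buffer_constants()
  set.seed(42)
  for (i in 1:10) {
    L <- runif(1, 1, 12); tot_ca <- runif(1, 0.05, 0.9) * L
    sol <- solution_spec(c(CsCl = 130, HEDTA = L, Ca = tot_ca), pH = 7.2,
                         ionic_strength = 0.15)
    r <- solve_equilibrium(sol, tab)
    expect_lt(r$residual, 1e-12)
    expect_lte(r$free[["Ca"]], tot_ca / 1000)
    # oracle on the same apparent constant
    K_app <- apparent_constant(tab, "HEDTA", 7.2, 22, 0.15)
    oracle <- bisect_free_ca(tot_ca / 1000, L / 1000, K_app)
    expect_equal(r$free[["Ca"]], oracle, tolerance = 1e-9)
  }
})

test_that("free Ca is monotone in total Ca and identity holds without ligand", {
  r <- solve_equilibrium(solution_spec(c(CsCl = 130, Ca = 1), pH = 7.2))
  expect_equal(r$free[["Ca"]], 1e-3, tolerance = 1e-12)
  frees <- vapply(c(1, 2, 4, 6), function(tc)
    solve_equilibrium(std_solution(tc))$free[["Ca"]], numeric(1))
  expect_true(all(diff(frees) > 0))
})

test_that("the standard pipette recipe reproduces its design free Ca2+", {
  # 3.209 mM total Ca in 10 mM HEDTA at pH 7.2 was designed for 3 uM free
  r <- solve_equilibrium(std_solution(3.209))
  expect_equal(r$free[["Ca"]] * 1e6, 3, tolerance = 0.10)
})

test_that("zero-Ca2+ EGTA/Mg recipe buffers contaminant Ca below 1 nM", {
  sol <- solution_spec(c(CsCl = 130, HEPES = 10, EGTA = 2, Mg = 2,
                         Ca = 0.01), pH = 7.3)
  r <- solve_equilibrium(sol)
  expect_lt(r$free[["Ca"]], 1e-9)
  # Mg stays mostly free (EGTA affinity for Mg is weak)
  expect_gt(r$free[["Mg"]], 1.5e-3)
})

test_that("total_for_free inverts solve_equilibrium (round trip)", {
  sol <- std_solution()
  for (x in c(1, 3, 9, 100, 240) * 1e-6) {
    tot <- total_for_free(x, sol)
    s <- std_solution(tot)
    expect_equal(solve_equilibrium(s)$free[["Ca"]], x, tolerance = 1e-3)
  }
  # no ligand: total equals target
  nl <- solution_spec(c(CsCl = 130), pH = 7.2)
  expect_equal(total_for_free(5e-6, nl), 5e-3, tolerance = 1e-3)
})

test_that("degenerate buffer inputs error clearly", {
  expect_error(solution_spec(c(130, 10), pH = 7.2), "named")
  expect_error(solution_spec(c(CsCl = -1), pH = 7.2), ">= 0")
  expect_error(solution_spec(c(CsCl = 130), pH = 15), "pH")
  expect_error(total_for_free(-1e-6, std_solution()), "> 0")
  sol_unknown <- solution_spec(c(EGTA = 2), pH = 7)
  tab <- buffer_constants()
  tab_no <- tab[tab$ligand != "EGTA", ]
  class(tab_no) <- class(tab)
  expect_error(solve_equilibrium(sol_unknown, tab_no), "no constants")
})
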