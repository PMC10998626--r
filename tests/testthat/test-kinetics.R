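test_that("derived rate constants reproduce the reference rate set", {
  # rho_close back-computed from the quoted k21/k43; the quoted k_off3,
  # k_off4 close the thermodynamic cycle only to ~15%, so the exactly
  # balanced derived set can differ from them by up to that much
  p <- four_state_params(k_on = 172e6, rho_off = 266, rho_close = 0.381,
                         k12 = 34, k21 = 735, Kd_macro = 223e-6)
  r <- derive_rate_constants(p)
  expect_lt(abs(r$k43 - 1.93e3) / 1.93e3, 0.10)
  expect_lt(abs(r$k_off3 - 5.5e5) / 5.5e5, 0.15)
  expect_lt(abs(r$k_off4 - 2.1e3) / 2.1e3, 0.15)
  expect_lt(abs(r$k34 - 27e3) / 27e3, 0.15)
})

test_that("rho_off = 1 gives identical off-rates; conventions agree", {
  p <- four_state_params(1e8, 1, 0.5, 30, 700, 1e-4)
  r <- derive_rate_constants(p)
  expect_identical(r$k_off3, r$k_off4)
  # under the k34 convention rho_close divides k21 by k34 instead
  p2 <- four_state_params(1e8, 50, 2, 30, 700, 1e-4, convention = "k34")
  r2 <- derive_rate_constants(p2)
  expect_equal(p2$k21 / r2$k34, 2)
  expect_equal(r2$k34 / r2$k43, (30 / 700) * 50, tolerance = 1e-12)
})

test_that("detailed-balance closure holds for 1000 random parameter draws", {
  set.seed(101)
  for (i in 1:1000) {
    r <- random_rates()
    expect_lt(abs(balance_closure(r) - 1), 1e-10)
  }
})

test_that("non-positive parameters and unbalanced rate sets are rejected", {
  expect_error(four_state_params(-1e8, 266, 0.43, 34, 735, 223e-6),
               "positive")
  expect_error(rate_constants(34, 735, 172e6, 5.5e5, 2.1e3, 27e3, 1.93e3),
               "closure")
  expect_silent(rate_constants(34, 735, 172e6, 5.5e5, 2.1e3, 27e3, 1.93e3,
                               balance_tol = Inf))
})

test_that("macroscopic Kd matches a brute-force equilibrium oracle", {
  set.seed(7)
  for (i in 1:20) {
    r <- random_rates()
    Kd <- macroscopic_kd(r)
    # independent route: stationary distribution of the full exchange
    # matrix, find the L where the bound fraction is one half
    bound_frac <- function(L) {
      p <- oracle_stationary(oracle_K(r, L))
      p[3] + p[4]
    }
    root <- uniroot(function(L) bound_frac(L) - 0.5,
                    lower = Kd / 100, upper = Kd * 100, tol = Kd * 1e-12)
    expect_equal(root$root, Kd, tolerance = 1e-8)
  }
})

test_that("macroscopic Kd reduces to k_off3/k_on without conformational steps", {
  r <- rate_constants(k12 = 1e-6, k21 = 1e3, k_on = 1e8, k_off3 = 1e4,
                      k_off4 = 1e4, k34 = 1e-6, k43 = 1e3)
  expect_equal(macroscopic_kd(r), 1e4 / 1e8, tolerance = 1e-6)
})

test_that("Kd round-trips through derive_rate_constants", {
  set.seed(11)
  for (i in 1:50) {
    p <- four_state_params(10^runif(1, 6, 9), 10^runif(1, 0, 3),
                           10^runif(1, -3, 3), 10^runif(1, 0, 3),
                           10^runif(1, 1, 4), 10^runif(1, -6, -3))
    r <- derive_rate_constants(p)
    expect_equal(macroscopic_kd(r), p$Kd_macro, tolerance = 1e-10)
  }
})

test_that("equilibrium populations: limits, normalization, null-space oracle", {
  r <- ref_rates()
  p0 <- equilibrium_populations(r, 0)
  expect_identical(p0$p3, 0); expect_identical(p0$p4, 0)
  expect_equal(p0$p2 / p0$p1, r$k12 / r$k21, tolerance = 1e-12)

  pk <- equilibrium_populations(r, macroscopic_kd(r))
  expect_equal(pk$p1 + pk$p2, 0.5, tolerance = 1e-10)
  expect_equal(pk$p3 + pk$p4, 0.5, tolerance = 1e-10)

  set.seed(21)
  for (i in 1:25) {
    rr <- random_rates()
    L <- 10^runif(1, -7, -2)
    p <- equilibrium_populations(rr, L)
    v <- c(p$p1, p$p2, p$p3, p$p4)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_equal(v, oracle_stationary(oracle_K(rr, L)), tolerance = 1e-8)
    # bound-state partition is independent of L
    expect_equal(p$p3 / p$p4, rr$k43 / rr$k34, tolerance = 1e-10)
  }
})

test_that("bound-state partition from the quoted rate set is 93% open", {
  r <- galectin_rates(balanced = FALSE)
  p <- equilibrium_populations(r, 1e-4)
  expect_equal(round(p$p4 / (p$p3 + p$p4), 2), 0.93)
})

test_that("free ligand solves the mass balance", {
  r <- ref_rates()
  expect_identical(free_ligand(r, 0.5e-3, 0), 0)
  expect_identical(free_ligand(r, 0, 1e-3), 1e-3)
  # a 29 uM ligand load on 0.49 mM protein gives ~4% saturation
  L <- free_ligand(223e-6, 0.49e-3, 29e-6)
  bound <- 0.49e-3 * L / (L + 223e-6)
  expect_equal(bound / 0.49e-3, 0.040, tolerance = 0.02)
  # self-consistency of the closed form with the mass-balance equation
  set.seed(31)
  for (i in 1:20) {
    Kd <- 10^runif(1, -6, -3); P <- 10^runif(1, -5, -2)
    Lt <- 10^runif(1, -6, -2)
    L <- free_ligand(Kd, P, Lt)
    expect_lt(abs(L + P * L / (L + Kd) - Lt), 1e-10 * Lt)
    expect_true(L >= 0 && L <= Lt)
  }
})

test_that("saturation maps invert each other", {
  r <- ref_rates()
  for (s in c(0.01, 0.3, 0.76, 0.99))
    expect_equal(saturation_of(r, free_ligand_at_saturation(r, s)), s,
                 tolerance = 1e-12)
})

test_that("pathway fluxes: IF dominance at high saturation, guards, scaling", {
  r <- ref_rates()
  L76 <- free_ligand_at_saturation(r, 0.76)
  fl <- pathway_fluxes(r, equilibrium_populations(r, L76), 0.5e-3)
  expect_equal(round(100 * fl$frac_IF), 99)

  # zero ligand: both fluxes zero, flagged
  fl0 <- pathway_fluxes(r, equilibrium_populations(r, 0), 0.5e-3)
  expect_true(fl0$zero_ligand)
  expect_identical(fl0$F_CS, 0); expect_identical(fl0$F_IF, 0)

  # blocking the apo conformational step starves the CS pathway; under
  # detailed balance k34/k43 = (k12/k21) rho_off, so rho_off is raised in
  # step to keep the bound-state opening (IF branch) intact
  rb <- derive_rate_constants(four_state_params(172e6, 266e8, 0.43,
                                                k12 = 1e-8, k21 = 735,
                                                Kd_macro = 223e-6))
  flb <- pathway_fluxes(rb, equilibrium_populations(rb, 1e-4), 0.5e-3)
  expect_lt(flb$F_CS, 1e-6 * flb$F_IF)
  expect_gt(flb$F_IF, 0)

  # frac_IF is invariant under rescaling of the protein concentration
  p <- equilibrium_populations(r, L76)
  expect_equal(pathway_fluxes(r, p, 1e-5)$frac_IF,
               pathway_fluxes(r, p, 1e-2)$frac_IF, tolerance = 1e-12)
})

test_that("frac_IF grows monotonically with ligand for the reference rates", {
  r <- ref_rates()
  L <- 10^seq(-7, -2, length.out = 60)
  frac <- vapply(L, function(l)
    pathway_fluxes(r, equilibrium_populations(r, l), 1e-4)$frac_IF,
    numeric(1))
  expect_true(all(diff(frac) >= -1e-12))
})

test_that("flux crossover: symmetric network, presence and absence", {
  # symmetric toy where both waiting-time terms match pairwise: the
  # crossover sits exactly at L = k12 / k_on
  r <- rate_constants(k12 = 50, k21 = 500, k_on = 1e6, k_off3 = 500,
                      k_off4 = 500, k34 = 50, k43 = 500)
  expect_equal(flux_crossover(r), 50 / 1e6, tolerance = 1e-6)

  # reference rates: crossover in the low-micromolar region
  cr <- flux_crossover(ref_rates())
  expect_true(!is.na(cr) && cr < 20e-6)

  # a strongly IF-dominated network has no crossover
  r_if <- derive_rate_constants(four_state_params(172e6, 266, 0.43,
                                                  k12 = 0.1, k21 = 735,
                                                  Kd_macro = 223e-6))
  expect_true(is.na(flux_crossover(r_if)))
})

test_that("diffusion-limited on-rate: value, limits, linearity", {
  kD <- diffusion_limited_kon(20e-10, 0.57e-9, 0.126e-9)
  expect_lt(abs(kD - 10e9), 1e9)  # one unit in the last printed digit
  expect_lt(diffusion_limited_kon(1e-30, 0.5e-9, 0.1e-9), 1e-8)
  expect_equal(diffusion_limited_kon(20e-10, 2 * 0.57e-9, 2 * 0.126e-9),
               2 * kD, tolerance = 1e-12)
  expect_error(diffusion_limited_kon(-1e-10, 1e-9, 1e-9), "positive")
})
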