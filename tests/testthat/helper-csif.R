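# Shared fixtures for the test suite. Everything is generated in code; the
# reference parameter set is the galectin-3C/lactose system.

ref_params <- function(rho_close = 0.43) galectin_params(rho_close)
ref_rates <- function(rho_close = 0.43)
  derive_rate_constants(ref_params(rho_close))

# fixed-input list for four-state fitting, taken from a ground truth
fixed_from_gt <- function(truth) {
  res <- truth$shifts$residue
  list(k12 = truth$params$k12, k21 = truth$params$k21,
       Kd_macro = truth$params$Kd_macro,
       delta1 = setNames(as.list(truth$shifts$delta1), res),
       delta_lac = as.list(truth$delta_lac))
}

# random microscopically reversible rate set
random_rates <- function() {
  p <- four_state_params(k_on = 10^runif(1, 6, 9),
                         rho_off = 10^runif(1, 0, 3),
                         rho_close = 10^runif(1, -3, 3),
                         k12 = 10^runif(1, 0, 3),
                         k21 = 10^runif(1, 1, 4),
                         Kd_macro = 10^runif(1, -6, -3))
  derive_rate_constants(p)
}

# independent stationary-distribution oracle: solve K p = 0, sum(p) = 1 by
# replacing one row with the normalization constraint (base solve(), no
# package code)
oracle_stationary <- function(K) {
  A <- K
  A[nrow(A), ] <- 1
  b <- c(rep(0, nrow(A) - 1), 1)
  solve(A, b)
}

# independent exchange-matrix builder for the CS/IF topology
oracle_K <- function(r, L) {
  konL <- r$k_on * L
  K <- matrix(0, 4, 4)
  K[2, 1] <- r$k12; K[1, 2] <- r$k21
  K[3, 1] <- konL;  K[1, 3] <- r$k_off3
  K[4, 2] <- konL;  K[2, 4] <- r$k_off4
  K[4, 3] <- r$k34; K[3, 4] <- r$k43
  diag(K) <- -colSums(K)
  K
}

# small, fast study design for fitting tests
small_design <- function(seed = 1, n_residues = 4,
                         saturation_levels = c(0.08, 0.27, 0.75)) {
  suppressWarnings(study_design(
    n_residues = n_residues, saturation_levels = saturation_levels,
    seed = seed))
}

# two-state curve fixture shared by fitting and pipeline tests
make_two_state_curves <- function(kex, p, dd, r20 = c(`14.1` = 10, `18.8` = 12),
                                  sigma = 0.3, seed = NULL) {
  sched <- cpmg_schedule(default_nu_cp())
  rows <- lapply(names(r20), function(f) {
    fld <- field_config(as.numeric(f))
    pars <- two_state_params(kex, p, ppm_to_omega(dd, fld), r20[[f]])
    r2 <- simulate_dispersion(two_state_matrix(pars), c(1 - p, p), sched)$r2_s
    data.frame(residue = "resA", field_T = as.numeric(f),
               sample_id = "apo", nu_cp_hz = sched$nu_cp, r2_s = r2,
               r2_err_s = sigma)
  })
  d <- do.call(rbind, rows)
  if (!is.null(seed)) {
    set.seed(seed)
    d$r2_s <- d$r2_s + rnorm(nrow(d), sd = sigma)
  }
  d
}
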