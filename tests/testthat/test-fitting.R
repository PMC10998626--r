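test_that("noiseless two-state curves are recovered to high precision", {
  d <- make_two_state_curves(769, 0.0442, 1.9)
  fit <- fit_two_state_residue(d, starts = data.frame(k_ex = 500,
                                                      p_minor = 0.03))
  expect_true(fit$converged)
  expect_lt(abs(fit$par$k_ex - 769) / 769, 1e-5)
  expect_lt(abs(fit$par$p_minor - 0.0442) / 0.0442, 1e-5)
  expect_lt(abs(fit$par$dd_ppm - 1.9) / 1.9, 1e-5)
  expect_lt(abs(fit$par$R20_14.1 - 10), 1e-4)
})

test_that("F-test retains the flat model on equal fits and on flat truth", {
  d <- make_two_state_curves(769, 0.0442, 1.9, seed = 1)
  fe <- fit_two_state_residue(d)
  ff <- fit_flat(d)
  # identical chi2: F = 0, flat retained
  fake <- fe; fake$chi2 <- ff$chi2
  out <- ftest_exchange_vs_flat(fake, ff)
  expect_identical(out$F, 0)
  expect_false(out$reject)

  # flat truth: the exchange model must not be preferred (fixed seed)
  set.seed(99)
  dflat <- data.frame(residue = "resA", field_T = 14.1, sample_id = "apo",
                      nu_cp_hz = default_nu_cp(),
                      r2_s = 10 + rnorm(17, sd = 0.3), r2_err_s = 0.3)
  fe2 <- fit_two_state_residue(dflat)
  out2 <- ftest_exchange_vs_flat(fe2, fit_flat(dflat))
  expect_false(out2$reject)
})

test_that("strong dispersion is detected essentially always", {
  # Rex ~ 5 s^-1 against sigma = 0.2 s^-1
  n_reject <- 0L
  for (i in 1:30) {
    d <- make_two_state_curves(769, 0.0442, 1.9, r20 = c(`14.1` = 10),
                               sigma = 0.2, seed = 1000 + i)
    out <- ftest_exchange_vs_flat(fit_two_state_residue(d), fit_flat(d))
    n_reject <- n_reject + out$reject
  }
  expect_gte(n_reject, 29)
})

test_that("global two-state fit nests residue fits and ignores row order", {
  kex <- 900; p <- 0.03
  sched <- cpmg_schedule(default_nu_cp())
  mk <- function(res, dd, r20) {
    fld <- field_config(14.1)
    pars <- two_state_params(kex, p, ppm_to_omega(dd, fld), r20)
    data.frame(residue = res, field_T = 14.1, sample_id = "apo",
               nu_cp_hz = sched$nu_cp,
               r2_s = simulate_dispersion(two_state_matrix(pars),
                                          c(1 - p, p), sched)$r2_s,
               r2_err_s = 0.3)
  }
  d <- rbind(mk("resA", 1.2, 9), mk("resB", 2.4, 13))
  fg <- fit_two_state_global(d)
  fa <- fit_two_state_residue(d[d$residue == "resA", ])
  fb <- fit_two_state_residue(d[d$residue == "resB", ])
  # common truth, noiseless: the shared-parameter fit loses nothing
  expect_lt(fg$chi2, fa$chi2 + fb$chi2 + 1e-6)
  expect_lt(abs(fg$par$k_ex - kex) / kex, 1e-5)

  perm <- d[rev(seq_len(nrow(d))), ]
  fg2 <- fit_two_state_global(perm)
  expect_equal(fg2$par$k_ex, fg$par$k_ex, tolerance = 1e-8)
  expect_equal(fg2$par$p_minor, fg$par$p_minor, tolerance = 1e-8)
})

test_that("grid search recovers the generating node on noiseless data", {
  des <- small_design(seed = 2, n_residues = 3)
  truth <- ground_truth(des, galectin_params())
  tds <- generate_titration_dataset(des, truth, noiseless = TRUE)
  fixed <- fixed_from_gt(truth)
  grids <- list(k_on = c(0.5e8, 1.72e8, 3e8),
                rho_off = c(100, 266, 600),
                rho_close = c(0.2, 0.43, 0.9))
  gs <- grid_search_four_state(tds, fixed, grids)
  expect_equal(as.numeric(gs$argmin[c("k_on", "rho_off", "rho_close")]),
               c(1.72e8, 266, 0.43))
  expect_true(all(gs$argmin$chi2 <= gs$grid$chi2))
  expect_error(grid_search_four_state(tds, fixed,
                                      list(k_on = numeric(0),
                                           rho_off = 1, rho_close = 1)),
               "empty grid")
})

test_that("four-state global fit recovers noiseless truth to <0.1%", {
  des <- small_design(seed = 4, n_residues = 3)
  truth <- ground_truth(des, galectin_params())
  tds <- generate_titration_dataset(des, truth, noiseless = TRUE)
  fit <- fit_four_state_global(tds, fixed_from_gt(truth),
                               start = c(k_on = 1e8, rho_off = 150,
                                         rho_close = 0.7))
  expect_lt(abs(fit$par$k_on - 172e6) / 172e6, 1e-3)
  expect_lt(abs(fit$par$rho_off - 266) / 266, 1e-3)
  expect_lt(abs(fit$par$rho_close - 0.43) / 0.43, 1e-3)
  expect_lt(fit$chi2, 1e-3)
  # per-residue shifts come back too
  i <- 1
  expect_lt(abs(fit$par$delta2_res01 - truth$shifts$delta2[i]), 1e-3)
  expect_lt(abs(fit$par$delta4_res01 - truth$shifts$delta4[i]), 1e-3)
})

test_that("Monte-Carlo errors vanish with the noise and scale with it", {
  d <- make_two_state_curves(900, 0.05, 1.5, r20 = c(`14.1` = 10),
                             sigma = 0.25, seed = 12)
  fit <- fit_two_state_residue(d)
  # near-zero resimulation noise: parameter scatter collapses
  d0 <- d; d0$r2_err_s <- 1e-7
  fit0 <- fit_two_state_residue(d0)
  mc0 <- monte_carlo_errors(fit0, n_replicates = 100, seed = 5)
  expect_lt(mc0$se$k_ex, 1e-3)

  mc1 <- monte_carlo_errors(fit, n_replicates = 150, seed = 5)
  d2 <- d; d2$r2_err_s <- 2 * d2$r2_err_s
  fit2 <- fit_two_state_residue(d2)
  mc2 <- monte_carlo_errors(fit2, n_replicates = 150, seed = 5)
  expect_gt(mc2$se$k_ex / mc1$se$k_ex, 1.4)
  expect_lt(mc2$se$k_ex / mc1$se$k_ex, 2.8)
  expect_error(monte_carlo_errors(fit, n_replicates = 10), "at least 100")
})

test_that("shift-difference comparison table and statistics", {
  r <- ref_rates()
  # delta2 = delta4 and delta1 = delta3: the apo-dispersion and full
  # bound-state differences coincide
  sh <- data.frame(residue = paste0("r", 1:4),
                   delta1 = c(110, 115, 120, 125),
                   delta2 = c(111, 117, 119, 127))
  sh$delta3 <- sh$delta1; sh$delta4 <- sh$delta2
  out <- shift_difference_table(sh, r)
  expect_equal(out$table$dd_cpmg, out$table$dd_14)
  expect_equal(out$r_14, 1, tolerance = 1e-12)
  expect_equal(out$slope_14, 1, tolerance = 1e-12)

  # random shifts: statistics match direct formulas
  set.seed(8)
  sh2 <- data.frame(residue = paste0("r", 1:8),
                    delta1 = runif(8, 105, 130))
  sh2$delta2 <- sh2$delta1 + runif(8, -3, 3)
  sh2$delta3 <- sh2$delta1 + runif(8, -1, 1)
  sh2$delta4 <- sh2$delta2 + runif(8, -0.2, 0.2)
  out2 <- shift_difference_table(sh2, r)
  x <- out2$table$dd_14; y <- out2$table$dd_cpmg
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out2$r_14, r_direct, tolerance = 1e-12)
  expect_equal(out2$slope_14, sum(x * y) / sum(x * x), tolerance = 1e-12)

  # too few residues: flagged, no statistics
  out3 <- shift_difference_table(sh[1:2, ], r)
  expect_true(is.na(out3$r_14))
  expect_match(out3$flag, "fewer than 3")
})
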