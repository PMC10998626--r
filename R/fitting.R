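#' @title Fit-result container
#' @description Common return value of the fitting routines: named parameter
#'   estimates on their natural scales, the weighted sum of squared residuals
#'   (`chi2`), residual degrees of freedom, convergence metadata, the fitted
#'   values alongside the data, and internal state used by
#'   [monte_carlo_errors()] to refit replicates.
#' @param x A `csif_fit` object.
#' @param ... Unused.
#' @name csif_fit
NULL

new_csif_fit <- function(model, par, chi2, dof, n_points, converged, message,
                         fitted, data, refit, se = NULL) {
  structure(list(model = model, par = par, se = se, chi2 = chi2, dof = dof,
                 n_points = n_points, n_free = n_points - dof,
                 converged = converged, message = message,
                 fitted = fitted, data = data, refit = refit),
            class = "csif_fit")
}

#' @rdname csif_fit
#' @export
print.csif_fit <- function(x, ...) {
  cat(sprintf("%s fit: chi2 = %.4g on %d degrees of freedom (%d points)\n",
              x$model, x$chi2, x$dof, x$n_points))
  cat(sprintf("  converged: %s (%s)\n", x$converged, x$message))
  est <- x$par
  se <- if (is.null(x$se)) rep(NA_real_, length(est)) else x$se[names(est)]
  for (nm in names(est))
    cat(sprintf("  %-12s %12.6g  +/- %s\n", nm, est[[nm]],
                ifelse(is.finite(se[[nm]]), sprintf("%.3g", se[[nm]]), "NA")))
  invisible(x)
}

# Weighted chi2 of predictions against a dispersion table.
chi2_of <- function(obs, pred, sigma) sum(((obs - pred) / sigma)^2)

# Guarded residual evaluation: any numerical failure maps to large residuals
# so the optimizer backs away instead of aborting.
guard_residuals <- function(expr, n) {
  tryCatch(expr, error = function(e) rep(1e6, n))
}

# ---------------------------------------------------------------------------
# Two-state (Carver-Richards) fits

two_state_predict <- function(kex, p, dd_ppm, r20_by_field, data,
                              method = "bm", T_relax = 0.04) {
  pred <- numeric(nrow(data))
  for (f in names(r20_by_field)) {
    idx <- data$field_T == as.numeric(f)
    fld <- field_config(as.numeric(f))
    pars <- two_state_params(kex, p, ppm_to_omega(dd_ppm, fld),
                             r20_by_field[[f]])
    pred[idx] <- if (method == "cr") {
      carver_richards_r2(pars, data$nu_cp_hz[idx])
    } else {
      bm_r2eff_cpp(two_state_matrix(pars), c(1 - p, p),
                   data$nu_cp_hz[idx], T_relax)
    }
  }
  pred
}

#' Flat (no-exchange) fit of dispersion curves
#'
#' Models each curve (residue x field) as a constant `R20`, the
#' inverse-variance weighted mean; the nested null model for
#' [ftest_exchange_vs_flat()].
#'
#' @param data Dispersion table with columns `residue`, `field_T`,
#'   `nu_cp_hz`, `r2_s`, `r2_err_s`.
#' @return A `csif_fit` with one `R20` per curve.
#' @export
fit_flat <- function(data) {
  check_dispersion_columns(data)
  key <- interaction(data$residue, data$field_T, drop = TRUE)
  w <- 1 / data$r2_err_s^2
  means <- tapply(seq_len(nrow(data)), key, function(i)
    sum(data$r2_s[i] * w[i]) / sum(w[i]))
  pred <- as.numeric(means[key])
  par <- setNames(as.numeric(means), paste0("R20_", names(means)))
  fitted <- cbind(data, r2_fit = pred)
  new_csif_fit("flat", as.list(par),
               chi2 = chi2_of(data$r2_s, pred, data$r2_err_s),
               dof = nrow(data) - length(means), n_points = nrow(data),
               converged = TRUE, message = "weighted means",
               fitted = fitted, data = data,
               refit = function(d) fit_flat(d))
}

#' Residue-wise two-state Carver-Richards fit
#'
#' Fits one residue's dispersion curves (one or more static fields) to the
#' two-state closed form with shared `k_ex`, `p_minor` and chemical-shift
#' difference `|delta delta|` (in ppm, so `delta omega` scales with the
#' field) and one `R20` per field. Weighted least squares (`1/sigma^2`) via
#' Levenberg-Marquardt from a small multi-start grid; non-convergence is
#' flagged on the result rather than raised.
#'
#' @param data Dispersion table for a single residue: columns `field_T`,
#'   `nu_cp_hz`, `r2_s`, `r2_err_s` (and optionally `residue`, which must be
#'   unique).
#' @param starts Optional data frame of start values with columns `k_ex`,
#'   `p_minor`; defaults to a coarse grid spanning slow to fast exchange.
#' @param method Forward model for the likelihood: `"bm"` (default)
#'   evaluates the numerical propagator with the same finite-train,
#'   endpoint-sampled definition as the measured `R2eff`, avoiding the small
#'   finite-length bias of the asymptotic closed form in slow exchange;
#'   `"cr"` uses the Carver-Richards expression.
#' @param T_relax Relaxation period of the experiment (s); used by the
#'   `"bm"` model.
#' @return A `csif_fit` with parameters `k_ex`, `p_minor`, `dd_ppm`, and
#'   `R20_<field>` per field.
#' @export
fit_two_state_residue <- function(data, starts = NULL,
                                  method = c("bm", "cr"), T_relax = 0.04) {
  method <- match.arg(method)
  check_dispersion_columns(data, residue_required = FALSE)
  if (!is.null(data$residue) && length(unique(data$residue)) > 1)
    stop("fit_two_state_residue expects data for a single residue")
  fields <- sort(unique(data$field_T))
  fkey <- as.character(fields)
  nf <- length(fields)
  n <- nrow(data)
  if (is.null(starts))
    starts <- expand.grid(k_ex = c(200, 800, 3000), p_minor = c(0.02, 0.1))

  r20_start <- vapply(fields, function(f) {
    d <- data[data$field_T == f, ]
    mean(d$r2_s[order(-d$nu_cp_hz)][seq_len(min(3, nrow(d)))])
  }, numeric(1))
  rex0 <- max(max(data$r2_s) - min(r20_start), 0.5)

  unpack <- function(theta) {
    # clamp the log-scale parameters so runaway LM steps stay finite
    list(kex = exp(min(max(theta[1], -5), 30)),
         p = 0.5 * stats::plogis(theta[2]),
         dd = exp(min(max(theta[3], -8), 6)),
         r20 = setNames(as.list(theta[3 + seq_len(nf)]), fkey))
  }
  resfun <- function(theta) {
    guard_residuals({
      q <- unpack(theta)
      pred <- two_state_predict(q$kex, q$p, q$dd, q$r20, data,
                                method, T_relax)
      (data$r2_s - pred) / data$r2_err_s
    }, n)
  }

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    kex0 <- starts$k_ex[i]; p0 <- starts$p_minor[i]
    # fast-limit heuristic: Rex(0) ~ p (1-p) dw^2 / kex at the lowest field
    dw0 <- sqrt(rex0 * kex0 / (p0 * (1 - p0)))
    dd0 <- max(dw0 / (1e-6 * GAMMA_15N * min(fields)), 0.05)
    th0 <- c(log(kex0), stats::qlogis(min(p0 / 0.5, 0.999)), log(dd0),
             r20_start)
    ans <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(th0, fn = resfun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))),
      error = function(e) NULL)
    if (is.null(ans)) next
    chi2 <- sum(ans$fvec^2)
    if (is.null(best) || chi2 < best$chi2) best <- list(fit = ans, chi2 = chi2)
  }
  if (is.null(best))
    return(new_csif_fit("two_state", list(), NA_real_, n - (3 + nf), n,
                        FALSE, "no start converged", NULL, data,
                        function(d) fit_two_state_residue(d, starts, method,
                                                          T_relax)))
  th <- best$fit$par
  q <- unpack(th)
  par <- c(list(k_ex = q$kex, p_minor = q$p, dd_ppm = q$dd),
           setNames(q$r20, paste0("R20_", fkey)))
  pred <- two_state_predict(q$kex, q$p, q$dd, q$r20, data, method, T_relax)
  conv <- best$fit$info %in% 1:4
  new_csif_fit("two_state", par, best$chi2, n - (3 + nf), n, conv,
               best$fit$message, cbind(data, r2_fit = pred), data,
               refit = function(d) fit_two_state_residue(
                 d, starts = data.frame(k_ex = q$kex, p_minor = q$p),
                 method = method, T_relax = T_relax))
}

#' Global two-state fit across residues
#'
#' Simultaneous Carver-Richards fit of several residues assumed to report on
#' the same exchange process: one global `k_ex` and `p_minor`, a per-residue
#' `|delta delta|` (ppm) and a per-residue, per-field `R20`.
#'
#' @param data Dispersion table with columns `residue`, `field_T`,
#'   `nu_cp_hz`, `r2_s`, `r2_err_s`; at least two residues.
#' @param start Optional named list with `k_ex` and `p_minor` start values;
#'   defaults to the median of residue-wise fits.
#' @inheritParams fit_two_state_residue
#' @return A `csif_fit` with `k_ex`, `p_minor`, `dd_ppm_<residue>`, and
#'   `R20_<residue>_<field>` parameters.
#' @export
fit_two_state_global <- function(data, start = NULL,
                                 method = c("bm", "cr"), T_relax = 0.04) {
  method <- match.arg(method)
  check_dispersion_columns(data)
  residues <- sort(unique(as.character(data$residue)))
  if (length(residues) < 2)
    stop("global two-state fit requires at least two residues")
  groups <- lapply(residues, function(r) data[data$residue == r, ])
  names(groups) <- residues

  if (is.null(start)) {
    rw <- lapply(groups, fit_two_state_residue, method = method,
                 T_relax = T_relax)
    kex0 <- stats::median(vapply(rw, function(f) f$par$k_ex, numeric(1)),
                          na.rm = TRUE)
    p0 <- stats::median(vapply(rw, function(f) f$par$p_minor, numeric(1)),
                        na.rm = TRUE)
    dd0 <- vapply(rw, function(f) f$par$dd_ppm, numeric(1))
    start <- list(k_ex = kex0, p_minor = p0, dd_ppm = dd0)
  }
  fields_by_res <- lapply(groups, function(g) sort(unique(g$field_T)))
  nf_tot <- sum(lengths(fields_by_res))
  n <- nrow(data)
  dd0 <- if (!is.null(start$dd_ppm) && length(start$dd_ppm) == length(residues))
    start$dd_ppm else rep(1, length(residues))
  r200 <- unlist(lapply(groups, function(g) {
    vapply(sort(unique(g$field_T)), function(f) {
      d <- g[g$field_T == f, ]
      mean(d$r2_s[order(-d$nu_cp_hz)][seq_len(min(3, nrow(d)))])
    }, numeric(1))
  }))

  idx_dd <- 2 + seq_along(residues)
  idx_r20 <- 2 + length(residues) + seq_len(nf_tot)
  unpack <- function(theta) {
    kex <- exp(min(max(theta[1], -5), 30))
    p <- 0.5 * stats::plogis(theta[2])
    dd <- exp(pmin(pmax(theta[idx_dd], -8), 6))
    r20 <- theta[idx_r20]
    list(kex = kex, p = p, dd = dd, r20 = r20)
  }
  predict_all <- function(q) {
    pred <- numeric(n)
    off <- 0L
    for (j in seq_along(residues)) {
      g_idx <- data$residue == residues[j]
      flds <- fields_by_res[[j]]
      r20 <- setNames(as.list(q$r20[off + seq_along(flds)]),
                      as.character(flds))
      pred[g_idx] <- two_state_predict(q$kex, q$p, q$dd[j], r20,
                                       data[g_idx, ], method, T_relax)
      off <- off + length(flds)
    }
    pred
  }
  resfun <- function(theta) {
    guard_residuals({
      q <- unpack(theta)
      (data$r2_s - predict_all(q)) / data$r2_err_s
    }, n)
  }
  th0 <- c(log(start$k_ex), stats::qlogis(min(start$p_minor / 0.5, 0.999)),
           log(pmax(dd0, 0.02)), r200)
  ans <- suppressWarnings(
    minpack.lm::nls.lm(th0, fn = resfun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)))
  q <- unpack(ans$par)
  par <- c(list(k_ex = q$kex, p_minor = q$p),
           setNames(as.list(q$dd), paste0("dd_ppm_", residues)),
           setNames(as.list(q$r20),
                    unlist(lapply(seq_along(residues), function(j)
                      paste0("R20_", residues[j], "_",
                             fields_by_res[[j]])))))
  pred <- predict_all(q)
  n_free <- 2 + length(residues) + nf_tot
  new_csif_fit("two_state_global", par, sum(ans$fvec^2), n - n_free, n,
               ans$info %in% 1:4, ans$message,
               cbind(data, r2_fit = pred), data,
               refit = function(d) fit_two_state_global(
                 d, start = list(k_ex = q$kex, p_minor = q$p, dd_ppm = q$dd),
                 method = method, T_relax = T_relax))
}

#' F-test: exchange model against the flat model
#'
#' Compares a nested pair of fits on identical data with the statistic
#' `F = (delta chi2 / delta dof) / (chi2_full / dof_full)`; the flat model is
#' rejected when the tail probability falls below `alpha` (default 0.01).
#'
#' @param fit_exchange,fit_flat `csif_fit` objects fitted to the same points;
#'   `fit_flat` must have more residual degrees of freedom.
#' @param alpha Rejection level.
#' @return A list with `F`, `p_value`, `reject` (logical: prefer the
#'   exchange model), and the two degrees of freedom.
#' @export
ftest_exchange_vs_flat <- function(fit_exchange, fit_flat, alpha = 0.01) {
  stopifnot(inherits(fit_exchange, "csif_fit"), inherits(fit_flat, "csif_fit"))
  if (fit_exchange$n_points != fit_flat$n_points)
    stop("models were not fitted to the same data")
  d1 <- fit_flat$dof - fit_exchange$dof
  if (d1 <= 0) stop("models are not nested (flat must have fewer parameters)")
  d2 <- fit_exchange$dof
  dchi <- fit_flat$chi2 - fit_exchange$chi2
  Fstat <- if (dchi <= 0) 0 else (dchi / d1) / (fit_exchange$chi2 / d2)
  p <- pf(Fstat, d1, d2, lower.tail = FALSE)
  list(F = Fstat, p_value = p, reject = p < alpha, df1 = d1, df2 = d2)
}

# ---------------------------------------------------------------------------
# Four-state global fit

# Saturated-limit bound-state partition used by the delta_lac constraint:
# at L -> Inf, p3/p4 -> k43/k34.
saturated_partition <- function(rates) {
  p3 <- rates$k43 / (rates$k34 + rates$k43)
  c(p3 = p3, p4 = 1 - p3)
}

# delta4 back-computed from the lactose-saturated HSQC shift:
# delta_lac = p3s * delta3 + p4s * delta4.
delta4_from_constraint <- function(delta3, delta_lac, rates) {
  ps <- saturated_partition(rates)
  (delta_lac - ps["p3"] * delta3) / ps["p4"]
}

# Kinetic context shared by all residues at fixed global parameters: the
# per-sample exchange matrices (pseudo-first-order in L_free) and
# equilibrium populations. L_free is recomputed from the mass balance at the
# fixed macroscopic Kd.
fs_kinetic_context <- function(rates, samples, Kd) {
  S <- nrow(samples)
  Ks <- vector("list", S)
  pops <- matrix(0, 4, S)
  L_free <- numeric(S)
  for (s in seq_len(S)) {
    L <- free_ligand(Kd, samples$P_tot_M[s], samples$L_tot_M[s])
    L_free[s] <- L
    konL <- rates$k_on * L
    Ks[[s]] <- build_exchange_matrix(rates$k12, rates$k21, konL,
                                     rates$k_off3, konL, rates$k_off4,
                                     rates$k34, rates$k43)
    p <- equilibrium_populations(rates, L)
    pops[, s] <- c(p$p1, p$p2, p$p3, p$p4)
  }
  list(K = Ks, pops = pops, L_free = L_free, S = S)
}

# Residue-level model curves for fixed kinetics: theta = (delta2, delta3,
# R20); all samples share the residue's nu grid, so the propagation is
# batched across samples.
fs_residue_predict <- function(theta, ctx, rates, d1, dlac, gammaB0, nu,
                               T_relax) {
  d2 <- theta[1]; d3 <- theta[2]; r20 <- theta[3]
  d4 <- delta4_from_constraint(d3, dlac, rates)
  omega <- c(0, d2 - d1, d3 - d1, d4 - d1) * 1e-6 * gammaB0
  Mc <- array(0i, dim = c(4, 4, ctx$S))
  dmat <- diag(rep(r20, 4)) + 1i * diag(omega)
  for (s in seq_len(ctx$S)) Mc[, , s] <- ctx$K[[s]] - dmat
  as.numeric(bm_r2eff_batch(Mc, ctx$pops, nu, T_relax))
}

# Fit one residue's shifts and R20 at fixed global kinetics. Warm starts
# come from `start`; with start = NULL a small multi-start around the fixed
# shifts is used.
fs_residue_fit <- function(ctx, rates, rd, d1, dlac, gammaB0, T_relax,
                           start = NULL, maxiter = 60,
                           extra_starts = FALSE) {
  obs <- rd$obs; sig <- rd$sig; n <- length(obs)
  resfun <- function(theta) {
    guard_residuals({
      pred <- fs_residue_predict(theta, ctx, rates, d1, dlac, gammaB0,
                                 rd$nu, T_relax)
      (obs - pred) / sig
    }, n)
  }
  sep <- dlac - d1
  defaults <- list(c(dlac, d1 + 0.3 * sep, rd$r20_0),
                   c(dlac, d1 - 0.3 * sep, rd$r20_0),
                   c(2 * d1 - dlac, d1 + 0.3 * sep, rd$r20_0))
  # a warm start accelerates scans; with extra_starts the defaults are tried
  # as well, because residue parameters carried over from a distant grid
  # node can sit in the wrong branch of the shift degeneracy and inflate
  # chi2 there
  starts <- if (is.null(start)) defaults
            else if (extra_starts) c(list(start), defaults)
            else list(start)
  best <- NULL
  for (th0 in starts) {
    ans <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(th0, fn = resfun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter))),
      error = function(e) NULL)
    if (is.null(ans)) next
    chi2 <- sum(ans$fvec^2)
    if (is.null(best) || chi2 < best$chi2)
      best <- list(par = ans$par, chi2 = chi2, info = ans$info,
                   pred = obs - ans$fvec * sig)
  }
  if (is.null(best))
    best <- list(par = starts[[1]], chi2 = sum(resfun(starts[[1]])^2),
                 info = 0, pred = rep(NA_real_, n))
  best
}

fs_rates_from_globals <- function(globals, prep) {
  params <- four_state_params(globals[["k_on"]], globals[["rho_off"]],
                              globals[["rho_close"]],
                              prep$fixed$k12, prep$fixed$k21,
                              prep$fixed$Kd_macro,
                              convention = prep$convention)
  derive_rate_constants(params)
}

# Profiled chi2 over residue-level parameters at fixed global parameters.
# `cache` is an environment storing warm starts per residue.
fs_profile_chi2 <- function(globals, prep, cache = NULL, maxiter = 60,
                            extra_starts = FALSE) {
  rates <- fs_rates_from_globals(globals, prep)
  ctx <- fs_kinetic_context(rates, prep$samples, prep$fixed$Kd_macro)
  total <- 0
  details <- list()
  for (r in prep$residues) {
    start <- if (!is.null(cache) && !is.null(cache[[r]])) cache[[r]] else NULL
    ans <- fs_residue_fit(ctx, rates, prep$data_by_res[[r]],
                          prep$fixed$delta1[[r]], prep$fixed$delta_lac[[r]],
                          prep$gammaB0, prep$T_relax, start = start,
                          maxiter = maxiter, extra_starts = extra_starts)
    if (!is.null(cache)) cache[[r]] <- ans$par
    total <- total + ans$chi2
    details[[r]] <- ans
  }
  attr(total, "details") <- details
  attr(total, "rates") <- rates
  total
}

# Joint weighted least squares over the (log) globals and all residue-level
# parameters; the least-squares polish after simplex refinement, and the
# refitting engine for Monte-Carlo replicates.
fs_joint_fit <- function(prep, globals, res_theta, maxiter = 120) {
  nres <- length(prep$residues)
  th0 <- c(log(globals), unlist(res_theta))
  obs <- unlist(lapply(prep$data_by_res, `[[`, "obs"))
  sig <- unlist(lapply(prep$data_by_res, `[[`, "sig"))
  n <- length(obs)
  resfun <- function(theta) {
    guard_residuals({
      g <- setNames(exp(pmin(pmax(theta[1:3], -12), 26)),
                    c("k_on", "rho_off", "rho_close"))
      rates <- fs_rates_from_globals(g, prep)
      ctx <- fs_kinetic_context(rates, prep$samples, prep$fixed$Kd_macro)
      pred <- unlist(lapply(seq_len(nres), function(j) {
        r <- prep$residues[j]
        fs_residue_predict(theta[3 + (j - 1) * 3 + 1:3], ctx, rates,
                           prep$fixed$delta1[[r]],
                           prep$fixed$delta_lac[[r]],
                           prep$gammaB0, prep$data_by_res[[r]]$nu,
                           prep$T_relax)
      }))
      (obs - pred) / sig
    }, n)
  }
  ans <- suppressWarnings(
    minpack.lm::nls.lm(th0, fn = resfun,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter)))
  globals <- setNames(exp(ans$par[1:3]), c("k_on", "rho_off", "rho_close"))
  res_theta <- lapply(seq_len(nres), function(j) ans$par[3 + (j - 1) * 3 + 1:3])
  names(res_theta) <- prep$residues
  list(globals = globals, res_theta = res_theta, chi2 = sum(ans$fvec^2),
       info = ans$info, message = ans$message,
       pred = obs - ans$fvec * sig)
}

fs_prepare <- function(dataset, fixed, convention = "k43") {
  stopifnot(inherits(dataset, "titration_dataset"))
  data <- dataset$data
  samples <- dataset$samples[dataset$samples$L_tot_M > 0, , drop = FALSE]
  if (nrow(samples) < 2)
    stop("four-state fitting needs at least two ligand-containing samples")
  data <- data[data$sample_id %in% samples$sample_id, , drop = FALSE]
  field_T <- unique(samples$field_T)
  if (length(field_T) != 1)
    stop("titration samples must share a single static field")
  residues <- sort(unique(as.character(data$residue)))
  need <- c("k12", "k21", "Kd_macro", "delta1", "delta_lac")
  if (!all(need %in% names(fixed)))
    stop("fixed must supply ", paste(need, collapse = ", "))
  T_relax <- dataset$design$T_relax %||% 0.04
  # per residue: points ordered sample-major, nu ascending, all samples on
  # the residue's common nu grid
  data_by_res <- setNames(lapply(residues, function(r) {
    d <- data[data$residue == r, ]
    ord <- order(match(d$sample_id, samples$sample_id), d$nu_cp_hz)
    d <- d[ord, ]
    nus <- split(d$nu_cp_hz, factor(d$sample_id, levels = samples$sample_id))
    if (length(unique(vapply(nus, paste, character(1), collapse = ","))) != 1)
      stop("all samples of residue ", r, " must share one nu_cp grid")
    cpmg_schedule(nus[[1]], T_relax)  # validates echo counts
    list(df = d, obs = d$r2_s, sig = d$r2_err_s, nu = nus[[1]],
         r20_0 = mean(d$r2_s[order(-d$nu_cp_hz)][seq_len(min(5, nrow(d)))]))
  }), residues)
  fld <- field_config(field_T)
  list(data = data, samples = samples, data_by_res = data_by_res,
       residues = residues, field = fld, gammaB0 = fld$gamma * fld$B0,
       T_relax = T_relax, fixed = fixed, convention = convention)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default grid-search axes for the four-state global parameters
#'
#' Log-spaced grids over `k_on` in (8 to 300)e6 M^-1 s^-1, `rho_off` in 30 to
#' 1000, and `rho_close` in 0.001 to 1000. The chi2 surface is much sharper
#' along `rho_close` than along the other two axes, so that axis is sampled
#' more densely (half-decade steps) by default.
#'
#' @param n_kon,n_rho_off,n_rho_close Number of grid points per axis.
#' @return A named list of numeric axes.
#' @export
default_grids <- function(n_kon = 5, n_rho_off = 4, n_rho_close = 13) {
  list(k_on = 10^seq(log10(8e6), log10(300e6), length.out = n_kon),
       rho_off = 10^seq(log10(30), log10(1000), length.out = n_rho_off),
       rho_close = 10^seq(-3, 3, length.out = n_rho_close))
}

#' Grid search of the four-state global parameters
#'
#' Evaluates the profiled chi2 (chemical shifts and `R20` optimized per
#' residue) at every node of a `(k_on, rho_off, rho_close)` grid. Ties are
#' broken toward the lowest `k_on`, then the lowest `rho_off`.
#'
#' @param dataset A `titration_dataset`.
#' @param fixed Named list with `k12`, `k21`, `Kd_macro` and the per-residue
#'   `delta1` and `delta_lac` (named lists or vectors, ppm).
#' @param grids Axes as returned by [default_grids()].
#' @param convention `rho_close` convention, `"k43"` (default) or `"k34"`.
#' @param verbose Print progress.
#' @return An object of class `grid_search_result`: the grid data frame with
#'   `chi2`, the `argmin` node, and the axes.
#' @export
grid_search_four_state <- function(dataset, fixed, grids = default_grids(),
                                   convention = "k43", verbose = FALSE) {
  if (!length(grids$k_on) || !length(grids$rho_off) || !length(grids$rho_close))
    stop("empty grid")
  prep <- fs_prepare(dataset, fixed, convention)
  nodes <- expand.grid(k_on = grids$k_on, rho_off = grids$rho_off,
                       rho_close = grids$rho_close,
                       KEEP.OUT.ATTRS = FALSE)
  cache <- new.env(parent = emptyenv())
  chi2 <- numeric(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    g <- c(k_on = nodes$k_on[i], rho_off = nodes$rho_off[i],
           rho_close = nodes$rho_close[i])
    chi2[i] <- as.numeric(fs_profile_chi2(g, prep, cache, maxiter = 40))
    if (verbose && i %% 20 == 0)
      message(sprintf("grid %d/%d chi2=%.4g", i, nrow(nodes), chi2[i]))
  }
  nodes$chi2 <- chi2
  ord <- order(nodes$chi2, nodes$k_on, nodes$rho_off)
  structure(list(grid = nodes, argmin = nodes[ord[1], ], axes = grids),
            class = "grid_search_result")
}

#' Diverse low-chi2 start points from a grid search
#'
#' Returns up to `k` grid nodes ordered by chi2 whose `rho_close` values are
#' distinct. The chi2 surface is narrow along `rho_close`, so refining from
#' several slices of that axis guards against a coarse grid ranking a
#' compensating solution ahead of the true basin.
#'
#' @param gs A `grid_search_result`.
#' @param k Maximum number of starts.
#' @return A data frame of `k_on`, `rho_off`, `rho_close` rows, best first.
#' @export
grid_top_starts <- function(gs, k = 3) {
  stopifnot(inherits(gs, "grid_search_result"))
  g <- gs$grid[order(gs$grid$chi2, gs$grid$k_on, gs$grid$rho_off), ]
  g <- g[!duplicated(g$rho_close), , drop = FALSE]
  utils::head(g[c("k_on", "rho_off", "rho_close")], k)
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("Grid search over %d nodes; chi2 range [%.4g, %.4g]\n",
              nrow(x$grid), min(x$grid$chi2), max(x$grid$chi2)))
  cat("argmin:\n"); print(x$argmin, row.names = FALSE)
  invisible(x)
}

#' Global four-state Bloch-McConnell fit of a titration
#'
#' Fits the three global parameters `(k_on, rho_off, rho_close)` to all
#' dispersion curves of a ligand titration simultaneously. At each step the
#' remaining rate constants are derived under detailed balance from the fixed
#' `k12`, `k21` and `Kd_macro`; per-sample free-ligand concentrations follow
#' from the mass balance; `delta1` is fixed to the apo value, `delta2` and
#' `delta3` are fitted per residue, `delta4` is back-computed from the
#' lactose-saturated shift `delta_lac = p3 delta3 + p4 delta4` (saturated
#' populations), and a single `R20` per residue is shared across all ligand
#' concentrations. The outer objective over the (log-scaled) globals is
#' profiled: residue-level parameters are re-optimized by
#' Levenberg-Marquardt at every outer evaluation, and the outer minimization
#' uses Nelder-Mead simplex refinement from the supplied start (typically the
#' grid-search argmin).
#'
#' @inheritParams grid_search_four_state
#' @param start Named vector or list with `k_on`, `rho_off`, `rho_close`.
#' @param bounds List of length-2 numeric ranges for the globals; defaults to
#'   `k_on` in (1e6, 1e10), `rho_off` in (1, 1e4), `rho_close` in (1e-4, 1e4).
#' @param control Passed to [stats::optim()] (Nelder-Mead); defaults to
#'   `maxit = 400`, `reltol = 1e-9`.
#' @return A `csif_fit` with the global parameters, per-residue `delta2`,
#'   `delta3`, `delta4`, `R20`, the derived `rate_constants` in
#'   `$rates`, and convergence/at-bound flags.
#' @export
fit_four_state_global <- function(dataset, fixed, start,
                                  convention = "k43",
                                  bounds = list(k_on = c(1e6, 1e10),
                                                rho_off = c(1, 1e4),
                                                rho_close = c(1e-4, 1e4)),
                                  control = list(maxit = 80,
                                                 reltol = 1e-7)) {
  prep <- fs_prepare(dataset, fixed, convention)
  gname <- c("k_on", "rho_off", "rho_close")
  starts <- if (is.data.frame(start)) {
    lapply(seq_len(nrow(start)), function(i) unlist(start[i, gname]))
  } else list(unlist(start)[gname])
  lb <- log(vapply(bounds, `[`, numeric(1), 1))
  ub <- log(vapply(bounds, `[`, numeric(1), 2))

  # stage 1: joint least squares from each start (residue-level parameters
  # initialized by a profiled inner fit at the start node); keep the best
  best <- NULL
  for (g0 in starts) {
    prof <- fs_profile_chi2(g0, prep, maxiter = 100)
    th0 <- lapply(attr(prof, "details"), `[[`, "par")
    cand <- tryCatch(fs_joint_fit(prep, g0, th0), error = function(e) NULL)
    if (!is.null(cand) && (is.null(best) || cand$chi2 < best$chi2))
      best <- cand
  }
  if (is.null(best)) stop("four-state fit failed from every start")

  # stage 2: simplex refinement of the profiled objective around the
  # optimum, then a final joint polish; accepted only if it improves chi2
  cache <- new.env(parent = emptyenv())
  obj <- function(lg) {
    if (any(lg < lb) || any(lg > ub))
      return(1e12 * (1 + sum(pmax(lb - lg, 0) + pmax(lg - ub, 0))))
    as.numeric(fs_profile_chi2(setNames(exp(lg), gname), prep, cache))
  }
  opt <- optim(log(best$globals), obj, method = "Nelder-Mead",
               control = control)
  if (is.finite(opt$value)) {
    prof2 <- fs_profile_chi2(setNames(exp(opt$par), gname), prep, cache)
    cand2 <- tryCatch(
      fs_joint_fit(prep, setNames(exp(opt$par), gname),
                   lapply(attr(prof2, "details"), `[[`, "par")),
      error = function(e) NULL)
    if (!is.null(cand2) && cand2$chi2 < best$chi2) best <- cand2
  }
  polish <- best
  globals <- polish$globals
  rates <- fs_rates_from_globals(globals, prep)

  par <- as.list(globals)
  fitted_rows <- list()
  off <- 0L
  for (r in prep$residues) {
    th <- polish$res_theta[[r]]
    par[[paste0("delta2_", r)]] <- th[1]
    par[[paste0("delta3_", r)]] <- th[2]
    par[[paste0("delta4_", r)]] <-
      as.numeric(delta4_from_constraint(th[2], prep$fixed$delta_lac[[r]],
                                        rates))
    par[[paste0("R20_", r)]] <- th[3]
    d <- prep$data_by_res[[r]]$df
    d$r2_fit <- polish$pred[off + seq_len(nrow(d))]
    off <- off + nrow(d)
    fitted_rows[[r]] <- d
  }
  fitted <- do.call(rbind, fitted_rows)
  rownames(fitted) <- NULL
  n <- nrow(prep$data)
  n_free <- 3 + 3 * length(prep$residues)
  at_bound <- any(log(globals) - lb < 1e-6) || any(ub - log(globals) < 1e-6)
  conv <- polish$info %in% 1:4 && !at_bound
  msg <- if (at_bound) "parameter at bound"
         else sprintf("simplex + least-squares polish (%s)", polish$message)
  fit <- new_csif_fit("four_state", par, polish$chi2, n - n_free, n,
                      conv, msg, fitted, prep$data,
                      refit = NULL)
  fit$rates <- rates
  fit$globals <- globals
  fit$convention <- convention
  best_theta <- polish$res_theta
  fit$refit <- function(d) {
    ds <- dataset
    ds$data <- d
    prep2 <- fs_prepare(ds, fixed, convention)
    ans <- fs_joint_fit(prep2, globals, best_theta)
    # lightweight csif_fit for Monte-Carlo replicate collection
    par2 <- as.list(ans$globals)
    for (r in prep2$residues) {
      th <- ans$res_theta[[r]]
      par2[[paste0("delta2_", r)]] <- th[1]
      par2[[paste0("delta3_", r)]] <- th[2]
      par2[[paste0("delta4_", r)]] <- as.numeric(delta4_from_constraint(
        th[2], prep2$fixed$delta_lac[[r]],
        fs_rates_from_globals(ans$globals, prep2)))
      par2[[paste0("R20_", r)]] <- th[3]
    }
    new_csif_fit("four_state", par2, ans$chi2, n - n_free, n,
                 ans$info %in% 1:4, ans$message, NULL, d, refit = NULL)
  }
  fit
}

#' Monte-Carlo parameter uncertainties
#'
#' Resimulates `n_replicates` synthetic datasets from the best-fit curves
#' with Gaussian noise at the reported per-point uncertainties, refits each
#' replicate starting from the best-fit parameters, and reports the standard
#' deviation of every parameter across replicates. Conventional replicate
#' counts for this kind of analysis are 1000 for two-state fits and 500 for
#' four-state fits; smaller values trade precision of the error estimate for
#' runtime.
#'
#' @param fit A converged `csif_fit` with a `refit` closure (all fitters in
#'   this package attach one).
#' @param n_replicates Number of synthetic datasets (>= 100).
#' @param seed Integer seed; replicate `i` perturbs the data with a
#'   deterministic child seed.
#' @return The input fit with `$se` filled in, plus `$mc` holding the
#'   replicate parameter matrix and the non-convergence fraction (a warning
#'   is attached above 10%).
#' @export
monte_carlo_errors <- function(fit, n_replicates = 500, seed = 1) {
  stopifnot(inherits(fit, "csif_fit"))
  if (n_replicates < 100)
    stop("use at least 100 Monte-Carlo replicates")
  if (is.null(fit$fitted) || is.null(fit$refit))
    stop("fit does not carry fitted values / refit closure")
  base <- fit$fitted
  par_names <- names(fit$par)
  reps <- matrix(NA_real_, n_replicates, length(par_names),
                 dimnames = list(NULL, par_names))
  n_fail <- 0L
  for (i in seq_len(n_replicates)) {
    set.seed((seed * 100003L + i) %% .Machine$integer.max)
    d <- base
    d$r2_s <- d$r2_fit + rnorm(nrow(d), sd = d$r2_err_s)
    d$r2_fit <- NULL
    rf <- tryCatch(fit$refit(d), error = function(e) NULL)
    if (is.null(rf) || !all(par_names %in% names(rf$par))) {
      n_fail <- n_fail + 1L
      next
    }
    if (!isTRUE(rf$converged)) n_fail <- n_fail + 1L
    reps[i, ] <- unlist(rf$par[par_names])
  }
  se <- apply(reps, 2, sd, na.rm = TRUE)
  fit$se <- as.list(se)
  fit$mc <- list(replicates = reps, n_replicates = n_replicates,
                 nonconvergence_rate = n_fail / n_replicates)
  if (fit$mc$nonconvergence_rate > 0.10)
    warning(sprintf("Monte-Carlo replicate non-convergence rate %.1f%%",
                    100 * fit$mc$nonconvergence_rate))
  fit
}

#' Chemical-shift difference comparison table
#'
#' For each residue computes `dd_cpmg = |delta1 - delta2|` (the shift
#' difference seen by the apo-state dispersion experiment),
#' `dd_hsqc = |delta1 - (p3 delta3 + p4 delta4)/(p3 + p4)|` (the apparent
#' apo-to-bound shift change, using the saturated bound-state partition), and
#' `dd_14 = |delta1 - delta4|`, together with Pearson correlations and
#' through-origin regression slopes of `dd_cpmg` against the other two.
#'
#' @param shifts Data frame with columns `residue`, `delta1`..`delta4` (ppm).
#' @param rates A `rate_constants` object supplying the bound-state
#'   partition.
#' @return A list with the per-residue `table` and the statistics
#'   `r_hsqc`, `slope_hsqc`, `r_14`, `slope_14`; statistics are `NA` with a
#'   `flag` when fewer than 3 residues are available.
#' @export
shift_difference_table <- function(shifts, rates) {
  need <- c("residue", "delta1", "delta2", "delta3", "delta4")
  if (!all(need %in% names(shifts)))
    stop("shifts must have columns ", paste(need, collapse = ", "))
  ps <- saturated_partition(rates)
  bound <- (ps["p3"] * shifts$delta3 + ps["p4"] * shifts$delta4)
  tab <- data.frame(residue = shifts$residue,
                    dd_cpmg = abs(shifts$delta1 - shifts$delta2),
                    dd_hsqc = abs(shifts$delta1 - bound),
                    dd_14 = abs(shifts$delta1 - shifts$delta4))
  slope0 <- function(y, x) sum(x * y) / sum(x * x)
  if (nrow(tab) < 3) {
    return(list(table = tab, r_hsqc = NA_real_, slope_hsqc = NA_real_,
                r_14 = NA_real_, slope_14 = NA_real_,
                flag = "fewer than 3 residues: correlation undefined"))
  }
  list(table = tab,
       r_hsqc = cor(tab$dd_cpmg, tab$dd_hsqc),
       slope_hsqc = slope0(tab$dd_cpmg, tab$dd_hsqc),
       r_14 = cor(tab$dd_cpmg, tab$dd_14),
       slope_14 = slope0(tab$dd_cpmg, tab$dd_14),
       flag = NULL)
}
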