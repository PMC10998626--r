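#' Static-field configuration for the observed nucleus
#'
#' @param B0 Static magnetic field (T).
#' @param gamma Gyromagnetic ratio magnitude (rad s^-1 T^-1); defaults to 15N.
#' @return An object of class `field_config`.
#' @export
field_config <- function(B0, gamma = GAMMA_15N) {
  if (!is.finite(B0) || B0 <= 0) stop("B0 must be positive")
  structure(list(B0 = B0, gamma = gamma), class = "field_config")
}

#' Convert a chemical-shift difference from ppm to angular frequency
#'
#' `delta omega = delta delta * 1e-6 * gamma * B0` (rad s^-1).
#'
#' @param ddelta_ppm Chemical-shift difference (ppm).
#' @param field A `field_config` object.
#' @return Angular frequency difference (rad s^-1).
#' @export
ppm_to_omega <- function(ddelta_ppm, field) {
  stopifnot(inherits(field, "field_config"))
  ddelta_ppm * 1e-6 * field$gamma * field$B0
}

#' CPMG schedule: relaxation period and refocusing frequencies
#'
#' The refocusing-pulse spacing is `tau = 1/(2 nu_cp)` and the train consists
#' of `2 * T_relax * nu_cp` echo units `(tau/2 - 180 - tau/2)`; every
#' `nu_cp` must therefore give an integer echo count within `T_relax`
#' (checked to 1e-6).
#'
#' @param nu_cp Strictly increasing refocusing frequencies (Hz).
#' @param T_relax Total relaxation period (s); default 40 ms.
#' @return An object of class `cpmg_schedule`.
#' @export
cpmg_schedule <- function(nu_cp, T_relax = 0.04) {
  if (any(!is.finite(nu_cp)) || any(nu_cp <= 0))
    stop("nu_cp must be positive and finite")
  if (is.unsorted(nu_cp, strictly = TRUE))
    stop("nu_cp must be strictly increasing")
  n_echo <- 2 * T_relax * nu_cp
  if (any(abs(n_echo - round(n_echo)) > 1e-6))
    stop(sprintf("nu_cp values must give integer echo counts in T_relax = %g s (offenders: %s)",
                 T_relax,
                 paste(nu_cp[abs(n_echo - round(n_echo)) > 1e-6], collapse = ", ")))
  structure(list(nu_cp = as.numeric(nu_cp), T_relax = T_relax,
                 tau = 1 / (2 * as.numeric(nu_cp))),
            class = "cpmg_schedule")
}

#' Default nu_cp grid
#'
#' Seventeen refocusing frequencies between 25 and 1000 Hz, all multiples of
#' 25 Hz so that the echo count is exact for a 40 ms relaxation period.
#'
#' @return Numeric vector of frequencies (Hz).
#' @export
default_nu_cp <- function() {
  c(25, 50, 75, 100, 125, 150, 200, 250, 300, 350, 400,
    500, 600, 700, 800, 900, 1000)
}

#' Two-state exchange parameters
#'
#' @param k_ex Exchange rate, sum of forward and reverse rates (s^-1).
#' @param p_minor Minor-state population, in `(0, 0.5]`.
#' @param delta_omega Chemical-shift difference between the two states
#'   (rad s^-1); only its magnitude affects the dispersion.
#' @param R20 Exchange-free transverse relaxation rate (s^-1).
#' @return An object of class `two_state_params`.
#' @export
two_state_params <- function(k_ex, p_minor, delta_omega, R20) {
  if (!is.finite(k_ex) || k_ex <= 0) stop("k_ex must be positive")
  if (!is.finite(p_minor) || p_minor <= 0 || p_minor > 0.5)
    stop("p_minor must lie in (0, 0.5]")
  if (!is.finite(R20) || R20 < 0) stop("R20 must be non-negative")
  structure(list(k_ex = k_ex, p_minor = p_minor,
                 delta_omega = delta_omega, R20 = R20),
            class = "two_state_params")
}

# Complex-safe acosh with asymptotic branch for huge arguments supplied in
# log form; x >= 1 uses the real branch, |x| < 1 returns 0 (the real part of
# acosh on [-1, 1]), x < -1 returns the real part log|x|-ish branch.
acosh_real <- function(x) {
  out <- numeric(length(x))
  big <- is.finite(x) & x >= 1
  out[big] <- acosh(x[big])
  lo <- is.finite(x) & x < -1
  out[lo] <- Re(acosh(as.complex(x[lo])))
  out[!is.finite(x)] <- NA_real_
  out
}

#' Carver-Richards dispersion profile for two-state exchange
#'
#' Closed-form effective relaxation rate for two-site chemical exchange under
#' a CPMG train:
#' \deqn{R_2(1/\tau) = R_{20} + \frac{1}{2}\left[k_{ex} -
#'   \frac{1}{\tau}\cosh^{-1}(D_+\cosh\eta_+ - D_-\cos\eta_-)\right]}
#' with \eqn{\psi = k_{ex}^2 - \Delta\omega^2},
#' \eqn{\zeta = -2\Delta\omega k_{ex}(1-2p_{minor})},
#' \eqn{D_\pm = \frac{1}{2}[\pm 1 + (\psi + 2\Delta\omega^2)/
#'   \sqrt{\psi^2+\zeta^2}]},
#' \eqn{\eta_\pm = (\tau/\sqrt{2})[\pm\psi + \sqrt{\psi^2+\zeta^2}]^{1/2}},
#' and \eqn{\tau = 1/(2\nu_{cp})} the spacing between refocusing pulses.
#' The `acosh` is evaluated on the real branch with a continuation that
#' returns the real part when the argument drops below 1, and an asymptotic
#' expansion when `cosh(eta_+)` would overflow.
#'
#' @param params A `two_state_params` object.
#' @param schedule A `cpmg_schedule` object, or a numeric vector of
#'   `nu_cp` values (Hz).
#' @return Numeric vector of `R2eff` values (s^-1), one per `nu_cp`.
#' @export
carver_richards_r2 <- function(params, schedule) {
  stopifnot(inherits(params, "two_state_params"))
  nu <- if (inherits(schedule, "cpmg_schedule")) schedule$nu_cp
        else as.numeric(schedule)
  kex <- params$k_ex
  dw <- params$delta_omega
  p <- params$p_minor
  tau <- 1 / (2 * nu)
  psi <- kex^2 - dw^2
  zeta <- -2 * dw * kex * (1 - 2 * p)
  root <- sqrt(psi^2 + zeta^2)
  Dp <- 0.5 * ( 1 + (psi + 2 * dw^2) / root)
  Dm <- 0.5 * (-1 + (psi + 2 * dw^2) / root)
  etap <- tau / sqrt(2) * sqrt(pmax(psi + root, 0))
  etam <- tau / sqrt(2) * sqrt(pmax(-psi + root, 0))
  # acosh(Dp cosh etap - Dm cos etam); for large etap use
  # acosh(z) ~ log(2 z) expanded to avoid overflow of cosh
  ac <- numeric(length(nu))
  hi <- etap > 350   # cosh would overflow: use acosh(z) ~ log(2 z)
  if (any(hi)) {
    ac[hi] <- log(Dp) + etap[hi] +
      log1p(exp(-2 * etap[hi]) -
              2 * (Dm / Dp) * cos(etam[hi]) * exp(-etap[hi]))
  }
  if (any(!hi)) {
    arg <- Dp * cosh(etap[!hi]) - Dm * cos(etam[!hi])
    ac[!hi] <- acosh_real(arg)
  }
  r2 <- params$R20 + 0.5 * (kex - ac / tau)
  if (any(!is.finite(r2)))
    stop("non-finite value in Carver-Richards evaluation; check parameters")
  r2
}

# Build the exchange matrix K (columns sum to zero) for the Fig-1A topology
# from the eight directed edge rates; forbidden edges 1-4 and 2-3 are absent
# by construction.
build_exchange_matrix <- function(k12, k21, k13, k31, k24, k42, k34, k43) {
  K <- matrix(0, 4, 4)
  K[2, 1] <- k12; K[1, 2] <- k21
  K[3, 1] <- k13; K[1, 3] <- k31
  K[4, 2] <- k24; K[2, 4] <- k42
  K[4, 3] <- k34; K[3, 4] <- k43
  diag(K) <- -colSums(K)
  K
}

#' Bloch-McConnell evolution generator for the four-state network
#'
#' Returns the complex 4x4 generator `M = K - diag(R20) - i * diag(omega)`
#' acting on the transverse magnetization of states 1-4, where `K` is the
#' exchange matrix of the CS/IF topology (edges 1-2, 1-3, 2-4, 3-4 only),
#' ligand-binding steps enter as pseudo-first-order rates `k_on * L_free`,
#' `R20` is the exchange-free relaxation rate (shared by all states of a
#' residue at a given field), and `omega` holds the state resonance offsets.
#' Chemical shifts are referenced to `ref_ppm` (default: state 1), so only
#' shift differences matter.
#'
#' @param rates A `rate_constants` object.
#' @param L_free Free ligand concentration (M), >= 0.
#' @param shifts_ppm Numeric vector of the four state chemical shifts
#'   `c(delta1, delta2, delta3, delta4)` (ppm).
#' @param R20 Exchange-free relaxation rate (s^-1), scalar.
#' @param field A `field_config` object.
#' @param ref_ppm Reference shift (ppm) subtracted from all states.
#' @return A complex 4x4 matrix.
#' @export
bm_matrix <- function(rates, L_free, shifts_ppm, R20, field,
                      ref_ppm = shifts_ppm[1]) {
  stopifnot(inherits(rates, "rate_constants"), length(shifts_ppm) == 4)
  if (L_free < 0) stop("L_free must be non-negative")
  konL <- rates$k_on * L_free
  K <- build_exchange_matrix(rates$k12, rates$k21, konL, rates$k_off3,
                             konL, rates$k_off4, rates$k34, rates$k43)
  omega <- ppm_to_omega(shifts_ppm - ref_ppm, field)
  K - diag(rep(R20, 4)) - 1i * diag(omega)
}

#' Two-state Bloch-McConnell generator
#'
#' 2x2 generator for two-site exchange with forward rate
#' `k1 = p_minor * k_ex` and reverse rate `k_ex - k1`; used as the numerical
#' counterpart of [carver_richards_r2()].
#'
#' @param params A `two_state_params` object.
#' @return A complex 2x2 matrix (state 1 = major, on resonance; state 2 =
#'   minor, offset by `delta_omega`).
#' @export
two_state_matrix <- function(params) {
  stopifnot(inherits(params, "two_state_params"))
  k1 <- params$p_minor * params$k_ex   # major -> minor
  k2 <- params$k_ex - k1               # minor -> major
  K <- matrix(c(-k1, k1, k2, -k2), 2, 2)
  K - diag(rep(params$R20, 2)) - 1i * diag(c(0, params$delta_omega))
}

#' Stationary populations of an exchange matrix
#'
#' Solves `K p = 0`, `sum(p) = 1` on the connected component containing
#' `from` (states not connected to it get population zero), so it also
#' handles sub-networks in which some states are unreachable.
#'
#' @param K A real exchange matrix with zero column sums (e.g. the real part
#'   of a generator before relaxation/offset terms are added).
#' @param from State index anchoring the connected component (default 1).
#' @return Numeric vector of populations summing to 1.
#' @export
stationary_populations <- function(K, from = 1L) {
  n <- nrow(K)
  adj <- (abs(K) > 0) | (abs(t(K)) > 0)
  diag(adj) <- FALSE
  # reachability by repeated expansion
  comp <- rep(FALSE, n)
  comp[from] <- TRUE
  repeat {
    nxt <- comp | (adj %*% comp > 0)
    if (all(nxt == comp)) break
    comp <- nxt
  }
  idx <- which(comp)
  Ksub <- K[idx, idx, drop = FALSE]
  A <- rbind(Ksub, rep(1, length(idx)))
  b <- c(rep(0, length(idx)), 1)
  p_sub <- qr.solve(A, b)
  p <- rep(0, n)
  p[idx] <- p_sub
  p
}

#' Simulate a noiseless CPMG dispersion curve
#'
#' Propagates the transverse magnetization through the CPMG train for every
#' refocusing frequency in the schedule, starting from magnetization
#' proportional to the equilibrium populations (the experiment's
#' equilibration delay ensures exactly this initial condition). The ideal
#' 180-degree pulse is modeled as complex conjugation and
#' `R2eff = -log(I(T)/I(0)) / T` with `I` the summed real magnetization.
#'
#' @param M Complex NxN evolution generator (see [bm_matrix()]).
#' @param m0 Initial magnetization per state (real, typically equilibrium
#'   populations).
#' @param schedule A `cpmg_schedule` object.
#' @return A data frame with columns `nu_cp_hz` and `r2_s`.
#' @export
simulate_dispersion <- function(M, m0, schedule) {
  stopifnot(inherits(schedule, "cpmg_schedule"))
  r2 <- bm_r2eff_cpp(M, as.numeric(m0), schedule$nu_cp, schedule$T_relax)
  data.frame(nu_cp_hz = schedule$nu_cp, r2_s = r2)
}

#' Asymptotic CPMG relaxation rate from the echo-cycle propagator
#'
#' Pure-R numerical route independent of [simulate_dispersion()]: for each
#' `nu_cp` it forms the linear propagator of two consecutive echo units,
#' `B = U cc(U) cc(U) U` with `U = expm(M tau/2)` and `cc` complex
#' conjugation, and returns the decay rate of its slowest-decaying mode,
#' `-log(max |eig(B)|) / (2 tau)`. This is the infinite-train (asymptotic)
#' rate that closed-form dispersion expressions describe; it differs from
#' the finite-length, endpoint-sampled `R2eff` of [simulate_dispersion()]
#' by an amplitude term of order `1/T_relax` that matters only for slow
#' exchange with large minor populations.
#'
#' @param M Complex NxN evolution generator.
#' @param schedule A `cpmg_schedule` object or numeric `nu_cp` vector (Hz).
#' @return Numeric vector of asymptotic `R2` values (s^-1).
#' @export
bm_r2_asymptotic <- function(M, schedule) {
  nu <- if (inherits(schedule, "cpmg_schedule")) schedule$nu_cp
        else as.numeric(schedule)
  expmc <- function(A, t) {
    e <- eigen(A)
    e$vectors %*% diag(exp(e$values * t), nrow(A)) %*% solve(e$vectors)
  }
  vapply(nu, function(v) {
    tau <- 1 / (2 * v)
    U <- expmc(M, tau / 2)
    B <- U %*% Conj(U) %*% Conj(U) %*% U
    -log(max(abs(eigen(B, only.values = TRUE)$values))) / (2 * tau)
  }, numeric(1))
}

#' Dispersion-curve families diagnostic of the binding mechanism
#'
#' Simulates relaxation dispersion profiles over a ligand-saturation grid for
#' three mechanisms built from the same rate constants: conformational
#' selection only (binding to the closed state blocked, 1-2-4 sub-network),
#' induced fit only (binding to the open state and the apo conformational
#' exchange blocked, 1-3-4 sub-network), and the full four-state model.
#' Saturation is mapped to free-ligand concentration through the full
#' model's macroscopic Kd for all three families so the curves share a
#' concentration axis. Initial magnetization is the stationary distribution
#' of each sub-network.
#'
#' @param rates A `rate_constants` object.
#' @param shifts_ppm State chemical shifts `c(delta1..delta4)` (ppm).
#' @param R20 Exchange-free relaxation rate (s^-1).
#' @param field A `field_config` object.
#' @param schedule A `cpmg_schedule` object.
#' @param saturations Saturation grid in `[0, 0.9]`.
#' @return A data frame with columns `mechanism` (`"CS"`, `"IF"`,
#'   `"four_state"`), `saturation`, `L_free_M`, `nu_cp_hz`, `r2_s`.
#' @export
simulate_mechanism_panels <- function(rates, shifts_ppm, R20, field, schedule,
                                      saturations = seq(0, 0.9, by = 0.1)) {
  stopifnot(inherits(rates, "rate_constants"))
  if (any(saturations < 0 | saturations > 0.9))
    stop("saturations must lie in [0, 0.9]")
  Kd <- macroscopic_kd(rates)
  out <- list()
  for (sat in saturations) {
    L <- free_ligand_at_saturation(Kd, sat)
    konL <- rates$k_on * L
    edge_sets <- list(
      CS = list(k12 = rates$k12, k21 = rates$k21, k13 = 0, k31 = 0,
                k24 = konL, k42 = rates$k_off4,
                k34 = rates$k34, k43 = rates$k43),
      IF = list(k12 = 0, k21 = 0, k13 = konL, k31 = rates$k_off3,
                k24 = 0, k42 = 0, k34 = rates$k34, k43 = rates$k43),
      four_state = list(k12 = rates$k12, k21 = rates$k21,
                        k13 = konL, k31 = rates$k_off3,
                        k24 = konL, k42 = rates$k_off4,
                        k34 = rates$k34, k43 = rates$k43))
    omega <- ppm_to_omega(shifts_ppm - shifts_ppm[1], field)
    for (mech in names(edge_sets)) {
      K <- do.call(build_exchange_matrix, edge_sets[[mech]])
      pops <- stationary_populations(K)
      M <- K - diag(rep(R20, 4)) - 1i * diag(omega)
      curve <- simulate_dispersion(M, pops, schedule)
      out[[length(out) + 1L]] <- data.frame(
        mechanism = mech, saturation = sat, L_free_M = L,
        nu_cp_hz = curve$nu_cp_hz, r2_s = curve$r2_s)
    }
  }
  do.call(rbind, out)
}
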