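#' Study design for synthetic dispersion datasets
#'
#' Describes the experimental design the generator emulates: apo dispersion
#' at two static fields (14.1 and 18.8 T), a seven-point lactose titration
#' at 14.1 T spanning 4-75% saturation, eight reporting residues, a 17-point
#' `nu_cp` grid between 25 and 1000 Hz, 0.5 mM total protein, and Gaussian
#' noise with SD `max(noise_floor, noise_frac * R2)` per point.
#'
#' @param apo_fields Static fields for the apo experiments (T).
#' @param titration_field Static field for the titration (T).
#' @param n_residues Number of reporting residues.
#' @param saturation_levels Saturation fractions of the titration samples,
#'   each in `[0, 1)`.
#' @param P_tot Total protein concentration per sample (M).
#' @param noise_floor Noise SD floor (s^-1).
#' @param noise_frac Fractional noise SD (of the noiseless R2).
#' @param nu_cp Refocusing-frequency grid (Hz); 15-24 points.
#' @param T_relax Relaxation period (s).
#' @param seed Master seed; per-curve child seeds are derived
#'   deterministically from it and the curve identity.
#' @return An object of class `study_design`.
#' @export
study_design <- function(apo_fields = c(14.1, 18.8),
                         titration_field = 14.1,
                         n_residues = 8,
                         saturation_levels = c(0.04, 0.08, 0.11, 0.21,
                                               0.27, 0.30, 0.75),
                         P_tot = 0.5e-3,
                         noise_floor = 0.3,
                         noise_frac = 0.02,
                         nu_cp = default_nu_cp(),
                         T_relax = 0.04,
                         seed = 1L) {
  if (any(saturation_levels < 0 | saturation_levels >= 1))
    stop("saturation levels must lie in [0, 1)")
  if (noise_floor < 0 || noise_frac < 0)
    stop("noise parameters must be non-negative")
  if (length(nu_cp) < 15 || length(nu_cp) > 24)
    warning("nu_cp grid outside the emulated 15-24 point range")
  cpmg_schedule(nu_cp, T_relax)  # validates the grid
  structure(list(apo_fields = apo_fields, titration_field = titration_field,
                 n_residues = as.integer(n_residues),
                 saturation_levels = saturation_levels, P_tot = P_tot,
                 noise_floor = noise_floor, noise_frac = noise_frac,
                 nu_cp = nu_cp, T_relax = T_relax, seed = as.integer(seed)),
            class = "study_design")
}

#' Ground truth for a synthetic study
#'
#' Draws per-residue chemical shifts and baseline relaxation rates and
#' derives the microscopically reversible rate set from the global
#' parameterization. Shift patterns follow the expectation for a CS/IF
#' network probed in the binding site: `delta1` uniform in 105-130 ppm,
#' `|delta2 - delta1|` in 0.5-3 ppm, `|delta3 - delta1|` in 0.1-1 ppm on the
#' same side, and `delta4` within 0.2 ppm of `delta2` (the open-state shifts
#' with and without ligand are similar). `R20` is uniform in 8-15 s^-1 per
#' residue and field. The lactose-saturated observable shift `delta_lac`
#' is computed from the saturated bound-state partition.
#'
#' @param design A `study_design` object.
#' @param params A `four_state_params` object; defaults to
#'   [galectin_params()].
#' @return An object of class `ground_truth` with the `params`, derived
#'   `rates`, per-residue `shifts` (data frame), `R20` matrix
#'   (residue x field), and `delta_lac`.
#' @export
ground_truth <- function(design, params = galectin_params()) {
  stopifnot(inherits(design, "study_design"))
  rates <- derive_rate_constants(params)
  set.seed(design$seed)
  n <- design$n_residues
  res <- sprintf("res%02d", seq_len(n))
  d1 <- runif(n, 105, 130)
  dir <- sample(c(-1, 1), n, replace = TRUE)
  d2 <- d1 + dir * runif(n, 0.5, 3)
  d3 <- d1 + dir * runif(n, 0.1, 1)
  d4 <- d2 + runif(n, -0.2, 0.2)
  fields <- sort(unique(c(design$apo_fields, design$titration_field)))
  R20 <- matrix(runif(n * length(fields), 8, 15), n, length(fields),
                dimnames = list(res, as.character(fields)))
  ps <- saturated_partition(rates)
  structure(list(params = params, rates = rates,
                 shifts = data.frame(residue = res, delta1 = d1, delta2 = d2,
                                     delta3 = d3, delta4 = d4),
                 R20 = R20,
                 delta_lac = setNames(ps["p3"] * d3 + ps["p4"] * d4, res)),
            class = "ground_truth")
}

# Deterministic per-curve child seed from the master seed and the curve
# identity (residue, field, total ligand), so that e.g. a zero-ligand
# titration sample reproduces the apo generator's noise exactly.
curve_seed <- function(seed, residue, field_T, L_tot) {
  key <- paste(residue, format(field_T, digits = 10),
               format(L_tot, digits = 10), sep = "|")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (seed * 48271 + h * 16807) %% 2147483647L
}

add_noise <- function(r2_true, design, seed) {
  sd <- pmax(design$noise_floor, design$noise_frac * r2_true)
  set.seed(seed)
  list(r2 = r2_true + rnorm(length(r2_true), sd = sd), sd = sd)
}

simulate_curve_rows <- function(truth, design, residue, field_T, sample_id,
                                L_free, L_tot, P_tot, noiseless = FALSE) {
  schedule <- cpmg_schedule(design$nu_cp, design$T_relax)
  fld <- field_config(field_T)
  sh <- truth$shifts[truth$shifts$residue == residue, ]
  shifts <- c(sh$delta1, sh$delta2, sh$delta3, sh$delta4)
  r20 <- truth$R20[residue, as.character(field_T)]
  M <- bm_matrix(truth$rates, L_free, shifts, r20, fld)
  pops <- equilibrium_populations(truth$rates, L_free)
  curve <- simulate_dispersion(M, c(pops$p1, pops$p2, pops$p3, pops$p4),
                               schedule)
  if (noiseless) {
    r2 <- curve$r2_s
    sd <- pmax(design$noise_floor, design$noise_frac * curve$r2_s)
  } else {
    nz <- add_noise(curve$r2_s, design,
                    curve_seed(design$seed, residue, field_T, L_tot))
    r2 <- nz$r2; sd <- nz$sd
  }
  data.frame(residue = residue, field_T = field_T, sample_id = sample_id,
             nu_cp_hz = curve$nu_cp_hz, r2_s = r2, r2_err_s = sd)
}

#' Generate a synthetic apo dataset (two fields, two-state exchange)
#'
#' Simulates the apo protein's dispersion curves (no ligand, so only states
#' 1 and 2 are populated) for every residue at each apo field, through the
#' full Bloch-McConnell propagator, and adds seeded Gaussian noise.
#'
#' @param design A `study_design`.
#' @param truth A `ground_truth`; defaults to `ground_truth(design)`.
#' @param noiseless Skip the noise (the error column still carries the
#'   would-be SDs).
#' @return A `titration_dataset` whose samples are the apo measurements.
#' @export
generate_apo_dataset <- function(design, truth = ground_truth(design),
                                 noiseless = FALSE) {
  rows <- list()
  samples <- list()
  for (f in design$apo_fields) {
    samples[[length(samples) + 1L]] <-
      data.frame(sample_id = "apo", field_T = f, P_tot_M = design$P_tot,
                 L_tot_M = 0, saturation = 0)
    for (r in truth$shifts$residue)
      rows[[length(rows) + 1L]] <-
        simulate_curve_rows(truth, design, r, f, "apo", 0, 0, design$P_tot,
                            noiseless)
  }
  new_titration_dataset(do.call(rbind, rows), do.call(rbind, samples),
                        truth, design)
}

#' Generate a synthetic ligand-titration dataset
#'
#' For each saturation level, computes the total ligand concentration that
#' produces it at the design protein concentration (mass balance with the
#' ground-truth macroscopic Kd), simulates four-state dispersion curves for
#' every residue at the titration field, and adds seeded Gaussian noise.
#'
#' @inheritParams generate_apo_dataset
#' @param include_apo Also include the two-field apo curves in the dataset.
#' @return A `titration_dataset`.
#' @export
generate_titration_dataset <- function(design, truth = ground_truth(design),
                                       include_apo = FALSE,
                                       noiseless = FALSE) {
  Kd <- macroscopic_kd(truth$rates)
  rows <- list()
  samples <- list()
  if (include_apo) {
    apo <- generate_apo_dataset(design, truth, noiseless)
    rows[[1L]] <- apo$data
    samples[[1L]] <- apo$samples
  }
  for (i in seq_along(design$saturation_levels)) {
    sat <- design$saturation_levels[i]
    L_free <- free_ligand_at_saturation(Kd, sat)
    L_tot <- L_free + sat * design$P_tot
    sid <- sprintf("s%02d", i)
    samples[[length(samples) + 1L]] <-
      data.frame(sample_id = sid, field_T = design$titration_field,
                 P_tot_M = design$P_tot, L_tot_M = L_tot, saturation = sat)
    for (r in truth$shifts$residue)
      rows[[length(rows) + 1L]] <-
        simulate_curve_rows(truth, design, r, design$titration_field, sid,
                            L_free, L_tot, design$P_tot, noiseless)
  }
  new_titration_dataset(do.call(rbind, rows), do.call(rbind, samples),
                        truth, design)
}

#' Generate a synthetic two-state dataset (single exchange process)
#'
#' Utility generator for an isolated two-state process (e.g. the fast
#' exchange observed away from a binding site): per-residue shifts drawn as
#' in [ground_truth()], shared `k_ex` and `p_minor`, Bloch-McConnell
#' simulation and seeded noise.
#'
#' @param design A `study_design` (its fields, grid, noise and seed are
#'   used).
#' @param k_ex,p_minor Exchange parameters of the shared process.
#' @param dd_range Range of `|delta2 - delta1|` draws (ppm).
#' @param n_residues Number of residues; defaults to the design's.
#' @return A `titration_dataset` with apo-style samples.
#' @export
generate_two_state_dataset <- function(design, k_ex, p_minor,
                                       dd_range = c(1.5, 4),
                                       n_residues = design$n_residues) {
  set.seed(design$seed + 7L)
  res <- sprintf("res%02d", seq_len(n_residues))
  dd <- runif(n_residues, dd_range[1], dd_range[2])
  fields <- design$apo_fields
  R20 <- matrix(runif(n_residues * length(fields), 8, 15),
                n_residues, length(fields),
                dimnames = list(res, as.character(fields)))
  schedule <- cpmg_schedule(design$nu_cp, design$T_relax)
  rows <- list(); samples <- list()
  for (f in fields) {
    samples[[length(samples) + 1L]] <-
      data.frame(sample_id = "apo", field_T = f, P_tot_M = design$P_tot,
                 L_tot_M = 0, saturation = 0)
    fld <- field_config(f)
    for (j in seq_len(n_residues)) {
      pars <- two_state_params(k_ex, p_minor, ppm_to_omega(dd[j], fld),
                               R20[j, as.character(f)])
      M <- two_state_matrix(pars)
      curve <- simulate_dispersion2(M, c(1 - p_minor, p_minor), schedule)
      nz <- add_noise(curve$r2_s, design,
                      curve_seed(design$seed + 7L, res[j], f, -1))
      rows[[length(rows) + 1L]] <-
        data.frame(residue = res[j], field_T = f, sample_id = "apo",
                   nu_cp_hz = curve$nu_cp_hz, r2_s = nz$r2,
                   r2_err_s = nz$sd)
    }
  }
  truth <- list(k_ex = k_ex, p_minor = p_minor,
                dd = setNames(dd, res), R20 = R20)
  new_titration_dataset(do.call(rbind, rows), do.call(rbind, samples),
                        truth, design)
}

# two-state wrapper around the propagator (simulate_dispersion asserts its
# own class; this one skips the 4-state-specific pieces)
simulate_dispersion2 <- function(M, m0, schedule) {
  data.frame(nu_cp_hz = schedule$nu_cp,
             r2_s = bm_r2eff_cpp(M, m0, schedule$nu_cp, schedule$T_relax))
}

new_titration_dataset <- function(data, samples, truth, design) {
  rownames(data) <- NULL
  rownames(samples) <- NULL
  structure(list(data = data, samples = samples, truth = truth,
                 design = design),
            class = "titration_dataset")
}

#' @export
print.titration_dataset <- function(x, ...) {
  nc <- nrow(unique(x$data[c("residue", "field_T", "sample_id")]))
  cat(sprintf("Dispersion dataset: %d curves (%d residues, %d samples), %d points\n",
              nc, length(unique(x$data$residue)),
              nrow(x$samples), nrow(x$data)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Plain-text serialization

required_columns <- c("residue", "field_T", "sample_id", "nu_cp_hz",
                      "r2_s", "r2_err_s")

check_dispersion_columns <- function(data, residue_required = TRUE) {
  need <- c("nu_cp_hz", "r2_s", "r2_err_s", "field_T")
  if (residue_required) need <- c("residue", need)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("dispersion table is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(data$r2_err_s)) || any(data$r2_err_s <= 0))
    stop("r2_err_s must be positive")
  invisible(data)
}

#' Read / write dispersion tables
#'
#' Tab-separated tables with the header line
#' `residue field_T sample_id nu_cp_hz r2_s r2_err_s`; lines starting with
#' `#` are comments. Parse failures report the offending file and, where
#' possible, line.
#'
#' @param path File path.
#' @return `read_dispersion_tsv()`: a data frame with the six required
#'   columns.
#' @export
read_dispersion_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e)))
  miss <- setdiff(required_columns, names(tab))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         " (header line required)")
  num <- c("field_T", "nu_cp_hz", "r2_s", "r2_err_s")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (any(is.na(v) & !is.na(tab[[cn]]))) {
      bad <- which(is.na(v) & !is.na(tab[[cn]]))[1]
      stop(sprintf("%s: non-numeric value in column %s near data line %d",
                   path, cn, bad))
    }
    tab[[cn]] <- v
  }
  if (anyNA(tab[required_columns]))
    stop(path, ": missing values in required columns")
  tab
}

#' @rdname read_dispersion_tsv
#' @param data Dispersion table with the required columns.
#' @export
write_dispersion_tsv <- function(data, path) {
  check_dispersion_columns(data)
  write.table(data[required_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Save / load a dataset with its ground-truth sidecar
#'
#' `save_dataset()` writes the dispersion table as TSV plus a JSON sidecar
#' (`<stem>.json`) holding the sample metadata, the design, and - for
#' synthetic data - the ground truth. `load_dataset()` restores the
#' `titration_dataset`.
#'
#' @param dataset A `titration_dataset`.
#' @param stem Output path stem; writes `<stem>.tsv` and `<stem>.json`.
#' @return `save_dataset()`: the two paths, invisibly. `load_dataset()`: a
#'   `titration_dataset`.
#' @export
save_dataset <- function(dataset, stem) {
  stopifnot(inherits(dataset, "titration_dataset"))
  tsv <- paste0(stem, ".tsv")
  side <- paste0(stem, ".json")
  write_dispersion_tsv(dataset$data, tsv)
  truth <- dataset$truth
  side_obj <- list(samples = dataset$samples,
                   design = unclass(dataset$design))
  if (!is.null(truth)) {
    side_obj$truth <- serialize_truth(truth)
  }
  jsonlite::write_json(side_obj, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, sidecar = side))
}

serialize_truth <- function(truth) {
  if (inherits(truth, "ground_truth")) {
    list(kind = "four_state",
         params = unclass(truth$params),
         rates = unclass(truth$rates),
         shifts = truth$shifts,
         R20 = as.data.frame(truth$R20),
         R20_residues = rownames(truth$R20),
         delta_lac = as.list(truth$delta_lac))
  } else truth
}

#' @rdname save_dataset
#' @export
load_dataset <- function(stem) {
  tsv <- paste0(stem, ".tsv")
  side <- paste0(stem, ".json")
  data <- read_dispersion_tsv(tsv)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  design <- meta$design
  if (!is.null(design)) class(design) <- "study_design"
  truth <- meta$truth
  if (!is.null(truth) && identical(truth$kind, "four_state")) {
    params <- truth$params
    truth <- list(
      params = four_state_params(params$k_on, params$rho_off,
                                 params$rho_close, params$k12, params$k21,
                                 params$Kd_macro,
                                 convention = params$convention),
      rates = do.call(rate_constants,
                      c(truth$rates[c("k12", "k21", "k_on", "k_off3",
                                      "k_off4", "k34", "k43")],
                        list(balance_tol = 1e-6))),
      shifts = truth$shifts,
      R20 = {
        m <- as.matrix(truth$R20)
        rownames(m) <- truth$R20_residues
        m
      },
      delta_lac = unlist(truth$delta_lac))
    class(truth) <- "ground_truth"
  }
  new_titration_dataset(data, meta$samples, truth, design)
}
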