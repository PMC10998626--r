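#' Run configuration
#'
#' Pipelines are driven by a named list (or JSON file) of options. Unknown
#' fields are rejected to catch typos; all paths are interpreted relative to
#' the working directory. Units at the I/O boundary: rates s^-1 or
#' M^-1 s^-1, shifts ppm, fields T, concentrations M.
#'
#' @param path JSON file with configuration fields.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(cfg, source_path = path)
}

known_config_fields <- c(
  "seed", "out_dir", "mode", "design", "params", "dataset",
  "mc_replicates", "grids", "fixed", "saturation_grid", "P_tot", "plots")

#' @rdname read_run_config
#' @param cfg Named list of configuration fields.
#' @param source_path Optional path the config was read from (echoed into
#'   the log).
#' @export
as_run_config <- function(cfg, source_path = NULL) {
  bad <- setdiff(names(cfg), known_config_fields)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  defaults <- list(seed = 1L, out_dir = "csif_out", mode = "study",
                   mc_replicates = NULL, plots = FALSE)
  cfg <- modifyList(defaults, cfg)
  attr(cfg, "source_path") <- source_path
  class(cfg) <- "run_config"
  cfg
}

design_from_config <- function(cfg) {
  args <- cfg$design %||% list()
  args$seed <- cfg$seed
  do.call(study_design, args)
}

prepare_out_dir <- function(cfg, stage) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(cfg$out_dir, paste0(stage, "_config.json"))
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_path <- file.path(cfg$out_dir, paste0(stage, "_log.txt"))
  writeLines(c(
    sprintf("stage: %s", stage),
    sprintf("csif version: %s", as.character(packageVersion("csif"))),
    sprintf("seed: %s", cfg$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    log_path)
  invisible(log_path)
}

#' Simulate a synthetic study and write it to disk
#'
#' Generates the dataset described by the config (`mode` one of
#' `"apo"`, `"titration"`, `"study"` = titration plus apo) and writes
#' `dataset.tsv` / `dataset.json` plus a log into `out_dir`.
#'
#' @param cfg A `run_config` (or plain named list).
#' @return Paths of the written files, invisibly.
#' @export
run_simulate <- function(cfg) {
  cfg <- if (inherits(cfg, "run_config")) cfg else as_run_config(cfg)
  design <- design_from_config(cfg)
  params <- if (!is.null(cfg$params))
    do.call(four_state_params, cfg$params) else galectin_params()
  truth <- ground_truth(design, params)
  ds <- switch(cfg$mode,
    apo = generate_apo_dataset(design, truth),
    titration = generate_titration_dataset(design, truth),
    study = generate_titration_dataset(design, truth, include_apo = TRUE),
    stop("unknown mode: ", cfg$mode))
  prepare_out_dir(cfg, "simulate")
  paths <- save_dataset(ds, file.path(cfg$out_dir, "dataset"))
  invisible(paths)
}

write_parameter_table <- function(fit, path) {
  se <- fit$se
  tab <- data.frame(parameter = names(fit$par),
                    value = unlist(fit$par),
                    sd = if (is.null(se)) NA_real_
                         else unlist(se)[names(fit$par)],
                    row.names = NULL)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Two-state analysis pipeline for apo data
#'
#' Loads the dataset (`cfg$dataset` path stem), runs the global two-state
#' fit across all residues, estimates Monte-Carlo errors, and writes a
#' parameter table, a text report, and optionally residual plots.
#'
#' @param cfg A `run_config`; uses `dataset`, `out_dir`, `seed`,
#'   `mc_replicates` (default 1000), `plots`.
#' @return The fitted `csif_fit`, invisibly.
#' @export
run_fit_apo <- function(cfg) {
  cfg <- if (inherits(cfg, "run_config")) cfg else as_run_config(cfg)
  ds <- load_dataset(cfg$dataset)
  fit <- fit_two_state_global(ds$data)
  fit <- monte_carlo_errors(fit, n_replicates = cfg$mc_replicates %||% 1000,
                            seed = cfg$seed)
  prepare_out_dir(cfg, "fit_apo")
  write_parameter_table(fit, file.path(cfg$out_dir, "apo_parameters.tsv"))
  k12 <- fit$par$p_minor * fit$par$k_ex
  rpt <- c(sprintf("global two-state fit: chi2 = %.4g, dof = %d",
                   fit$chi2, fit$dof),
           sprintf("k_ex = %.4g s^-1, p_minor = %.4g", fit$par$k_ex,
                   fit$par$p_minor),
           sprintf("k12 = p_minor * k_ex = %.4g s^-1, k21 = %.4g s^-1",
                   k12, fit$par$k_ex - k12),
           sprintf("converged: %s", fit$converged))
  writeLines(rpt, file.path(cfg$out_dir, "apo_report.txt"))
  if (isTRUE(cfg$plots))
    plot_dispersion_fit(fit, file.path(cfg$out_dir, "apo_fit.pdf"))
  invisible(fit)
}

#' Four-state analysis pipeline for a titration
#'
#' Loads the dataset, runs the grid search and the global four-state fit,
#' estimates Monte-Carlo errors, and writes the parameter table, the derived
#' rate-constant table, and a report. Fixed inputs (`k12`, `k21`,
#' `Kd_macro`, per-residue `delta1`, `delta_lac`) come from `cfg$fixed` or,
#' for synthetic data, from the dataset's ground-truth sidecar.
#'
#' @param cfg A `run_config`; uses `dataset`, `out_dir`, `seed`, `grids`,
#'   `mc_replicates` (default 500), `plots`.
#' @return The fitted `csif_fit`, invisibly.
#' @export
run_fit_global <- function(cfg) {
  cfg <- if (inherits(cfg, "run_config")) cfg else as_run_config(cfg)
  ds <- load_dataset(cfg$dataset)
  fixed <- cfg$fixed %||% fixed_from_truth(ds$truth)
  grids <- if (!is.null(cfg$grids)) do.call(default_grids, cfg$grids)
           else default_grids()
  gs <- grid_search_four_state(ds, fixed, grids)
  fit <- fit_four_state_global(ds, fixed, start = grid_top_starts(gs, 3))
  fit <- monte_carlo_errors(fit, n_replicates = cfg$mc_replicates %||% 500,
                            seed = cfg$seed)
  prepare_out_dir(cfg, "fit_global")
  write_parameter_table(fit, file.path(cfg$out_dir, "global_parameters.tsv"))
  rt <- fit$rates
  rate_tab <- data.frame(
    rate = c("k12", "k21", "k_on", "k_off3", "k_off4", "k34", "k43"),
    value = c(rt$k12, rt$k21, rt$k_on, rt$k_off3, rt$k_off4, rt$k34, rt$k43),
    unit = c(rep("s^-1", 2), "M^-1 s^-1", rep("s^-1", 4)),
    fixed = c(TRUE, TRUE, FALSE, rep(FALSE, 4)))
  write.table(rate_tab, file.path(cfg$out_dir, "rate_constants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    sprintf("four-state global fit: chi2 = %.4g, dof = %d", fit$chi2, fit$dof),
    sprintf("k_on = %.4g M^-1 s^-1, rho_off = %.4g, rho_close = %.4g",
            fit$par$k_on, fit$par$rho_off, fit$par$rho_close),
    sprintf("converged: %s (%s)", fit$converged, fit$message)),
    file.path(cfg$out_dir, "global_report.txt"))
  if (isTRUE(cfg$plots))
    plot_dispersion_fit(fit, file.path(cfg$out_dir, "global_fit.pdf"))
  invisible(fit)
}

fixed_from_truth <- function(truth) {
  if (is.null(truth) || !inherits(truth, "ground_truth"))
    stop("no fixed parameters in config and no ground-truth sidecar")
  res <- truth$shifts$residue
  list(k12 = truth$params$k12, k21 = truth$params$k21,
       Kd_macro = truth$params$Kd_macro,
       delta1 = setNames(as.list(truth$shifts$delta1), res),
       delta_lac = as.list(truth$delta_lac))
}

#' Flux and population report over a saturation grid
#'
#' Tabulates equilibrium populations, pathway fluxes, and the IF flux share
#' over a saturation grid for a set of rate constants, reports the CS-to-IF
#' crossover concentration if one exists, and optionally plots the curves.
#'
#' @param rates A `rate_constants` object (e.g. from [galectin_rates()] or a
#'   four-state fit).
#' @param saturations Saturation grid in `[0, 1)`.
#' @param P_tot Total protein concentration (M).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param plots Write a population/flux plot.
#' @return A list with the `table` (data frame) and `crossover_M`.
#' @export
run_flux <- function(rates, saturations = seq(0, 0.9, by = 0.01),
                     P_tot = 0.5e-3, out_dir = NULL, plots = FALSE) {
  stopifnot(inherits(rates, "rate_constants"))
  Kd <- macroscopic_kd(rates)
  rows <- lapply(saturations, function(sat) {
    L <- free_ligand_at_saturation(Kd, sat)
    pops <- equilibrium_populations(rates, L)
    fl <- pathway_fluxes(rates, pops, P_tot)
    data.frame(saturation = sat, L_free_M = L, p1 = pops$p1, p2 = pops$p2,
               p3 = pops$p3, p4 = pops$p4, F_CS = fl$F_CS, F_IF = fl$F_IF,
               frac_IF = fl$frac_IF)
  })
  tab <- do.call(rbind, rows)
  cross <- flux_crossover(rates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(tab, file.path(out_dir, "flux_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(sprintf("CS->IF crossover: %s",
                       ifelse(is.na(cross), "none",
                              sprintf("%.4g M free ligand", cross))),
               file.path(out_dir, "flux_report.txt"))
    if (isTRUE(plots))
      plot_flux_populations(tab, file.path(out_dir, "flux.pdf"))
  }
  list(table = tab, crossover_M = cross)
}

#' Diagnostic plots
#'
#' `plot_dispersion_fit()` draws observed versus fitted dispersion curves,
#' one panel per curve; `plot_flux_populations()` draws state populations
#' and the IF flux fraction versus saturation. Both write PDF files so the
#' pipelines run headless.
#'
#' @param fit A `csif_fit` with fitted values.
#' @param path Output PDF path.
#' @return The path, invisibly.
#' @export
plot_dispersion_fit <- function(fit, path) {
  stopifnot(inherits(fit, "csif_fit"), !is.null(fit$fitted))
  d <- fit$fitted
  key <- interaction(d$residue, d$field_T, d$sample_id, drop = TRUE)
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  for (k in levels(key)) {
    g <- d[key == k, ]
    graphics::plot(g$nu_cp_hz, g$r2_s, pch = 16, cex = 0.7,
                   xlab = expression(nu[cp] ~ "(Hz)"),
                   ylab = expression(R[2] ~ (s^-1)), main = k)
    graphics::arrows(g$nu_cp_hz, g$r2_s - g$r2_err_s, g$nu_cp_hz,
                     g$r2_s + g$r2_err_s, angle = 90, code = 3,
                     length = 0.02)
    graphics::lines(g$nu_cp_hz[order(g$nu_cp_hz)],
                    g$r2_fit[order(g$nu_cp_hz)], col = 2)
  }
  invisible(path)
}

#' @rdname plot_dispersion_fit
#' @param flux_table Table from [run_flux()].
#' @export
plot_flux_populations <- function(flux_table, path) {
  grDevices::pdf(path, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  graphics::matplot(flux_table$saturation,
                    flux_table[, c("p1", "p2", "p3", "p4")], type = "l",
                    lty = 1, xlab = "saturation", ylab = "population")
  graphics::legend("right", legend = paste0("p", 1:4), col = 1:4, lty = 1)
  graphics::plot(flux_table$saturation, flux_table$frac_IF, type = "l",
                 xlab = "saturation", ylab = "IF flux fraction")
  invisible(path)
}
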