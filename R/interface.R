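#' Load a run configuration
#'
#' Run configurations are YAML documents (schema version 1) binding the
#' pipeline stages together. Sections:
#' \describe{
#'   \item{mode}{`simulate`, `fit`, `generate` or `validate`.}
#'   \item{drug}{either `builtin: besifloxacin` or the full argument list
#'     of [drug_parameters()].}
#'   \item{formulation}{either `builtin: besivance` (+ optional
#'     `dosage_mode`) or the argument list of [formulation_spec()].}
#'   \item{physiology}{`species` plus optional `overrides` for
#'     [builtin_physiology()].}
#'   \item{protocol}{`times` (h) and optional `volume` (uL) /
#'     `strength` (mg/mL).}
#'   \item{solver}{optional `t_end`, `n_out`, `rtol`, `atol`.}
#'   \item{seed}{integer used by every stochastic stage.}
#'   \item{fit / generate / validate}{mode-specific sections, see the
#'     bundled example configs under `system.file("configs",
#'     package = "oculopk")`.}
#' }
#' Validation problems are aggregated into a single error naming every
#' missing or malformed section.
#'
#' @param path Path to a YAML configuration.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$.path <- path
  problems <- character(0)
  need <- function(section) {
    if (is.null(cfg[[section]])) {
      problems <<- c(problems, paste0("missing required section: ", section))
      FALSE
    } else TRUE
  }
  need("mode")
  if (!is.null(cfg$mode) &&
      !cfg$mode %in% c("simulate", "fit", "generate", "validate")) {
    problems <- c(problems, paste0("unknown mode: ", cfg$mode))
  }
  for (s in c("drug", "formulation", "physiology", "protocol")) need(s)
  if (identical(cfg$mode, "fit") && is.null(cfg$fit)) {
    problems <- c(problems, "missing required section: fit (fit mode)")
  }
  if (identical(cfg$mode, "generate") && is.null(cfg$generate)) {
    problems <- c(problems, "missing required section: generate (generate mode)")
  }
  if (identical(cfg$mode, "validate") && is.null(cfg$validate)) {
    problems <- c(problems, "missing required section: validate (validate mode)")
  }
  if (length(problems) > 0) {
    stop("invalid run configuration (", path, "):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

config_drug <- function(cfg) {
  d <- cfg$drug
  if (!is.null(d$builtin)) {
    if (d$builtin != "besifloxacin") {
      stop("unknown builtin drug: ", d$builtin, call. = FALSE)
    }
    drug <- besifloxacin_parameters()
    for (nm in setdiff(names(d), "builtin")) drug[[nm]] <- d[[nm]]
    validate_drug_parameters(drug)
    return(drug)
  }
  d$tissue_permeabilities <- unlist(d$tissue_permeabilities)
  d$systemic_absorption_rates <- unlist(d$systemic_absorption_rates)
  do.call(drug_parameters, d)
}

config_formulation <- function(cfg) {
  f <- cfg$formulation
  if (!is.null(f$builtin)) {
    if (f$builtin != "besivance") {
      stop("unknown builtin formulation: ", f$builtin, call. = FALSE)
    }
    mode <- if (is.null(f$dosage_mode)) "mixed_solution_cr" else f$dosage_mode
    return(besivance_formulation(mode))
  }
  do.call(formulation_spec, f)
}

config_physiology <- function(cfg) {
  p <- cfg$physiology
  builtin_physiology(p$species, overrides = p$overrides)
}

config_protocol <- function(cfg, formulation) {
  pr <- cfg$protocol
  dosing_protocol(
    times = unlist(pr$times),
    formulation = formulation,
    volume = if (is.null(pr$volume)) formulation$drop_volume else pr$volume,
    strength = if (is.null(pr$strength)) formulation$strength else pr$strength
  )
}

config_solver <- function(cfg) {
  s <- if (is.null(cfg$solver)) list() else cfg$solver
  list(
    t_end = if (is.null(s$t_end)) 24 else s$t_end,
    n_out = if (is.null(s$n_out)) 241 else s$n_out,
    rtol = if (is.null(s$rtol)) 1e-8 else s$rtol,
    atol = if (is.null(s$atol)) 1e-12 else s$atol
  )
}

write_run_log <- function(path, cfg, sim = NULL, extra = list()) {
  lines <- c(
    paste0("oculopk run log"),
    paste0("config: ", cfg$.path),
    paste0("mode: ", cfg$mode),
    paste0("config_checksum: ",
           paste(utils::head(strsplit(digest_file(cfg$.path), "")[[1]], 16),
                 collapse = ""))
  )
  if (!is.null(sim)) {
    g <- glance(sim)
    lines <- c(lines,
               sprintf("species: %s", g$species),
               sprintf("dose_total_ug: %.6g", g$dose_total),
               sprintf("n_doses: %d", g$n_doses),
               sprintf("max_mass_balance_error: %.3e", g$max_balance_error),
               sprintf("weibull: Max=%s A=%s b=%s",
                       format(sim$formulation$weibull$Max %||% NA),
                       format(sim$formulation$weibull$A %||% NA),
                       format(sim$formulation$weibull$b %||% NA)))
  }
  for (nm in names(extra)) {
    lines <- c(lines, paste0(nm, ": ", format(extra[[nm]])))
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# order-insensitive content fingerprint (sum of char codes per line,
# folded) — enough to tie a run log to the config text it used.
digest_file <- function(path) {
  txt <- readLines(path, warn = FALSE)
  acc <- 0
  for (ln in txt) {
    acc <- (acc * 31 + sum(utf8ToInt(ln)) + nchar(ln)) %% 2^31
  }
  sprintf("%08x%08x", acc, sum(nchar(txt)) %% 2^31)
}

#' Run a configured simulation
#'
#' Executes one simulation described by a run configuration and writes the
#' tidy trajectory (`<prefix>_trajectories.tsv`: time, compartment,
#' amount, concentration), the effective physiology table
#' (`<prefix>_physiology.tsv`) and a run log with the parameter echo and
#' mass-balance report (`<prefix>_run.log`). Outputs are deterministic
#' given the config.
#'
#' @param config Path to a YAML config or a `run_config`.
#' @param out_dir Output directory (created if needed).
#' @param prefix Output file prefix (default: config file stem).
#' @return The `ocular_simulation`, invisibly; the written file paths in
#'   attribute `"files"`.
#' @export
run_simulate <- function(config, out_dir = ".", prefix = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  drug <- config_drug(cfg)
  formulation <- config_formulation(cfg)
  physiology <- config_physiology(cfg)
  protocol <- config_protocol(cfg, formulation)
  sv <- config_solver(cfg)

  sim <- simulate_ocular(drug, formulation, physiology, protocol,
                         t_end = sv$t_end, n_out = sv$n_out,
                         rtol = sv$rtol, atol = sv$atol)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- sub("\\.ya?ml$", "", basename(cfg$.path))
  f_traj <- file.path(out_dir, paste0(prefix, "_trajectories.tsv"))
  f_phys <- file.path(out_dir, paste0(prefix, "_physiology.tsv"))
  f_log <- file.path(out_dir, paste0(prefix, "_run.log"))
  utils::write.table(tidy(sim), f_traj, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(tidy(physiology), f_phys, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_run_log(f_log, cfg, sim)
  attr(sim, "files") <- c(f_traj, f_phys, f_log)
  invisible(sim)
}

#' Run a configured parameter fit
#'
#' The `fit` section supplies `parameters` (list of `name`, `initial`,
#' `lower`, `upper`, optional `log_scale`), `data` (paths to observed
#' dataset files, relative to the config), and optional `objective`,
#' `n_starts`. Writes the estimate table (`<prefix>_estimates.tsv`) and a
#' run log.
#'
#' @inheritParams run_simulate
#' @return The `ocular_fit`, invisibly.
#' @export
run_fit <- function(config, out_dir = ".", prefix = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  drug <- config_drug(cfg)
  formulation <- config_formulation(cfg)
  physiology <- config_physiology(cfg)
  protocol <- config_protocol(cfg, formulation)
  sv <- config_solver(cfg)

  fp <- dplyr::bind_rows(lapply(cfg$fit$parameters, tibble::as_tibble))
  datasets <- lapply(cfg$fit$data, function(rel) {
    read_observed_dataset(file.path(dirname(cfg$.path), rel))
  })
  prob <- fit_problem(
    fp, datasets, drug, formulation, physiology, protocol,
    objective = cfg$fit$objective %||% "log_wls",
    t_end = sv$t_end, n_out = sv$n_out)
  fit <- fit_model(prob,
                   n_starts = cfg$fit$n_starts %||% 5,
                   seed = cfg$seed %||% 1)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- sub("\\.ya?ml$", "", basename(cfg$.path))
  f_est <- file.path(out_dir, paste0(prefix, "_estimates.tsv"))
  f_log <- file.path(out_dir, paste0(prefix, "_run.log"))
  utils::write.table(tidy(fit), f_est, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_run_log(f_log, cfg, extra = list(
    objective = fit$objective, converged = fit$converged,
    seed = fit$audit$seed, n_evals = fit$audit$n_evals))
  attr(fit, "files") <- c(f_est, f_log)
  invisible(fit)
}

#' Run a configured synthetic-study generation
#'
#' The `generate` section supplies `timepoints`, `tissues`, `cv`,
#' `n_subjects`, optional `sampling` and `study_code`. Writes the dataset
#' (`<prefix>_observed.tsv`) and a run log.
#'
#' @inheritParams run_simulate
#' @return The dataset tibble, invisibly.
#' @export
run_generate <- function(config, out_dir = ".", prefix = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  g <- cfg$generate
  ds <- generate_study(
    config_drug(cfg), config_formulation(cfg), config_physiology(cfg),
    config_protocol(cfg, config_formulation(cfg)),
    timepoints = unlist(g$timepoints),
    tissues = unlist(g$tissues),
    noise = noise_model(cv = g$cv %||% 0.3,
                        n_subjects_per_timepoint = g$n_subjects %||% 4,
                        sampling = g$sampling %||% "destructive"),
    seed = cfg$seed %||% 1,
    study_code = g$study_code %||% "synthetic")

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- sub("\\.ya?ml$", "", basename(cfg$.path))
  f_obs <- file.path(out_dir, paste0(prefix, "_observed.tsv"))
  f_log <- file.path(out_dir, paste0(prefix, "_run.log"))
  write_observed_dataset(ds, f_obs)
  write_run_log(f_log, cfg, extra = list(
    seed = cfg$seed %||% 1, n_rows = nrow(ds)))
  attr(ds, "files") <- c(f_obs, f_log)
  invisible(ds)
}

#' Run a configured simulation-vs-observation validation
#'
#' The `validate` section supplies `data` (observed dataset paths) and
#' optional `fold_threshold` (default 3). Each observed tissue profile is
#' compared against the simulated profile at the observed times; the
#' per-study/tissue PK metrics and fold-error summaries are written to
#' `<prefix>_validation.tsv`.
#'
#' @inheritParams run_simulate
#' @return The validation tibble, invisibly.
#' @export
run_validate <- function(config, out_dir = ".", prefix = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  sim <- local({
    drug <- config_drug(cfg)
    formulation <- config_formulation(cfg)
    physiology <- config_physiology(cfg)
    sv <- config_solver(cfg)
    simulate_ocular(drug, formulation, physiology,
                    config_protocol(cfg, formulation),
                    t_end = sv$t_end, n_out = sv$n_out)
  })
  k <- cfg$validate$fold_threshold %||% 3

  rows <- list()
  for (rel in cfg$validate$data) {
    obs <- read_observed_dataset(file.path(dirname(cfg$.path), rel))
    for (tt in unique(obs$tissue)) {
      ds <- obs[obs$tissue == tt, ]
      prof <- tissue_concentration(sim, tt)
      pred <- stats::approx(prof$time, prof$conc, xout = ds$time, rule = 2)$y
      fe <- fold_error(pred, ds$mean_conc, k = k)
      met_obs <- compute_pk_metrics(ds, tt)
      met_sim <- compute_pk_metrics(
        tibble::tibble(time = ds$time, conc = pred))
      rows[[length(rows) + 1]] <- tibble::tibble(
        study_code = ds$study_code[1], tissue = tt,
        n_obs = nrow(ds),
        cmax_obs = met_obs$cmax, cmax_sim = met_sim$cmax,
        auc_obs = met_obs$auc_0_t, auc_sim = met_sim$auc_0_t,
        geomean_fold = fe$summary$geomean_fold,
        max_fold = fe$summary$max_fold,
        within_k_fold = fe$summary$within_k_fold, k = k)
    }
  }
  out <- dplyr::bind_rows(rows)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- sub("\\.ya?ml$", "", basename(cfg$.path))
  f_val <- file.path(out_dir, paste0(prefix, "_validation.tsv"))
  f_log <- file.path(out_dir, paste0(prefix, "_run.log"))
  utils::write.table(out, f_val, sep = "\t", row.names = FALSE, quote = FALSE)
  write_run_log(f_log, cfg, sim)
  attr(out, "files") <- c(f_val, f_log)
  invisible(out)
}
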