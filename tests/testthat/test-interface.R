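bundled_config <- function(name) {
  system.file("configs", name, package = "oculopk", mustWork = TRUE)
}

test_that("bundled single-dose config runs end-to-end and writes tidy output", {
  out <- withr::local_tempdir()
  sim <- run_simulate(bundled_config("Bes.NZ.1.yaml"), out_dir = out)
  files <- attr(sim, "files")
  expect_true(all(file.exists(files)))
  traj <- read.delim(files[1])
  expect_true(all(c("time", "compartment", "amount", "concentration") %in%
                    names(traj)))
  log_txt <- readLines(files[3])
  expect_true(any(grepl("mass_balance_error", log_txt)))
  expect_true(any(grepl("Weibull|weibull", log_txt)))
})

test_that("identical configs produce byte-identical data outputs", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  s1 <- run_simulate(bundled_config("Bes.NZ.1.yaml"), out_dir = out1)
  s2 <- run_simulate(bundled_config("Bes.NZ.1.yaml"), out_dir = out2)
  f1 <- attr(s1, "files")[1]
  f2 <- attr(s2, "files")[1]
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every bundled protocol satisfies mass balance", {
  configs <- list.files(system.file("configs", package = "oculopk"),
                        full.names = TRUE)
  expect_length(configs, 8)
  out <- withr::local_tempdir()
  for (cfg in configs) {
    sim <- run_simulate(cfg, out_dir = out)
    expect_lt(max(sim$states$balance_error), 1e-6)
  }
})

test_that("the repeated-administration config encodes four drops 10 min apart", {
  cfg <- read_run_config(bundled_config("Bes.Hum.4.yaml"))
  times_h <- unlist(cfg$protocol$times)
  expect_length(times_h, 4)
  expect_equal(diff(times_h) * 60, rep(10, 3), tolerance = 1e-6)
  expect_equal(cfg$protocol$volume, 50)
  expect_equal(cfg$protocol$strength, 6)
})

test_that("config validation aggregates missing sections by name", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("mode: fit", "drug:", "  builtin: besifloxacin"), path)
  err <- tryCatch(read_run_config(path), error = function(e) conditionMessage(e))
  expect_match(err, "formulation")
  expect_match(err, "physiology")
  expect_match(err, "protocol")
  expect_match(err, "fit \\(fit mode\\)")
  expect_error(read_run_config(tempfile()), "not found")
})

test_that("generate -> fit round trip recovers the generating Weibull", {
  out <- withr::local_tempdir()
  gen_cfg <- file.path(out, "gen.yaml")
  writeLines(c(
    "schema_version: 1", "mode: generate", "seed: 4",
    "drug: {builtin: besifloxacin}",
    "formulation: {builtin: besivance}",
    "physiology: {species: NZ_rabbit}",
    "protocol: {times: [0]}",
    "solver: {t_end: 24}",
    "generate:",
    "  timepoints: [0.5, 1, 2, 4, 8, 12, 18, 24]",
    "  tissues: [cornea]",
    "  cv: 0",
    "  n_subjects: 1"), gen_cfg)
  ds <- run_generate(gen_cfg, out_dir = out)
  obs_file <- attr(ds, "files")[1]

  fit_cfg <- file.path(out, "fit.yaml")
  writeLines(c(
    "schema_version: 1", "mode: fit", "seed: 4",
    "drug: {builtin: besifloxacin}",
    "formulation: {builtin: besivance}",
    "physiology: {species: NZ_rabbit}",
    "protocol: {times: [0]}",
    "solver: {t_end: 24}",
    "fit:",
    "  n_starts: 1",
    "  parameters:",
    "    - name: weibull.Max",
    "      initial: 35",
    "      lower: 5",
    "      upper: 80",
    "      log_scale: yes",
    paste0("  data: [", basename(obs_file), "]")), fit_cfg)
  fit <- run_fit(fit_cfg, out_dir = out)
  expect_true(fit$converged)
  expect_equal(fit$estimates$estimate[1], 25.47, tolerance = 5e-3)
  est_file <- attr(fit, "files")[1]
  expect_true(file.exists(est_file))
})

test_that("validating a simulation against its own zero-noise sampling gives fold 1", {
  out <- withr::local_tempdir()
  ds <- generate_study(bes_drug(), bes_cr(), human_phys(),
                       timepoints = c(0.5, 1, 2, 4, 8),
                       tissues = c("tears", "aqueous_humor"),
                       noise = noise_model(cv = 0,
                                           n_subjects_per_timepoint = 1),
                       seed = 1)
  obs_file <- file.path(out, "obs.tsv")
  write_observed_dataset(ds, obs_file)
  val_cfg <- file.path(out, "val.yaml")
  writeLines(c(
    "schema_version: 1", "mode: validate", "seed: 1",
    "drug: {builtin: besifloxacin}",
    "formulation: {builtin: besivance}",
    "physiology: {species: human}",
    "protocol: {times: [0]}",
    "solver: {t_end: 24}",
    "validate: {data: [obs.tsv]}"), val_cfg)
  rep <- run_validate(val_cfg, out_dir = out)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$geomean_fold, rep(1, 2), tolerance = 1e-6)
  expect_equal(rep$max_fold, rep(1, 2), tolerance = 1e-6)
  expect_true(all(rep$within_k_fold))
})
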