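weibull_truth <- list(Max = 25.47, A = 11.93, b = 0.88)

noiseless_release <- function(n = 25, t_max = 48) {
  t <- seq(0, t_max, length.out = n)
  tibble::tibble(time = t,
                 mean_conc = weibull_fraction_released(
                   t, weibull_truth$Max, weibull_truth$A, weibull_truth$b))
}

test_that("objective is zero at a perfect fit and counts log residuals", {
  ds <- noiseless_release()
  ds_full <- tibble::tibble(study_code = "x", species_label = "NA",
                            tissue = "cr_release", time = ds$time,
                            mean_conc = ds$mean_conc, sd = 0, n = 1L)
  fp <- tibble::tibble(name = c("weibull.Max", "weibull.A", "weibull.b"),
                       initial = c(25.47, 11.93, 0.88),
                       lower = c(1, 0.1, 0.1), upper = c(100, 100, 5))
  prob <- fit_problem(fp, list(ds_full), bes_drug(), bes_cr(), rabbit_phys(),
                      conc_floor = 1e-8)
  truth <- c(weibull.Max = 25.47, weibull.A = 11.93, weibull.b = 0.88)
  expect_equal(objective_value(truth, prob), 0, tolerance = 1e-12)

  # one observation off by a factor of e contributes exactly 1
  ds_off <- ds_full
  ds_off$mean_conc[10] <- ds_off$mean_conc[10] * exp(1)
  prob_off <- fit_problem(fp, list(ds_off), bes_drug(), bes_cr(),
                          rabbit_phys(), conc_floor = 1e-8)
  expect_equal(objective_value(truth, prob_off), 1, tolerance = 1e-10)
})

test_that("three-parameter Weibull fit recovers the generating triplet", {
  fit <- fit_weibull_release(
    noiseless_release(),
    initial = c(Max = 25.47 * 1.5, A = 11.93 * 1.5, b = 0.88 * 1.5),
    n_starts = 5, seed = 1)
  est <- setNames(fit$estimates$estimate, fit$estimates$name)
  expect_true(fit$converged)
  expect_equal(est[["weibull.Max"]], 25.47, tolerance = 5e-3)
  expect_equal(est[["weibull.A"]], 11.93, tolerance = 5e-3)
  expect_equal(est[["weibull.b"]], 0.88, tolerance = 5e-3)
  expect_lt(fit$objective, 1e-8)
})

test_that("fits are reproducible bit-for-bit given the seed", {
  f1 <- fit_weibull_release(noiseless_release(n = 12), n_starts = 3, seed = 9)
  f2 <- fit_weibull_release(noiseless_release(n = 12), n_starts = 3, seed = 9)
  expect_identical(f1$estimates$estimate, f2$estimates$estimate)
  expect_identical(f1$objective, f2$objective)
})

test_that("starting at the truth converges immediately", {
  fit <- fit_weibull_release(
    noiseless_release(n = 12),
    initial = c(Max = 25.47, A = 11.93, b = 0.88), n_starts = 1, seed = 1)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-10)
  expect_lte(fit$objective, fit$objective_at_initial)
})

test_that("single-parameter permeability fit recovers the generating value", {
  truth <- 1e-7
  obs <- generate_study(
    bes_drug(), bes_cr(), rabbit_phys(),
    timepoints = c(0.5, 1, 2, 4, 8, 12, 18, 24), tissues = "cornea",
    noise = noise_model(cv = 0, n_subjects_per_timepoint = 1), seed = 1)
  fp <- tibble::tibble(name = "perm.cornea_epithelium",
                       initial = 3 * truth, lower = 1e-9, upper = 1e-5,
                       log_scale = TRUE)
  prob <- fit_problem(fp, list(obs), bes_drug(), bes_cr(), rabbit_phys())
  fit <- fit_model(prob, n_starts = 1, seed = 1)
  est <- fit$estimates$estimate[1]
  expect_true(fit$converged)
  expect_equal(est, truth, tolerance = 1e-2)
})

test_that("fit problems validate bounds and tissue mapping", {
  fp_bad <- tibble::tibble(name = "weibull.Max", initial = 200,
                           lower = 1, upper = 100)
  expect_error(fit_problem(fp_bad, list(), bes_drug(), bes_cr(),
                           rabbit_phys()), "outside bounds")
  ds <- tibble::tibble(study_code = "x", species_label = "NZ_rabbit",
                       tissue = "spleen", time = 1, mean_conc = 1,
                       sd = 0, n = 1L)
  fp <- tibble::tibble(name = "weibull.Max", initial = 25,
                       lower = 1, upper = 100)
  expect_error(fit_problem(fp, list(ds), bes_drug(), bes_cr(), rabbit_phys()),
               "does not map")
})

test_that("objective returns a large finite penalty when simulation fails", {
  ds <- tibble::tibble(study_code = "x", species_label = "NZ_rabbit",
                       tissue = "cornea", time = c(1, 2),
                       mean_conc = c(1, 0.5), sd = 0, n = 1L)
  fp <- tibble::tibble(name = "dissolved_fraction", initial = 0.5,
                       lower = 0, upper = 5) # upper > 1 allows invalid values
  prob <- fit_problem(fp, list(ds), bes_drug(), bes_cr(), rabbit_phys())
  val <- objective_value(c(dissolved_fraction = 4), prob)
  expect_true(is.finite(val))
  expect_gte(val, 1e9)
})
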