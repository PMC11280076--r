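test_that("dose events retain the volume-limited fraction and spill the rest", {
  phys <- rabbit_phys()
  form <- bes_cr()
  y <- stats::setNames(numeric(length(oculopk:::state_names())),
                       oculopk:::state_names())
  y[["precornea_volume"]] <- phys$tear_volume / 1000

  upd <- apply_dose_event(y, list(volume = 50, strength = 6), phys, form)
  expect_equal(upd$dose, 300)
  st <- upd$state
  expect_equal(st[["precornea_volume"]], 35 / 1000)
  retained <- st[["precornea_dissolved"]] + st[["precornea_solid"]] +
    st[["cr_depot"]]
  expect_equal(retained, 300 * 0.6) # phi = 30/50
  expect_equal(st[["spillage_loss"]], 300 * 0.4)

  # human at baseline: same retained fraction
  hu <- human_phys()
  y[["precornea_volume"]] <- hu$tear_volume / 1000
  st_h <- apply_dose_event(y, list(volume = 50, strength = 6), hu, form)$state
  expect_equal(st_h[["spillage_loss"]] / 300, 0.4)

  # a 30 uL drop exactly fills the allowance: nothing spills
  y[["precornea_volume"]] <- phys$tear_volume / 1000
  st30 <- apply_dose_event(y, list(volume = 30, strength = 6), phys, form)$state
  expect_equal(st30[["spillage_loss"]], 0)
})

test_that("pre-corneal excess volume decays with a 6.93 min half-life", {
  sim <- single_dose_sim(t_end = 2, n_out = 601)
  vol_uL <- sim$states$precornea_volume * 1000
  t_half <- log(2) / (0.1 * 60) # h; = 6.93 min
  v_at_half <- approx(sim$states$time, vol_uL, xout = t_half)$y
  expect_equal(v_at_half, 5 + 30 / 2, tolerance = 1e-4)
  # closed form along the whole grid
  expect_equal(vol_uL, 5 + 30 * exp(-6 * sim$states$time), tolerance = 1e-6)
  expect_true(all(vol_uL <= 35 + 1e-9))
  expect_true(all(diff(vol_uL) <= 1e-12))
})

test_that("mass balance and non-negativity hold for both dosage modes and species", {
  for (sim in list(single_dose_sim(bes_cr(), rabbit_phys()),
                   single_dose_sim(bes_susp(), rabbit_phys()),
                   single_dose_sim(bes_cr(), human_phys()))) {
    expect_lt(max(sim$states$balance_error), 1e-6)
    amt_cols <- c("precornea_dissolved", "precornea_solid",
                  ocular_compartments(), "nasolacrimal_gi_depot",
                  "systemic", "cr_depot")
    expect_true(all(as.matrix(sim$states[amt_cols]) > -1e-9))
  }
})

test_that("CR depots release per the Weibull clock, locked remainder stays", {
  sim <- single_dose_sim(t_end = 24)
  depot0 <- sim$cr_schedule$amount
  expect_equal(depot0, 300 * 0.6 * (1 - 1 / 6), tolerance = 1e-9) # 249.9 * phi
  last <- sim$states[nrow(sim$states), ]
  released_pct <- last$cr_released_cum / depot0 * 100
  expect_equal(released_pct, weibull_fraction_released(24, 25.47, 11.93, 0.88),
               tolerance = 1e-4)
  # the never-released balance is still booked in the depot
  expect_equal(last$cr_depot + last$cr_released_cum, depot0, tolerance = 1e-6)
})

test_that("repeated human dosing piles volume up to the pre-corneal maximum", {
  form <- bes_cr()
  protocol <- dosing_protocol(c(0, 10, 20, 30) / 60, form)
  sim <- simulate_ocular(bes_drug(), form, human_phys(), protocol,
                         t_end = 12)
  expect_equal(sim$dose_total, 1200)
  expect_equal(nrow(sim$cr_schedule), 4)
  expect_lt(max(sim$states$balance_error), 1e-6)
  expect_true(all(sim$states$precornea_volume <= 37 / 1000 + 1e-12))
  # later drops land on a still-swollen surface, so spill more
  expect_gt(sim$states$spillage_loss[nrow(sim$states)], 1200 * 0.4)
})

test_that("fully dissolved dosing is linear in dose", {
  f1 <- solution_formulation()
  sim1 <- simulate_ocular(bes_drug(), f1, rabbit_phys(),
                          dosing_protocol(0, f1), t_end = 12)
  f2 <- solution_formulation(strength = 12)
  sim2 <- simulate_ocular(bes_drug(), f2, rabbit_phys(),
                          dosing_protocol(0, f2), t_end = 12)
  amt_cols <- c("precornea_dissolved", ocular_compartments(),
                "nasolacrimal_gi_depot", "systemic",
                "systemic_cleared", "gi_unabsorbed")
  a1 <- as.matrix(sim1$states[amt_cols])
  a2 <- as.matrix(sim2$states[amt_cols])
  expect_equal(a2, 2 * a1, tolerance = 1e-6)
})

test_that("suspension mode with dissolved fraction 1 collapses to solution dosing", {
  susp <- solution_formulation() # suspension mode, dissolved_fraction = 1
  mixed <- formulation_spec(6, dissolved_fraction = 1,
                            dosage_mode = "mixed_solution_cr",
                            weibull = list(Max = 25.47, A = 11.93, b = 0.88))
  s1 <- simulate_ocular(bes_drug(), susp, rabbit_phys(),
                        dosing_protocol(0, susp), t_end = 12)
  s2 <- simulate_ocular(bes_drug(), mixed, rabbit_phys(),
                        dosing_protocol(0, mixed), t_end = 12)
  expect_equal(s1$states$cornea_epithelium, s2$states$cornea_epithelium,
               tolerance = 1e-8)
  expect_equal(s1$states$systemic, s2$states$systemic, tolerance = 1e-8)
})

test_that("with permeation shut off, drug never passes the ocular surface", {
  sim <- single_dose_sim(drug = isolated_drug(), t_end = 24)
  tissue_max <- vapply(sim$states[ocular_compartments()], max, numeric(1))
  expect_true(all(tissue_max < 1e-12))
  # everything administered is accounted for by surface routes alone
  last <- sim$states[nrow(sim$states), ]
  surface <- last$drainage_cum + last$spillage_loss + last$cr_depot +
    last$precornea_dissolved + last$precornea_solid
  expect_equal(surface, sim$dose_total, tolerance = 1e-6)
})

test_that("a systemic bolus decays mono-exponentially at CL / (Vc * BW)", {
  # dose a fully dissolved drop, then compare the systemic washout rate
  # once inflows are negligible, against the closed-form rate constant
  d <- isolated_drug()
  d$gi_ka <- 50 # drain the GI depot fast so disposition dominates
  ke <- d$CL / (d$Vc * 2.5) # 15.42 / (1.62 * 2.5) per hour
  expect_equal(ke, 3.8074, tolerance = 1e-4)
  f <- solution_formulation()
  sim <- simulate_ocular(d, f, rabbit_phys(), dosing_protocol(0, f),
                         t_end = 4, n_out = 401)
  st <- sim$states
  # inflows are exhausted well before 2 h; terminal slope = ke
  idx <- st$time >= 2.5
  slope <- -coef(lm(log(st$systemic[idx]) ~ st$time[idx]))[[2]]
  expect_equal(slope, ke, tolerance = 1e-3)
})

test_that("adaptive solver trajectories match a fine-step Euler oracle", {
  d <- isolated_drug()
  d$tissue_permeabilities[["cornea_epithelium"]] <- 1e-6
  f <- solution_formulation()
  phys <- rabbit_phys()
  sim <- simulate_ocular(d, f, phys, dosing_protocol(0, f), t_end = 3,
                         n_out = 301)
  rec <- c(0.25, 0.5, 1, 2, 3)
  oracle <- euler_reduced_oracle(
    dose_ug = 300, phys = phys, perm_ce = 1e-6,
    area_ce = phys$exchange_areas[["precornea-cornea_epithelium"]],
    ka = d$gi_ka, fabs = d$gi_fabs, CL = d$CL, Vc = d$Vc,
    t_end = 3, dt = 1e-4, record_times = rec)
  sim_at <- function(col) approx(sim$states$time, sim$states[[col]],
                                 xout = oracle$time, rule = 2)$y
  expect_equal(sim_at("precornea_dissolved"), oracle$A_pc, tolerance = 5e-3)
  expect_equal(sim_at("cornea_epithelium"), oracle$A_ce, tolerance = 5e-3)
  expect_equal(sim_at("systemic"), oracle$sys, tolerance = 5e-3)
})

test_that("simulation rejects ill-posed protocols", {
  f <- bes_cr()
  expect_error(simulate_ocular(bes_drug(), f, rabbit_phys(),
                               dosing_protocol(c(0, 6), f), t_end = 4),
               "beyond the last dose")
  expect_error(dosing_protocol(numeric(0), f), "at least one dose")
})

test_that("tidy/glance/tissue accessors are coherent", {
  sim <- single_dose_sim(t_end = 6, n_out = 61)
  long <- tidy(sim)
  expect_true(all(c("time", "compartment", "amount", "concentration") %in%
                    names(long)))
  ah <- long[long$compartment == "aqueous_humor", ]
  expect_equal(ah$concentration,
               ah$amount / rabbit_phys()$compartment_volumes[["aqueous_humor"]])
  tears <- tissue_concentration(sim, "tears")
  expect_equal(tears$conc,
               sim$states$precornea_dissolved / sim$states$precornea_volume)
  expect_error(tissue_concentration(sim, "eyelid"), "unknown tissue")
  g <- glance(sim)
  expect_equal(g$dose_total, 300)
  p <- autoplot(sim)
  expect_s3_class(p, "ggplot")
})
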