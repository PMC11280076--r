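# Independent brute-force oracle: fixed-step explicit Euler on a reduced
# solution-only model (pre-corneal fluid + cornea epithelium + GI depot +
# systemic). Written directly from the model equations, without calling
# any package integration code, so it can cross-check the adaptive solver.
#
# Arguments in the package's native units (uL, mg/mL, cm/s, kg);
# internally uses ug / mL / h like the package.
euler_reduced_oracle <- function(dose_ug, phys, perm_ce, area_ce,
                                 ka, fabs, CL, Vc, t_end, dt = 1e-4,
                                 record_times) {
  kd <- phys$drainage_rate * 60
  V_tear <- phys$tear_volume / 1000
  Q_tear <- phys$tear_turnover_rate * 60 / 1000
  V_ce <- phys$compartment_volumes[["cornea_epithelium"]]
  PA <- perm_ce * area_ce * 3600
  ke <- CL / (Vc * phys$body_weight)

  # instillation: drop fills to the pre-corneal maximum, excess spills
  V <- phys$precornea_max_volume / 1000
  phi <- (V - V_tear) / (50 / 1000)
  A_pc <- dose_ug * phi
  A_ce <- 0
  depot <- 0
  sys <- 0

  out <- matrix(NA_real_, nrow = length(record_times), ncol = 5,
                dimnames = list(NULL, c("time", "A_pc", "A_ce", "depot", "sys")))
  next_rec <- 1
  t <- 0
  n_steps <- ceiling(t_end / dt)
  for (step in 0:n_steps) {
    while (next_rec <= length(record_times) &&
           record_times[next_rec] <= t + dt / 2) {
      out[next_rec, ] <- c(t, A_pc, A_ce, depot, sys)
      next_rec <- next_rec + 1
    }
    if (next_rec > length(record_times)) break
    washout <- kd * max(V - V_tear, 0) / V
    flux <- PA * (A_pc / V - A_ce / V_ce)
    drained <- (washout + Q_tear / V) * A_pc
    dV <- -kd * (V - V_tear)
    dA_pc <- -drained - flux
    dA_ce <- flux
    ddepot <- drained - ka * depot
    dsys <- fabs * ka * depot - ke * sys
    V <- V + dt * dV
    A_pc <- A_pc + dt * dA_pc
    A_ce <- A_ce + dt * dA_ce
    depot <- depot + dt * ddepot
    sys <- sys + dt * dsys
    t <- t + dt
  }
  as.data.frame(out)
}
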