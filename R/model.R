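#' Dose events and dosing protocols
#'
#' A dosing protocol is a tibble with one row per instilled drop: `time`
#' (h), `volume` (uL) and `strength` (mg/mL). `dosing_protocol()` builds
#' one from a vector of dose times, defaulting volume and strength from a
#' formulation.
#'
#' @param times Dose times (h), non-negative.
#' @param formulation A `formulation_spec` supplying default volume and
#'   strength.
#' @param volume Drop volume (uL).
#' @param strength Label concentration (mg/mL).
#' @return A tibble with columns `time`, `volume`, `strength`.
#' @examples
#' # four drops ten minutes apart
#' dosing_protocol(c(0, 10, 20, 30) / 60, besivance_formulation())
#' @export
dosing_protocol <- function(times, formulation = NULL,
                            volume = formulation$drop_volume,
                            strength = formulation$strength) {
  if (length(times) < 1) stop("protocol needs at least one dose", call. = FALSE)
  if (any(times < 0)) stop("dose times must be >= 0", call. = FALSE)
  if (any(volume <= 0)) stop("dose volumes must be > 0", call. = FALSE)
  tibble::tibble(time = sort(times), volume = volume, strength = strength)
}

# --- internal state vector layout -------------------------------------------
# Amounts in ug, pre-corneal volume in mL, particle radius in um, time in h.
state_names <- function() {
  c("precornea_volume", "precornea_dissolved", "precornea_solid",
    "particle_radius", ocular_compartments(),
    "nasolacrimal_gi_depot", "systemic", "cr_depot",
    "spillage_loss", "systemic_cleared", "gi_unabsorbed",
    "drainage_cum", "cr_released_cum")
}

# Unit-converted constant bundle used by the RHS.
build_model_parms <- function(drug, formulation, physiology) {
  edges <- ocular_edges()
  perm <- drug$tissue_permeabilities[edges$perm_tissue]
  area <- physiology$exchange_areas[edges$edge]
  list(
    kd = physiology$drainage_rate * 60,                 # 1/h
    V_tear = physiology$tear_volume / 1000,             # mL
    V_max = physiology$precornea_max_volume / 1000,     # mL
    Q_tear = physiology$tear_turnover_rate * 60 / 1000, # mL/h
    Q_ah = physiology$aqueous_turnover_rate * 60 / 1000,
    vols = physiology$compartment_volumes,              # mL
    edge_from = edges$from,
    edge_to = edges$to,
    PA = unname(perm * area * 3600),                    # mL/h per edge
    sar = drug$systemic_absorption_rates * 3600,        # 1/h
    ke = drug$CL / (drug$Vc * physiology$body_weight),  # 1/h
    V_sys = drug$Vc * physiology$body_weight * 1000,    # mL
    Cs = drug$water_solubility * 1000,                  # ug/mL
    D = drug$diffusion_coefficient,
    rho = drug$true_density,
    ka = drug$gi_ka,
    fabs = drug$gi_fabs,
    weibull = formulation$weibull
  )
}

# Full right-hand side. cr_times / cr_amounts describe the CR depots
# spawned so far (each dose event has its own release clock).
ocular_rhs <- function(t, y, p, cr_times, cr_amounts) {
  d <- stats::setNames(numeric(length(y)), names(y))
  V <- y[["precornea_volume"]]
  A_dis <- y[["precornea_dissolved"]]
  A_sol <- y[["precornea_solid"]]
  r <- y[["particle_radius"]]

  # pre-corneal volume decay and washout of excess fluid
  d[["precornea_volume"]] <- -p$kd * (V - p$V_tear)
  washout <- p$kd * max(V - p$V_tear, 0) / V
  C_pc <- A_dis / V
  drain_dis <- washout * A_dis + p$Q_tear / V * A_dis
  drain_sol <- washout * A_sol
  d[["precornea_dissolved"]] <- -drain_dis
  d[["precornea_solid"]] <- -drain_sol

  # particle dissolution (shrinking sphere); the vanishing-particle limit
  # (r -> 0) has an unbounded rate coefficient, so dissolution is switched
  # off once less than 1e-6 ug of solid or 1e-3 um of radius remains --
  # far below the solver's non-negativity tolerance in relative terms
  if (A_sol > 1e-6 && r > 1e-3) {
    diss <- dissolution_rate(A_sol, r, C_pc, p$Cs, p$D, p$rho, V)
    d[["precornea_solid"]] <- d[["precornea_solid"]] + diss$dM_dt
    d[["precornea_dissolved"]] <- d[["precornea_dissolved"]] - diss$dM_dt
    d[["particle_radius"]] <- diss$dr_dt
  }

  # controlled-release depots: superposed Weibull release clocks
  if (length(cr_times) > 0) {
    active <- t > cr_times
    if (any(active)) {
      w <- p$weibull
      rel <- sum(cr_amounts[active] *
                   weibull_release_rate(t - cr_times[active], w$Max, w$A, w$b)) / 100
      d[["cr_depot"]] <- -rel
      d[["precornea_dissolved"]] <- d[["precornea_dissolved"]] + rel
      d[["cr_released_cum"]] <- rel
    }
  }

  # tissue-to-tissue permeation: P * SA * (C_i - C_j) per edge
  conc <- y[ocular_compartments()] / p$vols[ocular_compartments()]
  get_conc <- function(nm) if (nm == "precornea") C_pc else conc[[nm]]
  for (k in seq_along(p$PA)) {
    from <- p$edge_from[k]
    to <- p$edge_to[k]
    flux <- p$PA[k] * (get_conc(from) - get_conc(to))
    key_from <- if (from == "precornea") "precornea_dissolved" else from
    d[[key_from]] <- d[[key_from]] - flux
    d[[to]] <- d[[to]] + flux
  }

  # systemic absorption from vascularised tissues
  sys_in <- 0
  for (tt in names(p$sar)) {
    loss <- p$sar[[tt]] * y[[tt]]
    d[[tt]] <- d[[tt]] - loss
    sys_in <- sys_in + loss
  }

  # aqueous humor turnover outflow to systemic
  ah_out <- p$Q_ah * conc[["aqueous_humor"]]
  d[["aqueous_humor"]] <- d[["aqueous_humor"]] - ah_out
  sys_in <- sys_in + ah_out

  # nasolacrimal/GI depot: drained drug in, first-order absorption out
  depot <- y[["nasolacrimal_gi_depot"]]
  d[["nasolacrimal_gi_depot"]] <- drain_dis + drain_sol - p$ka * depot
  sys_in <- sys_in + p$fabs * p$ka * depot
  d[["gi_unabsorbed"]] <- (1 - p$fabs) * p$ka * depot
  d[["drainage_cum"]] <- drain_dis + drain_sol

  # one-compartment systemic disposition
  cleared <- p$ke * y[["systemic"]]
  d[["systemic"]] <- sys_in - cleared
  d[["systemic_cleared"]] <- cleared

  list(unname(d))
}

#' Apply a dose event to a model state
#'
#' Instils one drop into the pre-corneal compartment. The volume rises to
#' at most the physiology's pre-corneal maximum; when the drop would
#' overfill it, only the retained fraction
#' `phi = (new volume - current volume) / drop volume` of the dose enters
#' the model and the balance is booked to the spillage sink (the excess
#' fluid carries its drug content with it). Retained drug is split across
#' solution, CR depot and suspended solid per [split_dose()]; newly
#' instilled solid resets the (monodisperse) particle radius to the
#' formulation radius.
#'
#' @param state Named numeric state vector (internal layout); use
#'   [simulate_ocular()] for end-to-end runs.
#' @param event One-row data frame or list with `volume` (uL) and
#'   `strength` (mg/mL).
#' @param physiology An `ocular_physiology`.
#' @param formulation A `formulation_spec`.
#' @return List with the updated `state`, the spawned `cr_amount` (ug) and
#'   the `dose` administered (ug).
#' @export
apply_dose_event <- function(state, event, physiology, formulation) {
  V <- state[["precornea_volume"]]
  vol_ml <- event$volume / 1000
  V_max <- physiology$precornea_max_volume / 1000
  V_new <- min(V + vol_ml, V_max)
  phi <- (V_new - V) / vol_ml
  dose <- event$volume * event$strength # uL * mg/mL = ug
  parts <- split_dose(dose, formulation) * phi
  spill <- dose * (1 - phi)

  state[["precornea_volume"]] <- V_new
  state[["precornea_dissolved"]] <- state[["precornea_dissolved"]] + parts[["solution"]]
  state[["precornea_solid"]] <- state[["precornea_solid"]] + parts[["solid"]]
  if (parts[["solid"]] > 0) {
    state[["particle_radius"]] <- formulation$particle_diameter / 2
  }
  state[["cr_depot"]] <- state[["cr_depot"]] + parts[["cr_depot"]]
  state[["spillage_loss"]] <- state[["spillage_loss"]] + spill
  list(state = state, cr_amount = unname(parts[["cr_depot"]]), dose = dose)
}

#' Simulate topical ocular dosing
#'
#' Integrates the full ocular model — pre-corneal tear dynamics with
#' nasolacrimal drainage, particle dissolution, Weibull controlled-release
#' depots, tissue-to-tissue permeation, systemic absorption and
#' disposition, and the nasolacrimal/GI depot — over a dosing protocol,
#' with an integration restart at every dose event. Uses a stiff-capable
#' adaptive integrator (`deSolve::lsoda`). A mass-balance audit is run at
#' every output point; a relative violation above `mass_balance_tol` is a
#' hard error.
#'
#' @param drug A `drug_parameters`.
#' @param formulation A `formulation_spec`.
#' @param physiology An `ocular_physiology`.
#' @param protocol A dosing protocol tibble from [dosing_protocol()].
#' @param t_end End of simulation (h); must lie beyond the last dose.
#' @param n_out Number of output grid points (dose times are always
#'   included).
#' @param rtol,atol Solver relative / absolute tolerances (atol in ug).
#' @param mass_balance_tol Maximum tolerated relative mass-balance error.
#' @return An object of class `ocular_simulation`: a list with `states`
#'   (wide tibble of the full state trajectory plus `administered` and
#'   `balance_error` columns), the inputs, solver settings, and the CR
#'   depot schedule.
#' @examples
#' sim <- simulate_ocular(
#'   besifloxacin_parameters(), besivance_formulation(),
#'   builtin_physiology("NZ_rabbit"), t_end = 24
#' )
#' glance(sim)
#' @export
simulate_ocular <- function(drug, formulation, physiology,
                            protocol = dosing_protocol(0, formulation),
                            t_end = 24, n_out = 241,
                            rtol = 1e-8, atol = 1e-12,
                            mass_balance_tol = 1e-6) {
  stopifnot(inherits(drug, "drug_parameters"),
            inherits(formulation, "formulation_spec"),
            inherits(physiology, "ocular_physiology"))
  protocol <- tibble::as_tibble(protocol)
  if (nrow(protocol) == 0) stop("protocol must contain at least one dose", call. = FALSE)
  if (t_end <= max(protocol$time)) {
    stop("t_end must lie beyond the last dose time", call. = FALSE)
  }

  p <- build_model_parms(drug, formulation, physiology)
  grid <- sort(unique(c(seq(0, t_end, length.out = n_out), protocol$time)))

  y <- stats::setNames(numeric(length(state_names())), state_names())
  y[["precornea_volume"]] <- physiology$tear_volume / 1000
  y[["particle_radius"]] <- formulation$particle_diameter / 2

  cr_times <- numeric(0)
  cr_amounts <- numeric(0)
  administered <- 0

  # segment boundaries: start, every dose time, end
  bounds <- sort(unique(c(0, protocol$time, t_end)))
  out_rows <- list()
  adm_rows <- list()

  record <- function(time, state) {
    out_rows[[length(out_rows) + 1]] <<- c(time = time, state)
    adm_rows[[length(adm_rows) + 1]] <<- administered
  }

  for (i in seq_along(bounds)) {
    t0 <- bounds[i]
    # apply any dose scheduled at t0
    due <- which(abs(protocol$time - t0) < 1e-12)
    for (j in due) {
      upd <- apply_dose_event(y, protocol[j, ], physiology, formulation)
      y <- upd$state
      administered <- administered + upd$dose
      if (upd$cr_amount > 0) {
        cr_times <- c(cr_times, t0)
        cr_amounts <- c(cr_amounts, upd$cr_amount)
      }
    }
    record(t0, y)
    if (i == length(bounds)) break
    t1 <- bounds[i + 1]
    seg_times <- unique(c(t0, grid[grid > t0 & grid <= t1], t1))
    if (length(seg_times) < 2) next
    sol <- deSolve::lsoda(
      y = y, times = seg_times,
      func = function(t, y, parms) ocular_rhs(t, y, parms, cr_times, cr_amounts),
      parms = p, rtol = rtol, atol = atol, maxsteps = 50000
    )
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf(
        "ODE integration failed on [%g, %g] h (species %s, mode %s)",
        t0, t1, physiology$species_label, formulation$dosage_mode),
        call. = FALSE)
    }
    for (k in 2:nrow(sol)) {
      st <- stats::setNames(as.numeric(sol[k, -1]), state_names())
      if (sol[k, 1] < t1 - 1e-12) record(sol[k, 1], st)
    }
    y <- stats::setNames(as.numeric(sol[nrow(sol), -1]), state_names())
    # the t1 record happens at the top of the next iteration (post-dose)
    if (i + 1 == length(bounds) && !any(abs(protocol$time - t1) < 1e-12)) {
      # no dose at t_end; fall through to final record
    }
  }
  record(t_end, y)

  states <- tibble::as_tibble(do.call(rbind, out_rows))
  states$administered <- unlist(adm_rows)
  states <- dplyr::distinct(states, .data$time, .keep_all = TRUE)

  amount_cols <- c("precornea_dissolved", "precornea_solid",
                   ocular_compartments(), "nasolacrimal_gi_depot",
                   "systemic", "cr_depot")
  sink_cols <- c("spillage_loss", "systemic_cleared", "gi_unabsorbed")
  accounted <- rowSums(states[amount_cols]) + rowSums(states[sink_cols])
  states$balance_error <- ifelse(
    states$administered > 0,
    abs(states$administered - accounted) / states$administered, 0)

  if (any(states$balance_error > mass_balance_tol)) {
    stop(sprintf(
      "mass-balance violation: max relative error %.3g exceeds %.1g",
      max(states$balance_error), mass_balance_tol), call. = FALSE)
  }
  neg <- vapply(states[amount_cols], min, numeric(1))
  if (any(neg < -1e-9)) {
    stop(sprintf("negative compartment amount (%.3g ug) beyond tolerance",
                 min(neg)), call. = FALSE)
  }

  structure(
    list(
      states = states,
      drug = drug, formulation = formulation, physiology = physiology,
      protocol = protocol,
      cr_schedule = tibble::tibble(time = cr_times, amount = cr_amounts),
      solver = list(rtol = rtol, atol = atol, n_out = n_out,
                    t_end = t_end, method = "lsoda"),
      dose_total = administered
    ),
    class = "ocular_simulation"
  )
}

#' @export
print.ocular_simulation <- function(x, ...) {
  cat(sprintf(
    "<ocular_simulation: %s, %s, %d dose(s), 0-%g h, %d output points>\n",
    x$drug$name, x$physiology$species_label, nrow(x$protocol),
    x$solver$t_end, nrow(x$states)))
  cat(sprintf("  dose total %g ug; max mass-balance error %.2e\n",
              x$dose_total, max(x$states$balance_error)))
  invisible(x)
}

# volume (mL) used to convert a compartment amount to a concentration;
# NA marks states that are not concentration-bearing.
compartment_volume_ml <- function(sim, compartment) {
  phys <- sim$physiology
  if (compartment %in% ocular_compartments()) {
    return(phys$compartment_volumes[[compartment]])
  }
  if (compartment == "systemic") {
    return(sim$drug$Vc * phys$body_weight * 1000)
  }
  NA_real_
}

#' Tidy a simulation into long format
#'
#' @param x An `ocular_simulation`.
#' @param ... Unused.
#' @return A tibble with columns `time` (h), `compartment`, `amount` (ug)
#'   and `concentration` (ug/mL; `NA` for depot/sink states with no
#'   defined volume). The pre-corneal dissolved concentration uses the
#'   time-varying tear-film volume.
#' @export
tidy.ocular_simulation <- function(x, ...) {
  st <- x$states
  comps <- c("precornea_dissolved", "precornea_solid", ocular_compartments(),
             "nasolacrimal_gi_depot", "systemic", "cr_depot")
  long <- tidyr::pivot_longer(
    st[c("time", "precornea_volume", comps)],
    cols = dplyr::all_of(comps),
    names_to = "compartment", values_to = "amount")
  vols <- vapply(comps, function(cc) compartment_volume_ml(x, cc), numeric(1))
  long$concentration <- long$amount / as.numeric(vols[long$compartment])
  pc <- long$compartment == "precornea_dissolved"
  long$concentration[pc] <- long$amount[pc] / long$precornea_volume[pc]
  long$precornea_volume <- NULL
  long
}

#' One-row summary of a simulation
#'
#' @param x An `ocular_simulation`.
#' @param ... Unused.
#' @return A tibble with the dose total, final sink partition, CR depot
#'   remainder and the maximum relative mass-balance error.
#' @export
glance.ocular_simulation <- function(x, ...) {
  last <- x$states[nrow(x$states), ]
  tibble::tibble(
    species = x$physiology$species_label,
    n_doses = nrow(x$protocol),
    t_end = x$solver$t_end,
    dose_total = x$dose_total,
    spillage_loss = last$spillage_loss,
    systemic_cleared = last$systemic_cleared,
    gi_unabsorbed = last$gi_unabsorbed,
    cr_depot_remaining = last$cr_depot,
    cr_released = last$cr_released_cum,
    drainage_cum = last$drainage_cum,
    max_balance_error = max(x$states$balance_error)
  )
}

#' Observable tissue concentration-time profile
#'
#' Maps a sampled tissue to the model states that represent it and returns
#' its concentration-time profile: `tears` is the dissolved pre-corneal
#' concentration over the time-varying tear-film volume; `cornea` pools
#' epithelium and stroma (amount over combined volume); `plasma` is the
#' systemic amount over the central volume of distribution.
#'
#' @param sim An `ocular_simulation`.
#' @param tissue One of `"tears"`, `"cornea"`, `"conjunctiva"`,
#'   `"aqueous_humor"`, `"plasma"`, or any model compartment name.
#' @return A tibble with columns `time` (h) and `conc` (ug/mL).
#' @export
tissue_concentration <- function(sim, tissue) {
  st <- sim$states
  conc <- switch(
    tissue,
    tears = st$precornea_dissolved / st$precornea_volume,
    cornea = (st$cornea_epithelium + st$cornea_stroma) /
      sum(sim$physiology$compartment_volumes[c("cornea_epithelium",
                                               "cornea_stroma")]),
    plasma = st$systemic / (sim$drug$Vc * sim$physiology$body_weight * 1000),
    {
      if (!tissue %in% ocular_compartments()) {
        stop("unknown tissue: ", tissue, call. = FALSE)
      }
      st[[tissue]] / sim$physiology$compartment_volumes[[tissue]]
    }
  )
  tibble::tibble(time = st$time, conc = conc)
}

#' Plot a simulated concentration-time course
#'
#' @param object An `ocular_simulation`.
#' @param tissues Tissues to draw (see [tissue_concentration()]).
#' @param log_y Draw the concentration axis on a log10 scale (profiles
#'   spanning several decades are the norm for topical dosing).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ocular_simulation <- function(object,
                                       tissues = c("tears", "cornea",
                                                   "conjunctiva",
                                                   "aqueous_humor", "plasma"),
                                       log_y = TRUE, ...) {
  df <- purrr::map_dfr(tissues, function(tt) {
    dplyr::mutate(tissue_concentration(object, tt), tissue = tt)
  })
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$conc,
                                         colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (h)", y = "Concentration (µg/mL)",
                  colour = "Tissue",
                  title = sprintf("%s — %s", object$drug$name,
                                  object$physiology$species_label)) +
    ggplot2::theme_minimal()
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}
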