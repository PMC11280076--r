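#' Dissolved fraction of a suspension at instillation
#'
#' For a suspension whose label strength exceeds the aqueous solubility of
#' the dosed form, only `solubility / strength` of the dose is in solution
#' when the drop lands; the remainder is suspended solid. The fraction is
#' capped at 1 for fully dissolved products.
#'
#' For the besifloxacin case study: the salt solubility of 1 mg/mL against
#' a 6 mg/mL strength gives 16.7% dissolved; 2.5 mg/mL would give 41.66%;
#' 0.09 mg/mL gives 1.5%.
#'
#' @param solubility mg/mL; strictly positive.
#' @param strength Label concentration, mg/mL; strictly positive.
#' @return Fraction in (0, 1].
#' @examples
#' derive_dissolved_fraction(1, 6)   # 0.1667
#' derive_dissolved_fraction(2.5, 6) # 0.4167
#' @export
derive_dissolved_fraction <- function(solubility, strength) {
  if (!is.numeric(solubility) || any(!is.finite(solubility)) ||
      any(solubility <= 0)) {
    stop("solubility must be strictly positive", call. = FALSE)
  }
  if (!is.numeric(strength) || any(!is.finite(strength)) ||
      any(strength <= 0)) {
    stop("strength must be strictly positive", call. = FALSE)
  }
  pmin(1, solubility / strength)
}

#' Weibull cumulative release
#'
#' Cumulative percent of a controlled-release depot released by time `t`:
#' \deqn{F(t) = Max \, (1 - e^{-t^b / A})}
#' with `Max` the asymptotic percent released, `A` the time scale (units
#' h^b) and `b` the shape. `F(0) = 0`, F is non-decreasing, and
#' `F(t) <= Max` always.
#'
#' @param t Time (h), vectorised; must be non-negative.
#' @param Max Asymptotic percent released, in (0, 100].
#' @param A Time scale, h^b, strictly positive.
#' @param b Shape, strictly positive.
#' @return Percent released at each `t`.
#' @examples
#' weibull_fraction_released(24, Max = 25.47, A = 11.93, b = 0.88) # ~19.0
#' @export
weibull_fraction_released <- function(t, Max, A, b) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be non-negative and finite", call. = FALSE)
  }
  check_weibull(Max, A, b)
  Max * (1 - exp(-t^b / A))
}

# Instantaneous release rate dF/dt in percent/h (finite limit at t = 0
# only when b >= 1; for b < 1 the rate diverges at 0+, handled by callers).
weibull_release_rate <- function(t, Max, A, b) {
  rate <- numeric(length(t))
  pos <- t > 0
  rate[pos] <- Max * exp(-t[pos]^b / A) * b * t[pos]^(b - 1) / A
  rate[!pos] <- if (b >= 1) Max * b * (if (b == 1) 1 else 0) / A else 0
  rate
}

check_weibull <- function(Max, A, b) {
  if (!is.numeric(Max) || Max <= 0 || Max > 100) {
    stop("Weibull Max must lie in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(A) || A <= 0) stop("Weibull A must be > 0", call. = FALSE)
  if (!is.numeric(b) || b <= 0) stop("Weibull b must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' Construct a formulation specification
#'
#' Describes one ophthalmic dosage form. Two modes are supported:
#' `"suspension"` — the undissolved fraction is dosed as solid particles
#' that dissolve in the tears (shrinking-sphere kinetics); and
#' `"mixed_solution_cr"` — the undissolved fraction is dosed as a
#' controlled-release depot emptied according to a Weibull function, the
#' representation used when a mucoadhesive vehicle retains drug on the eye
#' surface. In both modes the dissolved fraction is dosed as solution.
#'
#' @param strength Label concentration, mg/mL.
#' @param drop_volume Instilled drop volume, uL.
#' @param particle_diameter Mean particle diameter, um (monodisperse).
#' @param dissolved_fraction Fraction of the dose in solution at
#'   instillation, in [0, 1]. Defaults to
#'   `derive_dissolved_fraction(solubility, strength)` when a solubility is
#'   given.
#' @param dosage_mode `"suspension"` or `"mixed_solution_cr"`.
#' @param weibull Named list/vector with `Max` (percent), `A` (h^b), `b`;
#'   required in `mixed_solution_cr` mode.
#' @param solubility Optional mg/mL used to derive `dissolved_fraction`.
#' @return An object of class `formulation_spec`.
#' @seealso [besivance_formulation()] for the bundled case study.
#' @export
formulation_spec <- function(strength, drop_volume = 50,
                             particle_diameter = 3,
                             dissolved_fraction = NULL,
                             dosage_mode = c("suspension", "mixed_solution_cr"),
                             weibull = NULL, solubility = NULL) {
  dosage_mode <- match.arg(dosage_mode)
  if (is.null(dissolved_fraction)) {
    if (is.null(solubility)) {
      stop("supply either dissolved_fraction or solubility", call. = FALSE)
    }
    dissolved_fraction <- derive_dissolved_fraction(solubility, strength)
  }
  if (dissolved_fraction < 0 || dissolved_fraction > 1) {
    stop("dissolved_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (strength <= 0) stop("strength must be > 0", call. = FALSE)
  if (drop_volume <= 0) stop("drop_volume must be > 0", call. = FALSE)
  if (particle_diameter <= 0) stop("particle_diameter must be > 0", call. = FALSE)
  if (dosage_mode == "mixed_solution_cr") {
    if (is.null(weibull)) {
      stop("mixed_solution_cr mode requires weibull parameters", call. = FALSE)
    }
    weibull <- as.list(weibull)
    check_weibull(weibull$Max, weibull$A, weibull$b)
  }
  structure(
    list(
      strength = strength,
      drop_volume = drop_volume,
      particle_diameter = particle_diameter,
      dissolved_fraction = dissolved_fraction,
      dosage_mode = dosage_mode,
      weibull = weibull
    ),
    class = "formulation_spec"
  )
}

#' Besifloxacin 0.6% suspension formulation
#'
#' The bundled case-study formulation: 6 mg/mL strength, 50 uL drop, 3 um
#' assumed mean particle diameter, 16.7% dissolved at instillation (from
#' the 1 mg/mL salt solubility). In `mixed_solution_cr` mode the 83.3%
#' undissolved balance is dosed as a controlled-release depot with fitted
#' Weibull parameters Max = 25.47%, A = 11.93 h^b, b = 0.88, standing in
#' for the combined effect of particle dissolution, release from the
#' mucoadhesive polymer layer, and tear-mediated elimination (the
#' never-released balance).
#'
#' @param dosage_mode `"mixed_solution_cr"` (default) or `"suspension"`.
#' @return A `formulation_spec`.
#' @export
besivance_formulation <- function(dosage_mode = c("mixed_solution_cr",
                                                  "suspension")) {
  dosage_mode <- match.arg(dosage_mode)
  formulation_spec(
    strength = 6, drop_volume = 50, particle_diameter = 3,
    solubility = 1, dosage_mode = dosage_mode,
    weibull = list(Max = 25.47, A = 11.93, b = 0.88)
  )
}

#' Shrinking-sphere dissolution rate
#'
#' Dissolution rate of a monodisperse population of spherical particles
#' with a particle-size-dependent diffusion layer (thickness
#' `h = min(radius, 30 um)`):
#' \deqn{dM/dt = - \frac{3 D M}{\rho h r} (C_s - C)}
#' with `M` the undissolved mass, `r` the particle radius, `D` the
#' diffusion coefficient, `rho` the true density, `C_s` the solubility and
#' `C` the bulk dissolved concentration. The radius shrinks in proportion:
#' `dr/dt = (r / 3M) dM/dt`. The rate is zero at saturation and reverses
#' sign under supersaturation (precipitation onto remaining particles).
#'
#' Under sink conditions (`C = 0`, `h = r`) the radius obeys the analytic
#' square-root-of-time law `r(t)^2 = r0^2 - 2 D Cs t / rho`.
#'
#' @param mass_undissolved ug, non-negative.
#' @param radius um, strictly positive while mass remains.
#' @param dissolved_conc Bulk concentration, ug/mL.
#' @param solubility ug/mL.
#' @param D Diffusion coefficient, cm^2/s.
#' @param density True density, g/mL.
#' @param fluid_volume Dissolution medium volume, mL (used by callers to
#'   convert the mass rate to a concentration rate; must be positive).
#' @return Named list with `dM_dt` (ug/h, negative when dissolving) and
#'   `dr_dt` (um/h).
#' @export
dissolution_rate <- function(mass_undissolved, radius, dissolved_conc,
                             solubility, D, density, fluid_volume) {
  if (fluid_volume <= 0) stop("fluid_volume must be > 0", call. = FALSE)
  if (mass_undissolved < 0) stop("mass_undissolved must be >= 0", call. = FALSE)
  if (mass_undissolved > 0 && radius <= 0) {
    stop("inconsistent state: positive undissolved mass with non-positive radius",
         call. = FALSE)
  }
  if (mass_undissolved <= 0 || radius <= 0) {
    return(list(dM_dt = 0, dr_dt = 0))
  }
  r_cm <- radius * 1e-4
  h_cm <- min(r_cm, 30e-4)
  rho_ug_ml <- density * 1e6
  # ug/s, then per hour
  dM_dt <- -3 * D * mass_undissolved * (solubility - dissolved_conc) /
    (rho_ug_ml * h_cm * r_cm) * 3600
  dr_dt <- radius / (3 * mass_undissolved) * dM_dt
  list(dM_dt = dM_dt, dr_dt = dr_dt)
}

#' Partition a dose across solution, CR depot and solid
#'
#' Splits a total instilled dose according to the formulation's dissolved
#' fraction and dosage mode. In `mixed_solution_cr` mode the undissolved
#' balance is booked to the controlled-release depot; in `suspension` mode
#' it is dosed as suspended solid. The three parts always sum exactly to
#' the input dose.
#'
#' @param total_dose ug, non-negative.
#' @param spec A `formulation_spec`.
#' @return Named numeric vector `c(solution, cr_depot, solid)` in ug.
#' @examples
#' split_dose(300, besivance_formulation())              # 50.1 / 249.9 / 0
#' split_dose(300, besivance_formulation("suspension"))  # 50.1 / 0 / 249.9
#' @export
split_dose <- function(total_dose, spec) {
  stopifnot(inherits(spec, "formulation_spec"))
  if (total_dose < 0) stop("total_dose must be >= 0", call. = FALSE)
  f <- spec$dissolved_fraction
  solution <- f * total_dose
  rest <- total_dose - solution
  if (spec$dosage_mode == "mixed_solution_cr") {
    c(solution = solution, cr_depot = rest, solid = 0)
  } else {
    c(solution = solution, cr_depot = 0, solid = rest)
  }
}

#' @export
print.formulation_spec <- function(x, ...) {
  cat(sprintf("<formulation_spec: %g mg/mL, %g uL drop, %s mode>\n",
              x$strength, x$drop_volume, x$dosage_mode))
  cat(sprintf("  dissolved fraction %.4f, particle diameter %g um\n",
              x$dissolved_fraction, x$particle_diameter))
  if (!is.null(x$weibull)) {
    cat(sprintf("  Weibull: Max %g%%, A %g h^b, b %g\n",
                x$weibull$Max, x$weibull$A, x$weibull$b))
  }
  invisible(x)
}
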