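#' Construct a drug parameter set
#'
#' Collects the physicochemical, ocular-permeability, systemic-absorption
#' and disposition constants for one active pharmaceutical ingredient.
#' Permeabilities are membrane permeabilities in cm/s for each tissue
#' interface; systemic absorption rates (SARs) are first-order constants in
#' 1/s moving drug from vascularised ocular tissues into the systemic
#' compartment.
#'
#' @param name Drug name (free text).
#' @param molecular_weight g/mol.
#' @param logP Octanol/water log partition coefficient (neutral species).
#' @param pKa_list List of `list(value =, type =)` entries, `type` one of
#'   `"acid"`, `"base"`. Carried for documentation; the model is pH-static.
#' @param fu_plasma Fraction unbound in plasma, in (0, 1].
#' @param fu_melanin Fraction unbound to melanin, in (0, 1]. Melanin
#'   binding is not modelled; keep at 1.
#' @param blood_to_plasma_ratio Dimensionless.
#' @param water_solubility mg/mL (solubility of the dosed salt form).
#' @param intestinal_permeability Effective intestinal permeability, in
#'   units of 1e-4 cm/s.
#' @param Vc Central volume of distribution, L/kg.
#' @param CL Systemic clearance, L/h (absolute, for the reference body
#'   weight of the physiology in use).
#' @param tissue_permeabilities Named numeric vector, cm/s, one entry per
#'   compartment of [ocular_compartments()].
#' @param systemic_absorption_rates Named numeric vector, 1/s, one entry
#'   per tissue of `conjunctiva`, `iris_ciliary_body`, `choroid`, `retina`.
#' @param diffusion_coefficient Aqueous diffusion coefficient for the
#'   dissolution model, cm^2/s.
#' @param true_density Particle true density, g/mL.
#' @param gi_ka First-order absorption rate from the nasolacrimal/GI depot,
#'   1/h.
#' @param gi_fabs Fraction of the drained dose absorbed from the GI depot,
#'   in (0, 1]; the remainder is booked unabsorbed.
#' @return An object of class `drug_parameters`.
#' @seealso [besifloxacin_parameters()] for the bundled case-study values.
#' @export
drug_parameters <- function(name, molecular_weight, logP, pKa_list,
                            fu_plasma, fu_melanin, blood_to_plasma_ratio,
                            water_solubility, intestinal_permeability,
                            Vc, CL, tissue_permeabilities,
                            systemic_absorption_rates,
                            diffusion_coefficient = 8e-6,
                            true_density = 1.3,
                            gi_ka = 0.5, gi_fabs = 0.7) {
  d <- structure(
    list(
      name = name,
      molecular_weight = molecular_weight,
      logP = logP,
      pKa_list = pKa_list,
      fu_plasma = fu_plasma,
      fu_melanin = fu_melanin,
      blood_to_plasma_ratio = blood_to_plasma_ratio,
      water_solubility = water_solubility,
      intestinal_permeability = intestinal_permeability,
      Vc = Vc,
      CL = CL,
      tissue_permeabilities = tissue_permeabilities,
      systemic_absorption_rates = systemic_absorption_rates,
      diffusion_coefficient = diffusion_coefficient,
      true_density = true_density,
      gi_ka = gi_ka,
      gi_fabs = gi_fabs
    ),
    class = "drug_parameters"
  )
  validate_drug_parameters(d)
  d
}

validate_drug_parameters <- function(d) {
  stop_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
  pos <- function(x) is.numeric(x) && all(is.finite(x)) && all(x > 0)
  for (f in c("molecular_weight", "water_solubility", "Vc", "CL",
              "diffusion_coefficient", "true_density", "gi_ka")) {
    stop_if(!pos(d[[f]]), paste0(f, " must be strictly positive"))
  }
  for (f in c("fu_plasma", "fu_melanin", "gi_fabs")) {
    stop_if(!pos(d[[f]]) || d[[f]] > 1, paste0(f, " must lie in (0, 1]"))
  }
  comps <- ocular_compartments()
  stop_if(!setequal(names(d$tissue_permeabilities), comps),
          "tissue_permeabilities must name exactly the ocular compartments")
  stop_if(!pos(d$tissue_permeabilities),
          "all tissue permeabilities must be strictly positive")
  stop_if(!setequal(names(d$systemic_absorption_rates), sar_tissues()),
          "systemic_absorption_rates must name exactly conjunctiva, iris_ciliary_body, choroid, retina")
  stop_if(!pos(d$systemic_absorption_rates),
          "all systemic absorption rates must be strictly positive")
  invisible(d)
}

#' Besifloxacin parameter set
#'
#' The bundled parameter set for besifloxacin (dosed as the hydrochloride
#' salt in a 0.6% w/v ophthalmic suspension). Cornea epithelium and
#' conjunctiva permeabilities (1e-7 and 1.4e-7 cm/s) and the iris-ciliary
#' body systemic absorption rate (5e-3 1/s) are values estimated against
#' rabbit ocular concentration data; the remaining permeabilities are
#' structure-based estimates. Clearance (15.42 L/h) and central volume
#' (1.62 L/kg) describe rabbit systemic disposition.
#'
#' @return A `drug_parameters` object.
#' @examples
#' bes <- besifloxacin_parameters()
#' bes$tissue_permeabilities[["cornea_epithelium"]] # 1e-7 cm/s
#' @export
besifloxacin_parameters <- function() {
  drug_parameters(
    name = "besifloxacin",
    molecular_weight = 393.85,
    logP = 0.26,
    pKa_list = list(
      list(value = 1.8, type = "base"),
      list(value = 6.0, type = "acid"),
      list(value = 9.9, type = "base")
    ),
    fu_plasma = 0.415,
    fu_melanin = 1,
    blood_to_plasma_ratio = 1.33,
    water_solubility = 1,          # mg/mL, besifloxacin HCl at pH 7
    intestinal_permeability = 0.39, # x 1e-4 cm/s
    Vc = 1.62,
    CL = 15.42,
    tissue_permeabilities = c(
      cornea_epithelium = 1e-7,
      cornea_stroma     = 1.86e-5,
      conjunctiva       = 1.4e-7,
      aqueous_humor     = 8.51e-6,
      iris_ciliary_body = 7.74e-4,
      sclera            = 1.02e-5,
      choroid           = 1.84e-4,
      retina            = 1.73e-5,
      vitreous_humor    = 6.7e-6
    ),
    systemic_absorption_rates = c(
      conjunctiva       = 3.81e-4,
      iris_ciliary_body = 5e-3,
      choroid           = 2.75e-4,
      retina            = 1.2e-3
    )
  )
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat(sprintf("<drug_parameters: %s>\n", x$name))
  cat(sprintf("  MW %g g/mol, logP %g, solubility %g mg/mL\n",
              x$molecular_weight, x$logP, x$water_solubility))
  cat(sprintf("  Vc %g L/kg, CL %g L/h\n", x$Vc, x$CL))
  invisible(x)
}
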