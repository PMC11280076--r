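# Shared fixtures: the bundled besifloxacin case-study context.

rabbit_phys <- function() builtin_physiology("NZ_rabbit")
human_phys <- function() builtin_physiology("human")

bes_drug <- function() besifloxacin_parameters()

# mixed solution/controlled-release besifloxacin 0.6% formulation
bes_cr <- function() besivance_formulation("mixed_solution_cr")
bes_susp <- function() besivance_formulation("suspension")

# a fully dissolved (solution-only) formulation at the same strength
solution_formulation <- function(strength = 6) {
  formulation_spec(strength = strength, drop_volume = 50,
                   particle_diameter = 3, dissolved_fraction = 1,
                   dosage_mode = "suspension")
}

single_dose_sim <- function(formulation = bes_cr(),
                            physiology = rabbit_phys(),
                            drug = bes_drug(), t_end = 24, ...) {
  simulate_ocular(drug, formulation, physiology,
                  dosing_protocol(0, formulation), t_end = t_end, ...)
}

# drug clone with near-zero ocular permeabilities and systemic absorption
# (the validators require strictly positive values, so "off" is 1e-30)
isolated_drug <- function() {
  d <- bes_drug()
  d$tissue_permeabilities[] <- 1e-30
  d$systemic_absorption_rates[] <- 1e-30
  d
}
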