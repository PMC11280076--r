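---
title: "Methods: ocular PBPK modelling of topical suspensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular PBPK modelling of topical suspensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculopk)
```

`oculopk` simulates what happens to a drop of an ophthalmic suspension
between the moment it lands on the eye and its eventual clearance, and
estimates the model's free parameters from sparse tissue concentration
data. This vignette is the package's account of the science: the model
and its assumptions, the parameters that matter, the numerical choices,
and what the test suite does and does not demonstrate.

## The compartmental model

The ocular surface is represented by a pre-corneal compartment with
**time-varying volume**. A drop can raise that volume only to
`V_max = V_tear + 30` µL (35 µL in rabbit, 37 µL in human); anything
beyond spills immediately, taking its proportional drug content with it.
The excess volume then drains at first order,

$$\frac{dV}{dt} = -k_d\,(V - V_\mathrm{tear}),\qquad k_d = 0.1\ \mathrm{min}^{-1},$$

so the excess halves every $\ln 2 / k_d \approx 6.93$ min. The drainage
constant is a viscosity-adjusted value appropriate for a viscous
suspension vehicle, applied to all species. Washout removes dissolved
and suspended drug at the same fractional rate $k_d (V-V_\mathrm{tear})/V$
(the fluid that leaves carries both phases); baseline tear turnover
(0.66 µL/min rabbit, 1.2 µL/min human) removes dissolved drug only,
since at physiological volume the particles are assumed retained in the
cul-de-sac. Whether both phases truly drain at identical fractional
rates is not observable at this resolution; equal rates are the simplest
assumption consistent with both phases being removed. Evaporation is
neglected.

**Suspended particles** dissolve by shrinking-sphere kinetics with a
particle-size-limited diffusion layer $h = \min(r, 30\ \mu m)$:

$$\frac{dM}{dt} = -\frac{3 D M}{\rho\, h\, r}\,(C_s - C),\qquad
\frac{dr}{dt} = \frac{r}{3M}\frac{dM}{dt}.$$

The population is monodisperse (default diameter 3 µm); polydisperse
bins are an extension point, not implemented. The rate reverses sign
under supersaturation (precipitation onto remaining particles, no
nucleation model). Under sink conditions the radius obeys
$r^2(t) = r_0^2 - 2 D C_s t/\rho$, which the tests verify to 0.1%
against an independent fine-step integration. For a drug with
$C_s = 1$ mg/mL a 3 µm particle dissolves within seconds, so in
suspension mode the tear film saturates almost instantly and the solid
acts as a reservoir against drainage.

**Controlled release.** A mucoadhesive vehicle (e.g. a polycarbophil
gel) retains drug on the globe and releases it slowly. This is modelled
as a depot emptied according to a Weibull function

$$F(t) = \mathrm{Max}\,\bigl(1 - e^{-t^b/A}\bigr),$$

with `Max` in percent, `A` in $h^b$ and `b` dimensionless; the
functional form is fixed by the unit of `A`, and no lag time is used.
The bundled besifloxacin profile (`Max` 25.47%, `A` 11.93, `b` 0.88) is
deliberately *lumped*: it stands for particle dissolution, release from
the polymer layer, **and** tear-mediated elimination — the asymptotically
unreleased balance ($100-\mathrm{Max} = 74.53\%$) is drug that the vehicle
carries away without ever presenting it for absorption. For that reason
the depot itself is not subject to drainage, and the unreleased balance
simply remains in the depot state at the end of a simulation (it is part
of the mass balance, reported as `cr_depot_remaining`). Each dose event
spawns its own depot with its own release clock (superposition). In
`mixed_solution_cr` mode the dissolved fraction of the dose
($\min(1, C_s/\mathrm{strength})$; 16.7% for a 1 mg/mL-soluble salt in a
6 mg/mL product) is dosed as solution and the balance as CR depot.
The dissolved fraction is an explicit input: the package reproduces the
arithmetic for any solubility assumption (1 mg/mL → 16.7%,
2.5 mg/mL → 41.66%, 0.09 mg/mL → 1.5%) without adjudicating which value
is "true" for a given product.

**Permeation and disposition.** Tissue-to-tissue transfer uses
symmetric permeability–area–concentration-difference fluxes,
$J_{ij} = P\,SA\,(C_i - C_j)$, along a fixed topology (cornea route,
conjunctiva–sclera route, anterior and posterior chambers). No tissue
partition coefficients are applied; the permeability governing an
interface is that of the deeper tissue of the pair (e.g. the
precornea–cornea interface uses the cornea epithelium permeability, the
conjunctiva–sclera interface the sclera permeability). Vascularised
tissues (conjunctiva, iris–ciliary body, choroid, retina) lose drug to
the systemic compartment at first-order systemic absorption rates;
aqueous humor turnover (3 µL/min rabbit, 2.5 µL/min human) also routes
to systemic. Drained pre-corneal drug enters a nasolacrimal/GI depot
absorbed at $k_a = 0.5\ h^{-1}$ with fraction absorbed 0.7 (a simple
first-order stand-in for gut transit; ocular suspensions produce
near-negligible systemic levels, so nothing downstream is sensitive to
it). Systemic disposition is one-compartment,
$k_e = CL/(V_c\,BW)$, with plasma concentration $A/(V_c\,BW)$. The
clearance input is treated as absolute for the reference body weight.
Melanin binding, corneal metabolism and transporters are not modelled;
in consequence the two rabbit strains (albino New Zealand and pigmented
Dutch Belted) share one physiology.

## Parameters and defaults

Pinned by the case-study configuration: tear volumes 5/7 µL
(rabbit/human), pre-corneal maxima 35/37 µL, drainage 0.1 min⁻¹, 50 µL
drops of 6 mg/mL, 3 µm particles, and the drug parameter set in
`besifloxacin_parameters()` (permeabilities, systemic absorption rates,
$V_c$ 1.62 L/kg, $CL$ 15.42 L/h).

Ocular tissue volumes and exchange areas are **documented stand-in
defaults** from general ocular-anatomy literature (e.g. aqueous humor
0.3/0.25 mL, corneal surface 1.5/1.0 cm²); authoritative per-tissue
values are not public for the reference implementation of this model
class. They are overridable per run (`builtin_physiology(...,
overrides=)` or the YAML `physiology: overrides:` section), and every
headline quantity the package reports — dissolved-fraction arithmetic,
Weibull release and its recovery, volume kinetics, permeability
*recovery* (self-consistent generate-then-fit) — is insensitive to them
by construction. Absolute simulated tissue concentrations are **not**
insensitive to them, and should be interpreted accordingly.

## Numerical choices

* Internal units: µg, mL, h; all cm/s, s⁻¹ and per-minute inputs are
  converted on ingestion (0.1 min⁻¹ = 6 h⁻¹).
* Integration: `deSolve::lsoda` (adaptive, stiff-capable), rtol $10^{-8}$,
  atol $10^{-12}$ µg, with an integration restart at every dose event.
* Mass balance is audited at every output point; a relative error above
  $10^{-6}$ of the administered dose is a hard error, as is a negative
  amount beyond $10^{-9}$ µg.
* The vanishing-particle limit $r \to 0$ has an unbounded rate
  coefficient; dissolution is switched off below 1 µm·10⁻³ of radius or
  $10^{-6}$ µg of solid, leaving a sub-nanogram inert residue (relative
  error $\sim 10^{-9}$ of a dose).
* The Weibull release rate diverges as $t \to t_\mathrm{dose}^+$ for
  $b < 1$; the singularity is integrable and the restart at the dose
  time lets the solver start with small steps. The realised cumulative
  release matches the closed form to $\sim 10^{-6}$ relative.
* Fitting: least squares on log concentrations (observations below
  $10^{-4}$ µg/mL excluded), minimised by Nelder–Mead — Brent for a
  single parameter — in an unconstrained space obtained by a logistic
  box transform (log-spaced for rates and permeabilities), with five
  seeded multi-starts and a final polish. The reported estimate is never
  worse than the declared initial. Standard errors come from a
  finite-difference curvature of the objective and are indicative only.
  The objective and weighting of the reference tooling for this model
  class are not public; these choices are documented, not claimed
  identical.
* Weibull release can be fitted either to cumulative-release curves or
  to full tissue profiles; release-curve fitting is preferred where the
  point is the release estimate itself, because it decouples the result
  from the tissue-topology defaults.

## The synthetic-data generator

`generate_study()` emulates the destructive sparse-sampling designs of
ocular PK studies: simulate the true profiles, then per timepoint and
tissue draw $n$ mean-preserving lognormal deviates (CV as specified) and
report mean, SD and $n$. Lognormal noise was chosen because tissue
concentrations are strictly positive and reported SDs often exceed the
means, implying right skew. Destructive sampling draws independent
subjects per timepoint; serial sampling reuses one deviate per subject
across timepoints. Default timepoint grid: 0.25, 0.5, 1, 2, 4, 8, 12,
24 h; default CV 30% with $n=4$ — stand-ins for typical designs, since
true per-tissue inter-animal CVs are unknown.

What passing tests show: the machinery is self-consistent — parameters
used to generate data are recovered by fitting, conservation and
closed-form limits hold, and the noise model has the stated moments.
What they do not show: that the model reproduces any *real* animal or
clinical dataset; no observed concentration tables ship with the
package, and real tear-film dynamics (blinking, reflex tearing,
vehicle–mucin interaction) are far richer than a first-order drainage
law.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run single- and four-dose
simulations over 24 h on a 241-point grid, a 25-point release curve for
the three-parameter Weibull recovery, an 8-timepoint cornea profile for
the one-parameter permeability recovery, $10^4$ replicates for the
noise-model moment check, and a $10^{-4}$ h fixed-step Euler oracle over
2–3 h for the integrator cross-check. These sizes make the whole suite
run in well under a minute while leaving each check several digits of
headroom against its tolerance.

## Known limitations

* The lumped Weibull profile is conditional on the dissolved-fraction
  assumption; a different solubility implies a different fitted release
  profile. The package makes both inputs explicit rather than resolving
  the ambiguity.
* Monodisperse particles; single pH; no melanin binding (so pigmented-
  and albino-strain predictions coincide); no age/disease physiology
  variants; no mechanistic gel-swelling model.
* Tissue volumes/areas are defaults, so absolute deep-tissue
  concentrations carry their uncertainty.
* Repeated dosing pools newly instilled solid with existing solid at the
  formulation radius (a single-radius state); at realistic dosing gaps
  the approximation error is negligible because particles either
  dissolve or drain long before the next drop.
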