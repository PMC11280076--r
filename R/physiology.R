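#' Construct an ocular physiology
#'
#' An ocular physiology collects the species-specific anatomy the model
#' needs: baseline tear volume, the pre-corneal maximum volume (tear volume
#' plus the standard 30 uL an instilled drop can add before the excess
#' spills), the nasolacrimal drainage rate constant, baseline tear turnover,
#' aqueous humor turnover, tissue compartment volumes, exchange-surface
#' areas for every permitted transfer edge, and body weight.
#'
#' @param species_label One of `"NZ_rabbit"`, `"DB_rabbit"`, `"human"`.
#' @param tear_volume Baseline pre-corneal fluid volume (uL).
#' @param precornea_max_volume Maximum pre-corneal volume (uL); must equal
#'   `tear_volume + 30`.
#' @param drainage_rate First-order nasolacrimal drainage rate constant
#'   (1/min) acting on the excess pre-corneal volume.
#' @param tear_turnover_rate Baseline tear production/drainage flow (uL/min)
#'   at physiological volume; removes dissolved drug only.
#' @param aqueous_turnover_rate Aqueous humor turnover flow (uL/min),
#'   routed to the systemic compartment.
#' @param compartment_volumes Named numeric vector of tissue volumes (mL),
#'   one per compartment of [ocular_compartments()].
#' @param exchange_areas Named numeric vector of exchange areas (cm^2), one
#'   per edge label of [ocular_edges()].
#' @param body_weight Body weight (kg); used to convert the central volume
#'   of distribution (L/kg) to an absolute volume.
#' @return An object of class `ocular_physiology` (a named list).
#' @seealso [builtin_physiology()] for the shipped species defaults,
#'   [validate_physiology()] for the invariant checks.
#' @export
ocular_physiology <- function(species_label, tear_volume, precornea_max_volume,
                              drainage_rate, tear_turnover_rate,
                              aqueous_turnover_rate,
                              compartment_volumes, exchange_areas,
                              body_weight) {
  p <- structure(
    list(
      species_label = species_label,
      tear_volume = tear_volume,
      precornea_max_volume = precornea_max_volume,
      drainage_rate = drainage_rate,
      tear_turnover_rate = tear_turnover_rate,
      aqueous_turnover_rate = aqueous_turnover_rate,
      compartment_volumes = compartment_volumes,
      exchange_areas = exchange_areas,
      body_weight = body_weight
    ),
    class = "ocular_physiology"
  )
  violations <- validate_physiology(p)
  if (length(violations) > 0) {
    stop("invalid ocular_physiology:\n  ", paste(violations, collapse = "\n  "),
         call. = FALSE)
  }
  p
}

#' Built-in species physiologies
#'
#' Returns the shipped default physiology for a supported species. The
#' values that are pinned by the model configuration are: rabbit tear
#' volume 5 uL and human 7 uL; pre-corneal maximum volume 35 uL (rabbit)
#' and 37 uL (human), i.e. tear volume + 30 uL; drainage rate constant
#' 0.1 1/min for all species (the viscosity-adjusted value for the
#' suspension vehicle). Dutch Belted rabbits share the New Zealand white
#' physiology: the only strain difference a model would carry is melanin
#' binding, which is not modelled here.
#'
#' Tissue volumes and exchange areas are documented stand-in defaults drawn
#' from standard ocular-anatomy literature (e.g. aqueous humor ~0.3 mL in
#' rabbit, ~0.25 mL in human; corneal surface ~1.5 cm^2 rabbit, ~1.0 cm^2
#' human); they are deliberately overridable via `overrides` or the run
#' configuration, and none of the package's headline behaviours depend on
#' their exact values.
#'
#' @param species_label One of `"NZ_rabbit"`, `"DB_rabbit"`, `"human"`.
#' @param overrides Optional named list of fields to override (any
#'   constructor argument of [ocular_physiology()]; `compartment_volumes`
#'   and `exchange_areas` entries are merged element-wise).
#' @return An `ocular_physiology` object.
#' @examples
#' builtin_physiology("NZ_rabbit")$precornea_max_volume # 35
#' builtin_physiology("human")$tear_volume              # 7
#' @export
builtin_physiology <- function(species_label, overrides = NULL) {
  supported <- c("NZ_rabbit", "DB_rabbit", "human")
  if (!is.character(species_label) || length(species_label) != 1 ||
      !(species_label %in% supported)) {
    stop("unknown species label ", deparse(species_label),
         "; supported species: ", paste(supported, collapse = ", "),
         call. = FALSE)
  }

  if (species_label %in% c("NZ_rabbit", "DB_rabbit")) {
    args <- list(
      species_label = species_label,
      tear_volume = 5,
      precornea_max_volume = 35,
      drainage_rate = 0.1,
      tear_turnover_rate = 0.66,
      aqueous_turnover_rate = 3,
      compartment_volumes = c(
        cornea_epithelium = 0.006,
        cornea_stroma     = 0.054,
        conjunctiva       = 0.28,
        aqueous_humor     = 0.30,
        iris_ciliary_body = 0.06,
        sclera            = 0.54,
        choroid           = 0.07,
        retina            = 0.06,
        vitreous_humor    = 1.50
      ),
      exchange_areas = c(
        "precornea-cornea_epithelium"     = 1.5,
        "cornea_epithelium-cornea_stroma" = 1.5,
        "cornea_stroma-aqueous_humor"     = 1.5,
        "precornea-conjunctiva"           = 8.0,
        "conjunctiva-sclera"              = 8.0,
        "sclera-choroid"                  = 5.0,
        "choroid-retina"                  = 5.0,
        "retina-vitreous_humor"           = 5.0,
        "aqueous_humor-iris_ciliary_body" = 1.0,
        "aqueous_humor-vitreous_humor"    = 1.0
      ),
      body_weight = 2.5
    )
  } else {
    args <- list(
      species_label = "human",
      tear_volume = 7,
      precornea_max_volume = 37,
      drainage_rate = 0.1,
      tear_turnover_rate = 1.2,
      aqueous_turnover_rate = 2.5,
      compartment_volumes = c(
        cornea_epithelium = 0.005,
        cornea_stroma     = 0.060,
        conjunctiva       = 0.30,
        aqueous_humor     = 0.25,
        iris_ciliary_body = 0.07,
        sclera            = 0.70,
        choroid           = 0.20,
        retina            = 0.20,
        vitreous_humor    = 4.00
      ),
      exchange_areas = c(
        "precornea-cornea_epithelium"     = 1.0,
        "cornea_epithelium-cornea_stroma" = 1.0,
        "cornea_stroma-aqueous_humor"     = 1.0,
        "precornea-conjunctiva"           = 15.0,
        "conjunctiva-sclera"              = 15.0,
        "sclera-choroid"                  = 10.0,
        "choroid-retina"                  = 10.0,
        "retina-vitreous_humor"           = 10.0,
        "aqueous_humor-iris_ciliary_body" = 1.5,
        "aqueous_humor-vitreous_humor"    = 1.5
      ),
      body_weight = 70
    )
  }

  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (nm %in% c("compartment_volumes", "exchange_areas")) {
        vals <- unlist(overrides[[nm]])
        args[[nm]][names(vals)] <- vals
      } else {
        args[[nm]] <- overrides[[nm]]
      }
    }
  }
  do.call(ocular_physiology, args)
}

#' Validate an ocular physiology
#'
#' Checks every physiology invariant and returns a character vector of
#' human-readable violations (empty when the object is valid). Violations
#' are returned rather than raised so callers can aggregate them.
#'
#' Rules: all volumes, areas and rates strictly positive; the pre-corneal
#' maximum volume equals tear volume + 30 uL (the standard instilled-drop
#' allowance); compartment volumes and exchange areas cover exactly the
#' fixed model topology, with no missing or extra entries.
#'
#' @param p An `ocular_physiology`-like list.
#' @return Character vector of violation descriptions; `character(0)` when
#'   all invariants hold.
#' @export
validate_physiology <- function(p) {
  v <- character(0)
  pos_scalar <- function(name) {
    x <- p[[name]]
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      return(sprintf("%s must be a single strictly positive number", name))
    }
    character(0)
  }
  for (f in c("tear_volume", "precornea_max_volume", "drainage_rate",
              "tear_turnover_rate", "aqueous_turnover_rate", "body_weight")) {
    v <- c(v, pos_scalar(f))
  }

  if (is.numeric(p$tear_volume) && is.numeric(p$precornea_max_volume) &&
      length(p$tear_volume) == 1 && length(p$precornea_max_volume) == 1) {
    if (!isTRUE(all.equal(p$precornea_max_volume, p$tear_volume + 30))) {
      v <- c(v, sprintf(
        "precornea_max_volume (%g uL) must equal tear_volume + 30 uL (%g uL)",
        p$precornea_max_volume, p$tear_volume + 30))
    }
  }

  comps <- ocular_compartments()
  cv <- p$compartment_volumes
  missing_cv <- setdiff(comps, names(cv))
  extra_cv <- setdiff(names(cv), comps)
  if (length(missing_cv) > 0) {
    v <- c(v, paste0("compartment_volumes missing: ",
                     paste(missing_cv, collapse = ", ")))
  }
  if (length(extra_cv) > 0) {
    v <- c(v, paste0("compartment_volumes has unknown compartments: ",
                     paste(extra_cv, collapse = ", ")))
  }
  bad_cv <- names(cv)[!is.finite(cv) | cv <= 0]
  for (nm in bad_cv) {
    v <- c(v, sprintf("compartment_volumes[%s] must be strictly positive", nm))
  }

  edge_names <- ocular_edges()$edge
  ea <- p$exchange_areas
  missing_ea <- setdiff(edge_names, names(ea))
  extra_ea <- setdiff(names(ea), edge_names)
  if (length(missing_ea) > 0) {
    v <- c(v, paste0("exchange_areas missing edges: ",
                     paste(missing_ea, collapse = ", ")))
  }
  if (length(extra_ea) > 0) {
    v <- c(v, paste0("exchange_areas has unknown edges: ",
                     paste(extra_ea, collapse = ", ")))
  }
  bad_ea <- names(ea)[!is.finite(ea) | ea <= 0]
  for (nm in bad_ea) {
    v <- c(v, sprintf("exchange_areas[%s] must be strictly positive", nm))
  }

  v
}

#' @export
print.ocular_physiology <- function(x, ...) {
  cat(sprintf(
    "<ocular_physiology: %s>\n  tear volume %g uL, pre-cornea max %g uL\n",
    x$species_label, x$tear_volume, x$precornea_max_volume))
  cat(sprintf(
    "  drainage %g /min, tear turnover %g uL/min, AH turnover %g uL/min, BW %g kg\n",
    x$drainage_rate, x$tear_turnover_rate, x$aqueous_turnover_rate,
    x$body_weight))
  invisible(x)
}

#' Tabulate a physiology for auditing
#'
#' Flattens a physiology into a tidy two-column table (field, value) so
#' the full effective parameterisation can be written to a delimited file.
#'
#' @param x An `ocular_physiology`.
#' @param ... Unused.
#' @return A tibble with columns `field`, `value`, `units`.
#' @export
tidy.ocular_physiology <- function(x, ...) {
  scalars <- tibble::tibble(
    field = c("species_label", "tear_volume", "precornea_max_volume",
              "drainage_rate", "tear_turnover_rate", "aqueous_turnover_rate",
              "body_weight"),
    value = c(x$species_label, x$tear_volume, x$precornea_max_volume,
              x$drainage_rate, x$tear_turnover_rate, x$aqueous_turnover_rate,
              x$body_weight),
    units = c("", "uL", "uL", "1/min", "uL/min", "uL/min", "kg")
  )
  vols <- tibble::tibble(
    field = paste0("volume.", names(x$compartment_volumes)),
    value = as.character(unname(x$compartment_volumes)),
    units = "mL"
  )
  areas <- tibble::tibble(
    field = paste0("area.", names(x$exchange_areas)),
    value = as.character(unname(x$exchange_areas)),
    units = "cm^2"
  )
  dplyr::bind_rows(scalars, vols, areas)
}
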