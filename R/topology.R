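#' Fixed ocular model topology
#'
#' The compartmental structure is fixed: a pre-corneal tear compartment
#' feeding two absorption routes (cornea and conjunctiva), the anterior
#' chamber, and the posterior segment. These helpers enumerate the tissue
#' compartments and the permitted transfer edges so that physiologies and
#' parameter sets can be validated against one topology.
#'
#' @return `ocular_compartments()` returns the nine ocular tissue
#'   compartment names. `ocular_edges()` returns a data frame with one row
#'   per permitted transfer edge: the two endpoints (`from`, `to`), the
#'   edge label used for exchange areas, and `perm_tissue`, the tissue whose
#'   membrane permeability governs that interface (the deeper tissue of the
#'   pair, by convention).
#' @examples
#' ocular_compartments()
#' ocular_edges()
#' @export
ocular_compartments <- function() {
  c(
    "cornea_epithelium", "cornea_stroma", "conjunctiva", "aqueous_humor",
    "iris_ciliary_body", "sclera", "choroid", "retina", "vitreous_humor"
  )
}

#' @rdname ocular_compartments
#' @export
ocular_edges <- function() {
  edges <- tibble::tribble(
    ~from,               ~to,                  ~perm_tissue,
    "precornea",         "cornea_epithelium",  "cornea_epithelium",
    "cornea_epithelium", "cornea_stroma",      "cornea_stroma",
    "cornea_stroma",     "aqueous_humor",      "aqueous_humor",
    "precornea",         "conjunctiva",        "conjunctiva",
    "conjunctiva",       "sclera",             "sclera",
    "sclera",            "choroid",            "choroid",
    "choroid",           "retina",             "retina",
    "retina",            "vitreous_humor",     "vitreous_humor",
    "aqueous_humor",     "iris_ciliary_body",  "iris_ciliary_body",
    "aqueous_humor",     "vitreous_humor",     "vitreous_humor"
  )
  edges$edge <- paste(edges$from, edges$to, sep = "-")
  edges
}

# Tissues with direct systemic absorption (vascularised surfaces).
sar_tissues <- function() {
  c("conjunctiva", "iris_ciliary_body", "choroid", "retina")
}
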