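#' Element parameter table
#'
#' Per-element physicochemical parameters used when building molecular
#' interaction fields: van der Waals radius and Lennard-Jones well depth in the
#' style of the Tripos force field, a coarse element-level hydrophobicity
#' contribution, and whether the element can act as a hydrogen-bond donor or
#' acceptor. Synthetic molecules carry explicit per-atom properties and bypass
#' this table; for molecules read from chemical files the table supplies
#' defaults keyed on the element symbol.
#'
#' Radii are in Angstrom, well depths in kcal/mol. Hydrophobicity values are a
#' simplified element-level surrogate for fragment-based atom contributions
#' (carbon and sulfur positive, heteroatoms negative); they are dimensionless.
#'
#' @return A tibble with columns `element`, `vdw_radius`, `lj_depth`,
#'   `hydrophobicity`, `hba`, `hbd_capable`.
#' @export
element_parameters <- function() {
  tibble::tribble(
    ~element, ~vdw_radius, ~lj_depth, ~hydrophobicity, ~hba,  ~hbd_capable,
    "H",      1.50,        0.042,      0.10,           FALSE, FALSE,
    "C",      1.70,        0.107,      0.50,           FALSE, FALSE,
    "N",      1.55,        0.095,     -0.50,           TRUE,  TRUE,
    "O",      1.52,        0.116,     -0.50,           TRUE,  TRUE,
    "S",      1.80,        0.314,      0.30,           FALSE, FALSE,
    "P",      1.80,        0.314,     -0.30,           FALSE, FALSE,
    "F",      1.47,        0.109,      0.20,           TRUE,  FALSE,
    "Cl",     1.75,        0.314,      0.50,           FALSE, FALSE,
    "Br",     1.85,        0.434,      0.55,           FALSE, FALSE,
    "I",      1.98,        0.623,      0.60,           FALSE, FALSE
  )
}

# Fast lookup returning one row per element symbol; unknown elements error
# (fields must not be computed with silently-invented parameters).
lookup_element <- function(elements) {
  tab <- element_parameters()
  idx <- match(elements, tab$element)
  if (anyNA(idx)) {
    bad <- unique(elements[is.na(idx)])
    stop("no force-field parameters for element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab[idx, , drop = FALSE]
}

#' CoMFA probe atom parameters
#'
#' The CoMFA probe is an sp3 carbon bearing a +1 charge; the CoMSIA probe has
#' radius 1.0 Angstrom and all similarity properties equal to +1.
#'
#' @param kind `"comfa"` or `"comsia"`.
#' @return A list of probe properties.
#' @export
probe_spec <- function(kind = c("comfa", "comsia")) {
  kind <- match.arg(kind)
  if (kind == "comfa") {
    list(kind = "comfa", charge = 1.0, vdw_radius = 1.70, lj_depth = 0.107)
  } else {
    list(kind = "comsia", charge = 1.0, radius = 1.0, steric = 1.0,
         electrostatic = 1.0, hydrophobicity = 1.0, hbd = 1.0, hba = 1.0)
  }
}
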