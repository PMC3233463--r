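#' Construct a molecule
#'
#' A molecule is a tibble of atoms (one row per atom) carrying its identity,
#' bonds and optional activity as attributes. Atom columns are `element`,
#' Cartesian coordinates `x`, `y`, `z` (Angstrom), `charge` (partial charge,
#' elementary charge units), `vdw_radius` (Angstrom), `hydrophobicity`
#' (dimensionless atom contribution) and the logical hydrogen-bond flags
#' `is_hbd`, `is_hba`. Missing per-atom properties are filled from
#' [element_parameters()]; donor flags additionally require an attached
#' hydrogen, determined from the bond list.
#'
#' @param atoms Data frame with at least `element`, `x`, `y`, `z`. Optional:
#'   `charge`, `vdw_radius`, `hydrophobicity`, `is_hbd`, `is_hba`.
#' @param bonds Data frame with columns `i`, `j` (1-based atom indices) and
#'   optionally `order`; may be empty.
#' @param id Molecule identifier (string).
#' @param pic50 Optional activity, \eqn{-\log_{10}} of the IC50 in molar.
#' @param charges_present Logical; whether `charge` carries real values (as
#'   opposed to a zero placeholder).
#' @return A tibble of atoms with class `qsar_mol`.
#' @export
#' @examples
#' mol <- molecule(
#'   data.frame(element = c("C", "O"), x = c(0, 1.2), y = 0, z = 0),
#'   bonds = data.frame(i = 1, j = 2, order = 2), id = "co"
#' )
#' n_atoms(mol)
molecule <- function(atoms, bonds = NULL, id = "mol", pic50 = NA_real_,
                     charges_present = NULL) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(nrow(atoms) >= 1, all(c("element", "x", "y", "z") %in% names(atoms)))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates", call. = FALSE)
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- tibble::as_tibble(bonds)
    if (!("order" %in% names(bonds))) bonds$order <- 1L
    bonds <- bonds[, c("i", "j", "order")]
    if (any(bonds$i < 1 | bonds$i > nrow(atoms) | bonds$j < 1 | bonds$j > nrow(atoms)))
      stop("bond indices out of range", call. = FALSE)
  }

  el <- lookup_element(atoms$element)
  if (is.null(charges_present)) {
    charges_present <- "charge" %in% names(atoms) && !all(is.na(atoms$charge))
  }
  if (!("charge" %in% names(atoms))) atoms$charge <- NA_real_
  if (!("vdw_radius" %in% names(atoms))) atoms$vdw_radius <- el$vdw_radius
  atoms$vdw_radius[is.na(atoms$vdw_radius)] <- el$vdw_radius[is.na(atoms$vdw_radius)]
  if (any(atoms$vdw_radius <= 0)) stop("vdw_radius must be positive", call. = FALSE)
  if (!("hydrophobicity" %in% names(atoms))) atoms$hydrophobicity <- el$hydrophobicity
  atoms$hydrophobicity[is.na(atoms$hydrophobicity)] <-
    el$hydrophobicity[is.na(atoms$hydrophobicity)]

  # Donor flag needs connectivity: N/O with at least one bonded hydrogen.
  if (!("is_hbd" %in% names(atoms)) || any(is.na(atoms$is_hbd))) {
    has_h <- rep(FALSE, nrow(atoms))
    if (nrow(bonds) > 0) {
      h_idx <- which(atoms$element == "H")
      has_h <- vapply(seq_len(nrow(atoms)), function(k) {
        nb <- c(bonds$j[bonds$i == k], bonds$i[bonds$j == k])
        any(nb %in% h_idx)
      }, logical(1))
    }
    default_hbd <- el$hbd_capable & has_h
    if (!("is_hbd" %in% names(atoms))) atoms$is_hbd <- default_hbd
    atoms$is_hbd[is.na(atoms$is_hbd)] <- default_hbd[is.na(atoms$is_hbd)]
  }
  if (!("is_hba" %in% names(atoms))) atoms$is_hba <- el$hba
  atoms$is_hba[is.na(atoms$is_hba)] <- el$hba[is.na(atoms$is_hba)]
  atoms$is_hbd <- as.logical(atoms$is_hbd)
  atoms$is_hba <- as.logical(atoms$is_hba)

  if (!is.na(pic50) && !is.finite(pic50)) stop("pic50 must be finite", call. = FALSE)

  out <- atoms[, c("element", "x", "y", "z", "charge", "vdw_radius",
                   "hydrophobicity", "is_hbd", "is_hba")]
  structure(out,
            class = c("qsar_mol", class(tibble::tibble()))
            , id = as.character(id), pic50 = as.numeric(pic50),
            bonds = bonds, charges_present = isTRUE(charges_present))
}

#' @export
print.qsar_mol <- function(x, ...) {
  cat(sprintf("<qsar_mol '%s': %d atoms, %d bonds%s>\n", mol_id(x), nrow(x),
              nrow(mol_bonds(x)),
              if (!is.na(mol_pic50(x))) sprintf(", pIC50 %.3f", mol_pic50(x)) else ""))
  NextMethod()
}

#' Molecule accessors
#'
#' @param mol A `qsar_mol`.
#' @return `mol_id()` the identifier, `mol_pic50()` the activity (`NA` if
#'   unset), `mol_bonds()` the bond tibble, `coords()` the n x 3 coordinate
#'   matrix, `n_atoms()` the atom count, `has_charges()` whether partial
#'   charges were supplied rather than defaulted.
#' @export
mol_id <- function(mol) attr(mol, "id")

#' @rdname mol_id
#' @export
mol_pic50 <- function(mol) attr(mol, "pic50")

#' @rdname mol_id
#' @export
mol_bonds <- function(mol) attr(mol, "bonds")

#' @rdname mol_id
#' @export
coords <- function(mol) unname(as.matrix(mol[, c("x", "y", "z")]))

#' @rdname mol_id
#' @export
n_atoms <- function(mol) nrow(mol)

#' @rdname mol_id
#' @export
has_charges <- function(mol) isTRUE(attr(mol, "charges_present"))

# Replace coordinates, preserving molecule attributes.
set_coords <- function(mol, xyz) {
  mol$x <- xyz[, 1]; mol$y <- xyz[, 2]; mol$z <- xyz[, 3]
  mol
}

#' Bundle molecules into a molecule-set tibble
#'
#' The package's tabular working unit: one row per molecule with columns `id`,
#' `mol` (list-column of [molecule()] objects), `n_atoms` and `pic50`.
#'
#' @param mols List of `qsar_mol` objects.
#' @return A tibble, one row per molecule.
#' @export
molecule_set <- function(mols) {
  if (length(mols) == 0) stop("no molecules", call. = FALSE)
  ids <- vapply(mols, mol_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "),
                               call. = FALSE)
  tibble::tibble(
    id = ids,
    n_atoms = vapply(mols, n_atoms, integer(1)),
    pic50 = vapply(mols, mol_pic50, numeric(1)),
    mol = mols
  )
}

#' Attach activities and train/test roles to a molecule set
#'
#' Builds the modelling dataset: every molecule receives a pIC50 and a role
#' (`"train"` or `"test"`). Roles may come from an explicit test-id list or
#' from [split_dataset()].
#'
#' @param data Molecule-set tibble from [molecule_set()] or [read_molecules()].
#' @param activities Named numeric vector or tibble (`id`, `pic50`), e.g. from
#'   [load_activity_table()]. If `NULL`, activities already present on the
#'   molecules are used.
#' @param test_ids Character vector of test-set molecule ids (may be empty).
#' @return The tibble with `pic50` and `role` columns filled in, classed
#'   `qsar_dataset`.
#' @export
qsar_dataset <- function(data, activities = NULL, test_ids = character()) {
  if (!is.null(activities)) {
    if (is.data.frame(activities)) {
      act <- stats::setNames(activities$pic50, activities$id)
    } else act <- activities
    missing <- setdiff(data$id, names(act))
    if (length(missing) > 0)
      stop("no activity for molecule(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    data$pic50 <- unname(act[data$id])
    data$mol <- purrr::map2(data$mol, data$pic50, function(m, y) {
      attr(m, "pic50") <- y; m
    })
  }
  if (any(!is.finite(data$pic50)))
    stop("every molecule needs a finite pIC50", call. = FALSE)
  unknown <- setdiff(test_ids, data$id)
  if (length(unknown) > 0)
    stop("unknown test id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  data$role <- ifelse(data$id %in% test_ids, "test", "train")
  class(data) <- unique(c("qsar_dataset", class(data)))
  data
}

train_idx <- function(data) which(data$role == "train")
test_idx <- function(data) which(data$role == "test")
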