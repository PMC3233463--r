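#' Build a regular lattice enclosing aligned molecules
#'
#' The grid box is the union bounding box of all atoms, extended by `margin`
#' on every face and snapped outward to whole grid steps (so the box spans an
#' integer number of spacings; a degenerate box still gets two planes per
#' axis). Lattice points are ordered x-fastest, then y, then z, which fixes
#' the descriptor column order.
#'
#' @param data Molecule-set tibble (aligned), or a list of `qsar_mol`.
#' @param spacing Lattice spacing in Angstrom (default 2.0).
#' @param margin Margin added on every face in Angstrom (default 4.0,
#'   the usual automatic-box convention).
#' @return A list of class `grid_spec`: `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(data, spacing = 2.0, margin = 4.0) {
  mols <- if (is.data.frame(data)) data$mol else data
  if (length(mols) == 0) stop("no molecules to grid", call. = FALSE)
  stopifnot(spacing > 0, margin >= 0)
  xyz <- do.call(rbind, lapply(mols, coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  steps <- pmax(1L, as.integer(ceiling((hi - lo) / spacing - 1e-9)))
  grid_spec(origin = lo, spacing = spacing, dims = steps + 1L)
}

#' Construct a grid specification
#' @param origin Lattice origin (length-3, Angstrom).
#' @param spacing Lattice spacing (Angstrom).
#' @param dims Integer lattice dimensions (nx, ny, nz), each >= 2.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(origin, spacing, dims) {
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(dims) == 3, all(dims >= 2), spacing > 0)
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: %d x %d x %d points, spacing %.2f A, origin (%.2f, %.2f, %.2f)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Lattice point coordinates
#'
#' @param grid A `grid_spec`.
#' @return An n x 3 matrix of lattice point coordinates, x varying fastest.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(k) grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1))
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  pts
}

n_grid_points <- function(grid) prod(grid$dims)

# squared distances, points (p x 3) x atoms (m x 3) -> p x m
dist2_points_atoms <- function(pts, axyz) {
  outer(pts[, 1], axyz[, 1], "-")^2 +
    outer(pts[, 2], axyz[, 2], "-")^2 +
    outer(pts[, 3], axyz[, 3], "-")^2
}

#' CoMFA steric field row for one molecule
#'
#' Lennard-Jones 6-12 probe energies at every lattice point, using an sp3
#' carbon probe: \eqn{E = \sum_i \epsilon_i [(R_i/r)^{12} - 2 (R_i/r)^6]} with
#' \eqn{R_i} the sum of probe and atom van der Waals radii and \eqn{\epsilon_i}
#' the geometric mean of the well depths. Values are truncated to
#' +/- `truncation` kcal/mol.
#'
#' @param mol A `qsar_mol`.
#' @param grid A `grid_spec`.
#' @param probe Probe parameters, see [probe_spec()].
#' @param truncation Truncation level in kcal/mol (default 30).
#' @return Numeric vector, one energy per lattice point.
#' @export
comfa_steric <- function(mol, grid, probe = probe_spec("comfa"), truncation = 30) {
  el <- lookup_element(mol$element)
  pts <- grid_points(grid)
  d2 <- dist2_points_atoms(pts, coords(mol))
  r2 <- pmax(d2, 1e-12)
  Rij <- mol$vdw_radius + probe$vdw_radius
  eps <- sqrt(el$lj_depth * probe$lj_depth)
  s6 <- sweep(1 / r2, 2, Rij^2, "*")^3        # (Rij^2/r^2)^3 = (Rij/r)^6
  e <- s6 * (s6 - 2)                           # (Rij/r)^12 - 2 (Rij/r)^6
  val <- as.vector(e %*% eps)
  pmin(pmax(val, -truncation), truncation)
}

#' CoMFA electrostatic field row for one molecule
#'
#' Coulomb probe energies with a distance-dependent dielectric
#' \eqn{\epsilon(r) = r} (so \eqn{E = 332.0636\, q_{probe} \sum_i q_i / r_i^2}
#' in kcal/mol) or a constant dielectric of 1, truncated to +/- `truncation`.
#' Replacement of values at sterically excluded points is handled at the
#' block level by [compute_field_block()].
#'
#' @inheritParams comfa_steric
#' @param dielectric `"distance"` (default) or `"constant"`.
#' @return Numeric vector, one energy per lattice point.
#' @export
comfa_electrostatic <- function(mol, grid, probe = probe_spec("comfa"),
                                truncation = 30,
                                dielectric = c("distance", "constant")) {
  dielectric <- match.arg(dielectric)
  if (!has_charges(mol) || any(!is.finite(mol$charge)))
    stop("molecule ", mol_id(mol), " has no partial charges", call. = FALSE)
  pts <- grid_points(grid)
  d2 <- pmax(dist2_points_atoms(pts, coords(mol)), 1e-12)
  denom <- if (dielectric == "distance") d2 else sqrt(d2)
  val <- 332.0636 * probe$charge * as.vector((1 / denom) %*% mol$charge)
  pmin(pmax(val, -truncation), truncation)
}

comsia_kinds <- c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")

comsia_atom_property <- function(mol, kind) {
  switch(kind,
         steric = mol$vdw_radius^3,
         electrostatic = {
           if (!has_charges(mol) || any(!is.finite(mol$charge)))
             stop("molecule ", mol_id(mol), " has no partial charges", call. = FALSE)
           mol$charge
         },
         hydrophobic = mol$hydrophobicity,
         donor = as.numeric(mol$is_hbd),
         acceptor = as.numeric(mol$is_hba),
         stop("unknown CoMSIA property kind: ", kind, call. = FALSE))
}

comsia_probe_property <- function(probe, kind) {
  switch(kind, steric = probe$steric, electrostatic = probe$electrostatic,
         hydrophobic = probe$hydrophobicity, donor = probe$hbd,
         acceptor = probe$hba)
}

#' CoMSIA similarity-index field row for one molecule
#'
#' Gaussian-attenuated similarity indices
#' \eqn{A_{F,k}^q(j) = -\sum_i \omega_{probe,k}\, \omega_{ik}\, e^{-\alpha r_{iq}^2}}
#' evaluated at every lattice point \eqn{q}, where \eqn{\omega_{ik}} is the
#' atom's value of property \eqn{k} (steric: \eqn{r_{vdW}^3}; electrostatic:
#' partial charge; hydrophobic: atom contribution; donor/acceptor: 0/1 flags)
#' and the probe carries +1 for every property. No truncation is applied.
#'
#' @inheritParams comfa_steric
#' @param kind One of `"steric"`, `"electrostatic"`, `"hydrophobic"`,
#'   `"donor"`, `"acceptor"`.
#' @param alpha Gaussian attenuation factor (default 0.3).
#' @return Numeric vector, one similarity index per lattice point.
#' @export
comsia_field <- function(mol, grid, kind, alpha = 0.3,
                         probe = probe_spec("comsia")) {
  kind <- match.arg(kind, comsia_kinds)
  w <- comsia_atom_property(mol, kind)
  wp <- comsia_probe_property(probe, kind)
  d2 <- dist2_points_atoms(grid_points(grid), coords(mol))
  -wp * as.vector(exp(-alpha * d2) %*% w)
}

#' Compute one molecular-field block for a whole dataset
#'
#' Evaluates a CoMFA or CoMSIA field of one kind for every molecule, returning
#' the molecules x lattice-points value matrix. For the CoMFA electrostatic
#' block, values at points where the molecule's steric field is clamped at the
#' truncation ceiling (probe inside the molecule) are replaced by the column
#' mean of the unclamped training molecules — the usual lattice-analysis
#' convention — and the replacements are recorded in the block's `clamped`
#' attribute.
#'
#' @param data Molecule-set or `qsar_dataset` tibble (aligned).
#' @param kind Field kind: `"steric"`, `"electrostatic"` for CoMFA;
#'   any of the five CoMSIA kinds for CoMSIA.
#' @param method `"comfa"` or `"comsia"`.
#' @param grid A `grid_spec`.
#' @param truncation CoMFA truncation (kcal/mol).
#' @param alpha CoMSIA attenuation factor.
#' @param dielectric CoMFA electrostatic dielectric model.
#' @return A list of class `field_block`: `kind`, `method`, `values`
#'   (n_molecules x n_points matrix, rows in dataset order), `grid`, and the
#'   parameters used.
#' @export
compute_field_block <- function(data, kind, method = c("comfa", "comsia"),
                                grid, truncation = 30, alpha = 0.3,
                                dielectric = "distance") {
  method <- match.arg(method)
  mols <- data$mol
  n <- length(mols)
  if (method == "comfa") {
    kind <- match.arg(kind, c("steric", "electrostatic"))
    probe <- probe_spec("comfa")
    if (kind == "steric") {
      vals <- t(vapply(mols, comfa_steric, numeric(n_grid_points(grid)),
                       grid = grid, probe = probe, truncation = truncation))
      clamped <- vals >= truncation - 1e-12
    } else {
      vals <- t(vapply(mols, comfa_electrostatic, numeric(n_grid_points(grid)),
                       grid = grid, probe = probe, truncation = truncation,
                       dielectric = dielectric))
      steric <- t(vapply(mols, comfa_steric, numeric(n_grid_points(grid)),
                         grid = grid, probe = probe, truncation = truncation))
      clamped <- steric >= truncation - 1e-12
      if (any(clamped)) {
        ref_rows <- if ("role" %in% names(data)) which(data$role == "train")
                    else seq_len(n)
        for (jcol in which(colSums(clamped) > 0)) {
          ok <- ref_rows[!clamped[ref_rows, jcol]]
          fill <- if (length(ok) > 0) mean(vals[ok, jcol]) else 0
          vals[clamped[, jcol], jcol] <- fill
        }
      }
    }
  } else {
    kind <- match.arg(kind, comsia_kinds)
    vals <- t(vapply(mols, comsia_field, numeric(n_grid_points(grid)),
                     grid = grid, kind = kind, alpha = alpha))
    clamped <- NULL
  }
  rownames(vals) <- data$id
  if (!is.null(clamped)) dimnames(clamped) <- dimnames(vals)
  structure(list(kind = kind, method = method, values = vals, grid = grid,
                 truncation = if (method == "comfa") truncation else NA_real_,
                 alpha = if (method == "comsia") alpha else NA_real_),
            class = "field_block", clamped = clamped)
}

#' @export
print.field_block <- function(x, ...) {
  cat(sprintf("<field_block %s/%s: %d molecules x %d points>\n", x$method,
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Assemble the descriptor matrix from field blocks
#'
#' Concatenates field blocks column-wise into the PLS descriptor matrix and
#' builds per-column metadata mapping each column back to its block and
#' lattice position.
#'
#' @param data Molecule-set or `qsar_dataset` tibble (row order must match the
#'   blocks).
#' @param blocks List of `field_block`s sharing one grid and molecule order.
#' @return A list of class `descriptor_matrix`: `X` (n x p), `metadata`
#'   (tibble: `column`, `block`, `method`, `kind`, `point`, `ix`, `iy`, `iz`,
#'   `x`, `y`, `z`), `grid`.
#' @export
assemble_descriptor_matrix <- function(data, blocks) {
  stopifnot(length(blocks) >= 1)
  g <- blocks[[1]]$grid
  for (b in blocks) {
    if (!isTRUE(all.equal(b$grid, g))) stop("blocks use different grids", call. = FALSE)
    if (nrow(b$values) != nrow(data)) stop("block/molecule count mismatch", call. = FALSE)
    if (!identical(rownames(b$values), data$id))
      stop("block row order does not match dataset", call. = FALSE)
  }
  np <- n_grid_points(g)
  idx <- arrayInd(seq_len(np), g$dims)
  pts <- grid_points(g)
  meta <- purrr::imap_dfr(blocks, function(b, bi) {
    tibble::tibble(block = paste(b$method, b$kind, sep = "_"), method = b$method,
                   kind = b$kind, point = seq_len(np),
                   ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
  meta$column <- seq_len(nrow(meta))
  meta <- meta[, c("column", "block", "method", "kind", "point",
                   "ix", "iy", "iz", "x", "y", "z")]
  X <- do.call(cbind, lapply(blocks, function(b) b$values))
  colnames(X) <- paste(meta$block, meta$point, sep = ".")
  structure(list(X = X, metadata = meta, grid = g), class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix: %d molecules x %d columns (%s)>\n",
              nrow(x$X), ncol(x$X), paste(unique(x$metadata$block), collapse = ", ")))
  invisible(x)
}

#' Drop near-constant descriptor columns
#'
#' Removes columns whose standard deviation across the training molecules is
#' below `min_sigma` (the "minimum sigma" column filter of lattice QSAR
#' programs). Filtering is always decided on training rows only.
#'
#' @param desc A `descriptor_matrix`.
#' @param min_sigma Threshold in field units; 0 keeps everything.
#' @param train Integer indices of training rows (default: the `role` column
#'   of the dataset used to build the matrix, else all rows).
#' @return The filtered `descriptor_matrix`; dropped columns are recorded in
#'   the `dropped` attribute (original column numbers).
#' @export
filter_columns <- function(desc, min_sigma = 0, train = NULL) {
  stopifnot(min_sigma >= 0)
  X <- desc$X
  if (is.null(train)) train <- seq_len(nrow(X))
  sds <- apply(X[train, , drop = FALSE], 2, stats::sd)
  keep <- sds >= min_sigma | (min_sigma == 0)
  if (!any(keep)) stop("min_sigma removed every column", call. = FALSE)
  out <- structure(list(X = X[, keep, drop = FALSE],
                        metadata = desc$metadata[keep, , drop = FALSE],
                        grid = desc$grid),
                   class = "descriptor_matrix",
                   dropped = desc$metadata$column[!keep])
  out
}
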