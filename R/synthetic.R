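#' Default scaffold for synthetic congeneric series
#'
#' A rigid anchor every generated molecule shares: a phosphate group (the
#' alignment anchor matched by [default_anchor_pattern()]) linked through an
#' ester oxygen to a three-atom core. Atoms carry explicit partial charges and
#' per-atom properties so generated series never require charge assignment.
#'
#' @return A list with `atoms` (tibble) and `bonds` (tibble).
#' @export
default_scaffold <- function() {
  atoms <- tibble::tribble(
    ~element, ~x,    ~y,    ~z,     ~charge, ~is_hbd, ~is_hba,
    "P",      0.00,  0.00,  0.00,    1.40,   FALSE,   FALSE,
    "O",      1.48,  0.00,  0.00,   -0.60,   FALSE,   TRUE,
    "O",     -0.49,  1.40,  0.00,   -0.90,   FALSE,   TRUE,
    "O",     -0.49, -0.70,  1.21,   -0.90,   FALSE,   TRUE,
    "O",     -0.49, -0.70, -1.21,   -0.90,   FALSE,   TRUE,
    "C",      2.90,  0.40,  0.20,    0.10,   FALSE,   FALSE,
    "C",      4.20, -0.30,  0.10,    0.00,   FALSE,   FALSE,
    "N",      5.35,  0.45,  0.25,   -0.40,   TRUE,    TRUE
  )
  bonds <- tibble::tibble(i = c(1, 1, 1, 1, 2, 6, 7),
                          j = c(2, 3, 4, 5, 6, 7, 8),
                          order = 1L)
  list(atoms = atoms, bonds = bonds)
}

#' Default substituent sites
#'
#' Candidate positions for variable pseudo-atoms, each attached to a scaffold
#' atom. Sites sit 1.5-3.5 Angstrom from the core so substituent occupancy
#' modulates the molecular fields at nearby receptor centers.
#'
#' @return Tibble `site`, `x`, `y`, `z`, `attach` (scaffold atom index).
#' @export
default_substituent_sites <- function() {
  tibble::tribble(
    ~site, ~x,   ~y,    ~z,    ~attach,
    1L,    5.20, -1.60,  0.00,  7L,
    2L,    6.70,  0.10,  0.40,  8L,
    3L,    5.60,  1.90,  0.50,  8L,
    4L,    3.00,  1.90,  0.40,  6L,
    5L,    4.30, -0.50, -1.70,  7L,
    6L,    4.40, -0.40,  1.90,  7L
  )
}

#' Synthetic pseudo-receptor specification
#'
#' The planted ground truth: weighted interaction centers in the aligned
#' frame. A molecule's noiseless activity is
#' `activity_offset + sum(weight * field value at the center)`, where the
#' field value is the CoMSIA similarity index of the center's kind.
#'
#' @param centers Tibble with `x`, `y`, `z`, `kind` (CoMSIA kind) and `weight`
#'   (pIC50 per field unit).
#' @param noise_sd Activity noise standard deviation (pIC50 units).
#' @param activity_offset Baseline activity (pIC50).
#' @param seed Integer seed for the noise draw.
#' @return A list of class `receptor_spec`.
#' @export
receptor_spec <- function(centers, noise_sd = 0.1, activity_offset = 6.4,
                          seed = 1L) {
  centers <- tibble::as_tibble(centers)
  stopifnot(nrow(centers) >= 1,
            all(c("x", "y", "z", "kind", "weight") %in% names(centers)),
            noise_sd >= 0)
  centers$kind <- vapply(centers$kind, match.arg, character(1),
                         choices = comsia_kinds)
  structure(list(centers = centers, noise_sd = noise_sd,
                 activity_offset = activity_offset, seed = as.integer(seed)),
            class = "receptor_spec")
}

#' Default pseudo-receptor
#'
#' Centers placed at the default substituent sites, mixing steric,
#' electrostatic and hydrogen-bond kinds with both favourable and
#' unfavourable weights.
#'
#' @inheritParams receptor_spec
#' @return A `receptor_spec`.
#' @export
default_receptor_spec <- function(noise_sd = 0.1, seed = 1L) {
  s <- default_substituent_sites()
  centers <- tibble::tibble(
    x = s$x, y = s$y, z = s$z,
    kind = c("steric", "steric", "electrostatic", "electrostatic",
             "acceptor", "hydrophobic"),
    weight = c(-0.60, 0.45, 2.4, -2.0, -1.2, 0.9)
  )
  receptor_spec(centers, noise_sd = noise_sd, seed = seed)
}

#' @export
print.receptor_spec <- function(x, ...) {
  cat(sprintf("<receptor_spec: %d centers, noise_sd %.3g, offset %.3g>\n",
              nrow(x$centers), x$noise_sd, x$activity_offset))
  invisible(x)
}

#' Generate a synthetic congeneric series
#'
#' Builds `n_molecules` molecules sharing the scaffold anchor, each with a
#' random subset of substituent sites occupied by pseudo-atoms (randomised
#' element, charge and properties; position jittered by `jitter_sd` about the
#' site). Every molecule is emitted at a random rigid pose so downstream
#' alignment is exercised. Deterministic given `seed`.
#'
#' @param n_molecules Number of molecules (>= 4).
#' @param scaffold Scaffold definition, see [default_scaffold()].
#' @param sites Substituent sites, see [default_substituent_sites()].
#' @param seed Integer seed.
#' @param p_occupy Per-site occupancy probability.
#' @param jitter_sd Site position jitter (Angstrom).
#' @param pose Emit molecules at random rigid poses (default TRUE).
#' @return A molecule-set tibble.
#' @export
generate_series <- function(n_molecules = 105, scaffold = default_scaffold(),
                            sites = default_substituent_sites(), seed = 1L,
                            p_occupy = 0.5, jitter_sd = 0.3, pose = TRUE) {
  stopifnot(n_molecules >= 4)
  anchor_xyz <- as.matrix(scaffold$atoms[, c("x", "y", "z")])
  if (nrow(anchor_xyz) < 3 || svd(scale(anchor_xyz, scale = FALSE))$d[2] < 1e-6)
    stop("degenerate scaffold: need >= 3 non-collinear anchor atoms", call. = FALSE)
  elements <- c("C", "N", "O", "S", "Cl")
  el_prob <- c(0.4, 0.2, 0.2, 0.1, 0.1)
  el_charge <- c(C = 0.05, N = -0.30, O = -0.35, S = 0.00, Cl = -0.15)
  etab <- element_parameters()
  with_local_seed(seed, {
    mols <- lapply(seq_len(n_molecules), function(m) {
      atoms <- scaffold$atoms
      bonds <- scaffold$bonds
      occupied <- if (nrow(sites) > 0) stats::runif(nrow(sites)) < p_occupy
                  else logical(0)
      for (s in which(occupied)) {
        el <- sample(elements, 1, prob = el_prob)
        er <- etab[match(el, etab$element), ]
        atoms <- dplyr::bind_rows(atoms, tibble::tibble(
          element = el,
          x = sites$x[s] + stats::rnorm(1, 0, jitter_sd),
          y = sites$y[s] + stats::rnorm(1, 0, jitter_sd),
          z = sites$z[s] + stats::rnorm(1, 0, jitter_sd),
          charge = stats::rnorm(1, el_charge[[el]], 0.10),
          is_hbd = er$hbd_capable && stats::runif(1) < 0.3,
          is_hba = er$hba
        ))
        bonds <- dplyr::bind_rows(bonds, tibble::tibble(
          i = sites$attach[s], j = nrow(atoms), order = 1L))
      }
      mol <- molecule(atoms, bonds, id = sprintf("mol%03d", m),
                      charges_present = TRUE)
      if (pose) {
        A <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
        if (det(A) < 0) A[, 1] <- -A[, 1]
        shift <- stats::runif(3, -8, 8)
        mol <- set_coords(mol, sweep(coords(mol) %*% t(A), 2, shift, "+"))
      }
      mol
    })
    molecule_set(mols)
  })
}

# CoMSIA similarity value of one molecule at arbitrary probe positions.
comsia_value_at <- function(mol, pts, kind, alpha = 0.3,
                            probe = probe_spec("comsia")) {
  w <- comsia_atom_property(mol, kind)
  wp <- comsia_probe_property(probe, kind)
  d2 <- dist2_points_atoms(matrix(pts, ncol = 3), coords(mol))
  -wp * as.vector(exp(-alpha * d2) %*% w)
}

#' Plant activities from a pseudo-receptor
#'
#' Assigns each aligned molecule the activity
#' `offset + sum_c weight_c * A_c(molecule) + noise`, where `A_c` is the
#' CoMSIA similarity index of center `c`'s kind evaluated at its position.
#' When `rescale_to` is given (default the conventional assay range
#' 4.87-8.00) the noiseless signal is first mapped linearly onto that range
#' and the effective center weights are rescaled accordingly; the returned
#' dataset's `ground_truth` attribute records the effective receptor, the
#' noiseless signal and the noise draws.
#'
#' @param data Aligned molecule-set tibble.
#' @param receptor A `receptor_spec`.
#' @param grid A `grid_spec`; every center must lie inside it.
#' @param alpha CoMSIA attenuation factor used for the planted fields.
#' @param rescale_to Target activity range, or `NULL` to use raw signal.
#' @return The tibble with `pic50` filled in and a `ground_truth` attribute.
#' @export
plant_activities <- function(data, receptor, grid, alpha = 0.3,
                             rescale_to = c(4.87, 8.00)) {
  centers <- receptor$centers
  lo <- grid$origin - 1e-9
  hi <- grid$origin + (grid$dims - 1) * grid$spacing + 1e-9
  cxyz <- as.matrix(centers[, c("x", "y", "z")])
  inside <- cxyz[, 1] >= lo[1] & cxyz[, 1] <= hi[1] &
    cxyz[, 2] >= lo[2] & cxyz[, 2] <= hi[2] &
    cxyz[, 3] >= lo[3] & cxyz[, 3] <= hi[3]
  if (!all(inside))
    stop("receptor center(s) outside the grid box: ",
         paste(which(!inside), collapse = ", "), call. = FALSE)
  V <- vapply(seq_len(nrow(centers)), function(c_i) {
    vapply(data$mol, function(mol)
      comsia_value_at(mol, cxyz[c_i, , drop = FALSE], centers$kind[c_i],
                      alpha = alpha),
      numeric(1))
  }, numeric(nrow(data)))
  signal <- receptor$activity_offset + as.vector(V %*% centers$weight)
  eff <- receptor
  if (!is.null(rescale_to) && diff(range(signal)) > 1e-12) {
    a <- diff(rescale_to) / diff(range(signal))
    b <- rescale_to[1] - a * min(signal)
    signal <- a * signal + b
    eff$centers$weight <- centers$weight * a
    eff$activity_offset <- receptor$activity_offset * a + b
  }
  noise <- with_local_seed(receptor$seed,
                           stats::rnorm(nrow(data), 0, receptor$noise_sd))
  y <- signal + noise
  data$pic50 <- y
  data$mol <- purrr::map2(data$mol, y, function(m, yy) {
    attr(m, "pic50") <- yy; m
  })
  attr(data, "ground_truth") <- list(receptor = eff, signal = signal,
                                     noise = noise)
  data
}

#' Snap receptor centers to the nearest lattice points
#'
#' With centers exactly on lattice points the planted activity is an exact
#' linear function of the CoMSIA descriptor columns, which makes the pipeline
#' fully identifiable at zero noise.
#'
#' @param receptor A `receptor_spec`.
#' @param grid A `grid_spec`.
#' @return The receptor with center coordinates snapped.
#' @export
snap_centers <- function(receptor, grid) {
  cxyz <- as.matrix(receptor$centers[, c("x", "y", "z")])
  for (k in 1:3) {
    steps <- round((cxyz[, k] - grid$origin[k]) / grid$spacing)
    steps <- pmin(pmax(steps, 0), grid$dims[k] - 1)
    cxyz[, k] <- grid$origin[k] + steps * grid$spacing
  }
  receptor$centers$x <- cxyz[, 1]
  receptor$centers$y <- cxyz[, 2]
  receptor$centers$z <- cxyz[, 3]
  receptor
}

#' Canonicalize an aligned series into the scaffold frame
#'
#' After [align_dataset()] the common frame is the template's emitted pose.
#' Receptor centers and substituent sites are defined in the scaffold's
#' canonical coordinates, so synthetic workflows superpose the template's
#' anchor atoms (the first scaffold atoms, shared by construction) back onto
#' the canonical scaffold and apply that transform to every molecule.
#'
#' @param data Aligned molecule-set tibble from [generate_series()] +
#'   [align_dataset()].
#' @param scaffold The scaffold the series was generated from.
#' @return The tibble with all molecules in the canonical scaffold frame.
#' @export
canonicalize_frame <- function(data, scaffold = default_scaffold()) {
  n_anchor <- nrow(scaffold$atoms)
  ref <- as.matrix(scaffold$atoms[, c("x", "y", "z")])
  tf <- superpose(coords(data$mol[[1]])[seq_len(n_anchor), , drop = FALSE], ref)
  if (tf$rmsd > 1e-6)
    stop("first molecule's leading atoms do not match the scaffold (rmsd ",
         format(tf$rmsd), ")", call. = FALSE)
  data$mol <- lapply(data$mol, function(m)
    set_coords(m, apply_transform(coords(m), tf)))
  data
}

#' Generate a complete synthetic QSAR study
#'
#' One-stop generator for testing the whole pipeline: generates a posed
#' congeneric series, aligns it on its first molecule, canonicalizes into the
#' scaffold frame, builds the lattice, snaps the pseudo-receptor centers onto
#' it, plants activities and splits into training and test sets.
#'
#' @inheritParams generate_series
#' @param receptor A `receptor_spec` (default [default_receptor_spec()]).
#' @param test_fraction Test-set fraction for [split_dataset()].
#' @param spacing,margin Lattice geometry passed to [build_grid()].
#' @param alpha CoMSIA attenuation for the planted fields.
#' @param rescale_to Activity range passed to [plant_activities()].
#' @return A list: `data` (a `qsar_dataset`, aligned, activities planted),
#'   `receptor` (effective, snapped), `grid`, `ground_truth`.
#' @export
synthetic_qsar_data <- function(n_molecules = 105,
                                receptor = default_receptor_spec(),
                                seed = 1L, test_fraction = 28 / 105,
                                spacing = 2.0, margin = 4.0, alpha = 0.3,
                                p_occupy = 0.5, jitter_sd = 0.3,
                                rescale_to = c(4.87, 8.00)) {
  ser <- generate_series(n_molecules, seed = seed, p_occupy = p_occupy,
                         jitter_sd = jitter_sd)
  al <- align_dataset(ser, ser$id[1])
  al <- canonicalize_frame(al)
  al$align_rmsd <- NULL
  grid <- build_grid(al, spacing, margin)
  rec <- snap_centers(receptor, grid)
  planted <- plant_activities(al, rec, grid, alpha = alpha,
                              rescale_to = rescale_to)
  gt <- attr(planted, "ground_truth")
  data <- split_dataset(planted, test_fraction = test_fraction,
                        seed = receptor$seed + 1000L)
  attr(data, "ground_truth") <- gt
  list(data = data, receptor = gt$receptor, grid = grid, ground_truth = gt)
}

# lattice point index (x fastest) nearest to a coordinate
nearest_point_index <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  idx <- sapply(1:3, function(k) {
    s <- round((xyz[, k] - grid$origin[k]) / grid$spacing)
    pmin(pmax(s, 0), grid$dims[k] - 1)
  })
  idx <- matrix(idx, ncol = 3)
  as.integer(idx[, 1] + idx[, 2] * grid$dims[1] +
               idx[, 3] * grid$dims[1] * grid$dims[2] + 1)
}

#' Ground-truth recovery report
#'
#' Measures how well a fitted model recovers the planted pseudo-receptor:
#' the sign of the StDev*Coeff value at each planted center (nearest lattice
#' point, matching field kind) against the sign of the planted weight, for
#' centers whose |weight| reaches `weight_threshold`; plus any internal
#' (`q2`) and external (`r_pred2`) statistics passed through.
#'
#' @param model Fitted `qsar_pls`.
#' @param X Training descriptor matrix.
#' @param metadata Column metadata of `X`.
#' @param grid The descriptor lattice.
#' @param receptor The (effective) planted `receptor_spec`.
#' @param q2,r_pred2 Optional statistics to carry into the report.
#' @param weight_threshold Minimum |weight| for a center to be scored
#'   (default: half the maximum |weight|).
#' @return A list: `per_center` tibble, `sign_agreement`, `n_scored`, `q2`,
#'   `r_pred2`.
#' @export
recovery_report <- function(model, X, metadata, grid, receptor,
                            q2 = NA_real_, r_pred2 = NA_real_,
                            weight_threshold = NULL) {
  centers <- receptor$centers
  if (is.null(weight_threshold)) weight_threshold <- 0.5 * max(abs(centers$weight))
  pts <- nearest_point_index(grid, as.matrix(centers[, c("x", "y", "z")]))
  sc_val <- numeric(nrow(centers))
  for (k in unique(centers$kind)) {
    if (!(k %in% metadata$kind)) next
    cs <- stdev_coeff(model, X, metadata, k, grid)
    rows <- which(centers$kind == k)
    sc_val[rows] <- cs$values[pts[rows]]
  }
  per_center <- tibble::tibble(
    center = seq_len(nrow(centers)), kind = centers$kind,
    weight = centers$weight, stdev_coeff = sc_val,
    scored = abs(centers$weight) >= weight_threshold &
      centers$kind %in% metadata$kind,
    agrees = sign(sc_val) == sign(centers$weight)
  )
  scored <- per_center[per_center$scored, ]
  list(per_center = per_center,
       sign_agreement = if (nrow(scored) > 0) mean(scored$agrees) else NA_real_,
       n_scored = nrow(scored), q2 = q2, r_pred2 = r_pred2)
}
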