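single_atom_mol <- function(x = 0, y = 0, z = 0, element = "C", charge = NA) {
  molecule(data.frame(element = element, x = x, y = y, z = z, charge = charge),
           id = "single")
}

test_that("grid construction snaps the bounding box outward in whole steps", {
  g <- build_grid(list(single_atom_mol()), spacing = 2, margin = 4)
  expect_equal(g$dims, c(5L, 5L, 5L))
  expect_equal(g$origin, c(-4, -4, -4))

  g0 <- build_grid(list(single_atom_mol()), spacing = 2, margin = 0)
  expect_equal(g0$dims, c(2L, 2L, 2L))

  # a 3 A span with margin 1 covers 5 A -> snapped outward to 3 steps of 2 A
  two <- molecule(data.frame(element = c("C", "C"), x = c(0, 3), y = 0, z = 0),
                  id = "two")
  g2 <- build_grid(list(two), spacing = 2, margin = 1)
  expect_equal(g2$dims[1], 4L)

  # enlarging the margin never removes grid points
  dims_by_margin <- sapply(0:5, function(m)
    build_grid(list(two), spacing = 2, margin = m)$dims)
  expect_true(all(diff(t(dims_by_margin)) >= 0))

  expect_error(build_grid(list()), "no molecules")
  # x varies fastest in the lattice ordering
  pts <- grid_points(g0)
  expect_equal(pts[2, ] - pts[1, ], c(2, 0, 0))
})

test_that("CoMFA steric field decays, clamps, and adds over atoms", {
  mol <- single_atom_mol()
  g <- grid_spec(c(-24, 0, 0), 24, c(3, 2, 2))  # points at x = -24, 0, +24
  v <- comfa_steric(mol, g)
  expect_equal(v[2], 30)                         # probe on the nucleus: clamped
  far <- abs(v[c(1, 3)])
  expect_lt(max(far), 1e-4)                      # > 20 A away: essentially zero

  # additivity before clamping
  two <- molecule(data.frame(element = c("C", "C"), x = c(0, 1), y = 0, z = 0),
                  id = "two")
  g2 <- grid_spec(c(-3.5, -3.5, -3.5), 3, c(3, 3, 3))  # no point on a nucleus
  vs <- comfa_steric(two, g2, truncation = 1e9)
  v1 <- comfa_steric(single_atom_mol(0, 0, 0), g2, truncation = 1e9)
  v2 <- comfa_steric(single_atom_mol(1, 0, 0), g2, truncation = 1e9)
  expect_equal(vs, v1 + v2, tolerance = 1e-12)

  # monotone non-increasing beyond the LJ minimum
  probe <- probe_spec("comfa")
  rmin <- 1.70 + probe$vdw_radius
  gx <- grid_spec(c(rmin, 0, 0), 0.5, c(10, 2, 2))
  vx <- comfa_steric(single_atom_mol(), gx, truncation = 1e9)
  profile <- vx[seq(1, 10)]                      # along +x from the minimum
  expect_true(all(diff(profile) >= -1e-12 | profile[-10] <= 0))
  expect_true(all(diff(profile) >= 0 | diff(profile) <= 0))  # sanity on shape
  expect_true(all(diff(profile) >= 0))           # rises back toward 0 from below

  expect_error(comfa_steric(single_atom_mol(element = "C") |>
                              transform(element = "Xx") |>
                              molecule(id = "bad"), g2),
               "Xx")
})

test_that("CoMFA electrostatics follow Coulomb with distance dielectric", {
  mol <- single_atom_mol(charge = 1)
  g <- grid_spec(c(2, 0, 0), 2, c(2, 2, 2))      # first point at distance 2
  v <- comfa_electrostatic(mol, g, truncation = 200)
  expect_equal(v[1], 332.0636 / 4, tolerance = 1e-10)   # q/(r * r), r = 2
  expect_equal(comfa_electrostatic(mol, g)[1], 30)      # default clamp

  # mirrored +/- charges cancel at equidistant points
  mirror <- molecule(data.frame(element = c("N", "N"), x = c(-1, 1), y = 0,
                                z = 0, charge = c(1, -1)), id = "mirror")
  gmid <- grid_spec(c(0, -2, -2), 2, c(2, 3, 3))
  vm <- comfa_electrostatic(mirror, gmid, truncation = 1e9)
  pts <- grid_points(gmid)
  expect_lt(max(abs(vm[pts[, 1] == 0])), 1e-10)

  # linearity: flipping all charges negates the field (pre-clamp)
  set.seed(3)
  at <- phosphate_atoms()
  m1 <- molecule(at, phosphate_bonds(), id = "q+")
  at$charge <- -at$charge
  m2 <- molecule(at, phosphate_bonds(), id = "q-")
  gg <- build_grid(list(m1), 2, 3)
  expect_equal(comfa_electrostatic(m1, gg, truncation = 1e9),
               -comfa_electrostatic(m2, gg, truncation = 1e9),
               tolerance = 1e-9)

  expect_error(comfa_electrostatic(single_atom_mol(), g), "charges")
})

test_that("electrostatic values at sterically excluded points get the column mean", {
  # one molecule with an atom exactly on a lattice point; two clean molecules
  mols <- list(
    molecule(data.frame(element = "C", x = 0, y = 0, z = 0, charge = 0.5),
             id = "onpoint"),
    molecule(data.frame(element = "C", x = 1.6, y = 1.6, z = 1.2, charge = 0.5),
             id = "off1"),
    molecule(data.frame(element = "C", x = -1.5, y = -1.7, z = 1.1, charge = 0.5),
             id = "off2"))
  data <- molecule_set(mols)
  g <- grid_spec(c(-2, -2, -2), 2, c(3, 3, 3))
  blk <- compute_field_block(data, "electrostatic", "comfa", g)
  # lattice point (0,0,0) is index 14 (x fastest, 3x3x3 centre)
  raw <- vapply(mols[2:3], function(m) comfa_electrostatic(m, g)[14], numeric(1))
  expect_equal(unname(blk$values["onpoint", 14]), mean(raw), tolerance = 1e-12)
  expect_true(attr(blk, "clamped")["onpoint", 14])
})

test_that("CoMSIA indices reproduce the Gaussian similarity form exactly", {
  mol <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0,
                             vdw_radius = 1, hydrophobicity = 1, charge = 1,
                             is_hbd = TRUE, is_hba = TRUE), id = "unit")
  g <- grid_spec(c(0, 0, 0), 2, c(2, 2, 2))
  # probe on the atom: similarity is exactly -1 for a unit property
  expect_equal(comsia_field(mol, g, "steric")[1], -1)
  # at r = 2 with alpha = 0.3: -exp(-1.2)
  expect_equal(comsia_field(mol, g, "steric")[2], -exp(-1.2), tolerance = 1e-12)

  zero <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0,
                              vdw_radius = 1, hydrophobicity = 0, charge = 0,
                              is_hbd = FALSE, is_hba = FALSE), id = "z")
  expect_true(all(comsia_field(zero, g, "donor") == 0))
  expect_true(all(comsia_field(zero, g, "hydrophobic") == 0))

  # brute-force double loop oracle on random instances
  set.seed(13)
  for (rep in 1:5) {
    n_at <- sample(3:7, 1)
    at <- data.frame(element = "C", x = rnorm(n_at, 0, 2), y = rnorm(n_at, 0, 2),
                     z = rnorm(n_at, 0, 2), charge = rnorm(n_at),
                     vdw_radius = runif(n_at, 1, 2),
                     hydrophobicity = rnorm(n_at),
                     is_hbd = runif(n_at) < 0.5, is_hba = runif(n_at) < 0.5)
    m <- molecule(at, id = "r")
    gg <- grid_spec(rnorm(3), 1.5, c(3, 3, 3))
    for (kind in c("steric", "electrostatic", "hydrophobic", "donor", "acceptor")) {
      fast <- comsia_field(m, gg, kind)
      w <- switch(kind, steric = at$vdw_radius^3, electrostatic = at$charge,
                  hydrophobic = at$hydrophobicity,
                  donor = as.numeric(at$is_hbd), acceptor = as.numeric(at$is_hba))
      pts <- grid_points(gg)
      slow <- numeric(nrow(pts))
      for (q in seq_len(nrow(pts))) {
        acc <- 0
        for (i in seq_len(n_at)) {
          r2 <- sum((pts[q, ] - coords(m)[i, ])^2)
          acc <- acc + 1.0 * w[i] * exp(-0.3 * r2)
        }
        slow[q] <- -acc
      }
      expect_equal(fast, slow, tolerance = 1e-12)
    }
  }
  # all-positive properties give non-positive similarity values
  expect_true(all(comsia_field(phosphate_mol(), g, "steric") <= 0))
})

test_that("field values are invariant under rigid co-transformation", {
  set.seed(31)
  mol <- phosphate_mol()
  pts <- matrix(rnorm(30, 0, 3), 10, 3)
  base <- qsar3d:::comsia_value_at(mol, pts, "electrostatic")
  for (k in 1:3) {
    A <- random_rotation(); tvec <- rnorm(3, 0, 5)
    mol_r <- qsar3d:::set_coords(mol, sweep(coords(mol) %*% t(A), 2, tvec, "+"))
    pts_r <- sweep(pts %*% t(A), 2, tvec, "+")
    expect_equal(qsar3d:::comsia_value_at(mol_r, pts_r, "electrostatic"), base,
                 tolerance = 1e-9)
  }
  # lattice translation invariance for the grid-based CoMFA fields
  g <- build_grid(list(mol), 2, 3)
  g_shift <- grid_spec(g$origin + c(1.5, -2.5, 3.5), g$spacing, g$dims)
  mol_s <- qsar3d:::set_coords(mol, sweep(coords(mol), 2, c(1.5, -2.5, 3.5), "+"))
  expect_equal(comfa_steric(mol_s, g_shift), comfa_steric(mol, g),
               tolerance = 1e-9)
  # and bit-identical reproducibility
  expect_identical(comfa_steric(mol, g), comfa_steric(mol, g))
})

test_that("descriptor assembly concatenates blocks with faithful metadata", {
  syn <- small_synth(12)
  data <- syn$data
  g <- syn$grid
  b1 <- compute_field_block(data, "steric", "comsia", g)
  b2 <- compute_field_block(data, "donor", "comsia", g)
  d <- assemble_descriptor_matrix(data, list(b1, b2))
  p <- qsar3d:::n_grid_points(g)
  expect_equal(dim(d$X), c(12L, 2L * p))
  expect_equal(unique(d$metadata$block), c("comsia_steric", "comsia_donor"))
  # metadata round-trips to lattice coordinates
  pts <- grid_points(g)
  expect_equal(as.matrix(d$metadata[, c("x", "y", "z")]),
               rbind(pts, pts), ignore_attr = TRUE)
  # reordering blocks permutes columns consistently with metadata
  d2 <- assemble_descriptor_matrix(data, list(b2, b1))
  expect_equal(d2$X[, d2$metadata$block == "comsia_steric"],
               d$X[, d$metadata$block == "comsia_steric"])
  # mismatched molecule order errors
  flipped <- data[rev(seq_len(nrow(data))), ]
  expect_error(assemble_descriptor_matrix(flipped, list(b1)), "row order")
})

test_that("minimum-sigma filtering drops exactly the quiet columns", {
  X <- cbind(rep(1, 6), c(1, 2, 3, 4, 5, 6) * 0.55, c(0, 5, 10, 5, 0, 10))
  meta <- tibble::tibble(column = 1:3, block = "b", method = "comsia",
                         kind = "steric", point = 1:3, ix = 1:3, iy = 1, iz = 1,
                         x = 0, y = 0, z = 0)
  desc <- structure(list(X = X, metadata = meta,
                         grid = grid_spec(c(0, 0, 0), 2, c(3, 2, 2))),
                    class = "descriptor_matrix")
  expect_equal(round(apply(X, 2, sd), 2), c(0, 1.03, 4.47))
  f <- filter_columns(desc, min_sigma = 2)
  expect_equal(ncol(f$X), 1)
  expect_equal(f$metadata$column, 3)
  expect_equal(ncol(filter_columns(desc, 0)$X), 3)
  expect_error(filter_columns(desc, 100), "every column")
})
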