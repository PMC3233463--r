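# Shared in-code fixtures: a hand-built phosphate-anchored molecule, tiny
# random datasets, and a random proper rotation.

phosphate_atoms <- function() {
  data.frame(
    element = c("P", "O", "O", "O", "O", "C"),
    x = c(0, 1.48, -0.49, -0.49, -0.49, 2.90),
    y = c(0, 0, 1.40, -0.70, -0.70, 0.40),
    z = c(0, 0, 0, 1.21, -1.21, 0.20),
    charge = c(1.2, -0.8, -0.8, -0.8, -0.8, 0.1)
  )
}

phosphate_bonds <- function() {
  data.frame(i = c(1, 1, 1, 1, 2), j = c(2, 3, 4, 5, 6), order = 1)
}

phosphate_mol <- function(id = "phos", pic50 = NA_real_) {
  molecule(phosphate_atoms(), phosphate_bonds(), id = id, pic50 = pic50)
}

random_rotation <- function() {
  A <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(A) < 0) A[, 1] <- -A[, 1]
  A
}

posed_copy <- function(mol, id) {
  A <- random_rotation()
  shift <- runif(3, -6, 6)
  m <- qsar3d:::set_coords(mol, sweep(coords(mol) %*% t(A), 2, shift, "+"))
  attr(m, "id") <- id
  m
}

# methane SDF text (V2000, 3D)
methane_sdf_lines <- function() {
  c("methane", "  qsar3d", "3D",
    "  5  4  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300    0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300   -0.6300    0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.6300    0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.6300   -0.6300   -0.6300 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0", "  1  3  1  0  0  0  0",
    "  1  4  1  0  0  0  0", "  1  5  1  0  0  0  0",
    "M  END", "$$$$")
}

ethanol_mol <- function() {
  molecule(
    data.frame(
      element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
      x = c(-0.888, 0.528, 1.213, -1.245, -1.280, -1.245, 0.889, 0.889, 2.154),
      y = c(0.168, -0.446, 0.714, -0.521, 0.828, 0.818, -1.064, -1.064, 0.332),
      z = c(0, 0, 0, 0.885, 0.610, -0.900, 0.890, -0.890, 0)
    ),
    data.frame(i = c(1, 2, 1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 5, 6, 7, 8, 9)),
    id = "ethanol"
  )
}

# tiny single-kind descriptor setup for PLS tests
random_xy <- function(n, p, seed, noise = 0.1, beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- c(rep(1, min(3, p)), rep(0, p - min(3, p)))
  y <- as.vector(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

# independent LOO q2 oracle built on mixOmics (never on qsar3d's PLS)
mixomics_loo_q2 <- function(X, y, ncomp) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  preds <- vapply(seq_len(nrow(X)), function(i) {
    f <- mixOmics::pls(X[-i, , drop = FALSE], matrix(y[-i], ncol = 1),
                       ncomp = ncomp, mode = "regression", scale = FALSE)
    unname(predict(f, X[i, , drop = FALSE])$predict[, , ncomp])
  }, numeric(1))
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

# small planted synthetic study shared across tests (kept cheap)
small_synth <- function(n = 30, noise_sd = 0.1, seed = 11, rec_seed = 5) {
  synthetic_qsar_data(n, default_receptor_spec(noise_sd = noise_sd,
                                               seed = rec_seed),
                      seed = seed, margin = 3, test_fraction = 0.25)
}
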