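test_that("generated series share the anchor, are deterministic, and pose-vary", {
  ser <- generate_series(12, seed = 3)
  expect_equal(nrow(ser), 12)
  for (m in ser$mol) expect_gte(match_substructure(m, "P(O)(O)O")$n_matches, 1)

  f1 <- withr::local_tempfile(fileext = ".sdf")
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(generate_series(12, seed = 3), f1)
  write_molecules(generate_series(12, seed = 3), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1),
                         {
                           f3 <- withr::local_tempfile(fileext = ".sdf")
                           write_molecules(generate_series(12, seed = 4), f3)
                           readLines(f3)
                         }))

  # no substituent sites: all molecules identical up to rigid pose
  bare <- generate_series(5, sites = default_substituent_sites()[0, ], seed = 2)
  ref <- coords(bare$mol[[1]])
  for (m in bare$mol[-1])
    expect_lt(superpose(coords(m), ref)$rmsd, 1e-9)

  line_scaffold <- list(
    atoms = tibble::tibble(element = c("C", "C", "C"), x = c(0, 1, 2), y = 0,
                           z = 0, charge = 0, is_hbd = FALSE, is_hba = FALSE),
    bonds = tibble::tibble(i = c(1, 2), j = c(2, 3), order = 1L))
  expect_error(generate_series(5, scaffold = line_scaffold), "degenerate")
})

test_that("planted activities follow the receptor's weighted field values", {
  # two molecules differing only by a substituent near a single steric center
  base <- phosphate_atoms(); base$is_hbd <- FALSE; base$is_hba <- FALSE
  m1 <- molecule(base, phosphate_bonds(), id = "bare", charges_present = TRUE)
  with_sub <- rbind(base, data.frame(element = "C", x = 5, y = 0, z = 0,
                                     charge = 0, is_hbd = FALSE, is_hba = FALSE))
  m2 <- molecule(with_sub, rbind(phosphate_bonds(),
                                 data.frame(i = 6, j = 7, order = 1)),
                 id = "subst", charges_present = TRUE)
  data <- molecule_set(list(m1, m2))
  g <- build_grid(data, 2, 4)
  for (w in c(2, -2)) {
    rec <- receptor_spec(tibble::tibble(x = 5, y = 0, z = 0, kind = "steric",
                                        weight = w),
                         noise_sd = 0, activity_offset = 6, seed = 1)
    pl <- plant_activities(data, rec, g, rescale_to = NULL)
    # steric similarity at the center is negative, so the activity difference
    # carries the sign of -w times the added field magnitude: sign(diff) = -sign(w)
    expect_equal(sign(pl$pic50[2] - pl$pic50[1]), -sign(w))
  }

  # zero weights: every activity equals the offset
  rec0 <- receptor_spec(tibble::tibble(x = 5, y = 0, z = 0, kind = "steric",
                                       weight = 0),
                        noise_sd = 0, activity_offset = 6.4, seed = 1)
  pl0 <- plant_activities(data, rec0, g, rescale_to = NULL)
  expect_equal(pl0$pic50, c(6.4, 6.4))

  out <- receptor_spec(tibble::tibble(x = 500, y = 0, z = 0, kind = "steric",
                                      weight = 1), seed = 1)
  expect_error(plant_activities(data, out, g), "outside the grid")
})

test_that("default synthetic studies land in the conventional activity range", {
  syn <- synthetic_qsar_data(105, default_receptor_spec(noise_sd = 0, seed = 2),
                             seed = 2)
  expect_equal(nrow(syn$data), 105)
  expect_equal(sum(syn$data$role == "test"), 28)
  expect_equal(sum(syn$data$role == "train"), 77)
  expect_equal(range(syn$ground_truth$signal), c(4.87, 8.00), tolerance = 1e-9)
})

test_that("the pipeline is identifiable at zero noise with lattice centers", {
  syn <- synthetic_qsar_data(40, default_receptor_spec(noise_sd = 0, seed = 3),
                             seed = 7, margin = 3, test_fraction = 0.25)
  data <- syn$data
  cfg <- qsar_config(method = "comsia", min_sigma = 0, scaling = "none",
                     margin = 3)
  blocks <- qsar3d:::build_blocks(data, cfg, syn$grid)
  desc <- assemble_descriptor_matrix(data, blocks)
  tr <- which(data$role == "train")
  X <- desc$X[tr, ]; y <- data$pic50[tr]
  # enough components to span the planted columns; the exact count needed
  # depends on how the field columns correlate, so grow until converged
  ok <- FALSE
  for (nc in seq(10, length(tr) - 2, by = 4)) {
    fit <- tryCatch(fit_pls(X, y, nc), error = function(e) NULL)
    if (!is.null(fit) && sum((y - predict(fit, X))^2) < 1e-6) { ok <- TRUE; break }
  }
  expect_true(ok)
})

test_that("cross-validated performance degrades with activity noise", {
  q2_at_noise <- vapply(c(0.05, 1.5), function(ns) {
    mean(vapply(1:2, function(s) {
      syn <- small_synth(30, noise_sd = ns, seed = 20 + s, rec_seed = 30 + s)
      data <- syn$data
      cfg <- qsar_config(method = "comsia", margin = 3)
      blocks <- qsar3d:::build_blocks(data, cfg, syn$grid)
      desc <- filter_columns(assemble_descriptor_matrix(data, blocks), 0.01,
                             train = which(data$role == "train"))
      tr <- which(data$role == "train")
      loo_q2(desc$X[tr, ], data$pic50[tr], 4, scaling = "block",
             metadata = desc$metadata)$q2
    }, numeric(1)))
  }, numeric(1))
  expect_gt(q2_at_noise[1], q2_at_noise[2])
})

test_that("recovery reports score planted centers by StDev*Coeff sign", {
  syn <- small_synth(35, noise_sd = 0.05, seed = 41, rec_seed = 42)
  data <- syn$data
  cfg <- qsar_config(method = "comsia", margin = 3, max_pcs = 6)
  blocks <- qsar3d:::build_blocks(data, cfg, syn$grid)
  desc <- filter_columns(assemble_descriptor_matrix(data, blocks), 0.01,
                         train = which(data$role == "train"))
  tr <- which(data$role == "train")
  w <- scaling_weights(desc$X[tr, ], desc$metadata, "block")
  model <- fit_pls(desc$X[tr, ], data$pic50[tr], 6, col_weights = w)
  rr <- recovery_report(model, desc$X[tr, ], desc$metadata, syn$grid,
                        syn$receptor)
  expect_equal(nrow(rr$per_center), nrow(syn$receptor$centers))
  expect_gte(rr$sign_agreement, 0.5)
  expect_gt(rr$n_scored, 0)

  # scrambling the activities should wreck the agreement on average
  set.seed(1)
  y_scr <- sample(data$pic50[tr])
  m_scr <- fit_pls(desc$X[tr, ], y_scr, 6, col_weights = w)
  rr_scr <- recovery_report(m_scr, desc$X[tr, ], desc$metadata, syn$grid,
                            syn$receptor)
  expect_lte(rr_scr$sign_agreement, rr$sign_agreement)
})
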