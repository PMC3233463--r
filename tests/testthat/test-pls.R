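test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(1)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 5)
  Xn <- X; colnames(Xn) <- paste0("V", 1:50)
  oracle <- mixOmics::pls(Xn, matrix(y, ncol = 1), ncomp = 5,
                          mode = "regression", scale = FALSE)
  expect_equal(predict(fit, X),
               unname(predict(oracle, Xn)$predict[, , 5]),
               tolerance = 1e-8)
})

test_that("PLS at full rank equals least squares on the column space", {
  set.seed(2)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  fit <- fit_pls(X, y, 5)
  expect_equal(predict(fit, X), unname(fitted(lm(y ~ X))), tolerance = 1e-8)

  # exactly linear response: residuals vanish
  y_lin <- as.vector(X %*% c(1, -2, 0.5, 3, -1)) + 2
  expect_lt(max(abs(predict(fit_pls(X, y_lin, 5), X) - y_lin)), 1e-8)

  # one informative column: coefficient sign matches the correlation sign
  X1 <- cbind(seq_len(12) + rnorm(12, 0, 0.01))
  y1 <- -2 * X1[, 1] + rnorm(12, 0, 0.1)
  expect_lt(fit_pls(X1, y1, 1)$coefficients[1], 0)

  expect_error(fit_pls(X, y, 19), "rank bound")
  Xdup <- cbind(X[, 1], X[, 1])
  expect_error(fit_pls(Xdup, y, 2), "rank deficiency")
})

test_that("leave-one-out q2 matches brute-force per-fold refits", {
  skip_if_not_installed("mixOmics")
  for (n in c(8, 15, 25)) {
    d <- random_xy(n, 6, seed = n, noise = 0.3)
    for (a in c(1, 3)) {
      got <- loo_q2(d$X, d$y, a)
      expect_equal(got$q2, mixomics_loo_q2(d$X, d$y, a), tolerance = 1e-10)
    }
  }

  # hand-checkable n = 4, single-column case against per-fold lm()
  x <- c(1, 2, 3, 4.2); y <- c(1.1, 1.9, 3.2, 4.0)
  preds <- vapply(1:4, function(i) {
    f <- lm(y[-i] ~ x[-i])
    unname(coef(f)[1] + coef(f)[2] * x[i])
  }, numeric(1))
  got <- loo_q2(cbind(x), y, 1)
  expect_equal(got$press, sum((y - preds)^2), tolerance = 1e-12)
  expect_equal(got$q2, 1 - sum((y - preds)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)

  # noiseless linear system cross-validates perfectly
  set.seed(4)
  X <- matrix(rnorm(15 * 3), 15, 3)
  expect_equal(loo_q2(X, as.vector(X %*% c(1, 2, -1)), 3)$q2, 1,
               tolerance = 1e-8)
  expect_error(loo_q2(X, rep(1, 15), 2), "zero activity variance")
})

test_that("pure-noise responses give non-positive q2 in expectation", {
  set.seed(6)
  q2s <- replicate(60, {
    X <- matrix(rnorm(30 * 10), 30, 10)
    loo_q2(X, rnorm(30), 2)$q2
  })
  expect_lt(mean(q2s), 0.05)
})

test_that("component selection maximises q2 with a parsimony tie-break", {
  # planted 3-latent-factor structure
  # the third factor is weak in X but carries a large share of y, so the
  # third component must add a clearly resolvable q2 increment
  set.seed(9)
  scores <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))
  X <- scores %*% rbind(rnorm(40, 0, 3), rnorm(40, 0, 2), rnorm(40, 0, 0.3)) +
    matrix(rnorm(30 * 40, 0, 0.01), 30)
  y <- as.vector(scores %*% c(1, -1, 2)) + rnorm(30, 0, 0.01)
  sel <- select_components(X, y, 8)
  expect_true(sel$pcs %in% 3:4)
  expect_equal(nrow(sel$profile), 8)

  # single column: one component
  expect_equal(select_components(cbind(rnorm(10)), rnorm(10), 5)$pcs, 1)

  # flat-after-rise profile picks the smallest count within tolerance
  d <- random_xy(20, 3, seed = 3, noise = 0.01)
  sel2 <- select_components(d$X, d$y, 6)
  best <- max(sel2$profile$q2)
  expect_equal(sel2$pcs, min(sel2$profile$pcs[sel2$profile$q2 >= best - 0.005]))
})

test_that("internal statistics follow the conventional formulas", {
  d <- random_xy(10, 2, seed = 5, noise = 0.2)
  model <- fit_pls(d$X, d$y, 2)
  st <- internal_stats(model, d$X, d$y)
  fitted_y <- predict(model, d$X)
  expect_equal(st$r_ncv2, cor(fitted_y, d$y)^2, tolerance = 1e-12)
  ss_res <- sum((d$y - fitted_y)^2)
  expect_equal(st$see, sqrt(ss_res / (10 - 2 - 1)), tolerance = 1e-12)
  expect_equal(st$f_value,
               (st$r_ncv2 / 2) / ((1 - st$r_ncv2) / (10 - 2 - 1)),
               tolerance = 1e-12)
  # worked arithmetic: SS_res 0.9, n 10, pcs 2 -> SEE = sqrt(0.9/7)
  expect_equal(sqrt(0.9 / 7), 0.3585686, tolerance = 1e-6)

  # near-perfect fit
  y_lin <- as.vector(d$X %*% c(1, 2))
  m2 <- fit_pls(d$X, y_lin, 2)
  st2 <- internal_stats(m2, d$X, y_lin)
  expect_equal(st2$r_ncv2, 1, tolerance = 1e-10)
  expect_lt(st2$see, 1e-8)
  expect_error(internal_stats(model, d$X[1:3, ], d$y[1:3]), "exceed")
})

test_that("q2 is invariant under positive affine rescaling of the response", {
  d <- random_xy(16, 5, seed = 7, noise = 0.3)
  base <- loo_q2(d$X, d$y, 2)$q2
  for (ab in list(c(3, 1), c(-2, 0.5), c(10, 7))) {
    expect_equal(loo_q2(d$X, ab[1] + ab[2] * d$y, 2)$q2, base,
                 tolerance = 1e-10)
  }
})

test_that("block scaling makes predictions invariant to block-wide rescaling", {
  set.seed(12)
  X <- matrix(rnorm(15 * 8), 15, 8)
  meta <- tibble::tibble(block = rep(c("A", "B"), each = 4))
  y <- rnorm(15)
  w1 <- scaling_weights(X, meta, "block")
  f1 <- fit_pls(X, y, 3, col_weights = w1)
  X2 <- X; X2[, meta$block == "B"] <- X2[, meta$block == "B"] * 37
  w2 <- scaling_weights(X2, meta, "block")
  f2 <- fit_pls(X2, y, 3, col_weights = w2)
  expect_equal(predict(f1, X), predict(f2, X2), tolerance = 1e-9)
})

test_that("field contributions are normalised and symmetric for duplicated blocks", {
  set.seed(14)
  X <- matrix(rnorm(12 * 6), 12, 6)
  y <- rnorm(12)
  meta1 <- tibble::tibble(block = rep("only", 6))
  f <- fit_pls(X, y, 2)
  expect_equal(field_contributions(f, X, meta1)$contribution, 1)

  Xd <- cbind(X, X)
  metad <- tibble::tibble(block = rep(c("A", "B"), each = 6))
  w <- rep(1, 12)
  fd <- fit_pls(Xd, y, 2, col_weights = w)
  cd <- field_contributions(fd, Xd, metad)
  expect_equal(cd$contribution, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(cd$contribution), 1, tolerance = 1e-12)
})

test_that("broom-style methods expose coefficients and predictions", {
  d <- random_xy(12, 4, seed = 8)
  f <- fit_pls(d$X, d$y, 2)
  td <- tidy(f)
  expect_equal(nrow(td), 4)
  expect_named(td, c("column", "estimate"))
  g <- glance(f)
  expect_equal(g$ncomp, 2)
  au <- augment(f, d$X, d$y)
  expect_equal(au$.resid, d$y - predict(f, d$X))
})
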