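#' Column scaling weights for PLS
#'
#' Computes per-column multipliers applied to the descriptor matrix before
#' PLS. `"none"` leaves columns as-is; `"autoscale"` scales every column to
#' unit variance; `"block"` (CoMFA-standard scaling, the default for
#' multi-field models) scales each field block so all blocks contribute equal
#' total variance, preserving the relative weighting of lattice points within
#' a block.
#'
#' @param X Descriptor matrix.
#' @param metadata Column metadata (needs a `block` column) for block scaling.
#' @param scaling `"none"`, `"autoscale"` or `"block"`.
#' @param train Row indices used to measure variances (default all rows).
#' @return Numeric vector of per-column weights.
#' @export
scaling_weights <- function(X, metadata = NULL, scaling = c("block", "autoscale", "none"),
                            train = NULL) {
  scaling <- match.arg(scaling)
  p <- ncol(X)
  if (is.null(train)) train <- seq_len(nrow(X))
  if (scaling == "none") return(rep(1, p))
  if (scaling == "autoscale") {
    sds <- apply(X[train, , drop = FALSE], 2, stats::sd)
    w <- ifelse(sds > 0, 1 / sds, 0)
    return(w)
  }
  if (is.null(metadata)) stop("block scaling needs column metadata", call. = FALSE)
  stopifnot(nrow(metadata) == p)
  w <- numeric(p)
  for (b in unique(metadata$block)) {
    cols <- which(metadata$block == b)
    total_var <- sum(apply(X[train, cols, drop = FALSE], 2, stats::var))
    w[cols] <- if (total_var > 0) 1 / sqrt(total_var) else 0
  }
  w
}

#' Fit a PLS regression by NIPALS
#'
#' Univariate-response partial least squares fitted with the nonlinear
#' iterative partial least squares recursion: each latent component's weight
#' vector is the covariance direction between the deflated descriptors and the
#' response, scores are projections onto it, and both sides are deflated
#' before the next component. With as many components as the matrix rank the
#' fit coincides with ordinary least squares on the column space.
#'
#' @param X n x p descriptor matrix (rows = training molecules).
#' @param y Length-n response (pIC50).
#' @param ncomp Number of latent components (>= 1, <= min(n - 1, p)).
#' @param col_weights Optional per-column scaling weights, see
#'   [scaling_weights()]; applied internally, coefficients are reported on the
#'   original descriptor scale.
#' @return An object of class `qsar_pls` with elements `ncomp`,
#'   `coefficients` (original scale), `intercept`, `col_weights`, `x_mean`
#'   (weighted scale), `y_mean`, `scores`, `loadings`, `weights`, `y_loadings`.
#' @export
fit_pls <- function(X, y, ncomp, col_weights = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (ncomp < 1) stop("ncomp must be >= 1", call. = FALSE)
  if (ncomp > min(n - 1, p))
    stop("ncomp exceeds the rank bound min(n - 1, p)", call. = FALSE)
  if (n < ncomp + 2)
    stop("need at least ncomp + 2 training rows", call. = FALSE)
  if (is.null(col_weights)) col_weights <- rep(1, p)
  Xw <- sweep(X, 2, col_weights, "*")
  xm <- colMeans(Xw); ym <- mean(y)
  E <- sweep(Xw, 2, xm); f <- y - ym

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w_a <- crossprod(E, f)
    nw <- sqrt(sum(w_a^2))
    if (nw < 1e-12)
      stop("rank deficiency at component ", a,
           "; refit with fewer components", call. = FALSE)
    w_a <- w_a / nw
    t_a <- E %*% w_a
    tt <- sum(t_a^2)
    if (tt < 1e-12)
      stop("rank deficiency at component ", a,
           "; refit with fewer components", call. = FALSE)
    p_a <- crossprod(E, t_a) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - t_a %*% t(p_a)
    f <- f - q[a] * t_a
    W[, a] <- w_a; P[, a] <- p_a; Tm[, a] <- t_a
  }
  # regression vector in the weighted, centred descriptor space
  B_w <- W %*% solve(crossprod(P, W), q)
  coef_orig <- as.vector(col_weights * B_w)
  intercept <- ym - sum(xm * B_w)
  structure(list(ncomp = ncomp, coefficients = coef_orig, intercept = intercept,
                 col_weights = col_weights, x_mean = xm, y_mean = ym,
                 b_weighted = as.vector(B_w), scores = Tm, loadings = P,
                 weights = W, y_loadings = q, n = n),
            class = "qsar_pls")
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("<qsar_pls: %d components, %d descriptors, n = %d>\n",
              x$ncomp, length(x$coefficients), x$n))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param object A `qsar_pls`.
#' @param newdata Matrix with the same columns as the training descriptors.
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.qsar_pls <- function(object, newdata, ...) {
  Xw <- sweep(as.matrix(newdata), 2, object$col_weights, "*")
  as.vector(sweep(Xw, 2, object$x_mean) %*% object$b_weighted) + object$y_mean
}

#' Leave-one-out cross-validation
#'
#' Each training molecule is predicted by a model refitted without it — a full
#' refit including recomputation of the scaling weights on the reduced
#' training set. The cross-validated correlation coefficient is
#' \eqn{q^2 = 1 - \sum_i (y_i - \hat y_{(i)})^2 / \sum_i (y_i - \bar y)^2}
#' with \eqn{\bar y} the full training mean, and PRESS is the numerator.
#'
#' @inheritParams fit_pls
#' @param scaling Scaling mode recomputed per fold, see [scaling_weights()].
#' @param metadata Column metadata (for block scaling).
#' @return A list: `q2`, `press`, `predictions` (LOO predictions in row order).
#' @export
loo_q2 <- function(X, y, ncomp, scaling = "none", metadata = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out needs n >= 3", call. = FALSE)
  if (stats::var(y) == 0) stop("zero activity variance", call. = FALSE)
  if (ncomp > min(n - 2, ncol(X)))
    stop("ncomp exceeds the leave-one-out rank bound min(n - 2, p)", call. = FALSE)
  preds <- numeric(n)
  for (i in seq_len(n)) {
    w <- scaling_weights(X[-i, , drop = FALSE], metadata, scaling)
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], ncomp, col_weights = w)
    preds[i] <- predict(fit, X[i, , drop = FALSE])
  }
  press <- sum((y - preds)^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss, press = press, predictions = preds)
}

#' Select the number of latent components by cross-validation
#'
#' Computes the leave-one-out \eqn{q^2} profile over component counts and
#' returns the most parsimonious count whose \eqn{q^2} is within `tol` of the
#' profile maximum — additional components that do not improve cross-validated
#' performance are not retained.
#'
#' @inheritParams loo_q2
#' @param max_pcs Largest component count to examine (capped at the
#'   leave-one-out rank bound).
#' @param tol Parsimony tolerance on \eqn{q^2} (default 0.005).
#' @return A list: `pcs` (selected count), `profile` (tibble `pcs`, `q2`,
#'   `press`).
#' @export
select_components <- function(X, y, max_pcs = 10, scaling = "none",
                              metadata = NULL, tol = 0.005) {
  stopifnot(max_pcs >= 1)
  X <- as.matrix(X)
  cap <- min(max_pcs, nrow(X) - 2, ncol(X))
  rows <- list()
  for (a in seq_len(cap)) {
    cv <- tryCatch(loo_q2(X, y, a, scaling = scaling, metadata = metadata),
                   error = function(e) {
                     if (grepl("rank deficiency", conditionMessage(e))) NULL
                     else stop(e)
                   })
    if (is.null(cv)) break   # profile truncated at the achievable rank
    rows[[a]] <- tibble::tibble(pcs = a, q2 = cv$q2, press = cv$press)
  }
  if (length(rows) == 0)
    stop("leave-one-out failed at a single component; descriptors are degenerate",
         call. = FALSE)
  prof <- dplyr::bind_rows(rows)
  best <- max(prof$q2)
  pcs <- prof$pcs[which(prof$q2 >= best - tol)[1]]
  list(pcs = pcs, profile = prof)
}

#' Internal (non-cross-validated) model statistics
#'
#' The conventional lattice-QSAR internal statistics: squared Pearson
#' correlation of fitted versus observed activities (\eqn{r^2_{ncv}}),
#' standard error of estimate \eqn{SEE = \sqrt{SS_{res} / (n - pcs - 1)}},
#' and the F statistic \eqn{(r^2/pcs) / ((1 - r^2)/(n - pcs - 1))}.
#'
#' @param model A fitted `qsar_pls`.
#' @param X,y The training descriptors and activities the model was fitted on.
#' @return One-row tibble: `r_ncv2`, `see`, `f_value`, `pcs`, `n`.
#' @export
internal_stats <- function(model, X, y) {
  n <- length(y)
  pcs <- model$ncomp
  if (n <= pcs + 1) stop("n must exceed pcs + 1", call. = FALSE)
  fitted <- predict(model, X)
  if (stats::sd(fitted) == 0) {
    warning("constant fitted values; r_ncv2 reported as 0")
    r2 <- 0
  } else {
    r2 <- stats::cor(fitted, y)^2
  }
  ss_res <- sum((y - fitted)^2)
  see <- sqrt(ss_res / (n - pcs - 1))
  f_value <- (r2 / pcs) / ((1 - r2) / (n - pcs - 1))
  tibble::tibble(r_ncv2 = r2, see = see, f_value = f_value, pcs = pcs, n = n)
}

#' Relative field contributions
#'
#' Shares of the model attributable to each field block, computed as the sum
#' over the block's columns of |coefficient x training standard deviation|,
#' normalised to sum to one.
#'
#' @param model A fitted `qsar_pls`.
#' @param X Training descriptor matrix.
#' @param metadata Column metadata with a `block` column.
#' @return Tibble `block`, `contribution`.
#' @export
field_contributions <- function(model, X, metadata) {
  stopifnot(nrow(metadata) == ncol(X))
  sds <- apply(as.matrix(X), 2, stats::sd)
  mass <- abs(model$coefficients) * sds
  tot <- sum(mass)
  if (tot == 0) stop("all coefficients are zero", call. = FALSE)
  out <- tibble::tibble(block = metadata$block, mass = mass) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(contribution = sum(.data$mass) / tot, .groups = "drop")
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a fitted PLS model
#'
#' @param x A `qsar_pls`.
#' @param metadata Optional column metadata; when supplied the coefficient
#'   table carries the block/lattice annotation per descriptor column.
#' @param ... Unused.
#' @return Tibble of per-column coefficients.
#' @export
tidy.qsar_pls <- function(x, metadata = NULL, ...) {
  out <- tibble::tibble(column = seq_along(x$coefficients),
                        estimate = x$coefficients)
  if (!is.null(metadata)) out <- dplyr::bind_cols(metadata["block"], out)
  out
}

#' One-row summary of a fitted PLS model
#'
#' @param x A `qsar_pls`.
#' @param ... Unused.
#' @return One-row tibble: `ncomp`, `n`, `intercept`.
#' @export
glance.qsar_pls <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n = x$n, intercept = x$intercept)
}

#' Augment data with PLS predictions
#'
#' @param x A `qsar_pls`.
#' @param data Descriptor matrix to predict on.
#' @param y Optional observed activities to include as `observed`.
#' @param ... Unused.
#' @return Tibble with `.fitted` (and `observed`, `.resid` when `y` given).
#' @export
augment.qsar_pls <- function(x, data, y = NULL, ...) {
  out <- tibble::tibble(.fitted = predict(x, data))
  if (!is.null(y)) {
    out$observed <- y
    out$.resid <- y - out$.fitted
  }
  out
}
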