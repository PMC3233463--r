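#' Modified external r-squared (rm2)
#'
#' \eqn{r_m^2 = r_{test}^2 (1 - \sqrt{r_{test}^2 - r_0^2})}: an external
#' validity statistic that penalises divergence between the conventional test
#' correlation and its through-origin counterpart. Equals \eqn{r_{test}^2}
#' when the two agree; values above 0.5 are conventionally considered
#' acceptable. When \eqn{r_0^2 > r_{test}^2} the difference is clamped at zero
#' with a warning.
#'
#' @param r_test2 Squared Pearson correlation between observed and predicted
#'   test activities.
#' @param r0_2 Through-origin r-squared, see [external_stats()].
#' @return The rm2 value.
#' @export
#' @examples
#' rm_squared(0.909, 0.901)
rm_squared <- function(r_test2, r0_2) {
  d <- r_test2 - r0_2
  if (any(d < 0)) {
    warning("r0_2 exceeds r_test2; difference clamped at 0")
    d <- pmax(d, 0)
  }
  r_test2 * (1 - sqrt(d))
}

#' External-validation statistics for a test set
#'
#' Computes the full external battery from observed and predicted test-set
#' activities: the predictive \eqn{r_{pred}^2 = 1 - PRESS/SD} where SD sums
#' squared deviations of the observed test activities from the *training*
#' mean; the conventional \eqn{r_{test}^2}; the through-origin slopes `k`
#' (observed regressed on predicted) and `k_prime` (predicted on observed);
#' the through-origin \eqn{r_0^2} (residuals of observed about `k` times
#' predicted, referenced to the observed mean) and its alternate
#' \eqn{r_0'^2}; the relative gap `ratio` \eqn{= (r_{test}^2 - r_0^2) /
#' r_{test}^2}; and [rm_squared()].
#'
#' @param y_obs Observed test activities.
#' @param y_pred Predicted test activities.
#' @param y_train_mean Mean activity of the training set.
#' @return One-row tibble: `n_test`, `r_test2`, `r_pred2`, `r0_2`,
#'   `r0_2_prime`, `ratio`, `rm2`, `k`, `k_prime`, `sd`, `press_ext`.
#' @export
external_stats <- function(y_obs, y_pred, y_train_mean) {
  if (length(y_obs) != length(y_pred))
    stop("observed and predicted lengths differ", call. = FALSE)
  n <- length(y_obs)
  if (n < 3) stop("need at least 3 test compounds", call. = FALSE)
  if (stats::var(y_obs) == 0) stop("zero variance in observed test activities",
                                   call. = FALSE)
  press <- sum((y_obs - y_pred)^2)
  sd_tot <- sum((y_obs - y_train_mean)^2)
  r_pred2 <- 1 - press / sd_tot
  if (stats::sd(y_pred) == 0) {
    warning("constant predictions; r_test2 reported as 0")
    r_test2 <- 0
  } else {
    r_test2 <- stats::cor(y_obs, y_pred)^2
  }
  k <- sum(y_obs * y_pred) / sum(y_pred^2)
  k_prime <- sum(y_obs * y_pred) / sum(y_obs^2)
  r0_2 <- 1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  r0_2_prime <- 1 - sum((y_pred - k_prime * y_obs)^2) /
    sum((y_pred - mean(y_pred))^2)
  ratio <- (r_test2 - r0_2) / r_test2
  rm2 <- suppressWarnings(rm_squared(r_test2, r0_2))
  tibble::tibble(n_test = n, r_test2 = r_test2, r_pred2 = r_pred2, r0_2 = r0_2,
                 r0_2_prime = r0_2_prime, ratio = ratio, rm2 = rm2, k = k,
                 k_prime = k_prime, sd = sd_tot, press_ext = press)
}

#' Golbraikh-Tropsha acceptability criteria
#'
#' The standard external acceptability battery: \eqn{r_{pred}^2 > 0.5},
#' \eqn{r_{test}^2 > 0.6}, \eqn{(r_{test}^2 - r_0^2)/r_{test}^2 < 0.1}, and at
#' least one through-origin slope within \eqn{[0.85, 1.15]}. All inequalities
#' are strict where stated.
#'
#' @param report One-row tibble from [external_stats()] (or any tibble with
#'   columns `r_pred2`, `r_test2`, `ratio` — or `r_test2`/`r0_2` from which it
#'   is recomputed — plus `k`, `k_prime`).
#' @return One-row tibble of logicals: `r_pred2`, `r_test2`, `r0_ratio`,
#'   `slope`, `overall`.
#' @export
golbraikh_tropsha_check <- function(report) {
  ratio <- if ("ratio" %in% names(report)) report$ratio
           else (report$r_test2 - report$r0_2) / report$r_test2
  out <- tibble::tibble(
    r_pred2 = report$r_pred2 > 0.5,
    r_test2 = report$r_test2 > 0.6,
    r0_ratio = ratio < 0.1,
    slope = (report$k >= 0.85 & report$k <= 1.15) |
      (report$k_prime >= 0.85 & report$k_prime <= 1.15)
  )
  out$overall <- out$r_pred2 & out$r_test2 & out$r0_ratio & out$slope
  out
}

#' Bootstrap the training fit
#'
#' Resamples training rows with replacement `n_runs` times, refits the PLS
#' model at a fixed component count on each resample and records the in-sample
#' \eqn{r^2} and SEE. Resamples whose activities have zero variance are
#' redrawn (and counted in `n_redrawn`).
#'
#' @inheritParams fit_pls
#' @param pcs Component count held fixed across runs.
#' @param n_runs Number of bootstrap resamples (default 100).
#' @param seed Integer seed; runs are deterministic given it.
#' @param scaling,metadata Scaling recomputed per resample, see
#'   [scaling_weights()].
#' @return A list: `r_bs2`, `see_bs` (means), `runs` (tibble `run`, `r2`,
#'   `see`), `n_redrawn`.
#' @export
bootstrap_pls <- function(X, y, pcs, n_runs = 100, seed = 1L,
                          scaling = "none", metadata = NULL) {
  stopifnot(n_runs >= 2)
  X <- as.matrix(X)
  n <- nrow(X)
  res <- with_local_seed(seed, {
    r2 <- numeric(n_runs); see <- numeric(n_runs); redrawn <- 0L
    for (b in seq_len(n_runs)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::var(y[idx]) > 0 && length(unique(idx)) >= pcs + 2) break
        redrawn <- redrawn + 1L
      }
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      w <- scaling_weights(Xb, metadata, scaling)
      fit <- fit_pls(Xb, yb, pcs, col_weights = w)
      st <- internal_stats(fit, Xb, yb)
      r2[b] <- st$r_ncv2; see[b] <- st$see
    }
    list(r2 = r2, see = see, redrawn = redrawn)
  })
  list(r_bs2 = mean(res$r2), see_bs = mean(res$see),
       runs = tibble::tibble(run = seq_len(n_runs), r2 = res$r2, see = res$see),
       n_redrawn = res$redrawn)
}

#' y-randomization (response scrambling) check
#'
#' Permutes the activity vector `n_runs` times, recomputes the leave-one-out
#' \eqn{q^2} at the fixed component count for each scramble, and reports the
#' distribution. A real structure-activity signal should leave every scrambled
#' \eqn{q^2} well below the unscrambled one.
#'
#' @inheritParams bootstrap_pls
#' @param n_runs Number of scrambles (default 50).
#' @return A list of class `y_randomization`: `q2_values`, `q2_min`, `q2_max`,
#'   `n_runs`, `seed`.
#' @export
y_randomization <- function(X, y, pcs, n_runs = 50, seed = 1L,
                            scaling = "none", metadata = NULL) {
  stopifnot(n_runs >= 1)
  X <- as.matrix(X)
  q2s <- with_local_seed(seed, {
    vapply(seq_len(n_runs), function(b) {
      y_perm <- sample(y)
      loo_q2(X, y_perm, pcs, scaling = scaling, metadata = metadata)$q2
    }, numeric(1))
  })
  structure(list(q2_values = q2s, q2_min = min(q2s), q2_max = max(q2s),
                 n_runs = n_runs, seed = seed),
            class = "y_randomization")
}

#' @export
print.y_randomization <- function(x, ...) {
  cat(sprintf("<y_randomization: %d scrambles, q2 in [%.3f, %.3f]>\n",
              x$n_runs, x$q2_min, x$q2_max))
  invisible(x)
}
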