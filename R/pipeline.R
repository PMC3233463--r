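#' Pipeline configuration
#'
#' Validated configuration for [run_qsar()] / [field_combination_sweep()].
#' Unknown keys are rejected so typos fail before any computation.
#'
#' @param anchor_pattern Substructure anchor for alignment.
#' @param template_id Template molecule id; `NULL` selects the most potent
#'   training compound.
#' @param method `"comfa"`, `"comsia"` or `"both"`.
#' @param comsia_kinds CoMSIA field subset (default all five).
#' @param spacing,margin Lattice geometry (Angstrom).
#' @param min_sigma Column filter threshold (field units).
#' @param scaling Descriptor scaling: `"block"`, `"autoscale"`, `"none"`.
#' @param max_pcs Largest component count examined.
#' @param bootstrap_n Bootstrap resamples.
#' @param yrand_n y-randomization scrambles.
#' @param contour_pct Named list of `c(favored, disfavored)` percent levels
#'   per field kind.
#' @param dielectric CoMFA electrostatic dielectric model.
#' @param truncation CoMFA truncation (kcal/mol).
#' @param alpha CoMSIA attenuation factor.
#' @param seed Integer seed driving every stochastic stage.
#' @return A validated list of class `qsar_config`.
#' @export
qsar_config <- function(anchor_pattern = default_anchor_pattern(),
                        template_id = NULL,
                        method = c("comfa", "comsia", "both"),
                        comsia_kinds = c("steric", "electrostatic",
                                         "hydrophobic", "donor", "acceptor"),
                        spacing = 2.0, margin = 4.0, min_sigma = 0.01,
                        scaling = c("block", "autoscale", "none"),
                        max_pcs = 10, bootstrap_n = 100, yrand_n = 50,
                        contour_pct = NULL,
                        dielectric = c("distance", "constant"),
                        truncation = 30, alpha = 0.3, seed = 1L) {
  method <- match.arg(method)
  scaling <- match.arg(scaling)
  dielectric <- match.arg(dielectric)
  comsia_kinds <- match.arg(comsia_kinds, comsia_kinds, several.ok = TRUE)
  stopifnot(spacing > 0, margin >= 0, min_sigma >= 0, max_pcs >= 1,
            bootstrap_n >= 2, yrand_n >= 1, truncation > 0, alpha > 0)
  if (is.null(contour_pct)) {
    contour_pct <- list(steric = c(80, 20), electrostatic = c(80, 20),
                        hydrophobic = c(85, 15), donor = c(85, 15),
                        acceptor = c(85, 15))
  }
  structure(list(anchor_pattern = anchor_pattern, template_id = template_id,
                 method = method, comsia_kinds = comsia_kinds,
                 spacing = spacing, margin = margin, min_sigma = min_sigma,
                 scaling = scaling, max_pcs = max_pcs,
                 bootstrap_n = bootstrap_n, yrand_n = yrand_n,
                 contour_pct = contour_pct, dielectric = dielectric,
                 truncation = truncation, alpha = alpha, seed = as.integer(seed)),
            class = "qsar_config")
}

#' Read a flat key-value (YAML subset) config file
#'
#' @param path File of `key: value` lines; list values comma-separated.
#' @return A `qsar_config`.
#' @export
read_qsar_config <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path, warn = FALSE),
                invert = TRUE, value = TRUE)
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), character(1))
  allowed <- setdiff(names(formals(qsar_config)), "contour_pct")
  unknown <- setdiff(trimws(keys), allowed)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  args <- stats::setNames(as.list(trimws(vals)), trimws(keys))
  num_keys <- c("spacing", "margin", "min_sigma", "max_pcs", "bootstrap_n",
                "yrand_n", "truncation", "alpha", "seed")
  for (k in intersect(names(args), num_keys)) args[[k]] <- as.numeric(args[[k]])
  if ("comsia_kinds" %in% names(args))
    args$comsia_kinds <- trimws(strsplit(args$comsia_kinds, ",")[[1]])
  do.call(qsar_config, args)
}

build_blocks <- function(data, config, grid, kinds = NULL) {
  blocks <- list()
  if (config$method %in% c("comfa", "both")) {
    for (k in c("steric", "electrostatic")) {
      blocks[[paste0("comfa_", k)]] <-
        compute_field_block(data, k, "comfa", grid,
                            truncation = config$truncation,
                            dielectric = config$dielectric)
    }
  }
  if (config$method %in% c("comsia", "both")) {
    use <- if (is.null(kinds)) config$comsia_kinds else kinds
    for (k in use) {
      blocks[[paste0("comsia_", k)]] <-
        compute_field_block(data, k, "comsia", grid, alpha = config$alpha)
    }
  }
  blocks
}

#' Run the full 3D-QSAR workflow
#'
#' Stages: substructure alignment onto the template; lattice construction;
#' CoMFA and/or CoMSIA field computation; minimum-sigma column filtering
#' (training rows only); descriptor scaling; leave-one-out component
#' selection; final PLS fit with internal statistics, bootstrap and
#' y-randomization; external validation on the test set with the
#' Golbraikh-Tropsha battery; StDev*Coeff contour sets. Fully deterministic
#' given `config$seed`.
#'
#' @param data A `qsar_dataset` tibble (train/test roles and activities set).
#' @param config A [qsar_config()].
#' @return An object of class `qsar_run`; see [glance.qsar_run()].
#' @export
run_qsar <- function(data, config = qsar_config()) {
  if (!("role" %in% names(data)))
    stop("data must be a qsar_dataset with train/test roles", call. = FALSE)
  tr <- train_idx(data)
  te <- test_idx(data)
  if (length(tr) < 5) stop("too few training molecules", call. = FALSE)

  template_id <- config$template_id
  if (is.null(template_id)) {
    tr_data <- data[tr, ]
    template_id <- tr_data$id[which.max(tr_data$pic50)]
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  aligned <- stage("align", align_dataset(data, template_id, config$anchor_pattern))
  grid <- stage("grid", build_grid(aligned, config$spacing, config$margin))
  blocks <- stage("fields", build_blocks(aligned, config, grid))
  desc <- stage("assemble", assemble_descriptor_matrix(aligned, blocks))
  desc <- stage("filter", filter_columns(desc, config$min_sigma, train = tr))

  X_tr <- desc$X[tr, , drop = FALSE]
  y_tr <- aligned$pic50[tr]
  sel <- stage("select", select_components(X_tr, y_tr, config$max_pcs,
                                           scaling = config$scaling,
                                           metadata = desc$metadata))
  w <- scaling_weights(X_tr, desc$metadata, config$scaling)
  model <- stage("fit", fit_pls(X_tr, y_tr, sel$pcs, col_weights = w))
  istats <- internal_stats(model, X_tr, y_tr)
  cv <- loo_q2(X_tr, y_tr, sel$pcs, scaling = config$scaling,
               metadata = desc$metadata)
  contrib <- field_contributions(model, X_tr, desc$metadata)
  bs <- stage("bootstrap",
              bootstrap_pls(X_tr, y_tr, sel$pcs, n_runs = config$bootstrap_n,
                            seed = config$seed + 1L, scaling = config$scaling,
                            metadata = desc$metadata))
  yr <- stage("y_randomization",
              y_randomization(X_tr, y_tr, sel$pcs, n_runs = config$yrand_n,
                              seed = config$seed + 2L, scaling = config$scaling,
                              metadata = desc$metadata))

  external <- NULL; criteria <- NULL; y_pred_test <- NULL
  if (length(te) >= 3) {
    y_pred_test <- predict(model, desc$X[te, , drop = FALSE])
    external <- external_stats(aligned$pic50[te], y_pred_test, mean(y_tr))
    criteria <- golbraikh_tropsha_check(external)
  }

  contours <- list()
  for (k in unique(desc$metadata$kind)) {
    pct <- config$contour_pct[[k]] %||% c(80, 20)
    cs <- stdev_coeff(model, X_tr, desc$metadata, k, grid)
    contours[[k]] <- tryCatch(contour_levels(cs, pct[1], pct[2]),
                              error = function(e) cs, warning = function(w) {
                                suppressWarnings(contour_levels(cs, pct[1], pct[2]))
                              })
  }

  internal <- tibble::tibble(
    q2 = cv$q2, press = cv$press, pcs = sel$pcs, r_ncv2 = istats$r_ncv2,
    see = istats$see, f_value = istats$f_value, r_bs2 = bs$r_bs2,
    see_bs = bs$see_bs,
    r_pred2 = if (!is.null(external)) external$r_pred2 else NA_real_)

  predictions <- tibble::tibble(
    id = aligned$id, role = aligned$role, observed = aligned$pic50,
    predicted = NA_real_)
  predictions$predicted[tr] <- predict(model, X_tr)
  if (!is.null(y_pred_test)) predictions$predicted[te] <- y_pred_test
  predictions$loo_predicted <- NA_real_
  predictions$loo_predicted[tr] <- cv$predictions

  structure(list(config = config, template_id = template_id, data = aligned,
                 grid = grid, descriptors = desc, model = model,
                 internal = internal, contributions = contrib,
                 external = external, criteria = criteria,
                 q2_profile = sel$profile, bootstrap = bs,
                 y_randomization = yr, contours = contours,
                 predictions = predictions),
            class = "qsar_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.qsar_run <- function(x, ...) {
  cat(sprintf("<qsar_run: %s, %d train / %d test, %d descriptors>\n",
              x$config$method, sum(x$data$role == "train"),
              sum(x$data$role == "test"), ncol(x$descriptors$X)))
  print(glance(x))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' Internal and external statistics in the conventional reporting shape
#' (q2, PCs, r_ncv2, SEE, F, bootstrap means, r_pred2, plus the external
#' battery when a test set was present).
#'
#' @param x A `qsar_run`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.qsar_run <- function(x, ...) {
  out <- x$internal
  if (!is.null(x$external)) {
    ext <- x$external[, c("r_test2", "r0_2", "ratio", "rm2", "k", "k_prime")]
    out <- dplyr::bind_cols(out, ext, tibble::tibble(passes_gt = x$criteria$overall))
  }
  out
}

#' Per-molecule predictions of a pipeline run
#'
#' @param x A `qsar_run`.
#' @param ... Unused.
#' @return Tibble `id`, `role`, `observed`, `predicted`, `loo_predicted`.
#' @export
tidy.qsar_run <- function(x, ...) x$predictions

#' Write the machine-readable run report
#'
#' Emits the run's tables as CSV (internal statistics, external battery,
#' contributions, predictions, y-randomization), the contour sets as OpenDX
#' files, and a single JSON with everything. Byte-stable for a fixed seed.
#'
#' @param run A `qsar_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$internal, file.path(dir, "internal_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(run$contributions, file.path(dir, "field_contributions.csv"),
                   row.names = FALSE)
  utils::write.csv(run$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  if (!is.null(run$external)) {
    ext <- run$external[, c("r_test2", "r_pred2", "r0_2", "ratio", "rm2",
                            "k", "k_prime")]
    utils::write.csv(ext, file.path(dir, "external_stats.csv"), row.names = FALSE)
  }
  for (k in names(run$contours)) {
    export_contours(run$contours[[k]],
                    file.path(dir, paste0("contour_", k, ".dx")))
  }
  report <- list(
    config = unclass(run$config), template_id = run$template_id,
    internal = as.list(run$internal),
    contributions = stats::setNames(as.list(run$contributions$contribution),
                                    run$contributions$block),
    external = if (!is.null(run$external)) as.list(run$external),
    criteria = if (!is.null(run$criteria)) as.list(run$criteria),
    y_randomization = list(n_runs = run$y_randomization$n_runs,
                           q2_min = run$y_randomization$q2_min,
                           q2_max = run$y_randomization$q2_max),
    q2_profile = as.list(run$q2_profile),
    alignment_rmsd = stats::setNames(as.list(run$data$align_rmsd), run$data$id)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(dir)
}

#' Enumerate and rank all CoMSIA field-subset models
#'
#' Fits one model per non-empty subset of the configured CoMSIA kinds (31
#' subsets for all five fields): each subset's descriptor matrix is filtered,
#' scaled and cross-validated, components selected by [select_components()],
#' and the subsets ranked by leave-one-out q2. The winner's field
#' contributions are attached.
#'
#' @param data A `qsar_dataset`.
#' @param config A [qsar_config()] with `method = "comsia"`.
#' @return Tibble (one row per subset, ranked by `q2`): `fields`, `n_fields`,
#'   `pcs`, `q2`, `best`; winner contributions in the
#'   `winner_contributions` attribute.
#' @export
field_combination_sweep <- function(data, config = qsar_config(method = "comsia")) {
  if (config$method != "comsia")
    stop("field_combination_sweep requires method = 'comsia'", call. = FALSE)
  tr <- train_idx(data)
  template_id <- config$template_id
  if (is.null(template_id)) {
    tr_data <- data[tr, ]
    template_id <- tr_data$id[which.max(tr_data$pic50)]
  }
  aligned <- align_dataset(data, template_id, config$anchor_pattern)
  grid <- build_grid(aligned, config$spacing, config$margin)
  kinds <- config$comsia_kinds
  all_blocks <- build_blocks(aligned, config, grid)
  subsets <- unlist(lapply(seq_along(kinds), function(k)
    utils::combn(kinds, k, simplify = FALSE)), recursive = FALSE)

  rows <- purrr::map_dfr(subsets, function(sub) {
    desc <- assemble_descriptor_matrix(aligned,
                                       all_blocks[paste0("comsia_", sub)])
    desc <- filter_columns(desc, config$min_sigma, train = tr)
    X_tr <- desc$X[tr, , drop = FALSE]
    y_tr <- aligned$pic50[tr]
    sel <- select_components(X_tr, y_tr, config$max_pcs,
                             scaling = config$scaling, metadata = desc$metadata)
    tibble::tibble(fields = paste(sub, collapse = "+"),
                   n_fields = length(sub), pcs = sel$pcs,
                   q2 = sel$profile$q2[sel$profile$pcs == sel$pcs])
  })
  rows <- dplyr::arrange(rows, dplyr::desc(.data$q2))
  rows$best <- seq_len(nrow(rows)) == 1
  win <- strsplit(rows$fields[1], "\\+")[[1]]
  desc <- assemble_descriptor_matrix(aligned, all_blocks[paste0("comsia_", win)])
  desc <- filter_columns(desc, config$min_sigma, train = tr)
  X_tr <- desc$X[tr, , drop = FALSE]
  w <- scaling_weights(X_tr, desc$metadata, config$scaling)
  model <- fit_pls(X_tr, aligned$pic50[tr], rows$pcs[1], col_weights = w)
  attr(rows, "winner_contributions") <-
    field_contributions(model, X_tr, desc$metadata)
  rows
}
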