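#' StDev*Coeff contour field
#'
#' For one field kind, multiplies each retained descriptor column's training
#' standard deviation by its PLS coefficient and re-embeds the products on the
#' full lattice (columns removed by [filter_columns()] render as zero, keeping
#' the grid rectangular). This is the conventional "StDev*Coeff" field used to
#' contour favourable and unfavourable regions.
#'
#' @param model A fitted `qsar_pls`.
#' @param X Training descriptor matrix the model was fitted on (same columns).
#' @param metadata Column metadata of `X`.
#' @param kind Field kind to extract (must appear in `metadata$kind`).
#' @param grid The `grid_spec` of the descriptor lattice.
#' @param method Optional method filter when both CoMFA and CoMSIA blocks of
#'   the same kind are present.
#' @return A list of class `contour_set`: `kind`, `values` (one per lattice
#'   point, x fastest), `grid`, `levels` (filled by [contour_levels()]).
#' @export
stdev_coeff <- function(model, X, metadata, kind, grid, method = NULL) {
  sel <- metadata$kind == kind
  if (!is.null(method)) sel <- sel & metadata$method == method
  if (!any(sel)) stop("field kind '", kind, "' not present in metadata",
                      call. = FALSE)
  cols <- which(sel)
  sds <- apply(as.matrix(X)[, cols, drop = FALSE], 2, stats::sd)
  vals <- numeric(n_grid_points(grid))
  vals[metadata$point[cols]] <- sds * model$coefficients[cols]
  structure(list(kind = kind, values = vals, grid = grid, levels = NULL),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat(sprintf("<contour_set %s: %d lattice points, %d nonzero%s>\n", x$kind,
              length(x$values), sum(x$values != 0),
              if (!is.null(x$levels))
                sprintf(", levels [%.4g, %.4g]", x$levels["disfavored"],
                        x$levels["favored"]) else ""))
  invisible(x)
}

#' Favoured/disfavoured contour levels
#'
#' Computes display iso-levels from the nonzero StDev*Coeff distribution. In
#' `"percentile"` mode (default) the favoured level is the `favored_pct`-th
#' percentile of the positive values and the disfavoured level the
#' `disfavored_pct`-th percentile of the negative values. In `"mass"` mode the
#' levels bound the top (100 - pct)% of total |value| contribution on each
#' side. One-sided distributions yield an `NA` level with a warning.
#'
#' @param values Numeric StDev*Coeff values (or a `contour_set`).
#' @param favored_pct,disfavored_pct Percent levels, e.g. 80 and 20 (steric,
#'   electrostatic) or 85 and 15 (H-bond fields).
#' @param mode `"percentile"` or `"mass"`.
#' @return Named numeric vector `c(favored = , disfavored = )`.
#' @export
contour_levels <- function(values, favored_pct = 80, disfavored_pct = 20,
                           mode = c("percentile", "mass")) {
  mode <- match.arg(mode)
  cs <- NULL
  if (inherits(values, "contour_set")) {
    cs <- values
    values <- cs$values
  }
  stopifnot(favored_pct > 0, favored_pct < 100, disfavored_pct > 0,
            disfavored_pct < 100, favored_pct > disfavored_pct)
  nz <- values[values != 0]
  if (length(nz) == 0) stop("all StDev*Coeff values are zero", call. = FALSE)
  pos <- nz[nz > 0]; neg <- nz[nz < 0]
  one_side <- function(v, pct, side) {
    if (length(v) == 0) {
      warning("no ", side, " values; ", side, " level reported NA")
      return(NA_real_)
    }
    if (mode == "percentile") {
      p <- if (side == "favored") pct / 100 else pct / 100
      unname(stats::quantile(v, p, type = 7))
    } else {
      mag <- sort(abs(v), decreasing = TRUE)
      cum <- cumsum(mag) / sum(mag)
      lvl <- mag[which(cum >= (100 - pct) / 100)[1]]
      if (side == "favored") lvl else -lvl
    }
  }
  fav <- one_side(pos, favored_pct, "favored")
  dis <- one_side(neg, disfavored_pct, "disfavored")
  lv <- c(favored = fav, disfavored = dis)
  if (!is.null(cs)) {
    cs$levels <- lv
    return(cs)
  }
  lv
}

#' Export a contour set as an OpenDX scalar field
#'
#' Writes the lattice values as an OpenDX regular-grid scalar field readable
#' by standard molecular viewers. Iso-levels, when present, are recorded in
#' header comments. The DX body uses the format's canonical ordering (last
#' index fastest), permuted from the package's x-fastest internal order.
#'
#' @param contour_set A `contour_set` (optionally carrying levels).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_contours <- function(contour_set, path) {
  g <- contour_set$grid
  v <- contour_set$values
  if (length(v) != n_grid_points(g)) stop("value/grid length mismatch", call. = FALSE)
  # x-fastest -> z-fastest
  arr <- array(v, dim = g$dims)
  vz <- as.vector(aperm(arr, c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# qsar3d StDev*Coeff field: %s", contour_set$kind),
    if (!is.null(contour_set$levels))
      sprintf("# iso-levels: favored %.6g disfavored %.6g",
              contour_set$levels["favored"], contour_set$levels["disfavored"]),
    sprintf("object 1 class gridpositions counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("origin %.6f %.6f %.6f", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6f 0.000000 0.000000", g$spacing),
    sprintf("delta 0.000000 %.6f 0.000000", g$spacing),
    sprintf("delta 0.000000 0.000000 %.6f", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            g$dims[1], g$dims[2], g$dims[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            length(vz))
  ), con)
  body <- vapply(split(vz, ceiling(seq_along(vz) / 3)),
                 function(chunk) paste(sprintf("%.10g", chunk), collapse = " "),
                 character(1))
  writeLines(unname(body), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"regular positions regular connections\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [export_contours()]
#'
#' @param path DX file path.
#' @return A `contour_set` (kind taken from the header comment when present).
#' @export
read_contours <- function(path) {
  txt <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", txt, value = TRUE)[1]
  dims <- as.integer(strsplit(sub(".*counts ", "", gp), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin ", "", grep("^origin", txt, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- grep("^delta", txt, value = TRUE)
  spacing <- max(as.numeric(strsplit(sub("^delta ", "", deltas[1]), "\\s+")[[1]]))
  arr_line <- grep("class array", txt)
  n_items <- as.integer(sub(".*items (\\d+) .*", "\\1", txt[arr_line]))
  body_start <- arr_line + 1
  vals <- numeric(0)
  i <- body_start
  while (length(vals) < n_items && i <= length(txt)) {
    vals <- c(vals, as.numeric(strsplit(trimws(txt[i]), "\\s+")[[1]]))
    i <- i + 1
  }
  if (length(vals) != n_items) stop("truncated DX data block", call. = FALSE)
  arr <- array(vals, dim = rev(dims))          # z fastest as written
  v <- as.vector(aperm(arr, c(3, 2, 1)))       # back to x fastest
  kind_line <- grep("StDev\\*Coeff field:", txt, value = TRUE)
  kind <- if (length(kind_line) > 0) sub(".*field: ", "", kind_line[1]) else "unknown"
  structure(list(kind = kind, values = v,
                 grid = grid_spec(org, spacing, dims), levels = NULL),
            class = "contour_set")
}

#' Top contributing lattice points
#'
#' @param contour_set A `contour_set`.
#' @param n Number of points to report.
#' @return Tibble of the `n` largest-|StDev*Coeff| lattice points with
#'   coordinates and values.
#' @export
top_contour_points <- function(contour_set, n = 10) {
  g <- contour_set$grid
  pts <- grid_points(g)
  ord <- order(abs(contour_set$values), decreasing = TRUE)[seq_len(min(n, sum(contour_set$values != 0)))]
  tibble::tibble(point = ord, x = pts[ord, 1], y = pts[ord, 2], z = pts[ord, 3],
                 stdev_coeff = contour_set$values[ord])
}
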