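#' Parse an anchor substructure pattern
#'
#' Patterns use a deliberately small SMILES-like syntax sufficient to describe
#' rigid alignment anchors: element symbols (`P`, `O`, `Cl`, ...) chained
#' left-to-right into bonds, parenthesised branches, and `*` as an
#' any-element wildcard. `"P(O)(O)(O)O"` is a phosphorus bonded to four
#' oxygens; `"OCC"` an O-C-C chain. Bond orders are not constrained.
#'
#' @param query Pattern string.
#' @return A list with `elements` (character vector, `"*"` = wildcard) and
#'   `edges` (2-column integer matrix).
#' @export
parse_anchor_pattern <- function(query) {
  stopifnot(is.character(query), length(query) == 1, nzchar(query))
  chars <- strsplit(query, "")[[1]]
  elements <- character(0)
  edges <- matrix(integer(0), ncol = 2)
  prev <- NA_integer_
  stack <- integer(0)
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom in pattern: ", query, call. = FALSE)
      stack <- c(stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unbalanced ')' in pattern: ", query, call. = FALSE)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (grepl("[A-Z*]", ch)) {
      sym <- ch
      if (ch != "*" && i < length(chars) && grepl("[a-z]", chars[i + 1])) {
        sym <- paste0(ch, chars[i + 1])
        i <- i + 1
      }
      elements <- c(elements, sym)
      idx <- length(elements)
      if (!is.na(prev)) edges <- rbind(edges, c(prev, idx))
      prev <- idx
      i <- i + 1
    } else {
      stop("unexpected character '", ch, "' in pattern: ", query, call. = FALSE)
    }
  }
  if (length(stack) > 0) stop("unbalanced '(' in pattern: ", query, call. = FALSE)
  list(elements = elements, edges = edges)
}

#' Default alignment anchor: a phosphorus bonded to at least three oxygens
#' @export
default_anchor_pattern <- function() "P(O)(O)O"

#' Match a substructure pattern against a molecule
#'
#' Finds every embedding of the pattern in the molecule's bond graph
#' (igraph VF2/LAD subgraph isomorphism with element-constrained domains).
#' Matches are returned in deterministic lexicographic order of their molecule
#' atom-index tuples; the first is the canonical match. Symmetric patterns
#' (e.g. the terminal oxygens of a phosphate) yield multiple matches, all
#' reported so callers can resolve the ambiguity.
#'
#' @param mol A `qsar_mol` with a bond list.
#' @param query Pattern string, see [parse_anchor_pattern()].
#' @return A list of class `substructure_match`: `query`, `atom_map` (tibble
#'   `pattern_atom`, `mol_atom` for the canonical match), `matches` (list of
#'   integer vectors), `n_matches`.
#' @export
match_substructure <- function(mol, query) {
  pat <- parse_anchor_pattern(query)
  bonds <- mol_bonds(mol)
  if (nrow(bonds) == 0 && length(pat$elements) > 1)
    stop("molecule ", mol_id(mol), " has no connectivity", call. = FALSE)
  target <- igraph::make_empty_graph(n = n_atoms(mol), directed = FALSE)
  if (nrow(bonds) > 0)
    target <- igraph::add_edges(target, rbind(bonds$i, bonds$j))
  pattern <- igraph::make_empty_graph(n = length(pat$elements), directed = FALSE)
  if (nrow(pat$edges) > 0)
    pattern <- igraph::add_edges(pattern, t(pat$edges))
  domains <- lapply(pat$elements, function(el) {
    if (el == "*") seq_len(n_atoms(mol)) else which(mol$element == el)
  })
  if (any(lengths(domains) == 0))
    stop("no substructure match for pattern '", query, "' in molecule ",
         mol_id(mol), call. = FALSE)
  maps <- igraph::subgraph_isomorphisms(pattern, target, method = "lad",
                                        induced = FALSE, domains = domains)
  maps <- lapply(maps, as.integer)
  if (length(maps) == 0)
    stop("no substructure match for pattern '", query, "' in molecule ",
         mol_id(mol), call. = FALSE)
  ord <- do.call(order, as.data.frame(do.call(rbind, maps)))
  maps <- maps[ord]
  structure(list(query = query,
                 atom_map = tibble::tibble(pattern_atom = seq_along(maps[[1]]),
                                           mol_atom = maps[[1]]),
                 matches = maps,
                 n_matches = length(maps)),
            class = "substructure_match")
}

#' @export
print.substructure_match <- function(x, ...) {
  cat(sprintf("<substructure_match '%s': %d match(es); canonical: %s>\n",
              x$query, x$n_matches, paste(x$atom_map$mol_atom, collapse = ",")))
  invisible(x)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets, via singular value decomposition of the covariance
#' of the centred point sets with a determinant correction that excludes
#' reflections.
#'
#' @param mobile,reference n x 3 coordinate matrices of the mapped atoms
#'   (n >= 3, not collinear).
#' @return A list of class `rigid_transform`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` over the mapped atoms.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)) || ncol(mobile) != 3)
    stop("mobile and reference must be matched n x 3 matrices", call. = FALSE)
  n <- nrow(mobile)
  if (n < 3) stop("need at least 3 mapped atoms for a unique rigid fit",
                  call. = FALSE)
  mc <- colMeans(mobile); rc <- colMeans(reference)
  P <- sweep(mobile, 2, mc); Q <- sweep(reference, 2, rc)
  if (svd(P)$d[2] < 1e-8)
    stop("degenerate geometry: mapped atoms are collinear", call. = FALSE)
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- rc - as.vector(R %*% mc)
  fitted <- apply_transform(mobile, list(rotation = R, translation = t_vec))
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz n x 3 matrix.
#' @param transform A `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2, transform$translation, "+")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: rmsd %.4g A>\n", x$rmsd))
  invisible(x)
}

#' Align a dataset onto a template molecule via a common substructure
#'
#' Every molecule is rigidly superposed onto the template using only the
#' anchor atoms matched by `query` (database-alignment semantics: the fit
#' uses the mapped atoms, the transform moves the whole molecule). When the
#' anchor is symmetric, every automorphic match is evaluated and the
#' minimum-RMSD one kept; ties resolve to the lexicographically smallest
#' atom-index tuple. The template itself is left untouched.
#'
#' @param data Molecule-set or `qsar_dataset` tibble.
#' @param template_id Id of the template molecule (typically the most potent
#'   compound of the series).
#' @param query Anchor pattern, default [default_anchor_pattern()].
#' @return The input tibble with aligned molecules and an `align_rmsd` column
#'   (anchor-atom RMSD against the template; 0 for the template).
#' @export
align_dataset <- function(data, template_id, query = default_anchor_pattern()) {
  if (!(template_id %in% data$id))
    stop("template id '", template_id, "' not in dataset", call. = FALSE)
  template <- data$mol[[match(template_id, data$id)]]
  tmatch <- match_substructure(template, query)
  ref <- coords(template)[tmatch$atom_map$mol_atom, , drop = FALSE]

  failures <- character(0)
  matches <- vector("list", nrow(data))
  for (k in seq_len(nrow(data))) {
    matches[k] <- list(tryCatch(match_substructure(data$mol[[k]], query),
                                error = function(e) NULL))
    if (is.null(matches[[k]])) failures <- c(failures, data$id[k])
  }
  if (length(failures) > 0)
    stop("no anchor match for molecule(s): ", paste(failures, collapse = ", "),
         call. = FALSE)

  rmsds <- numeric(nrow(data))
  for (k in seq_len(nrow(data))) {
    mol <- data$mol[[k]]
    if (data$id[k] == template_id) {
      rmsds[k] <- 0
      next
    }
    best <- NULL
    for (map in matches[[k]]$matches) {
      tf <- superpose(coords(mol)[map, , drop = FALSE], ref)
      if (is.null(best) || tf$rmsd < best$rmsd) best <- tf
    }
    data$mol[[k]] <- set_coords(mol, apply_transform(coords(mol), best))
    rmsds[k] <- best$rmsd
  }
  data$align_rmsd <- rmsds
  data
}
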