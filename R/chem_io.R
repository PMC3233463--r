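#' Read molecules from an SDF or MOL2 file
#'
#' SDF files (V2000 only) are parsed with ChemmineR; MOL2 (TRIPOS) files with
#' bio3d. 3D coordinates are preserved exactly. Partial charges are taken from
#' the file when present — the MOL2 charge column, or an SDF data field
#' `PARTIAL_CHARGES` holding one value per atom — and flagged absent otherwise.
#' An SDF field `PIC50` populates the activity; `ATOM_PROPERTIES` (one
#' `vdw_radius,hydrophobicity,is_hbd,is_hba` record per atom, records separated
#' by `;`) overrides the element-table defaults, which is how synthetic series
#' round-trip their planted per-atom properties.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"sdf"` or `"mol2"`.
#' @return A molecule-set tibble (see [molecule_set()]).
#' @export
read_molecules <- function(path, format = c("auto", "sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  }
  if (format == "sdf") read_sdf_molecules(path) else read_mol2_molecules(path)
}

read_sdf_molecules <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0 || !any(nzchar(trimws(txt))))
    stop("no records in ", path, call. = FALSE)
  if (any(grepl("V3000", txt)))
    stop("V3000 SDF records are not supported; supply V2000", call. = FALSE)
  sdfset <- tryCatch(ChemmineR::read.SDFset(path),
                     error = function(e) stop("failed to parse SDF: ",
                                              conditionMessage(e), call. = FALSE))
  n <- length(sdfset)
  if (n == 0) stop("no records in ", path, call. = FALSE)
  mols <- vector("list", n)
  for (k in seq_len(n)) {
    sdf <- sdfset[[k]]
    hdr <- ChemmineR::header(sdf)
    ab <- ChemmineR::atomblock(sdf)
    if (nrow(ab) < 1) stop("unreadable record ", k, ": no atoms", call. = FALSE)
    dim_lines <- hdr[seq_len(min(3, length(hdr)))][-1]
    if (any(grepl("\\b2D\\b", dim_lines)))
      stop("record ", k, " has 2D-only coordinates", call. = FALSE)
    element <- sub("_.*$", "", rownames(ab))
    atoms <- tibble::tibble(element = element,
                            x = unname(ab[, 1]), y = unname(ab[, 2]),
                            z = unname(ab[, 3]))
    if (nrow(atoms) > 1 && all(atoms$z == 0) && all(atoms$y == 0))
      stop("record ", k, " has 2D-only coordinates", call. = FALSE)
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.matrix(bb) && nrow(bb) > 0) {
      tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                     order = as.integer(bb[, 3]))
    } else NULL
    db <- ChemmineR::datablock(sdf)
    id <- trimws(hdr[1])
    if (!nzchar(id)) id <- sprintf("mol%03d", k)
    pic50 <- NA_real_
    charges_present <- FALSE
    if (length(db) > 0 && !is.null(names(db))) {
      if ("PIC50" %in% names(db)) pic50 <- as.numeric(db[["PIC50"]])
      if ("PARTIAL_CHARGES" %in% names(db)) {
        ch <- as.numeric(strsplit(trimws(db[["PARTIAL_CHARGES"]]), "\\s+")[[1]])
        if (length(ch) != nrow(atoms))
          stop("record ", k, ": PARTIAL_CHARGES length != atom count", call. = FALSE)
        atoms$charge <- ch
        charges_present <- TRUE
      }
      if ("ATOM_PROPERTIES" %in% names(db)) {
        recs <- strsplit(strsplit(trimws(db[["ATOM_PROPERTIES"]]), ";")[[1]], ",")
        if (length(recs) != nrow(atoms))
          stop("record ", k, ": ATOM_PROPERTIES length != atom count", call. = FALSE)
        prop <- do.call(rbind, lapply(recs, as.numeric))
        atoms$vdw_radius <- prop[, 1]
        atoms$hydrophobicity <- prop[, 2]
        atoms$is_hbd <- prop[, 3] != 0
        atoms$is_hba <- prop[, 4] != 0
      }
    }
    mols[[k]] <- molecule(atoms, bonds = bonds, id = id, pic50 = pic50,
                          charges_present = charges_present)
  }
  molecule_set(mols)
}

read_mol2_molecules <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!any(grepl("@<TRIPOS>MOLECULE", txt, fixed = TRUE)))
    stop("no records in ", path, call. = FALSE)
  m <- tryCatch(bio3d::read.mol2(path),
                error = function(e) stop("failed to parse MOL2: ",
                                         conditionMessage(e), call. = FALSE))
  if (inherits(m, "mol2")) m <- list(m)
  # charge-type line is the 4th line of each MOLECULE record
  mol_starts <- grep("@<TRIPOS>MOLECULE", txt, fixed = TRUE)
  charge_types <- vapply(mol_starts, function(s) {
    if (s + 4 <= length(txt)) trimws(txt[s + 4]) else ""
  }, character(1))
  mols <- vector("list", length(m))
  for (k in seq_along(m)) {
    at <- m[[k]]$atom
    element <- sub("\\..*$", "", at$elety)
    atoms <- tibble::tibble(element = element,
                            x = as.numeric(at$x), y = as.numeric(at$y),
                            z = as.numeric(at$z))
    charges_present <- !identical(toupper(charge_types[min(k, length(charge_types))]),
                                  "NO_CHARGES")
    if (charges_present && "charge" %in% colnames(at)) {
      atoms$charge <- as.numeric(at$charge)
    }
    bd <- m[[k]]$bond
    bonds <- if (!is.null(bd) && nrow(bd) > 0) {
      tibble::tibble(i = as.integer(bd$origin), j = as.integer(bd$target),
                     order = suppressWarnings(as.integer(bd$type)))
    } else NULL
    if (!is.null(bonds)) bonds$order[is.na(bonds$order)] <- 1L
    id <- if (!is.null(m[[k]]$name) && nzchar(m[[k]]$name)) m[[k]]$name
          else sprintf("mol%03d", k)
    mols[[k]] <- molecule(atoms, bonds = bonds, id = id,
                          charges_present = charges_present)
  }
  molecule_set(mols)
}

#' Write molecules to an SDF V2000 file
#'
#' Inverse of [read_molecules()]: coordinates, bonds, partial charges
#' (`PARTIAL_CHARGES` data field), activities (`PIC50`) and per-atom
#' properties (`ATOM_PROPERTIES`) are emitted so that a write/read round trip
#' reproduces the molecule set.
#'
#' @param data Molecule-set tibble or list of `qsar_mol`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_molecules <- function(data, path) {
  mols <- if (is.data.frame(data)) data$mol else data
  sdfs <- lapply(mols, function(mol) {
    ab <- cbind(coords(mol), matrix(0, n_atoms(mol), 12))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    rownames(ab) <- paste(mol$element, seq_len(n_atoms(mol)), sep = "_")
    bd <- mol_bonds(mol)
    bb <- if (nrow(bd) > 0) {
      m <- cbind(bd$i, bd$j, bd$order, 0, 0, 0, 0)
      colnames(m) <- paste0("C", 1:7)
      rownames(m) <- as.character(seq_len(nrow(m)))
      m
    } else matrix(numeric(0), 0, 7, dimnames = list(NULL, paste0("C", 1:7)))
    db <- c(
      if (!is.na(mol_pic50(mol))) c(PIC50 = format(mol_pic50(mol), digits = 10)),
      if (has_charges(mol))
        c(PARTIAL_CHARGES = paste(format(mol$charge, digits = 8, trim = TRUE),
                                  collapse = " ")),
      c(ATOM_PROPERTIES = paste(sprintf("%.6g,%.6g,%d,%d", mol$vdw_radius,
                                        mol$hydrophobicity, as.integer(mol$is_hbd),
                                        as.integer(mol$is_hba)), collapse = ";"))
    )
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      n_atoms(mol), nrow(bd))
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = c(Molecule_Name = mol_id(mol), Source = "qsar3d",
                            Comment = "3D", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
  sdfset <- methods::new(methods::getClass("SDFset", where = asNamespace("ChemmineR")),
                         SDF = sdfs, ID = vapply(mols, mol_id, character(1)))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Assign Gasteiger (PEOE) partial charges
#'
#' Computes Gasteiger partial charges through the OpenBabel command-line tool
#' and writes them onto the molecule. File-supplied charges are the preferred
#' source for modelling; this is the fallback for structures that arrive
#' without charges.
#'
#' @param mol A `qsar_mol` with a chemically valid bond list.
#' @return The molecule with its `charge` column populated.
#' @export
assign_gasteiger_charges <- function(mol) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel))
    stop("OpenBabel ('obabel') not found on PATH; cannot assign Gasteiger charges",
         call. = FALSE)
  tmp_in <- tempfile(fileext = ".sdf")
  tmp_out <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  bare <- molecule(mol[, c("element", "x", "y", "z")], bonds = mol_bonds(mol),
                   id = mol_id(mol))
  write_molecules(list(bare), tmp_in)
  status <- system2(obabel, c(shQuote(tmp_in), "-O", shQuote(tmp_out),
                              "--partialcharge", "gasteiger"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(tmp_out))
    stop("OpenBabel failed to compute charges for molecule ", mol_id(mol),
         call. = FALSE)
  out <- read_mol2_molecules(tmp_out)
  if (nrow(out$mol[[1]]) != n_atoms(mol))
    stop("charge assignment changed the atom count for ", mol_id(mol),
         " (uninterpretable valence?)", call. = FALSE)
  ch <- out$mol[[1]]$charge
  if (any(!is.finite(ch)))
    stop("non-finite Gasteiger charges for ", mol_id(mol), call. = FALSE)
  mol$charge <- ch
  attr(mol, "charges_present") <- TRUE
  mol
}

#' Load an activity table
#'
#' Reads a CSV with an `id` column and either `pic50` or `ic50_M`; IC50 values
#' (molar) are converted as \eqn{pIC50 = -\log_{10} IC50}.
#'
#' @param path CSV path.
#' @return Tibble with columns `id`, `pic50`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = "a", ic50_M = 1e-6), f, row.names = FALSE)
#' load_activity_table(f)  # pIC50 6
load_activity_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!("id" %in% names(tab)))
    stop("activity table needs an 'id' column", call. = FALSE)
  if (anyDuplicated(tab$id))
    stop("duplicate id(s) in activity table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "), call. = FALSE)
  if ("pic50" %in% names(tab)) {
    pic50 <- as.numeric(tab$pic50)
  } else if ("ic50_M" %in% names(tab)) {
    ic50 <- as.numeric(tab$ic50_M)
    if (any(!is.finite(ic50)) || any(ic50 <= 0))
      stop("ic50_M values must be positive and finite", call. = FALSE)
    pic50 <- -log10(ic50)
  } else {
    stop("activity table needs a 'pic50' or 'ic50_M' column", call. = FALSE)
  }
  if (any(!is.finite(pic50))) stop("non-finite pIC50 values", call. = FALSE)
  tibble::tibble(id = as.character(tab$id), pic50 = pic50)
}

#' Split a dataset into training and test sets
#'
#' Either honours an explicit test-id list verbatim, or stratifies by pIC50 so
#' the test set spans the activity range: molecules are ranked by activity, the
#' global minimum and maximum are forced into the training set, the remainder
#' is cut into as many rank bins as test compounds and one member is sampled
#' per bin. Deterministic for a given `seed`.
#'
#' @param data Molecule-set tibble whose `pic50` column is populated (or with
#'   `activities` supplied).
#' @param test_ids Explicit character vector of test ids (overrides strategy).
#' @param test_fraction Fraction of molecules for the test set, in (0, 1).
#' @param seed Integer seed for the stratified draw.
#' @param activities Optional activity tibble passed to [qsar_dataset()].
#' @return A `qsar_dataset` tibble with a `role` column.
#' @export
split_dataset <- function(data, test_ids = NULL, test_fraction = NULL,
                          seed = 1L, activities = NULL) {
  data <- qsar_dataset(data, activities = activities)
  if (!is.null(test_ids)) return(qsar_dataset(data, test_ids = test_ids))
  if (is.null(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  n <- nrow(data)
  n_test <- max(1L, round(n * test_fraction))
  if (n_test > n - 2) stop("test_fraction too large for dataset size", call. = FALSE)
  ord <- order(data$pic50)
  anchors <- c(ord[1], ord[n])           # extremes stay in training
  pool <- setdiff(ord, anchors)          # already in ascending pic50 order
  bins <- split(pool, cut(seq_along(pool), breaks = n_test, labels = FALSE))
  picks <- with_local_seed(seed, {
    vapply(bins, function(b) if (length(b) == 1) b else b[sample.int(length(b), 1)],
           numeric(1))
  })
  qsar_dataset(data, test_ids = data$id[picks])
}

#' Read / write a test-set membership file (one molecule id per line)
#'
#' @param path File path.
#' @return `read_split_file()`: character vector of test ids.
#' @export
read_split_file <- function(path) {
  ids <- trimws(readLines(path, warn = FALSE))
  ids[nzchar(ids)]
}

#' @rdname read_split_file
#' @param test_ids Character vector of test ids.
#' @export
write_split_file <- function(test_ids, path) {
  writeLines(test_ids, path)
  invisible(path)
}

# Evaluate expr under a temporary RNG state so package functions never disturb
# the caller's random stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
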