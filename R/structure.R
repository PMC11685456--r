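#' Protein structure container
#'
#' A `structure3d` object holds an atom table shared by one or more
#' coordinate models (as in a multi-MODEL PDB entry). Coordinates are in
#' Angstroms. Residue numbering is author-assigned (PDB "auth" numbering).
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `residue_number`, `insertion_code`, `chain_id`,
#'   `occupancy`, `b_factor`, `het` (logical, HETATM record).
#' @param xyz a numeric N x 3 matrix, or a list of such matrices (one per
#'   model). All models must have the same atom count and ordering.
#'
#' @return An object of class `structure3d` with elements `atoms` and
#'   `xyz` (list of N x 3 matrices).
#' @examples
#' s <- make_ideal_helix(10)
#' s
#' natoms(s)
#' @export
structure3d <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "atom_name", "element", "residue_name",
            "residue_number", "insertion_code", "chain_id",
            "occupancy", "b_factor", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (is.matrix(xyz)) xyz <- list(xyz)
  stopifnot(is.list(xyz), length(xyz) >= 1)
  n <- nrow(atoms)
  if (n == 0L) stop("structure has zero atoms")
  for (m in seq_along(xyz)) {
    x <- xyz[[m]]
    if (!is.matrix(x) || ncol(x) != 3L || nrow(x) != n) {
      stop("model ", m, ": coordinate matrix must be ", n, " x 3")
    }
    if (!all(is.finite(x))) stop("model ", m, ": non-finite coordinates")
    storage.mode(xyz[[m]]) <- "double"
    dimnames(xyz[[m]]) <- NULL
  }
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$atom_name, sep = "\r")
  if (anyDuplicated(key)) {
    d <- atoms[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate atom identity within a model: chain ", d$chain_id,
         " residue ", d$residue_number, " atom ", d$atom_name)
  }
  rownames(atoms) <- NULL
  obj <- list(atoms = atoms, xyz = xyz)
  class(obj) <- "structure3d"
  obj
}

#' @rdname structure3d
#' @param x a `structure3d` object.
#' @export
natoms <- function(x) UseMethod("natoms")

#' @export
natoms.structure3d <- function(x) nrow(x$atoms)

#' @rdname structure3d
#' @export
nmodels <- function(x) UseMethod("nmodels")

#' @export
nmodels.structure3d <- function(x) length(x$xyz)

#' Coordinates of one model
#'
#' @param x a `structure3d` object.
#' @param model model index (default 1).
#' @return N x 3 numeric matrix of Angstrom coordinates.
#' @export
coords <- function(x, model = 1L) UseMethod("coords")

#' @export
coords.structure3d <- function(x, model = 1L) {
  if (model < 1L || model > nmodels(x)) {
    stop("model index ", model, " out of range (structure has ",
         nmodels(x), " model(s))")
  }
  x$xyz[[model]]
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms
  cat("structure3d:", nrow(a), "atoms,", length(unique(a$chain_id)),
      "chain(s),", nmodels(x), "model(s)\n")
  for (ch in unique(a$chain_id)) {
    r <- a$residue_number[a$chain_id == ch & !a$het]
    if (length(r)) {
      cat("  chain ", ch, ": residues ", min(r), "-", max(r), "\n", sep = "")
    }
  }
  nhet <- sum(a$het)
  if (nhet) cat(" ", nhet, "HETATM atom(s)\n")
  invisible(x)
}

# Internal: build an atom table row-wise from vectors, with defaults.
.atom_table <- function(atom_name, residue_name, residue_number, chain_id,
                        element = NULL, serial = NULL,
                        insertion_code = "", occupancy = 1, b_factor = 0,
                        het = FALSE) {
  n <- length(atom_name)
  if (is.null(element)) element <- substr(trimws(atom_name), 1L, 1L)
  if (is.null(serial)) serial <- seq_len(n)
  data.frame(
    serial = as.integer(serial),
    atom_name = as.character(atom_name),
    element = as.character(element),
    residue_name = as.character(residue_name),
    residue_number = as.integer(residue_number),
    insertion_code = rep_len(as.character(insertion_code), n),
    chain_id = rep_len(as.character(chain_id), n),
    occupancy = rep_len(as.numeric(occupancy), n),
    b_factor = rep_len(as.numeric(b_factor), n),
    het = rep_len(as.logical(het), n),
    stringsAsFactors = FALSE
  )
}
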