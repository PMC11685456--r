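#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records with PDB v3.3 fixed-column conventions.
#' Multiple `MODEL` blocks become multiple coordinate models sharing one
#' atom table. HETATM records are retained and flagged in the `het`
#' column. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties: first encountered).
#'
#' @param path path to the file.
#' @param format one of `"pdb"`, `"mmcif"`, `"auto"`. Only PDB input is
#'   supported; `"auto"` dispatches on the file extension.
#' @return A [structure3d] object.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_structure(make_ideal_helix(5), f)
#' read_structure(f)
#' @seealso [write_structure()], [read_trajectory()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  if (format == "mmcif") {
    stop("mmCIF input is not supported; convert to PDB format first")
  }
  .parse_pdb(readLines(path, warn = FALSE), src = path)
}

.parse_num <- function(txt, line_no, field) {
  v <- suppressWarnings(as.numeric(trimws(txt)))
  if (is.na(v)) {
    stop("malformed ", field, " field on line ", line_no,
         ": '", trimws(txt), "'")
  }
  v
}

.parse_pdb <- function(lines, src = "<text>") {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")

  # assign a model index to every line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L

  keep <- which(is_atom)
  if (!length(keep)) stop("zero atoms parsed from ", src)

  fx <- function(l, a, b) substr(lines[l], a, b)
  n <- length(keep)
  xyz <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    l <- keep[k]
    xyz[k, 1] <- .parse_num(fx(l, 31, 38), l, "x coordinate")
    xyz[k, 2] <- .parse_num(fx(l, 39, 46), l, "y coordinate")
    xyz[k, 3] <- .parse_num(fx(l, 47, 54), l, "z coordinate")
  }
  occ <- suppressWarnings(as.numeric(trimws(fx(keep, 55, 60))))
  occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(trimws(fx(keep, 61, 66))))
  bf[is.na(bf)] <- 0
  elem <- trimws(fx(keep, 77, 78))
  aname <- trimws(fx(keep, 13, 16))
  no_elem <- elem == ""
  if (any(no_elem)) elem[no_elem] <- gsub("[^A-Za-z].*$", "",
                                          substr(aname[no_elem], 1, 1))
  at <- data.frame(
    serial = suppressWarnings(as.integer(trimws(fx(keep, 7, 11)))),
    atom_name = aname,
    altloc = substr(lines[keep], 17, 17),
    element = elem,
    residue_name = trimws(fx(keep, 18, 20)),
    residue_number = suppressWarnings(as.integer(trimws(fx(keep, 23, 26)))),
    insertion_code = trimws(fx(keep, 27, 27)),
    chain_id = trimws(fx(keep, 22, 22)),
    occupancy = occ,
    b_factor = bf,
    het = rec[keep] == "HETATM",
    model = model_id[keep],
    stringsAsFactors = FALSE
  )
  if (anyNA(at$residue_number)) {
    stop("malformed residue number on line ",
         keep[which(is.na(at$residue_number))[1]])
  }

  # resolve alternate locations within each model: keep the
  # highest-occupancy conformer, ties broken by file order
  key <- paste(at$model, at$chain_id, at$residue_number,
               at$insertion_code, at$atom_name, sep = "\r")
  drop <- logical(nrow(at))
  if (any(at$altloc != " " & at$altloc != "")) {
    for (g in split(seq_len(nrow(at)), key)) {
      if (length(g) > 1L) {
        best <- g[which.max(at$occupancy[g])]
        drop[setdiff(g, best)] <- TRUE
      }
    }
    at <- at[!drop, , drop = FALSE]
    xyz <- xyz[!drop, , drop = FALSE]
  }

  models <- sort(unique(at$model))
  first <- at$model == models[1]
  atoms <- at[first, setdiff(names(at), c("altloc", "model")), drop = FALSE]
  xyz_list <- vector("list", length(models))
  ref_key <- paste(at$chain_id, at$residue_number, at$insertion_code,
                   at$atom_name, sep = "\r")[first]
  for (mi in seq_along(models)) {
    sel <- at$model == models[mi]
    if (sum(sel) != sum(first)) {
      stop("model ", mi, " has ", sum(sel), " atoms; model 1 has ",
           sum(first), " (all models must share the atom table)")
    }
    k <- paste(at$chain_id, at$residue_number, at$insertion_code,
               at$atom_name, sep = "\r")[sel]
    if (!identical(k, ref_key)) {
      stop("model ", mi, " atom ordering/identity differs from model 1")
    }
    xyz_list[[mi]] <- xyz[sel, , drop = FALSE]
  }
  structure3d(atoms, xyz_list)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records; multiple models are written as
#' MODEL/ENDMDL blocks. Coordinates are written with three decimals (the
#' PDB precision), so a write/read round trip preserves them to 1e-3 A.
#'
#' @param x a [structure3d] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  a <- x$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- nmodels(x) > 1L
  for (m in seq_len(nmodels(x))) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- x$xyz[[m]]
    rec <- ifelse(a$het, "HETATM", "ATOM  ")
    nm <- a$atom_name
    # short names start in column 14 by convention
    nm <- ifelse(nchar(nm) < 4 & nchar(a$element) == 1,
                 sprintf(" %-3s", nm), sprintf("%-4s", nm))
    lines <- sprintf(
      "%s%5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial %% 100000L, nm, a$residue_name,
      ifelse(a$chain_id == "", " ", a$chain_id),
      a$residue_number, ifelse(a$insertion_code == "", " ", a$insertion_code),
      xyz[, 1], xyz[, 2], xyz[, 3], a$occupancy, a$b_factor,
      toupper(a$element)
    )
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
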