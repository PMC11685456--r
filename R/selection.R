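#' Define a named domain selection
#'
#' A domain is a chain plus one or more inclusive author-numbered residue
#' ranges and an atom-name filter (default: the backbone atoms N, CA, C, O,
#' the atoms used for per-domain RMSD in this workflow). Ranges match on
#' `residue_number` ignoring insertion codes.
#'
#' @param label selection label (unique within a registry).
#' @param chain chain identifier.
#' @param ranges a numeric vector `c(start, end)` or a list of such
#'   inclusive ranges.
#' @param atom_names character vector of atom names to keep, or `NULL` for
#'   all atoms.
#' @return An object of class `domain_definition`.
#' @examples
#' domain_definition("SBDa_lid", "A", c(556, 639))
#' @export
domain_definition <- function(label, chain, ranges,
                              atom_names = c("N", "CA", "C", "O")) {
  if (!is.list(ranges)) ranges <- list(ranges)
  for (r in ranges) {
    if (length(r) != 2L || !is.numeric(r) || r[1] > r[2]) {
      stop("each range must be c(start, end) with start <= end")
    }
  }
  if (!length(ranges)) stop("at least one residue range is required")
  obj <- list(label = as.character(label), chain = as.character(chain),
              ranges = lapply(ranges, as.integer),
              atom_names = if (is.null(atom_names)) NULL
                           else as.character(atom_names))
  class(obj) <- "domain_definition"
  obj
}

#' @export
print.domain_definition <- function(x, ...) {
  rng <- paste(vapply(x$ranges, function(r) paste(r, collapse = "-"),
                      character(1)), collapse = ", ")
  cat("domain '", x$label, "': chain ", x$chain, ", residues ", rng,
      ", atoms ", if (is.null(x$atom_names)) "all"
                  else paste(x$atom_names, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Built-in domain definitions
#'
#' The Hsp70/GrpEL1 subdomains used for per-domain RMSD analysis, in
#' mortalin / GrpEL1 author numbering: the GrpEL1-B beta-wing
#' (residues 160-217), the mortalin SBD-alpha lid (556-639), the SBD-beta
#' sandwich (440-555), and the combined SBD (440-639). Backbone atoms
#' N, CA, C, O.
#'
#' @param mortalin_chain chain id carrying mortalin (default `"A"`).
#' @param grpel1b_chain chain id carrying the GrpEL1-B protomer
#'   (default `"C"`).
#' @return Named list of [domain_definition] objects.
#' @export
builtin_domains <- function(mortalin_chain = "A", grpel1b_chain = "C") {
  list(
    grpel1b_beta_wing = domain_definition("grpel1b_beta_wing",
                                          grpel1b_chain, c(160, 217)),
    sbd_alpha_lid = domain_definition("sbd_alpha_lid",
                                      mortalin_chain, c(556, 639)),
    sbd_beta = domain_definition("sbd_beta", mortalin_chain, c(440, 555)),
    sbd_alpha_beta = domain_definition("sbd_alpha_beta",
                                       mortalin_chain, c(440, 639))
  )
}

#' Resolve a domain definition against a structure
#'
#' Returns the indices of atoms matching the definition's chain, residue
#' ranges and atom-name filter, in structure order. Residues inside a
#' range that are present but lack some requested atom names are kept
#' with the atoms they have, with a warning; a selection that matches
#' nothing is an error.
#'
#' @param structure a [structure3d].
#' @param definition a [domain_definition].
#' @return An object of class `atom_selection`: list with `indices`
#'   (strictly increasing integer vector), `label`, and `n_structure`
#'   (atom count of the structure it was resolved against).
#' @export
select_atoms <- function(structure, definition) {
  stopifnot(inherits(structure, "structure3d"),
            inherits(definition, "domain_definition"))
  a <- structure$atoms
  if (!definition$chain %in% a$chain_id) {
    stop("chain '", definition$chain, "' not present in structure")
  }
  in_range <- rep(FALSE, nrow(a))
  for (r in definition$ranges) {
    in_range <- in_range |
      (a$residue_number >= r[1] & a$residue_number <= r[2])
  }
  sel <- a$chain_id == definition$chain & in_range
  if (!is.null(definition$atom_names)) {
    with_name <- sel & a$atom_name %in% definition$atom_names
    # warn about residues present in range but missing requested atoms
    if (any(sel) && any(with_name)) {
      res_all <- unique(a$residue_number[sel])
      cnt <- table(a$residue_number[with_name])
      short <- res_all[!(as.character(res_all) %in% names(cnt)) |
                         cnt[as.character(res_all)] <
                           length(definition$atom_names)]
      short <- short[!is.na(short)]
      if (length(short)) {
        warning("selection '", definition$label, "': residue(s) ",
                paste(utils::head(short, 5), collapse = ", "),
                if (length(short) > 5) " ..." else "",
                " are missing some requested atoms; kept partial residues")
      }
    }
    sel <- with_name
  }
  idx <- which(sel)
  if (!length(idx)) {
    stop("empty selection: '", definition$label, "' (chain ",
         definition$chain, ", ranges ",
         paste(vapply(definition$ranges,
                      function(r) paste(r, collapse = "-"),
                      character(1)), collapse = ","),
         ") matches no atoms")
  }
  atom_selection(idx, definition$label, natoms(structure))
}

#' Construct an atom selection from raw indices
#'
#' @param indices strictly increasing, duplicate-free atom indices.
#' @param label selection label.
#' @param n_structure atom count of the parent structure.
#' @return An `atom_selection` object.
#' @export
atom_selection <- function(indices, label = "selection",
                           n_structure = max(indices)) {
  indices <- as.integer(indices)
  if (!length(indices)) stop("empty selection: '", label, "'")
  if (anyNA(indices) || any(indices < 1L) || any(indices > n_structure)) {
    stop("selection '", label, "': indices out of range")
  }
  if (is.unsorted(indices, strictly = TRUE)) {
    stop("selection '", label, "': indices must be strictly increasing")
  }
  obj <- list(indices = indices, label = as.character(label),
              n_structure = as.integer(n_structure))
  class(obj) <- "atom_selection"
  obj
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection '", x$label, "': ", length(x$indices), " atoms\n",
      sep = "")
  invisible(x)
}

#' @export
length.atom_selection <- function(x) length(x$indices)

# Internal: coerce a selection-ish argument to integer indices.
.sel_idx <- function(sel, structure = NULL) {
  if (inherits(sel, "atom_selection")) return(sel$indices)
  if (inherits(sel, "domain_definition")) {
    if (is.null(structure)) stop("a structure is needed to resolve a domain")
    return(select_atoms(structure, sel)$indices)
  }
  as.integer(sel)
}
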