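#' Anisotropic network model Hessian
#'
#' Builds the 3N x 3N ANM Hessian for a set of network nodes (typically
#' Calpha atoms). For every node pair within the interaction cutoff the
#' off-diagonal 3 x 3 super-element is
#' `-gamma * (r_ij r_ij^T) / |r_ij|^2`; diagonal super-elements are minus
#' the sum of the row's off-diagonal super-elements, so every row of
#' blocks sums to zero (translational invariance) and the matrix is
#' symmetric by construction.
#'
#' @param node_coords N x 3 matrix of node coordinates (Angstrom),
#'   N >= 2, no two nodes closer than 1e-6 A.
#' @param cutoff interaction cutoff distance in Angstrom (default 10).
#' @param gamma uniform spring constant (arbitrary units, default 1).
#' @return 3N x 3N symmetric numeric matrix.
#' @export
build_hessian <- function(node_coords, cutoff = 10, gamma = 1) {
  x <- as.matrix(node_coords)
  stopifnot(ncol(x) == 3L)
  n <- nrow(x)
  if (n < 2L) stop("at least 2 nodes are required")
  d2 <- as.matrix(stats::dist(x))^2
  if (any(d2[upper.tri(d2)] < 1e-12)) {
    stop("coincident nodes (distance < 1e-6 A)")
  }
  h <- matrix(0, 3 * n, 3 * n)
  cut2 <- cutoff^2
  for (i in seq_len(n - 1L)) {
    js <- which(d2[i, ] <= cut2)
    js <- js[js > i]
    for (j in js) {
      rij <- x[j, ] - x[i, ]
      blk <- -gamma * tcrossprod(rij) / sum(rij^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      h[ii, jj] <- blk
      h[jj, ii] <- blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  h
}

#' Low-frequency modes of an ANM Hessian
#'
#' Full symmetric eigendecomposition; eigenvalues below a relative
#' tolerance of the largest are classified as rigid-body modes and
#' skipped (a connected network must have exactly six: three
#' translations, three rotations). The `n_modes` lowest non-rigid
#' eigenpairs are retained in ascending eigenvalue order, with each
#' eigenvector's sign fixed so its first non-zero component is positive.
#'
#' @param hessian symmetric 3N x 3N matrix from [build_hessian()].
#' @param n_modes number of non-rigid modes to retain (default 10).
#' @param rigid_tol relative rigid-mode tolerance (default 1e-8).
#' @return List with `eigenvalues` (ascending, length K), `modes`
#'   (3N x K orthonormal), `n_rigid_skipped`.
#' @export
compute_modes <- function(hessian, n_modes = 10L, rigid_tol = 1e-8) {
  h <- as.matrix(hessian)
  if (nrow(h) != ncol(h) || max(abs(h - t(h))) > 1e-8 * max(1, max(abs(h)))) {
    stop("hessian must be symmetric")
  }
  e <- eigen((h + t(h)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  tol <- rigid_tol * max(abs(vals))
  rigid <- which(vals < tol)
  if (length(rigid) != 6L) {
    stop("expected 6 rigid-body modes, found ", length(rigid),
         " (network disconnected or degenerate)")
  }
  keep <- setdiff(seq_along(vals), rigid)
  n_modes <- min(n_modes, length(keep))
  keep <- keep[seq_len(n_modes)]
  modes <- vecs[, keep, drop = FALSE]
  for (k in seq_len(ncol(modes))) {
    nz <- which(abs(modes[, k]) > 1e-10)[1]
    if (!is.na(nz) && modes[nz, k] < 0) modes[, k] <- -modes[, k]
  }
  list(eigenvalues = vals[keep], modes = modes, n_rigid_skipped = 6L)
}

#' Fit an anisotropic network model
#'
#' The fitting entry point for ANM flexibility analysis. Nodes are the
#' Calpha atoms of the structure (one per standard residue; residues
#' lacking a Calpha are dropped with a warning), or the rows of a bare
#' coordinate matrix. The study defaults are a 10 A interaction cutoff,
#' a uniform spring constant of 1, and the 10 lowest non-rigid modes.
#'
#' @param x a [structure3d] or an N x 3 coordinate matrix.
#' @param cutoff interaction cutoff (A, default 10).
#' @param gamma spring constant (default 1).
#' @param n_modes non-rigid modes to retain (default 10).
#' @param rigid_tol relative rigid-mode tolerance (default 1e-8).
#' @return An object of class `anm`: `node_coords`, `node_meta`
#'   (data.frame with chain/residue of each node, or NULL for bare
#'   coordinates), `cutoff`, `gamma`, `eigenvalues`, `modes`
#'   (3N x K orthonormal columns), `n_rigid_skipped`.
#' @examples
#' s <- make_ideal_helix(20)
#' m <- anm(s, n_modes = 5)
#' m
#' head(fluctuations(m))
#' @export
anm <- function(x, cutoff = 10, gamma = 1, n_modes = 10L,
                rigid_tol = 1e-8) {
  node_meta <- NULL
  if (inherits(x, "structure3d")) {
    a <- x$atoms
    ca <- which(a$atom_name == "CA" & !a$het)
    res_all <- unique(paste(a$chain_id, a$residue_number,
                            a$insertion_code, sep = ":")[!a$het])
    res_ca <- paste(a$chain_id, a$residue_number,
                    a$insertion_code, sep = ":")[ca]
    missing <- setdiff(res_all, res_ca)
    if (length(missing)) {
      warning(length(missing), " residue(s) lack a CA atom and were ",
              "dropped from the network")
    }
    if (length(ca) < 2L) stop("fewer than 2 CA nodes in structure")
    node_meta <- data.frame(chain_id = a$chain_id[ca],
                            residue_number = a$residue_number[ca],
                            insertion_code = a$insertion_code[ca],
                            atom_index = ca,
                            stringsAsFactors = FALSE)
    nodes <- coords(x)[ca, , drop = FALSE]
  } else {
    nodes <- as.matrix(x)
  }
  h <- build_hessian(nodes, cutoff = cutoff, gamma = gamma)
  md <- compute_modes(h, n_modes = n_modes, rigid_tol = rigid_tol)
  obj <- list(node_coords = nodes, node_meta = node_meta,
              cutoff = cutoff, gamma = gamma,
              eigenvalues = md$eigenvalues, modes = md$modes,
              n_rigid_skipped = md$n_rigid_skipped,
              call = match.call())
  class(obj) <- "anm"
  obj
}

#' @export
print.anm <- function(x, ...) {
  cat("Anisotropic network model\n")
  cat("  nodes:", nrow(x$node_coords), " cutoff:", x$cutoff,
      "A  gamma:", x$gamma, "\n")
  cat("  retained modes:", length(x$eigenvalues),
      " rigid modes skipped:", x$n_rigid_skipped, "\n")
  cat("  eigenvalues:",
      paste(sprintf("%.4g", utils::head(x$eigenvalues, 6)),
            collapse = ", "),
      if (length(x$eigenvalues) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.anm <- function(object, ...) {
  msf <- fluctuations(object)
  out <- list(n_nodes = nrow(object$node_coords),
              cutoff = object$cutoff, gamma = object$gamma,
              n_modes = length(object$eigenvalues),
              eigenvalues = object$eigenvalues,
              msf_range = range(msf),
              msf_peak_node = which.max(msf))
  class(out) <- "summary.anm"
  out
}

#' @export
print.summary.anm <- function(x, ...) {
  cat("ANM summary:", x$n_nodes, "nodes,", x$n_modes,
      "modes (cutoff", x$cutoff, "A, gamma", x$gamma, ")\n")
  cat("  lowest eigenvalue:", sprintf("%.4g", x$eigenvalues[1]), "\n")
  cat("  MSF range:", sprintf("%.4g - %.4g", x$msf_range[1],
                              x$msf_range[2]),
      " peak at node", x$msf_peak_node, "\n")
  invisible(x)
}

#' @export
plot.anm <- function(x, ...) {
  msf <- fluctuations(x)
  graphics::plot(seq_along(msf), msf, type = "l",
                 xlab = "node (residue) index",
                 ylab = expression("MSF (" * gamma^-1 * " units)"),
                 main = "ANM mean-square fluctuations", ...)
  invisible(x)
}

#' Mean-square fluctuations of an ANM
#'
#' `MSF_i = sum_k |u_{k,i}|^2 / lambda_k` over the retained modes, where
#' `u_{k,i}` is node i's 3-vector in mode k. Units are proportional to
#' Angstrom^2 / gamma (no temperature scaling is applied).
#'
#' @param model an [anm] object.
#' @param ... unused.
#' @return Numeric vector, one value per node, all positive.
#' @export
fluctuations <- function(model, ...) UseMethod("fluctuations")

#' @rdname fluctuations
#' @export
fluctuations.anm <- function(model, ...) {
  n <- nrow(model$node_coords)
  msf <- numeric(n)
  for (k in seq_along(model$eigenvalues)) {
    u <- matrix(model$modes[, k], ncol = 3, byrow = TRUE)
    msf <- msf + rowSums(u^2) / model$eigenvalues[k]
  }
  msf
}

#' Node-node cross-correlations of an ANM
#'
#' Normalized covariance of node displacements over the retained modes:
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` with
#' `<dr_i . dr_j> = sum_k (u_{k,i} . u_{k,j}) / lambda_k`. The diagonal
#' is exactly 1; entries lie in `[-1, 1]`.
#'
#' @param model an [anm] object.
#' @return N x N symmetric matrix.
#' @export
cross_correlations <- function(model) {
  stopifnot(inherits(model, "anm"))
  n <- nrow(model$node_coords)
  cov <- matrix(0, n, n)
  for (k in seq_along(model$eigenvalues)) {
    u <- matrix(model$modes[, k], ncol = 3, byrow = TRUE)
    cov <- cov + tcrossprod(u) / model$eigenvalues[k]
  }
  d <- sqrt(diag(cov))
  cc <- cov / tcrossprod(d)
  diag(cc) <- 1
  cc
}

#' Extend Calpha modes to all atoms
#'
#' Every atom of a residue is assigned its residue's Calpha mode vector
#' (the coarse-grained displacement is propagated rigidly within the
#' residue), then each extended column is re-normalized to unit length.
#'
#' @param model an [anm] fitted from a [structure3d] (node metadata is
#'   required to map residues to nodes).
#' @param full_structure the all-atom [structure3d]; every non-HETATM
#'   residue must have a mapped node.
#' @return `3M x K` matrix of unit-norm all-atom modes (M = atom count),
#'   with the eigenvalues carried over as attribute `eigenvalues`.
#' @export
extend_modes <- function(model, full_structure) {
  stopifnot(inherits(model, "anm"), inherits(full_structure, "structure3d"))
  if (is.null(model$node_meta)) {
    stop("model has no node metadata; fit it from a structure3d")
  }
  a <- full_structure$atoms
  akey <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = ":")
  nkey <- paste(model$node_meta$chain_id, model$node_meta$residue_number,
                model$node_meta$insertion_code, sep = ":")
  node_of <- match(akey, nkey)
  unmapped <- unique(akey[is.na(node_of) & !a$het])
  if (length(unmapped)) {
    stop("residue(s) without a network node: ",
         paste(utils::head(unmapped, 8), collapse = ", "),
         if (length(unmapped) > 8) " ..." else "")
  }
  keep <- !is.na(node_of)
  m <- sum(keep)
  k <- length(model$eigenvalues)
  ext <- matrix(0, 3 * m, k)
  rows3 <- function(i) c(3 * i - 2, 3 * i - 1, 3 * i)
  nidx <- node_of[keep]
  for (j in seq_len(k)) {
    u <- matrix(model$modes[, j], ncol = 3, byrow = TRUE)
    ext[, j] <- as.vector(t(u[nidx, , drop = FALSE]))
    ext[, j] <- ext[, j] / sqrt(sum(ext[, j]^2))
  }
  attr(ext, "eigenvalues") <- model$eigenvalues
  attr(ext, "atom_indices") <- which(keep)
  ext
}

#' Write modes in NMD plain-text format
#'
#' Emits a normal-mode (NMD) file readable by standard normal-mode
#' viewers: names, residue/chain identifiers, node coordinates, then one
#' `mode` line per retained mode carrying its index, eigenvalue and 3N
#' vector.
#'
#' @param model an [anm] object.
#' @param path output file path.
#' @param name dataset name recorded in the file.
#' @return `path`, invisibly.
#' @export
write_nmd <- function(model, path, name = "strucdyn_anm") {
  stopifnot(inherits(model, "anm"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(model$node_coords)
  writeLines(paste("name", name), con)
  writeLines(paste("atomnames", paste(rep("CA", n), collapse = " ")), con)
  if (!is.null(model$node_meta)) {
    writeLines(paste("resids",
                     paste(model$node_meta$residue_number, collapse = " ")),
               con)
    writeLines(paste("chainids",
                     paste(model$node_meta$chain_id, collapse = " ")), con)
  }
  writeLines(paste("coordinates",
                   paste(sprintf("%.3f", t(model$node_coords)),
                         collapse = " ")), con)
  for (k in seq_along(model$eigenvalues)) {
    writeLines(paste("mode", k, sprintf("%.8g", model$eigenvalues[k]),
                     paste(sprintf("%.8g", model$modes[, k]),
                           collapse = " ")), con)
  }
  invisible(path)
}
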