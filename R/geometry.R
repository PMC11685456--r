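#' Principal axis of a coordinate set
#'
#' First principal direction of the centered coordinates, as a unit
#' vector, with its sign oriented from the first to the last point
#' (N-terminus to C-terminus for a chain trace). Used as the helix-axis
#' estimator for rotation and stalk-bend measurements.
#'
#' @param x N x 3 matrix, N >= 3, not all coincident and not isotropic.
#' @return Unit length-3 vector.
#' @export
principal_axis <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("at least 3 points are required")
  xc <- sweep(x, 2, colMeans(x))
  s <- svd(xc, nu = 0)
  d2 <- s$d^2
  if (d2[1] < 1e-12) stop("degenerate point set: all points coincident")
  if ((d2[1] - d2[2]) / d2[1] < 1e-8) {
    stop("degenerate point set: no unique principal direction (isotropic)")
  }
  v <- s$v[, 1]
  span <- x[nrow(x), ] - x[1, ]
  if (sum(v * span) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# angle between two vectors, degrees in [0, 180]
.vec_angle <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length vector")
  ct <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, ct))) * 180 / pi
}

# resolve paired selections into matched coordinate matrices
.paired_coords <- function(struct_a, struct_b, pair, what = "selection") {
  if (inherits(pair, "atom_selection") ||
      inherits(pair, "domain_definition") || is.numeric(pair)) {
    pair <- list(pair, pair)
  }
  ia <- .sel_idx(pair[[1]], struct_a)
  ib <- .sel_idx(pair[[2]], struct_b)
  if (length(ia) != length(ib)) {
    stop(what, " pairing mismatch: ", length(ia), " vs ", length(ib),
         " atoms")
  }
  list(a = coords(struct_a)[ia, , drop = FALSE],
       b = coords(struct_b)[ib, , drop = FALSE])
}

#' Rotation of a subdomain between two structures
#'
#' Both structures are first superposed on the `align` selections (e.g.
#' the NBD IA+IB lobes); the rotation of the `probe` region (e.g. the
#' inward-facing IIB-lobe alpha-helix) is then measured either as the
#' angle between the probe helices' principal axes (`"helix-axis"`) or as
#' the rotation magnitude of the rigid fit between the probe selections
#' (`"axis-angle"`).
#'
#' @param struct_a,struct_b [structure3d] objects (a is the reference
#'   frame of the comparison).
#' @param align a single selection applied to both structures, or a list
#'   of two paired selections (equal atom counts).
#' @param probe probe selection(s), same conventions as `align`.
#' @param method `"axis-angle"` (default) or `"helix-axis"`.
#' @return Rotation in degrees, in `[0, 180]`.
#' @export
subdomain_rotation <- function(struct_a, struct_b, align, probe,
                               method = c("axis-angle", "helix-axis")) {
  method <- match.arg(method)
  al <- .paired_coords(struct_a, struct_b, align, "align")
  pr <- .paired_coords(struct_a, struct_b, probe, "probe")
  fit <- kabsch_fit(al$b, al$a)
  probe_b <- apply_transform(fit, pr$b)
  if (method == "helix-axis") {
    .vec_angle(principal_axis(pr$a), principal_axis(probe_b))
  } else {
    rotation_angle(kabsch_fit(pr$a, probe_b)$rotation)
  }
}

#' Bend angle of a helical stalk
#'
#' Splits the stalk at a residue boundary and measures the angle between
#' the principal axes of the proximal (residues `<= split`) and distal
#' (`> split`) segments. With `reference = "self"` the angle is measured
#' within `struct` directly (a straight helix gives ~0). With an
#' external straight reference structure, the proximal segments are
#' first superposed and the angle between the distal-segment axes is
#' returned, reproducing the comparison of a bent stalk against a
#' straight predicted dimer.
#'
#' @param struct a [structure3d] containing the stalk.
#' @param stalk a [domain_definition] covering the stalk (Calpha-bearing
#'   residues; the axis is computed from CA atoms).
#' @param split residue number ending the proximal segment; each side of
#'   the split needs at least 6 residues.
#' @param reference `"self"` or a [structure3d] holding the same stalk
#'   residues in a straight conformation.
#' @return Bend angle in degrees, in `[0, 180]`.
#' @export
stalk_bend_angle <- function(struct, stalk, split, reference = "self") {
  stopifnot(inherits(struct, "structure3d"),
            inherits(stalk, "domain_definition"))
  ca_def <- stalk
  ca_def$atom_names <- "CA"
  seg <- function(s) {
    idx <- select_atoms(s, ca_def)$indices
    resn <- s$atoms$residue_number[idx]
    list(prox = coords(s)[idx[resn <= split], , drop = FALSE],
         dist = coords(s)[idx[resn > split], , drop = FALSE])
  }
  x <- seg(struct)
  if (nrow(x$prox) < 6L || nrow(x$dist) < 6L) {
    stop("stalk split leaves fewer than 6 residues on one side (",
         nrow(x$prox), " proximal / ", nrow(x$dist), " distal)")
  }
  if (identical(reference, "self")) {
    return(.vec_angle(principal_axis(x$prox), principal_axis(x$dist)))
  }
  stopifnot(inherits(reference, "structure3d"))
  r <- seg(reference)
  if (nrow(r$prox) != nrow(x$prox) || nrow(r$dist) != nrow(x$dist)) {
    stop("reference stalk segments do not pair with the structure's")
  }
  fit <- kabsch_fit(x$prox, r$prox)
  dist_aligned <- apply_transform(fit, x$dist)
  .vec_angle(principal_axis(r$dist), principal_axis(dist_aligned))
}

#' Displacement of a subdomain centroid between two structures
#'
#' After superposing `struct_b` onto `struct_a` using the `align`
#' selections, returns the Euclidean distance between the centroids of
#' the `probe` selections (e.g. the SBD shift between wild-type and
#' mutant complexes).
#'
#' @inheritParams subdomain_rotation
#' @return Distance in Angstrom.
#' @export
centroid_displacement <- function(struct_a, struct_b, align, probe) {
  al <- .paired_coords(struct_a, struct_b, align, "align")
  pr <- .paired_coords(struct_a, struct_b, probe, "probe")
  fit <- kabsch_fit(al$b, al$a)
  cb <- colMeans(apply_transform(fit, pr$b))
  ca <- colMeans(pr$a)
  sqrt(sum((ca - cb)^2))
}
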