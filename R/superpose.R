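#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD
#' between the transformed mobile set (`x %*% t(R) + t`, rows as points)
#' and the reference set, by SVD of the covariance matrix with the
#' reflection branch corrected so `det(R) = +1`.
#'
#' @param mobile,reference numeric N x 3 matrices of paired points, N >= 3.
#' @return A list of class `rigid_transform`: `rotation` (3 x 3, proper
#'   orthonormal), `translation` (length-3), and `rmsd` (Angstrom, after
#'   superposition).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30), 10, 3)
#' f <- kabsch_fit(x, x)   # identity, rmsd 0
#' f$rmsd
#' @export
kabsch_fit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L) {
    stop("coordinate sets must be N x 3")
  }
  if (nrow(mobile) != nrow(reference)) {
    stop("point count mismatch: ", nrow(mobile), " vs ", nrow(reference))
  }
  n <- nrow(mobile)
  if (n < 3L) stop("at least 3 points are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  xm <- sweep(mobile, 2, cm); xr <- sweep(reference, 2, cr)
  # degeneracy: all points collinear in either set
  if (.rank3(xm) < 2L || .rank3(xr) < 2L) {
    stop("degenerate configuration: points are collinear")
  }
  h <- crossprod(xm, xr)          # 3 x 3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- xm %*% t(r)
  rms <- sqrt(sum((fitted - xr)^2) / n)
  tr <- as.numeric(cr - r %*% cm)
  out <- list(rotation = r, translation = tr, rmsd = rms)
  class(out) <- "rigid_transform"
  out
}

.rank3 <- function(x) {
  d <- svd(x, nu = 0, nv = 0)$d
  sum(d > max(d) * 1e-8)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle",
      sprintf("%.3f", rotation_angle(x$rotation)), "deg, translation (",
      paste(sprintf("%.3f", x$translation), collapse = ", "),
      "), rmsd", sprintf("%.4f", x$rmsd), "A\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform` from [kabsch_fit()].
#' @param x N x 3 coordinate matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  sweep(as.matrix(x) %*% t(transform$rotation), 2,
        -transform$translation)
}

#' Rotation magnitude of a rotation matrix
#'
#' @param r a 3 x 3 proper rotation matrix.
#' @return Rotation angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(r) {
  ct <- (sum(diag(r)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Root-mean-square deviation without superposition
#'
#' @param a,b numeric N x 3 matrices of paired coordinates.
#' @return RMSD in Angstrom.
#' @examples
#' rmsd(rbind(c(0,0,0), c(1,0,0)), rbind(c(0,0,0), c(1,1,0)))  # sqrt(1/2)
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) {
    stop("coordinate sets differ in size: ", nrow(a), " vs ", nrow(b))
  }
  sqrt(sum((a - b)^2) / nrow(a))
}

#' Per-domain RMSD series over a trajectory
#'
#' For each frame, the domain selection is first superposed onto the same
#' selection in the reference frame (removing collective rigid-body
#' motion so that internal flexibility is measured), then the RMSD over
#' the selection is reported.
#'
#' @param traj a [trajectory].
#' @param domain an `atom_selection` (or [domain_definition], resolved
#'   against the topology) defining both the alignment and the measured
#'   atoms.
#' @param reference_frame index of the reference frame (default 1, the
#'   initial structure).
#' @return data.frame with columns `frame`, `time`, `rmsd`; attributes
#'   `mean` and `sd` carry the series summary.
#' @export
domain_rmsd_series <- function(traj, domain, reference_frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- .sel_idx(domain, traj$topology)
  if (reference_frame < 1L || reference_frame > nframes(traj)) {
    stop("reference frame ", reference_frame, " out of range [1, ",
         nframes(traj), "]")
  }
  ref <- frame_coords(traj, reference_frame)[idx, , drop = FALSE]
  vals <- vapply(seq_len(nframes(traj)), function(f) {
    kabsch_fit(frame_coords(traj, f)[idx, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  out <- data.frame(frame = seq_len(nframes(traj)),
                    time = frame_times(traj), rmsd = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- stats::sd(vals)
  attr(out, "label") <- if (inherits(domain, "atom_selection"))
    domain$label else if (inherits(domain, "domain_definition"))
      domain$label else "selection"
  out
}

#' Per-atom deviation series over a trajectory
#'
#' Each frame is superposed onto the reference frame using the
#' `alignment` selection; for every atom in `atoms` the Euclidean
#' deviation from its reference-frame position is then reported per
#' frame. This is the anchor-atom deviation analysis (e.g. the Calpha
#' atoms defining the lateral/medial motion vectors).
#'
#' @param traj a [trajectory].
#' @param atoms selection of atoms to monitor.
#' @param alignment selection used for superposition; defaults to all
#'   backbone (N, CA, C, O) atoms of the topology.
#' @param reference_frame reference frame index (default 1).
#' @return data.frame with `frame`, `time`, then one column per monitored
#'   atom (named `chain.residue.atom`).
#' @export
per_atom_deviation_series <- function(traj, atoms, alignment = NULL,
                                      reference_frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  aidx <- .sel_idx(atoms, top)
  if (is.null(alignment)) {
    gidx <- which(top$atoms$atom_name %in% c("N", "CA", "C", "O") &
                    !top$atoms$het)
    if (length(gidx) < 3L) gidx <- seq_len(natoms(top))
  } else {
    gidx <- .sel_idx(alignment, top)
  }
  if (reference_frame < 1L || reference_frame > nframes(traj)) {
    stop("reference frame ", reference_frame, " out of range")
  }
  refall <- frame_coords(traj, reference_frame)
  refa <- refall[gidx, , drop = FALSE]
  refm <- refall[aidx, , drop = FALSE]
  dev <- matrix(NA_real_, nframes(traj), length(aidx))
  for (f in seq_len(nframes(traj))) {
    x <- frame_coords(traj, f)
    fit <- kabsch_fit(x[gidx, , drop = FALSE], refa)
    moved <- apply_transform(fit, x[aidx, , drop = FALSE])
    dev[f, ] <- sqrt(rowSums((moved - refm)^2))
  }
  a <- top$atoms[aidx, ]
  colnames(dev) <- paste(a$chain_id, a$residue_number, a$atom_name,
                         sep = ".")
  cbind(data.frame(frame = seq_len(nframes(traj)),
                   time = frame_times(traj)),
        as.data.frame(dev))
}
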