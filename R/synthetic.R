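# Seeded synthetic-structure and trajectory generators.
#
# These generators define the ground truth against which every analysis
# stage is validated: helices with a known axis, stalks with a known
# bend, domain pairs differing by a known rotation, two-chain complexes
# with a controllable interface, and trajectories whose anchor-defined
# angle follows a prescribed mixture of angular substates.

# dummy backbone offsets from CA (A); adequate for selections and SASA
# fixtures, not stereochemically exact
.BB_OFFSETS <- list(N = c(-0.80, 0.50, -0.90),
                    C = c(0.90, -0.40, 0.70),
                    O = c(1.40, 0.30, 1.10))

#' Ideal alpha-helix
#'
#' A canonical alpha-helical Calpha spiral about the z axis (rise 1.5 A
#' and twist 100 degrees per residue, radius 2.3 A), with dummy backbone
#' N, C, O atoms at fixed offsets from each Calpha. Fully deterministic.
#'
#' @param n_res number of residues (>= 4).
#' @param rise rise per residue (A).
#' @param twist twist per residue (degrees).
#' @param radius helix radius (A).
#' @param chain chain id.
#' @param first_residue residue number of the first residue.
#' @param phase starting phase angle (degrees).
#' @return A [structure3d] with atoms N, CA, C, O per residue.
#' @export
make_ideal_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                             chain = "A", first_residue = 1L, phase = 0) {
  if (n_res < 4L) stop("n_res must be >= 4")
  i <- seq_len(n_res) - 1L
  th <- (phase + twist * i) * pi / 180
  ca <- cbind(radius * cos(th), radius * sin(th), rise * i)
  nm <- c("N", "CA", "C", "O")
  n_at <- 4L * n_res
  xyz <- matrix(NA_real_, n_at, 3)
  for (r in seq_len(n_res)) {
    base <- 4L * (r - 1L)
    xyz[base + 1L, ] <- ca[r, ] + .BB_OFFSETS$N
    xyz[base + 2L, ] <- ca[r, ]
    xyz[base + 3L, ] <- ca[r, ] + .BB_OFFSETS$C
    xyz[base + 4L, ] <- ca[r, ] + .BB_OFFSETS$O
  }
  atoms <- .atom_table(
    atom_name = rep(nm, n_res),
    residue_name = "ALA",
    residue_number = rep(first_residue - 1L + seq_len(n_res), each = 4L),
    chain_id = chain,
    element = rep(c("N", "C", "C", "O"), n_res)
  )
  structure3d(atoms, xyz)
}

# rotation matrix about a unit axis (Rodrigues), angle in degrees
.rot_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  k <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}

#' Helical stalk with a known kink
#'
#' Builds a straight ideal helix and rotates the distal part (residues
#' after `split`) by `bend` degrees about an axis perpendicular to the
#' helix axis through the junction Calpha, producing a stalk whose true
#' bend angle is known by construction.
#'
#' @param n_res total residues.
#' @param bend bend angle in degrees.
#' @param split residue index ending the proximal segment
#'   (3 < split < n_res - 3).
#' @param chain chain id.
#' @return A [structure3d].
#' @export
make_bent_stalk <- function(n_res, bend, split, chain = "A") {
  if (!(split > 3L && split < n_res - 3L)) {
    stop("split must satisfy 3 < split < n_res - 3")
  }
  s <- make_ideal_helix(n_res, chain = chain)
  a <- s$atoms
  pivot_idx <- which(a$residue_number == split & a$atom_name == "CA")
  pivot <- coords(s)[pivot_idx, ]
  r <- .rot_about_axis(c(1, 0, 0), bend)
  distal <- which(a$residue_number > split)
  xyz <- coords(s)
  xyz[distal, ] <- sweep(sweep(xyz[distal, , drop = FALSE], 2, pivot) %*%
                           t(r), 2, pivot, "+")
  structure3d(a, xyz)
}

#' Pair of structures differing by a known subdomain rotation
#'
#' Copies `base` and rotates the atoms of `probe` by `angle` degrees
#' about a seeded random axis through the probe's centroid, leaving all
#' other atoms untouched. Ground truth for rotation-recovery tests.
#'
#' @param base a [structure3d].
#' @param probe a [domain_definition] or `atom_selection` naming the
#'   rotated region.
#' @param angle rotation in degrees, in `[0, 180]`.
#' @param seed integer seed (axis direction is drawn from the stream
#'   derived from it).
#' @return List with elements `a` (the base) and `b` (the rotated copy);
#'   the axis used is attached as attribute `axis` of `b`.
#' @export
make_rotated_pair <- function(base, probe, angle, seed = 1L) {
  stopifnot(inherits(base, "structure3d"), angle >= 0, angle <= 180)
  idx <- .sel_idx(probe, base)
  if (!length(idx)) stop("empty probe selection")
  axis <- with_stream(seed, "make_rotated_pair", {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  })
  xyz <- coords(base)
  ctr <- colMeans(xyz[idx, , drop = FALSE])
  r <- .rot_about_axis(axis, angle)
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, ctr) %*% t(r),
                      2, ctr, "+")
  b <- structure3d(base$atoms, xyz)
  attr(b, "axis") <- axis
  list(a = base, b = b)
}

#' Two-chain complex with a controllable interface
#'
#' Two compact helical bodies on chains A and B whose centroids are
#' separated by exactly `separation` Angstrom along x; chain B's
#' orientation is drawn from the seeded stream. Decreasing the
#' separation brings the partners into contact, so buried surface area
#' grows monotonically as they approach.
#'
#' @param size_a,size_b residues per chain (>= 5).
#' @param separation centroid-centroid distance (A).
#' @param seed integer seed.
#' @return A [structure3d] with chains `A` and `B`.
#' @export
make_two_domain_complex <- function(size_a, size_b, separation,
                                    seed = 1L) {
  stopifnot(size_a >= 5L, size_b >= 5L, separation >= 0)
  ha <- make_ideal_helix(size_a, chain = "A")
  hb <- make_ideal_helix(size_b, chain = "B")
  center <- function(x) sweep(x, 2, colMeans(x))
  xa <- center(coords(ha))
  rb <- with_stream(seed, "make_two_domain_complex", {
    axis <- stats::rnorm(3)
    .rot_about_axis(axis / sqrt(sum(axis^2)), stats::runif(1, 0, 360))
  })
  xb <- sweep(center(coords(hb)) %*% t(rb), 2, c(separation, 0, 0), "+")
  atoms <- rbind(ha$atoms, hb$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  structure3d(atoms, rbind(xa, xb))
}

#' Angular substate generator specification
#'
#' Describes a mixture of angular substates: per-region Gaussian centers
#' and widths, occupancies (a probability vector, or a row-stochastic
#' transition matrix for Markov-chain region sequences), isotropic
#' positional noise, frame count and seed.
#'
#' @param centers region centers (degrees).
#' @param widths region standard deviations (degrees, > 0).
#' @param occupancies probability vector summing to 1, or an
#'   `n x n` row-stochastic transition matrix.
#' @param noise_sigma isotropic Gaussian positional noise sd (A,
#'   default 0.3).
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @return A `substate_gen_spec`.
#' @export
substate_gen_spec <- function(centers, widths, occupancies,
                              noise_sigma = 0.3, n_frames = 5000L,
                              seed = 1L) {
  k <- length(centers)
  stopifnot(length(widths) == k, all(widths > 0), n_frames >= 1)
  if (is.matrix(occupancies)) {
    if (nrow(occupancies) != k || ncol(occupancies) != k) {
      stop("transition matrix must be ", k, " x ", k)
    }
    if (any(occupancies < 0) ||
        any(abs(rowSums(occupancies) - 1) > 1e-9)) {
      stop("transition matrix rows must be probabilities summing to 1")
    }
  } else {
    if (length(occupancies) != k) stop("need one occupancy per region")
    if (any(occupancies < 0) || abs(sum(occupancies) - 1) > 1e-9) {
      stop("occupancies must be >= 0 and sum to 1")
    }
  }
  obj <- list(centers = as.numeric(centers), widths = as.numeric(widths),
              occupancies = occupancies,
              noise_sigma = as.numeric(noise_sigma),
              n_frames = as.integer(n_frames), seed = as.integer(seed))
  class(obj) <- "substate_gen_spec"
  obj
}

# stationary distribution of a row-stochastic matrix (power iteration)
.stationary <- function(p) {
  v <- rep(1 / nrow(p), nrow(p))
  for (i in 1:200) v <- as.numeric(v %*% p)
  v / sum(v)
}

#' Synthetic trajectory with prescribed angular substates
#'
#' For each frame a region is drawn (independently with the prescribed
#' occupancies, or by a Markov chain if a transition matrix was given), a
#' target angle is sampled from that region's Gaussian, and the second
#' vector's tip atom is repositioned so the anchor-defined angle equals
#' the target exactly; isotropic Gaussian noise is then added to all
#' atoms. Reproducible: the same spec (including seed) yields bitwise
#' identical coordinates.
#'
#' @param topology a [structure3d] containing all anchor atoms.
#' @param anchors list of two [vector_definition]s `(a, b)`; the angle is
#'   realized by moving `b`'s tip atom.
#' @param spec a [substate_gen_spec()].
#' @param frame_interval frame time spacing (default 2).
#' @return A [trajectory]; attributes `regions` (drawn region index per
#'   frame) and `target_angles` (drawn target angle per frame) carry the
#'   ground truth.
#' @export
make_angle_trajectory <- function(topology, anchors, spec,
                                  frame_interval = 2) {
  stopifnot(inherits(topology, "structure3d"),
            inherits(spec, "substate_gen_spec"), length(anchors) == 2L)
  a <- anchors[[1]]; b <- anchors[[2]]
  stopifnot(inherits(a, "vector_definition"),
            inherits(b, "vector_definition"))
  i_fa <- .anchor_index(topology, a$from)
  i_ta <- .anchor_index(topology, a$to)
  i_fb <- .anchor_index(topology, b$from)
  i_tb <- .anchor_index(topology, b$to)
  base <- coords(topology)
  v1 <- base[i_ta, ] - base[i_fa, ]
  if (sqrt(sum(v1^2)) < 1e-9) stop("coincident anchors for vector a")
  v1h <- v1 / sqrt(sum(v1^2))
  # fixed in-plane perpendicular: deterministic function of v1 only
  ref <- if (abs(v1h[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * v1h) * v1h
  uh <- u / sqrt(sum(u^2))
  len_b <- sqrt(sum((base[i_tb, ] - base[i_fb, ])^2))
  if (len_b < 1e-9) stop("coincident anchors for vector b")

  k <- length(spec$centers)
  n <- spec$n_frames
  sim <- with_stream(spec$seed, "make_angle_trajectory", {
    if (is.matrix(spec$occupancies)) {
      regions <- integer(n)
      regions[1] <- sample.int(k, 1, prob = .stationary(spec$occupancies))
      if (n > 1) for (f in 2:n) {
        regions[f] <- sample.int(k, 1,
                                 prob = spec$occupancies[regions[f - 1], ])
      }
    } else {
      regions <- sample.int(k, n, replace = TRUE, prob = spec$occupancies)
    }
    targets <- stats::rnorm(n, spec$centers[regions], spec$widths[regions])
    targets <- pmin(179.9, pmax(0.1, targets))
    noise <- if (spec$noise_sigma > 0) {
      array(stats::rnorm(n * nrow(base) * 3, sd = spec$noise_sigma),
            dim = c(n, nrow(base), 3))
    } else {
      NULL
    }
    list(regions = regions, targets = targets, noise = noise)
  })
  arr <- array(rep(base, each = n), dim = c(n, nrow(base), 3))
  th <- sim$targets * pi / 180
  tips <- matrix(base[i_fb, ], n, 3, byrow = TRUE) +
    len_b * (cos(th) %o% v1h + sin(th) %o% uh)
  arr[, i_tb, ] <- tips
  if (!is.null(sim$noise)) arr <- arr + sim$noise
  tr <- trajectory(topology, arr, frame_interval = frame_interval)
  attr(tr, "regions") <- sim$regions
  attr(tr, "target_angles") <- sim$targets
  tr
}
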