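#' SASA parameters
#'
#' Parameters for the Shrake-Rupley solvent-accessible surface area
#' calculation: probe radius (water, 1.4 A), number of quasi-uniform
#' sphere points per atom, and a van der Waals radii table (Bondi-style)
#' with a fallback radius for unknown elements.
#'
#' @param probe_radius probe radius in Angstrom (> 0; default 1.4).
#' @param points_per_atom sphere points per atom (>= 100; default 960).
#' @param radii named numeric vector, element symbol -> vdW radius (A).
#' @param default_radius fallback radius for elements missing from
#'   `radii`; used with a warning. Set `NA` to make unknown elements an
#'   error.
#' @return A list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, points_per_atom = 960L,
                        radii = NULL, default_radius = 1.7) {
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (points_per_atom < 100L) stop("points_per_atom must be >= 100")
  if (is.null(radii)) {
    radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
               SE = 1.90, ZN = 1.39, MG = 1.73, FE = 1.40, CA = 2.31,
               "NA" = 2.27, K = 2.75, MN = 1.39)
  }
  obj <- list(probe_radius = probe_radius,
              points_per_atom = as.integer(points_per_atom),
              radii = radii, default_radius = default_radius)
  class(obj) <- "sasa_params"
  obj
}

# Deterministic golden-spiral lattice of n quasi-uniform unit-sphere
# points; reproducible bit-for-bit for a given n.
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.atom_radii <- function(elements, params) {
  el <- toupper(trimws(elements))
  r <- unname(params$radii[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    if (is.na(params$default_radius)) {
      stop("no vdW radius for element(s): ",
           paste(unique(el[unknown]), collapse = ", "))
    }
    warning("unknown element(s) ", paste(unique(el[unknown]),
                                         collapse = ", "),
            "; using default radius ", params$default_radius, " A")
    r[unknown] <- params$default_radius
  }
  r
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each atom, a deterministic golden-spiral lattice of test points is
#' placed on the sphere of radius `r_vdw + probe`; the accessible area is
#' the fraction of points not inside any neighbouring atom's expanded
#' sphere, times `4 * pi * (r_vdw + probe)^2`.
#'
#' @param structure a [structure3d], or an N x 3 coordinate matrix when
#'   `elements` is supplied.
#' @param params a [sasa_params] object.
#' @param subset optional atom indices / `atom_selection`: only these
#'   atoms are present in the calculation (others are removed, not just
#'   unmeasured).
#' @param elements element symbols when `structure` is a bare matrix.
#' @return Numeric vector of per-atom areas (A^2) for the atoms in the
#'   calculation, with the total as attribute `total`.
#' @examples
#' # isolated carbon: 4*pi*(1.7+1.4)^2 = 120.76 A^2
#' p <- sasa_params()
#' sum(sasa(matrix(0, 1, 3), p, elements = "C"))
#' @export
sasa <- function(structure, params = sasa_params(), subset = NULL,
                 elements = NULL) {
  stopifnot(inherits(params, "sasa_params"))
  if (inherits(structure, "structure3d")) {
    xyz <- coords(structure)
    el <- structure$atoms$element
  } else {
    xyz <- as.matrix(structure)
    if (is.null(elements)) stop("elements must be given for bare coordinates")
    el <- rep_len(elements, nrow(xyz))
  }
  if (!is.null(subset)) {
    idx <- .sel_idx(subset, if (inherits(structure, "structure3d"))
      structure else NULL)
    xyz <- xyz[idx, , drop = FALSE]
    el <- el[idx]
  }
  n <- nrow(xyz)
  rad <- .atom_radii(el, params)
  rexp <- rad + params$probe_radius
  pts <- golden_spiral_points(params$points_per_atom)
  area <- numeric(n)
  maxr <- max(rexp)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rexp[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rexp[i] + rexp[nb])^2]
    p <- sweep(pts * rexp[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj2 >= rexp[j]^2
    }
    area[i] <- mean(acc) * 4 * pi * rexp[i]^2
  }
  attr(area, "total") <- sum(area)
  area
}

#' Buried surface area between two selections
#'
#' Computes `SASA(A alone) + SASA(B alone) - SASA(A and B together)`.
#' With `convention = "total"` that quantity is returned; with
#' `"per-interface"` (the common interface-server convention, the
#' default) it is halved. Both values are carried in the result's
#' attributes because published areas do not always state their
#' convention.
#'
#' @param structure a [structure3d].
#' @param sel_a,sel_b disjoint `atom_selection`s (or index vectors).
#' @param params a [sasa_params].
#' @param convention `"per-interface"` or `"total"`.
#' @return Buried area in A^2 under the requested convention, with
#'   attributes `total`, `per_interface`, and `convention`.
#' @export
buried_surface_area <- function(structure, sel_a, sel_b,
                                params = sasa_params(),
                                convention = c("per-interface", "total")) {
  convention <- match.arg(convention)
  stopifnot(inherits(structure, "structure3d"))
  ia <- .sel_idx(sel_a, structure)
  ib <- .sel_idx(sel_b, structure)
  if (length(intersect(ia, ib))) {
    stop("selections overlap (", length(intersect(ia, ib)),
         " shared atoms); buried area requires disjoint partners")
  }
  sa <- attr(sasa(structure, params, subset = ia), "total")
  sb <- attr(sasa(structure, params, subset = ib), "total")
  sab <- attr(sasa(structure, params, subset = sort(c(ia, ib))), "total")
  total <- max(0, sa + sb - sab)
  out <- if (convention == "total") total else total / 2
  attr(out, "total") <- total
  attr(out, "per_interface") <- total / 2
  attr(out, "convention") <- convention
  out
}
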