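#' Define an anchor vector
#'
#' A vector between two anchor atoms, identified by chain, author residue
#' number and atom name — e.g. the lateral/medial SBD-lid motion vectors:
#' v1 from the Calpha of mortalin residue 569 to that of residue 597, v2
#' from residue 569 to GrpEL1-B residue 200, v3 from residue 569 to
#' GrpEL1-B residue 98.
#'
#' @param label vector label (e.g. `"v1"`).
#' @param from,to length-3 specifications `c(chain, residue_number,
#'   atom_name)` or lists with those elements.
#' @return An object of class `vector_definition`.
#' @examples
#' vector_definition("v1", c("A", 569, "CA"), c("A", 597, "CA"))
#' @export
vector_definition <- function(label, from, to) {
  norm <- function(x) {
    if (length(x) != 3L) stop("anchor must be c(chain, residue, atom_name)")
    list(chain = as.character(x[[1]]),
         residue_number = as.integer(x[[2]]),
         atom_name = as.character(x[[3]]))
  }
  from <- norm(from); to <- norm(to)
  if (identical(from, to)) stop("anchor atoms must be distinct")
  obj <- list(label = as.character(label), from = from, to = to)
  class(obj) <- "vector_definition"
  obj
}

#' @export
print.vector_definition <- function(x, ...) {
  f <- x$from; t <- x$to
  cat("vector '", x$label, "': ", f$chain, ":", f$residue_number, ":",
      f$atom_name, " -> ", t$chain, ":", t$residue_number, ":",
      t$atom_name, "\n", sep = "")
  invisible(x)
}

# Parse "chain:resnum:atom" into an anchor triple.
parse_anchor <- function(s) {
  tok <- strsplit(s, ":", fixed = TRUE)[[1]]
  if (length(tok) != 3L) stop("anchor must be 'chain:resnum:atom': ", s)
  c(tok[1], tok[2], tok[3])
}

.anchor_index <- function(topology, anchor) {
  a <- topology$atoms
  i <- which(a$chain_id == anchor$chain &
               a$residue_number == anchor$residue_number &
               a$atom_name == anchor$atom_name)
  if (!length(i)) {
    stop("anchor atom not found in topology: ", anchor$chain, ":",
         anchor$residue_number, ":", anchor$atom_name)
  }
  i[1]
}

#' Per-frame angle between two anchor vectors
#'
#' For each frame the two vectors are rebuilt from their anchor atoms'
#' coordinates and the angle `theta = acos(v . w / (|v||w|))` is taken,
#' with the cosine clamped to `[-1, 1]`. Vectors are undirected, so
#' angles lie in `[0, 180]` degrees.
#'
#' @param traj a [trajectory].
#' @param a,b [vector_definition] objects resolvable in the topology.
#' @return An `angle_series`: data.frame with `frame`, `time`, `angle`
#'   (degrees); attribute `pair` holds the two labels.
#' @export
angle_series <- function(traj, a, b) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(a, "vector_definition"),
            inherits(b, "vector_definition"))
  top <- traj$topology
  i <- c(.anchor_index(top, a$from), .anchor_index(top, a$to),
         .anchor_index(top, b$from), .anchor_index(top, b$to))
  n <- nframes(traj)
  v <- traj$coords[, i[2], , drop = FALSE] - traj$coords[, i[1], , drop = FALSE]
  w <- traj$coords[, i[4], , drop = FALSE] - traj$coords[, i[3], , drop = FALSE]
  dim(v) <- c(n, 3); dim(w) <- c(n, 3)
  nv <- sqrt(rowSums(v^2)); nw <- sqrt(rowSums(w^2))
  bad <- which(nv < 1e-12 | nw < 1e-12)
  if (length(bad)) {
    stop("zero-length anchor vector at frame ", bad[1])
  }
  ct <- pmin(1, pmax(-1, rowSums(v * w) / (nv * nw)))
  out <- data.frame(frame = seq_len(n), time = frame_times(traj),
                    angle = acos(ct) * 180 / pi)
  attr(out, "pair") <- c(a$label, b$label)
  class(out) <- c("angle_series", "data.frame")
  out
}

#' Substate specification from bin edges
#'
#' @param edges strictly increasing numeric bin edges (degrees), at
#'   least two.
#' @param labels optional region labels (default `region1`, ...).
#' @return A `substate_spec` (list with `edges`, `labels`).
#' @export
substate_spec <- function(edges, labels = NULL) {
  edges <- as.numeric(edges)
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be >= 2 strictly increasing values")
  }
  nr <- length(edges) - 1L
  if (is.null(labels)) labels <- paste0("region", seq_len(nr))
  if (length(labels) != nr) stop("need one label per region")
  obj <- list(edges = edges, labels = as.character(labels))
  class(obj) <- "substate_spec"
  obj
}

#' Contiguous substate boundaries from printed angular ranges
#'
#' Published substate ranges are often printed with small gaps (e.g.
#' 78-95.9, 96-105, 105.1-134). This converts such ordered,
#' non-overlapping ranges into contiguous bin edges by placing interior
#' edges at the gap midpoints (95.95, 105.05), so every frame maps to a
#' region.
#'
#' @param ranges list of `c(lo, hi)` pairs, ordered, non-overlapping.
#' @param labels optional region labels.
#' @return A [substate_spec()].
#' @examples
#' region_boundaries_from_printed(
#'   list(c(78, 95.9), c(96, 105), c(105.1, 134)))$edges
#' @export
region_boundaries_from_printed <- function(ranges, labels = NULL) {
  if (!is.list(ranges)) ranges <- list(ranges)
  lo <- vapply(ranges, function(r) r[1], numeric(1))
  hi <- vapply(ranges, function(r) r[2], numeric(1))
  if (any(hi <= lo)) stop("each printed range needs lo < hi")
  if (length(ranges) > 1L) {
    nxt <- lo[-1]
    if (any(nxt <= hi[-length(hi)])) {
      stop("printed ranges overlap or are unordered")
    }
    inner <- (hi[-length(hi)] + nxt) / 2
  } else {
    inner <- numeric(0)
  }
  substate_spec(c(lo[1], inner, hi[length(hi)]), labels)
}

#' Substate occupancy percentages
#'
#' Fraction of frames (as a percentage of all frames) whose angle falls
#' in each region. Bins are half-open `[lo, hi)`, with the last bin
#' closed. Frames outside the spec's range are counted separately and
#' reported in `out_of_range`.
#'
#' @param series an `angle_series` from [angle_series()], or a numeric
#'   vector of angles.
#' @param spec a [substate_spec()].
#' @return An `occupancy_report`: list with `labels`, `percent`,
#'   `counts`, `total_frames`, `out_of_range`.
#' @export
substate_occupancy <- function(series, spec) {
  stopifnot(inherits(spec, "substate_spec"))
  ang <- if (is.data.frame(series)) series$angle else as.numeric(series)
  if (!length(ang)) stop("empty angle series")
  e <- spec$edges
  nr <- length(e) - 1L
  counts <- integer(nr)
  for (r in seq_len(nr)) {
    if (r < nr) {
      counts[r] <- sum(ang >= e[r] & ang < e[r + 1])
    } else {
      counts[r] <- sum(ang >= e[r] & ang <= e[r + 1])
    }
  }
  oor <- length(ang) - sum(counts)
  out <- list(labels = spec$labels,
              percent = 100 * counts / length(ang),
              counts = counts,
              total_frames = length(ang),
              out_of_range = oor)
  class(out) <- "occupancy_report"
  out
}

#' @export
print.occupancy_report <- function(x, ...) {
  cat("substate occupancy (", x$total_frames, " frames):\n", sep = "")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-12s %6.2f %% (%d frames)\n", x$labels[i],
                x$percent[i], x$counts[i]))
  }
  if (x$out_of_range > 0) {
    cat("  out of range:", x$out_of_range, "frames\n")
  }
  invisible(x)
}

#' Kernel density estimate of an angle distribution
#'
#' Gaussian-kernel density evaluated on a regular grid spanning
#' `[min - 5, max + 5]` degrees. The default bandwidth is Silverman's
#' rule of thumb; a constant series has no Silverman bandwidth and
#' requires a fixed one.
#'
#' @param series an `angle_series` or numeric vector of angles (>= 2
#'   distinct values for the Silverman rule).
#' @param bandwidth `"silverman"` or a fixed numeric bandwidth in
#'   degrees.
#' @param grid_step grid spacing in degrees (default 0.5).
#' @return data.frame with columns `angle`, `density`; the curve
#'   integrates to 1 (trapezoid rule) within 1e-3.
#' @export
angle_kde <- function(series, bandwidth = "silverman", grid_step = 0.5) {
  ang <- if (is.data.frame(series)) series$angle else as.numeric(series)
  if (length(ang) < 2L) stop("need at least 2 angles")
  if (identical(bandwidth, "silverman")) {
    if (length(unique(ang)) < 2L) {
      stop("constant series: Silverman's rule is undefined; ",
           "supply a fixed numeric bandwidth")
    }
    bw <- stats::bw.nrd0(ang)
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  }
  lo <- min(ang) - 5; hi <- max(ang) + 5
  grid <- seq(lo, hi, by = grid_step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  d <- stats::density(ang, bw = bw, from = lo, to = hi, n = length(grid))
  out <- data.frame(angle = d$x, density = d$y)
  attr(out, "bandwidth") <- bw
  out
}

#' Mode (peak location) of a KDE curve
#'
#' @param kde data.frame from [angle_kde()].
#' @return Angle (degrees) at the maximum density.
#' @export
kde_mode <- function(kde) {
  kde$angle[which.max(kde$density)]
}
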