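#' Trajectory container
#'
#' A `trajectory` ties a frames x atoms x 3 coordinate array to a topology
#' [structure3d]. `frame_interval` is metadata (time between saved frames,
#' in ps by convention; MD runs in this workflow saved coordinates every
#' 2 ps).
#'
#' @param topology a [structure3d]; its atom table describes every frame.
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom), or a
#'   list of `n_atoms x 3` matrices.
#' @param frame_interval time between frames (default 2, i.e. 2 ps).
#' @return An object of class `trajectory` with elements `topology`,
#'   `coords` (3-d array) and `frame_interval`.
#' @export
trajectory <- function(topology, coords, frame_interval = 2) {
  stopifnot(inherits(topology, "structure3d"))
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  n <- natoms(topology)
  if (dim(coords)[2] != n || dim(coords)[3] != 3L) {
    stop("coords must be n_frames x ", n, " x 3; got ",
         paste(dim(coords), collapse = " x "))
  }
  if (dim(coords)[1] < 1L) stop("trajectory needs at least one frame")
  if (!all(is.finite(coords))) stop("non-finite trajectory coordinates")
  stopifnot(is.numeric(frame_interval), frame_interval > 0)
  obj <- list(topology = topology, coords = coords,
              frame_interval = as.numeric(frame_interval))
  class(obj) <- "trajectory"
  obj
}

#' @rdname trajectory
#' @param x a `trajectory`.
#' @export
nframes <- function(x) UseMethod("nframes")

#' @export
nframes.trajectory <- function(x) dim(x$coords)[1]

#' Coordinates of one frame
#' @param traj a [trajectory].
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(inherits(traj, "trajectory"))
  if (frame < 1L || frame > nframes(traj)) {
    stop("frame index ", frame, " out of range [1, ", nframes(traj), "]")
  }
  matrix(traj$coords[frame, , ], ncol = 3L)
}

#' Frame times
#' @param traj a [trajectory].
#' @return numeric vector of times, starting at 0, spaced `frame_interval`.
#' @export
frame_times <- function(traj) {
  (seq_len(nframes(traj)) - 1) * traj$frame_interval
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", nframes(x), "frames x", natoms(x$topology),
      "atoms; frame interval", x$frame_interval, "\n")
  invisible(x)
}

#' Read a trajectory file
#'
#' Two plain-text formats are supported: multi-model PDB (each MODEL block
#' is one frame) and XYZ (per frame: an atom-count line, a comment line,
#' then `element x y z` lines). Every frame must have exactly the
#' topology's atom count.
#'
#' @param path file path.
#' @param topology a [structure3d] describing the atoms of every frame.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @param frame_interval time between frames (metadata; default 2).
#' @return A [trajectory].
#' @export
read_trajectory <- function(path, topology,
                            format = c("auto", "pdb", "xyz"),
                            frame_interval = 2) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "structure3d"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "xyz") "xyz" else "pdb"
  }
  n <- natoms(topology)
  if (format == "pdb") {
    s <- read_structure(path, format = "pdb")
    if (natoms(s) != n) {
      stop("frame 1: atom count ", natoms(s),
           " does not match topology (", n, ")")
    }
    coords <- aperm(simplify2array(s$xyz), c(3, 1, 2))
  } else {
    lines <- readLines(path, warn = FALSE)
    frames <- list()
    i <- 1L
    fidx <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      fidx <- fidx + 1L
      cnt <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(cnt)) stop("frame ", fidx, ": bad atom-count line ", i)
      if (cnt != n) {
        stop("frame ", fidx, ": atom count ", cnt,
             " does not match topology (", n, ")")
      }
      if (i + 1L + cnt > length(lines)) {
        stop("frame ", fidx, ": truncated (expected ", cnt, " atom lines)")
      }
      blk <- lines[(i + 2L):(i + 1L + cnt)]
      m <- matrix(NA_real_, cnt, 3)
      for (k in seq_len(cnt)) {
        tok <- strsplit(trimws(blk[k]), "[[:space:]]+")[[1]]
        if (length(tok) < 4L) {
          stop("frame ", fidx, ": malformed atom line ", i + 1L + k)
        }
        v <- suppressWarnings(as.numeric(tok[2:4]))
        if (anyNA(v)) {
          stop("frame ", fidx, ": malformed coordinates on line ", i + 1L + k)
        }
        m[k, ] <- v
      }
      frames[[fidx]] <- m
      i <- i + 2L + cnt
    }
    if (!length(frames)) stop("no frames parsed from ", path)
    coords <- aperm(simplify2array(frames), c(3, 1, 2))
  }
  trajectory(topology, coords, frame_interval = frame_interval)
}

#' Write a trajectory file
#'
#' @param traj a [trajectory].
#' @param path output path.
#' @param format `"pdb"` (multi-model) or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"))
  if (format == "pdb") {
    s <- traj$topology
    s$xyz <- lapply(seq_len(nframes(traj)), function(f) frame_coords(traj, f))
    write_structure(s, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    el <- traj$topology$atoms$element
    for (f in seq_len(nframes(traj))) {
      xyz <- frame_coords(traj, f)
      writeLines(as.character(nrow(xyz)), con)
      writeLines(sprintf("frame %d", f), con)
      writeLines(sprintf("%-2s %12.6f %12.6f %12.6f",
                         el, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  }
  invisible(path)
}
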