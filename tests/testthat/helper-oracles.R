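# Independent oracles and small fixture builders used across the suite.

# quaternion -> rotation matrix
qrot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() qrot(rnorm(4))

# brute-force minimum RMSD over rotations: dense random-quaternion grid
# followed by Nelder-Mead polish of the best start; independent of the
# SVD route used by kabsch_fit
brute_force_rmsd <- function(mobile, ref, n_grid = 4000) {
  xm <- sweep(mobile, 2, colMeans(mobile))
  xr <- sweep(ref, 2, colMeans(ref))
  obj <- function(q) {
    r <- qrot(q)
    sqrt(sum((xm %*% t(r) - xr)^2) / nrow(xm))
  }
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj)
  o <- stats::optim(qs[which.min(vals), ], obj, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-14))
  o$value
}

# elastic-network potential energy for the finite-difference Hessian
# oracle; v is the flat (x1,y1,z1,x2,...) coordinate vector
en_energy <- function(v, ref_coords, gamma, cutoff) {
  n <- nrow(ref_coords)
  y <- t(matrix(v, 3, n))
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d0 <- sqrt(sum((ref_coords[j, ] - ref_coords[i, ])^2))
      if (d0 <= cutoff) {
        d <- sqrt(sum((y[j, ] - y[i, ])^2))
        s <- s + 0.5 * gamma * (d - d0)^2
      }
    }
  }
  s
}

fd_hessian <- function(ref_coords, gamma, cutoff, eps = 1e-4) {
  n <- 3 * nrow(ref_coords)
  v0 <- as.vector(t(ref_coords))
  h <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      ea <- eb <- rep(0, n); ea[a] <- eps; eb[b] <- eps
      h[a, b] <- (en_energy(v0 + ea + eb, ref_coords, gamma, cutoff) -
                    en_energy(v0 + ea - eb, ref_coords, gamma, cutoff) -
                    en_energy(v0 - ea + eb, ref_coords, gamma, cutoff) +
                    en_energy(v0 - ea - eb, ref_coords, gamma, cutoff)) /
        (4 * eps^2)
    }
  }
  h
}

# Moore-Penrose pseudo-inverse of a symmetric matrix, skipping the
# near-null (rigid) space
sym_pinv <- function(h, tol = 1e-8) {
  e <- eigen(h, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / e$values[keep], sum(keep)) %*%
    t(e$vectors[, keep, drop = FALSE])
}

# standard synthetic fixtures
fixture_complex <- function(seed = 3) {
  make_two_domain_complex(25, 25, 30, seed = seed)
}

fixture_vectors <- function() {
  list(v1 = vector_definition("v1", c("A", 3, "CA"), c("A", 23, "CA")),
       v3 = vector_definition("v3", c("A", 3, "CA"), c("B", 12, "CA")))
}

# lateral-motion substate ranges as printed in the study's figure
lateral_ranges <- function() list(c(78, 95.9), c(96, 105), c(105.1, 134))

fixture_angle_spec <- function(n_frames = 2000, seed = 11,
                               noise_sigma = 0.3) {
  substate_gen_spec(centers = c(87, 100.5, 119.5),
                    widths = c(1.5, 1.5, 1.5),
                    occupancies = c(0.55, 0.30, 0.15),
                    noise_sigma = noise_sigma,
                    n_frames = n_frames, seed = seed)
}
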