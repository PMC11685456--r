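test_that("Hessian super-elements match the analytic dyadic form", {
  h <- build_hessian(rbind(c(0, 0, 0), c(2, 0, 0)), cutoff = 10, gamma = 1)
  off <- h[1:3, 4:6]
  expect_equal(off, matrix(c(-1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3),
               tolerance = 1e-12)
  expect_equal(h[1:3, 1:3], -off, tolerance = 1e-12)
  expect_identical(h, t(h))
})

test_that("Hessian equals finite-difference second derivatives of the EN potential", {
  set.seed(18)
  x <- matrix(rnorm(15, sd = 3), 5, 3)
  for (gamma in c(1, 1.7)) {
    h <- build_hessian(x, cutoff = 100, gamma = gamma)
    expect_lt(max(abs(h - fd_hessian(x, gamma, 100))), 1e-5)
  }
  # with a finite cutoff excluding some pairs
  h2 <- build_hessian(x, cutoff = 5, gamma = 1)
  expect_lt(max(abs(h2 - fd_hessian(x, 1, 5))), 1e-5)
})

test_that("block rows sum to zero (translational invariance) exactly", {
  set.seed(19)
  x <- matrix(rnorm(60, sd = 4), 20, 3)
  h <- build_hessian(x, cutoff = 12)
  n <- nrow(x)
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    blocksum <- matrix(0, 3, 3)
    for (j in seq_len(n)) {
      blocksum <- blocksum + h[rows, (3 * j - 2):(3 * j)]
    }
    expect_lt(max(abs(blocksum)), 1e-10)
  }
  expect_error(build_hessian(rbind(c(0, 0, 0), c(0, 0, 0))), "coincident")
})

test_that("a connected network has exactly 6 rigid modes and clean eigenpairs", {
  set.seed(20)
  x <- matrix(rnorm(60, sd = 3), 20, 3)
  h <- build_hessian(x, cutoff = 100)
  md <- compute_modes(h, n_modes = 10)
  expect_equal(md$n_rigid_skipped, 6L)
  expect_true(all(md$eigenvalues > 0))
  expect_true(!is.unsorted(md$eigenvalues))
  # orthonormal modes and eigen-residuals
  g <- crossprod(md$modes)
  expect_lt(max(abs(g - diag(ncol(md$modes)))), 1e-8)
  for (k in seq_along(md$eigenvalues)) {
    resid <- h %*% md$modes[, k] - md$eigenvalues[k] * md$modes[, k]
    expect_lt(max(abs(resid)), 1e-8 * max(abs(h)))
  }
})

test_that("disconnected networks are reported via their rigid-mode count", {
  # two clusters far beyond the cutoff: > 6 near-zero modes
  x <- rbind(matrix(rnorm(15), 5, 3), matrix(rnorm(15), 5, 3) + 100)
  h <- build_hessian(x, cutoff = 10)
  expect_error(compute_modes(h), "rigid")
})

test_that("eigenvalues scale linearly with gamma; modes are gamma-invariant", {
  set.seed(21)
  x <- matrix(rnorm(45, sd = 3), 15, 3)
  m1 <- anm(x, cutoff = 100, gamma = 1, n_modes = 5)
  m3 <- anm(x, cutoff = 100, gamma = 3, n_modes = 5)
  expect_equal(m3$eigenvalues, 3 * m1$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(m3$modes), abs(m1$modes), tolerance = 1e-8)
})

test_that("increasing the cutoff stiffens the lowest non-rigid mode", {
  # nested networks on a helix CA trace (connected at every cutoff)
  h <- make_ideal_helix(30)
  x <- coords(h)[h$atoms$atom_name == "CA", ]
  lams <- vapply(c(8, 10, 14, 20, 100), function(ct) {
    anm(x, cutoff = ct, n_modes = 1)$eigenvalues[1]
  }, numeric(1))
  expect_true(all(diff(lams) >= -1e-10))
})

test_that("MSF and cross-correlations match the Hessian pseudo-inverse when all modes are kept", {
  set.seed(23)
  x <- matrix(rnorm(36, sd = 3), 12, 3)
  h <- build_hessian(x, cutoff = 100)
  m <- anm(x, cutoff = 100, n_modes = 3 * 12 - 6)
  pinv <- sym_pinv(h)
  n <- nrow(x)
  msf_oracle <- vapply(seq_len(n), function(i) {
    sum(diag(pinv[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)]))
  }, numeric(1))
  expect_lt(max(abs(fluctuations(m) - msf_oracle)), 1e-8)
  cov_oracle <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cov_oracle[i, j] <- sum(diag(pinv[(3 * i - 2):(3 * i),
                                      (3 * j - 2):(3 * j)]))
  }
  cc_oracle <- cov_oracle / sqrt(outer(diag(cov_oracle), diag(cov_oracle)))
  cc <- cross_correlations(m)
  expect_lt(max(abs(cc - cc_oracle)), 1e-8)
  expect_equal(diag(cc), rep(1, n))
  expect_true(all(cc >= -1 - 1e-10 & cc <= 1 + 1e-10))
  expect_lt(max(abs(cc - t(cc))), 1e-12)
  expect_true(all(fluctuations(m) > 0))
})

test_that("MSF is invariant under rigid rotation of the input coordinates", {
  set.seed(24)
  x <- matrix(rnorm(60, sd = 3), 20, 3)
  m0 <- anm(x, cutoff = 100, n_modes = 8)
  r <- random_rotation()
  m1 <- anm(sweep(x %*% t(r), 2, c(3, 1, -2), "+"), cutoff = 100,
            n_modes = 8)
  expect_equal(fluctuations(m1), fluctuations(m0), tolerance = 1e-6)
})

test_that("mode shapes agree with an independent elastic-network implementation", {
  s <- make_two_domain_complex(20, 20, 12, seed = 25)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  m <- anm(s, cutoff = 10, n_modes = 5)
  pdb <- bio3d::read.pdb(f)
  ref <- suppressWarnings(bio3d::nma(pdb, ff = "anm", cutoff = 10,
                                     mass = FALSE, temp = NULL))
  # compare the first non-rigid modes, allowing sign flips
  for (k in 1:3) {
    ours <- m$modes[, k]
    theirs <- ref$modes[, 6 + k]
    theirs <- theirs / sqrt(sum(theirs^2))
    expect_gt(abs(sum(ours * theirs)), 0.95)
  }
})

test_that("extending modes to all atoms copies node directions and renormalizes", {
  s <- make_ideal_helix(15)
  m <- anm(s, cutoff = 12, n_modes = 4)
  ext <- extend_modes(m, s)
  expect_equal(dim(ext), c(3L * natoms(s), 4L))
  # unit norm columns
  expect_equal(colSums(ext^2), rep(1, 4), tolerance = 1e-10)
  # all 4 atoms of a residue share its node direction
  u1 <- matrix(ext[, 1], ncol = 3, byrow = TRUE)
  for (res in c(1L, 8L)) {
    rows <- which(s$atoms$residue_number == res)
    d <- u1[rows, , drop = FALSE]
    d <- d / sqrt(rowSums(d^2))
    expect_lt(max(abs(sweep(d, 2, d[1, ]))), 1e-10)
  }
  # collapsing back to CA entries reproduces the node directions
  ca_rows <- which(s$atoms$atom_name == "CA")
  u_ca <- u1[ca_rows, ]
  u_node <- matrix(m$modes[, 1], ncol = 3, byrow = TRUE)
  u_node <- u_node / sqrt(sum(u_node^2))  # same overall normalization
  cosang <- sum(u_ca * u_node) /
    sqrt(sum(u_ca^2) * sum(u_node^2))
  expect_equal(abs(cosang), 1, tolerance = 1e-10)
})

test_that("anm model object prints, summarizes and exports NMD", {
  s <- make_ideal_helix(20)
  m <- anm(s, n_modes = 5)
  expect_output(print(m), "Anisotropic network model")
  expect_output(print(summary(m)), "MSF range")
  f <- withr::local_tempfile(fileext = ".nmd")
  write_nmd(m, f)
  lines <- readLines(f)
  expect_true(any(startsWith(lines, "coordinates")))
  expect_equal(sum(startsWith(lines, "mode")), 5L)
})
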