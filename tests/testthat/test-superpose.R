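test_that("kabsch_fit recovers constructed rigid transforms", {
  set.seed(1)
  x <- matrix(rnorm(30, sd = 3), 10, 3)
  # identity
  f0 <- kabsch_fit(x, x)
  expect_lt(f0$rmsd, 1e-10)
  expect_lt(max(abs(f0$rotation - diag(3))), 1e-8)
  # 30 deg about z plus shift (1,2,3): recovered transform inverts it
  th <- 30 * pi / 180
  rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  y <- sweep(x %*% t(rz), 2, c(1, 2, 3), "+")
  f <- kabsch_fit(y, x)
  expect_lt(f$rmsd, 1e-8)
  expect_lt(max(abs(apply_transform(f, y) - x)), 1e-8)
  expect_equal(rotation_angle(f$rotation), 30, tolerance = 1e-6)
})

test_that("kabsch_fit matches a dense quaternion-grid brute-force search", {
  set.seed(3)
  for (i in 1:3) {
    a <- matrix(rnorm(30, sd = 3), 10, 3)
    b <- matrix(rnorm(30, sd = 3), 10, 3)
    k <- kabsch_fit(a, b)$rmsd
    br <- brute_force_rmsd(a, b)
    expect_lt(abs(k - br), 1e-3)
    expect_lte(k, br + 1e-9)  # kabsch is the optimum
  }
})

test_that("kabsch transforms are proper rotations and inputs validated", {
  set.seed(4)
  x <- matrix(rnorm(30), 10, 3)
  y <- x + matrix(rnorm(30, sd = 0.3), 10, 3)
  f <- kabsch_fit(x, y)
  expect_lt(max(abs(crossprod(f$rotation) - diag(3))), 1e-8)
  expect_equal(det(f$rotation), 1, tolerance = 1e-8)
  expect_error(kabsch_fit(x, y[1:9, ]), "mismatch")
  expect_error(kabsch_fit(x[1:2, ], y[1:2, ]), "3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 1), "collinear")
})

test_that("superposition never increases RMSD and is invariant to joint rigid motion", {
  set.seed(5)
  for (i in 1:5) {
    a <- matrix(rnorm(24, sd = 2), 8, 3)
    b <- matrix(rnorm(24, sd = 2), 8, 3)
    expect_lte(kabsch_fit(a, b)$rmsd, rmsd(a, b) + 1e-12)
    r <- random_rotation(); t <- rnorm(3)
    a2 <- sweep(a %*% t(r), 2, t, "+")
    b2 <- sweep(b %*% t(r), 2, t, "+")
    expect_equal(kabsch_fit(a2, b2)$rmsd, kabsch_fit(a, b)$rmsd,
                 tolerance = 1e-8)
  }
})

test_that("rmsd matches hand computation and the identity-constrained fit", {
  expect_equal(rmsd(rbind(c(0, 0, 0), c(1, 0, 0)),
                    rbind(c(0, 0, 0), c(1, 1, 0))),
               sqrt(1 / 2), tolerance = 1e-10)
  expect_equal(rmsd(diag(3), diag(3)), 0)
  expect_error(rmsd(matrix(0, 2, 3), matrix(0, 3, 3)), "differ")
})

test_that("domain RMSD series is zero for static or rigidly moving trajectories", {
  s <- make_ideal_helix(20)
  n <- natoms(s)
  # identical frames
  arr <- array(rep(coords(s), each = 4), dim = c(4, n, 3))
  tr <- trajectory(s, arr)
  dom <- select_atoms(s, domain_definition("d", "A", c(1, 20)))
  ser <- domain_rmsd_series(tr, dom)
  expect_true(all(ser$rmsd < 1e-10))
  # frames that are rigid transforms of the reference
  set.seed(6)
  for (f in 2:4) {
    r <- random_rotation()
    arr[f, , ] <- sweep(coords(s) %*% t(r), 2, rnorm(3, sd = 5), "+")
  }
  ser2 <- domain_rmsd_series(trajectory(s, arr), dom)
  expect_true(all(ser2$rmsd < 1e-6))
  expect_error(domain_rmsd_series(tr, dom, reference_frame = 9),
               "out of range")
})

test_that("each domain RMSD value equals an independent per-frame Kabsch fit", {
  s <- fixture_complex()
  v <- fixture_vectors()
  tr <- make_angle_trajectory(s, list(v$v1, v$v3),
                              fixture_angle_spec(n_frames = 6))
  dom <- select_atoms(s, domain_definition("d", "B", c(1, 25)))
  ser <- domain_rmsd_series(tr, dom)
  ref <- frame_coords(tr, 1)[dom$indices, ]
  for (f in seq_len(nframes(tr))) {
    expect_equal(ser$rmsd[f],
                 kabsch_fit(frame_coords(tr, f)[dom$indices, ], ref)$rmsd,
                 tolerance = 1e-12)
  }
})

test_that("domain RMSD under isotropic noise matches the analytic expectation", {
  # with per-atom Gaussian noise sigma in each coordinate, the expected
  # squared deviation per atom after fitting reference noise-free coords
  # is ~ 3 sigma^2 (alignment absorbs a small share for large N)
  s <- make_ideal_helix(100)
  n <- natoms(s)
  sigma <- 0.5
  set.seed(7)
  arr <- array(NA_real_, dim = c(30, n, 3))
  arr[1, , ] <- coords(s)
  for (f in 2:30) arr[f, , ] <- coords(s) + rnorm(n * 3, sd = sigma)
  dom <- select_atoms(s, domain_definition("d", "A", c(1, 100)))
  ser <- domain_rmsd_series(trajectory(s, arr), dom)
  expect_equal(mean(ser$rmsd[-1]), sqrt(3) * sigma, tolerance = 0.1)
  # exact at sigma = 0 (static case)
  expect_equal(ser$rmsd[1], 0)
})

test_that("per-atom deviation series isolates the displaced atom", {
  s <- make_ideal_helix(20)
  n <- natoms(s)
  arr <- array(rep(coords(s), each = 5), dim = c(5, n, 3))
  # displace one CA by 2 A in frame 3 only
  ca_idx <- which(s$atoms$atom_name == "CA" & s$atoms$residue_number == 10)
  arr[3, ca_idx, 1] <- arr[3, ca_idx, 1] + 2
  tr <- trajectory(s, arr)
  align <- select_atoms(s, domain_definition("al", "A", c(1, 5)))
  ser <- per_atom_deviation_series(tr, atom_selection(ca_idx, "probe", n),
                                   align)
  vals <- ser[[3]]
  expect_equal(vals[3], 2.0, tolerance = 1e-8)
  expect_true(all(vals[-3] < 1e-10))
})

test_that("single-atom deviation with external alignment matches its own distance series", {
  s <- fixture_complex()
  v <- fixture_vectors()
  tr <- make_angle_trajectory(s, list(v$v1, v$v3),
                              fixture_angle_spec(n_frames = 5))
  top <- tr$topology
  ca_idx <- which(top$atoms$chain_id == "B" &
                    top$atoms$residue_number == 12 &
                    top$atoms$atom_name == "CA")
  align <- select_atoms(top, domain_definition("al", "A", c(1, 25)))
  ser <- per_atom_deviation_series(tr, atom_selection(ca_idx, "x",
                                                      natoms(top)), align)
  # independent recomputation
  ref <- frame_coords(tr, 1)
  for (f in seq_len(nframes(tr))) {
    x <- frame_coords(tr, f)
    fit <- kabsch_fit(x[align$indices, ], ref[align$indices, ])
    moved <- apply_transform(fit, x[ca_idx, , drop = FALSE])
    expect_equal(ser[[3]][f], sqrt(sum((moved - ref[ca_idx, ])^2)),
                 tolerance = 1e-10)
  }
})
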