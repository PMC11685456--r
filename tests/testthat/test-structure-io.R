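test_that("a minimal single-atom PDB line parses to the stated record", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A  12      11.104  -6.320   2.500  1.00 20.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(natoms(s), 1L)
  a <- s$atoms
  expect_equal(a$atom_name, "CA")
  expect_equal(a$residue_name, "ALA")
  expect_equal(a$residue_number, 12L)
  expect_equal(a$chain_id, "A")
  expect_equal(unname(coords(s)[1, ]), c(11.104, -6.320, 2.500))
  expect_false(a$het)
})

test_that("write/read round trip preserves identity exactly and coordinates to PDB precision", {
  s <- make_two_domain_complex(8, 8, 15, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_identical(s2$atoms$atom_name, s$atoms$atom_name)
  expect_identical(s2$atoms$residue_number, s$atoms$residue_number)
  expect_identical(s2$atoms$chain_id, s$atoms$chain_id)
  expect_identical(s2$atoms$element, s$atoms$element)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
})

test_that("our PDB writer agrees with an independent PDB reader", {
  s <- make_ideal_helix(10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  b <- bio3d::read.pdb(f)
  expect_equal(nrow(b$atom), natoms(s))
  expect_lt(max(abs(matrix(b$xyz, ncol = 3, byrow = TRUE) - coords(s))),
            1e-3)
  expect_identical(b$atom$resno, s$atoms$residue_number)
})

test_that("malformed coordinate lines and empty files raise named errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       1.000   xx.000  3.000  1.00  0.00           C"),
    f)
  expect_error(read_structure(f), "line 2")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f2)
  expect_error(read_structure(f2), "zero atoms")
  expect_error(read_structure(f, format = "mmcif"), "not supported")
})

test_that("multi-MODEL blocks become models sharing one atom table", {
  s <- make_ideal_helix(5)
  tr <- trajectory(s, array(rep(coords(s), each = 3),
                            dim = c(3, natoms(s), 3)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  s2 <- read_structure(f)
  expect_equal(nmodels(s2), 3L)
  expect_equal(natoms(s2), natoms(s))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C"),
    f)
  s <- read_structure(f)
  expect_equal(natoms(s), 1L)
  expect_equal(coords(s)[1, 1], 2.000)
})

test_that("HETATM records are retained and flagged", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2 ZN    ZN A 200       5.000   5.000   5.000  1.00  0.00          ZN"),
    f)
  s <- read_structure(f)
  expect_identical(s$atoms$het, c(FALSE, TRUE))
})

test_that("select_atoms returns exactly the matching backbone atoms", {
  s <- make_ideal_helix(58)
  sel <- select_atoms(s, domain_definition("all", "A", c(1, 58)))
  expect_equal(length(sel), 58L * 4L)
  # full-structure definition covers every atom
  sel_all <- select_atoms(s, domain_definition("full", "A", c(1, 58),
                                               atom_names = NULL))
  expect_equal(length(sel_all), natoms(s))
  # CA-only
  sel_ca <- select_atoms(s, domain_definition("ca", "A", c(10, 20),
                                              atom_names = "CA"))
  expect_equal(length(sel_ca), 11L)
  expect_true(all(s$atoms$atom_name[sel_ca$indices] == "CA"))
})

test_that("empty selections are an explicit error, not silently empty", {
  s <- make_ideal_helix(10)
  expect_error(select_atoms(s, domain_definition("x", "A", c(100, 120))),
               "empty selection")
  expect_error(select_atoms(s, domain_definition("x", "Z", c(1, 5))),
               "chain")
})

test_that("selection is order-stable and unions of disjoint ranges concatenate", {
  s <- make_ideal_helix(30)
  a <- select_atoms(s, domain_definition("a", "A", c(1, 10)))
  b <- select_atoms(s, domain_definition("b", "A", c(21, 30)))
  u <- select_atoms(s, domain_definition("u", "A",
                                         list(c(1, 10), c(21, 30))))
  expect_identical(u$indices, sort(c(a$indices, b$indices)))
  # idempotence: re-resolving gives the same indices
  expect_identical(select_atoms(s, domain_definition("a", "A",
                                                     c(1, 10)))$indices,
                   a$indices)
  expect_false(is.unsorted(u$indices, strictly = TRUE))
})

test_that("trajectory readers enforce per-frame atom counts", {
  s <- make_ideal_helix(5)
  # single-model file -> one frame identical to topology
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  tr <- read_trajectory(f, s)
  expect_equal(nframes(tr), 1L)
  expect_lt(max(abs(frame_coords(tr, 1) - coords(s))), 1e-3)
  # 10-frame xyz file
  arr <- array(rep(coords(s), each = 10), dim = c(10, natoms(s), 3))
  fx <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(trajectory(s, arr), fx, format = "xyz")
  t10 <- read_trajectory(fx, s, format = "xyz")
  expect_equal(dim(t10$coords), c(10L, natoms(s), 3L))
  # frame with one atom missing -> error naming the frame
  lines <- readLines(fx)
  block <- natoms(s) + 2L
  lines[2 * block + 1] <- as.character(natoms(s) - 1L)
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(lines[-(2 * block + 2)], bad)
  expect_error(read_trajectory(bad, s, format = "xyz"), "frame 3")
})

test_that("trajectory round trips preserve coordinates", {
  s <- fixture_complex()
  v <- fixture_vectors()
  tr <- make_angle_trajectory(s, list(v$v1, v$v3),
                              fixture_angle_spec(n_frames = 4))
  fp <- withr::local_tempfile(fileext = ".pdb")
  fx <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(tr, fp)
  write_trajectory(tr, fx, format = "xyz")
  expect_lt(max(abs(read_trajectory(fp, s)$coords - tr$coords)), 1e-3)
  expect_lt(max(abs(read_trajectory(fx, s)$coords - tr$coords)), 1e-3)
})
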