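test_that("configuration enforces its invariants", {
  expect_error(configuration(matrix(1, 1, 2)), "N x 3")
  expect_error(configuration(matrix(c(1, NA, 3), 1, 3)), "finite")
  expect_error(configuration(matrix(0, 2, 3), groups = list(g = 3L)),
               "outside")
  conf <- configuration(matrix(0, 3, 3), groups = list(g = c(1L, 3L)))
  expect_equal(n_atoms(conf), 3)
  expect_equal(resolve_selection(conf, "g"), c(1L, 3L))
  expect_error(resolve_selection(conf, "nope"), "no group")
})

test_that("trajectory rejects mismatched frames and bad times", {
  a <- configuration(matrix(0, 2, 3))
  b <- configuration(matrix(0, 3, 3))
  expect_error(trajectory(list(a, b)), "atoms")
  expect_error(trajectory(list(a, a), times = c(1, 1)), "increasing")
  tr <- trajectory(list(a, a, a))
  expect_equal(tr$times, c(0, 1, 2)) # default times are frame indices in ps
})

test_that("XYZ round-trips coordinates, times and frame structure", {
  set.seed(1)
  frames <- lapply(1:2, function(i)
    configuration(matrix(rnorm(9), 3, 3), elements = c("C", "O", "H")))
  tr <- trajectory(frames, times = c(0.5, 1.25))
  f <- tempfile(fileext = ".xyz")
  write_xyz(tr, f)
  rt <- read_xyz(f)
  expect_equal(n_frames(rt), 2)
  expect_equal(n_atoms(rt), 3)
  expect_equal(rt$times, c(0.5, 1.25))
  expect_equal(rt$frames[[2]]$elements, c("C", "O", "H"))
  expect_equal(rt$frames[[1]]$coords, round(tr$frames[[1]]$coords, 6))
  # second write is byte-identical (fixed precision)
  f2 <- tempfile(fileext = ".xyz")
  write_xyz(rt, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed XYZ input errors name the offending line", {
  f <- tempfile()
  writeLines(c("2", "t=0", "C 0 0 0", "C 1 0 0", "3", "t=1", "C 0 0 0",
               "C 1 0 0", "C 2 0 0"), f)
  expect_error(read_xyz(f), "3 atoms but previous frames have 2")
  writeLines(c("x", "comment"), f)
  expect_error(read_xyz(f), "line 1")
  writeLines(c("3", "t=0", "C 0 0 0"), f)
  expect_error(read_xyz(f), "truncated")
  writeLines(c("1", "t=0", "C a b c"), f)
  expect_error(read_xyz(f), "non-numeric")
})

test_that("minimal PDB reader populates groups and round-trips geometry", {
  f <- tempfile(fileext = ".pdb")
  conf0 <- configuration(matrix(c(0, 0, 0, 1.5, 0, 0, 0, 1.5, 0, 5, 5, 5),
                                4, 3, byrow = TRUE),
                         elements = c("C", "C", "N", "O"),
                         names = c("CA", "CB", "N", "O"))
  conf0$resname <- c("ALA", "ALA", "GLY", "HOH")
  conf0$resid <- c(1L, 1L, 2L, 3L)
  write_pdb_minimal(conf0, f)
  conf <- read_pdb_minimal(f)
  expect_equal(n_atoms(conf), 4)
  expect_equal(conf$coords, conf0$coords, tolerance = 1e-6)
  expect_equal(conf$groups$water_O, 4L)
  expect_equal(conf$groups$backbone_ref, 1L)
  expect_equal(sort(conf$groups$ALA), c(1L, 2L))
})

test_that("PDB reader rejects empty and corrupt records", {
  f <- tempfile()
  writeLines(c("REMARK nothing", "END"), f)
  expect_error(read_pdb_minimal(f), "empty structure")
  writeLines("ATOM      1  CA  ALA A   1      xxxxxxx   0.000   0.000  1.00  0.00           C", f)
  expect_error(read_pdb_minimal(f), "non-numeric")
})

test_that("pocket fixture PDB matches the generator's bookkeeping", {
  sys <- build_toy_pocket(toy_pocket_spec(n_solvent = 5, ligand_atoms = 4))
  f <- tempfile(fileext = ".pdb")
  write_pdb_minimal(sys$configuration, f)
  conf <- read_pdb_minimal(f)
  expect_equal(n_atoms(conf), n_atoms(sys$configuration)) # 4 + 7 + 5
  expect_equal(n_atoms(conf), 16)
})

test_that("units convention: kB * 300 K is 0.5962 kcal/mol", {
  expect_equal(signif(thermal_energy(300), 4), 0.5962)
})
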