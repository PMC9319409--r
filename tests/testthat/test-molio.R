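test_that("a single-record SDF with charges parses into one 5-atom molecule", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(methane(), path)
  mols <- read_molecules(path, "sdf")
  expect_length(mols, 1)
  expect_equal(nrow(mols[[1]]$atoms), 5)
  expect_equal(mols[[1]]$atoms$charge, c(-0.4, 0.1, 0.1, 0.1, 0.1),
               tolerance = 1e-6)
})

test_that("SDF round trip preserves ids, order, coordinates and charges", {
  ser <- get_series(1)
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(ser$molecules, path)
  back <- read_molecules(path, "sdf")
  expect_length(back, 35)
  expect_equal(vapply(back, `[[`, "", "id"),
               vapply(ser$molecules, `[[`, "", "id"))
  for (i in c(1, 17, 35)) {
    a0 <- ser$molecules[[i]]$atoms
    a1 <- back[[i]]$atoms
    expect_equal(a1$element, a0$element)
    expect_equal(as.matrix(a1[, c("x", "y", "z")]),
                 as.matrix(a0[, c("x", "y", "z")]),
                 tolerance = 1e-4, ignore_attr = TRUE)
    expect_equal(a1$charge, a0$charge, tolerance = 1e-4)
    expect_equal(back[[i]]$pic50, ser$molecules[[i]]$pic50, tolerance = 1e-5)
  }
})

test_that("writing the same series twice is byte-identical", {
  ser <- get_series(2)
  p1 <- withr::local_tempfile(fileext = ".sdf")
  p2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(ser$molecules, p1)
  write_sdf(ser$molecules, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("2D-flagged flat records and malformed MOL2 blocks are rejected", {
  flat <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("flat", "  prog              2D", "",
               "  2  1  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "    1.5000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  2  1  0", "M  END", "$$$$"), flat)
  expect_error(read_molecules(flat, "sdf"), "2D")

  bad <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "bad", "2 1 0 0 0", "SMALL", "USER_CHARGES",
               "@<TRIPOS>ATOM",
               "1 C1 0.000 0.000 0.000 C.3 1 LIG 0.10",
               "2 C2 oops broken",
               "@<TRIPOS>BOND", "1 1 2 1"), bad)
  expect_error(read_molecules(bad, "mol2"), "line 8")
})

test_that("MOL2 charges are taken from the file", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "water_frag", "3 2 0 0 0", "SMALL",
               "USER_CHARGES",
               "@<TRIPOS>ATOM",
               "1 O1 0.0000 0.0000 0.0000 O.3 1 LIG -0.6000",
               "2 H1 0.9600 0.0000 0.0000 H 1 LIG 0.3000",
               "3 H2 -0.2400 0.9300 0.0000 H 1 LIG 0.3000",
               "@<TRIPOS>BOND", "1 1 2 1", "2 1 3 1"), path)
  mols <- read_molecules(path, "mol2")
  expect_equal(mols[[1]]$atoms$charge, c(-0.6, 0.3, 0.3))
  expect_equal(mols[[1]]$atoms$element, c("O", "H", "H"))
})

test_that("atom parameterization follows the frozen tables and typing rules", {
  m <- carbon_at_origin()
  expect_equal(m$atoms$vdw_radius, 1.70)
  expect_equal(m$atoms$steric_weight, 1.70^3)

  # water-like O-H fragment: O acceptor, H-on-O donor
  w <- mk_mol(c("O", "H", "H"),
              c(0, 0, 0, 0.96, 0, 0, -0.24, 0.93, 0),
              charges = c(-0.6, 0.3, 0.3))
  expect_true(w$atoms$is_acceptor[1])
  expect_false(w$atoms$is_donor[1])
  expect_true(all(w$atoms$is_donor[2:3]))
  expect_true(all(w$atoms$hydrophobicity[2:3] < 0))

  # H on carbon stays apolar and is no donor
  ch <- methane()
  expect_false(any(ch$atoms$is_donor))
  expect_true(all(ch$atoms$hydrophobicity > 0))

  expect_error(assign_atom_params(
    aligned_molecule("x", data.frame(element = "Xx", x = 0, y = 0, z = 0,
                                     charge = 0))), "Xx")
})

test_that("assign_atom_params is idempotent", {
  m1 <- assign_atom_params(methane())
  m2 <- assign_atom_params(m1)
  expect_identical(m1$atoms, m2$atoms)
})

test_that("energy table parsing types rows, keeps extras and flags errors", {
  tab <- energies()
  expect_s3_class(tab, "energy_table")
  expect_equal(nrow(tab), 8)
  expect_true(all(is.finite(tab$fmax)))

  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,dg_exp,dg_fep,extra_term", p)
  expect_equal(nrow(read_energy_table(p)), 0)

  writeLines(c("id,dg_exp", "A,-8.0", "A,-9.0"), p)
  expect_error(read_energy_table(p), "duplicate")

  writeLines(c("id,dg_exp,extra_term", "A,-8.0,1.5", "B,,2.5"), p)
  t2 <- read_energy_table(p)
  expect_true(is.na(t2$dg_exp[2]))        # missing cell is NA, not zero
  expect_equal(t2$extra_term, c(1.5, 2.5)) # unknown column preserved

  writeLines(c("id,dg_exp", "A,-8.0", "B,oops"), p)
  expect_error(read_energy_table(p), "row 2")
})

test_that("activity tables require unique ids and finite activities", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,pic50", "C01,5.5", "C02,8.1"), p)
  act <- read_activity_table(p)
  expect_equal(act$pic50, c(5.5, 8.1))
  writeLines(c("id,pic50", "C01,5.5", "C01,8.1"), p)
  expect_error(read_activity_table(p), "duplicate")
})
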