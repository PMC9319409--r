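test_that("grid construction covers the bounding box plus margin, deterministically", {
  g <- build_grid(carbon_at_origin(), spacing = 2.0, margin = 4.0)
  expect_equal(g$origin, c(-4, -4, -4))
  expect_equal(g$npoints, rep(5L, 3))

  two <- mk_mol(c("C", "C"), c(0, 0, 0, 10, 0, 0))
  g2 <- build_grid(two, spacing = 2.0, margin = 4.0)
  xs <- range(grid_points(g2)[, 1])
  expect_lte(xs[1], -4); expect_gte(xs[2], 14)

  ser <- get_series(1)
  ga <- build_grid(ser$molecules)
  gb <- build_grid(ser$molecules)
  expect_identical(ga, gb)

  expect_error(build_grid(list()), "empty")
})

test_that("CoMFA fields satisfy asymptotics, the cap, and the LJ minimum oracle", {
  s <- field_settings()
  m <- carbon_at_origin()

  far <- field_grid(c(3 * s$energy_cutoff, 0, 0), 1, c(1, 1, 1))
  f <- comfa_fields(m, far, s)
  expect_lt(abs(f$steric), 1e-6)
  expect_lt(abs(f$electrostatic), 1e-6)

  on_atom <- field_grid(c(0, 0, 0), 1, c(1, 1, 1))
  f0 <- comfa_fields(m, on_atom, s)
  expect_equal(f0$steric, 30)        # truncated exactly at the cap
  expect_true(f0$excluded)

  # closed-form LJ oracle: at r = R* the energy is exactly -eps*
  rstar <- 1.70 + s$probe_radius
  epsstar <- sqrt(0.086 * s$probe_well_depth)
  at_min <- field_grid(c(rstar, 0, 0), 1, c(1, 1, 1))
  fm <- comfa_fields(m, at_min, s)
  expect_equal(fm$steric, -epsstar, tolerance = 1e-12)
})

test_that("electrostatic field uses the distance-dependent dielectric", {
  m <- carbon_at_origin(charge = 0.5)
  g <- field_grid(c(4, 0, 0), 1, c(1, 1, 1))
  f <- comfa_fields(m, g)
  expect_equal(f$electrostatic, 332.0636 * 0.5 / 16, tolerance = 1e-10)
})

test_that("CoMFA truncation bounds hold over a crowded series", {
  ser <- get_series(1)
  g <- build_grid(ser$molecules[1:5], spacing = 2.0)
  for (m in ser$molecules[1:5]) {
    f <- comfa_fields(m, g)
    expect_lte(max(abs(f$steric)), 30)
    expect_lte(max(abs(f$electrostatic)), 30)
  }
})

test_that("CoMSIA fields match hand-summed Gaussians and the r = 0 limit", {
  s <- field_settings()
  m <- carbon_at_origin()
  at_center <- field_grid(c(0, 0, 0), 1, c(1, 1, 1))
  expect_equal(comsia_fields(m, at_center, s, "S")$comsia_S, -1.70^3)

  two <- mk_mol(c("C", "O"), c(0, 0, 0, 1.5, 0, 0), charges = c(0.2, -0.4))
  probe <- field_grid(c(0.5, 1.0, 0), 1, c(1, 1, 1))
  got <- comsia_fields(two, probe, s, c("S", "E", "H"))
  r2 <- c(0.5^2 + 1, 1^2 + 1)
  gau <- exp(-0.3 * r2)
  expect_equal(got$comsia_S, -sum(c(1.70^3, 1.52^3) * gau), tolerance = 1e-12)
  expect_equal(got$comsia_E, -sum(c(0.2, -0.4) * gau), tolerance = 1e-12)
  expect_equal(got$comsia_H, -sum(c(0.70, -0.60) * gau), tolerance = 1e-12)
})

test_that("fields are invariant under a joint rigid motion of molecule and grid", {
  ser <- get_series(1)
  m <- ser$molecules[[3]]
  g <- field_grid(c(-3, -3, -1), 2.0, c(4, 4, 2))
  s <- field_settings()
  ref_comfa <- comfa_fields(m, g, s)
  ref_comsia <- comsia_fields(m, g, s, c("S", "H"))

  mt <- transform_mol(m)
  pts_t <- rigid_transform(grid_points(g))
  got_comsia <- fieldqsar:::.comsia_at_points(mt, pts_t, s,
                                              c("comsia_S", "comsia_H"))
  expect_equal(got_comsia$comsia_S, ref_comsia$comsia_S, tolerance = 1e-8)
  expect_equal(got_comsia$comsia_H, ref_comsia$comsia_H, tolerance = 1e-8)

  # CoMFA: evaluate via single-point grids at the transformed positions
  d2 <- fieldqsar:::.dist2(as.matrix(mt$atoms[, c("x", "y", "z")]), pts_t)
  d2r <- fieldqsar:::.dist2(as.matrix(m$atoms[, c("x", "y", "z")]),
                            grid_points(g))
  expect_equal(d2, d2r, tolerance = 1e-8)
})

test_that("fields are additive over disjoint fragments", {
  s <- field_settings()
  g <- field_grid(c(-2, -2, -2), 2.0, c(4, 4, 4))
  f1 <- mk_mol(c("C", "N"), c(0, 0, 0, 1.4, 0, 0), charges = c(0.1, -0.3))
  f2 <- mk_mol(c("O", "H"), c(5, 1, 0, 5.9, 1, 0), charges = c(-0.5, 0.3))
  both <- mk_mol(c("C", "N", "O", "H"),
                 c(0, 0, 0, 1.4, 0, 0, 5, 1, 0, 5.9, 1, 0),
                 charges = c(0.1, -0.3, -0.5, 0.3))
  a <- comsia_fields(f1, g, s, c("S", "E", "H", "D", "A"))
  b <- comsia_fields(f2, g, s, c("S", "E", "H", "D", "A"))
  ab <- comsia_fields(both, g, s, c("S", "E", "H", "D", "A"))
  for (k in names(ab)) {
    expect_equal(ab[[k]], a[[k]] + b[[k]], tolerance = 1e-10)
  }
})

test_that("descriptor assembly imputes excluded entries and filters flat columns", {
  # constant field over all molecules -> degenerate matrix
  same <- lapply(1:4, function(i) {
    m <- carbon_at_origin()
    m$pic50 <- i
    m
  })
  g <- build_grid(same, spacing = 2.0, margin = 2.0)
  expect_error(build_descriptor_matrix(same, g, "comsia_S"), "degenerate")

  # excluded electrostatic entry equals the mean of the non-excluded ones
  mols <- lapply(1:5, function(i) {
    # one atom fixed at origin; the fifth molecule gets a second atom on the
    # probe point so that point is sterically excluded for it only
    if (i < 5) {
      mk_mol("C", c(0, 0, 0), charges = 0.1 * i, id = paste0("m", i))
    } else {
      mk_mol(c("C", "C"), c(0, 0, 0, 2, 0, 0), charges = c(0.5, 0.4),
             id = "m5")
    }
  })
  g2 <- field_grid(c(2, 0, 0), 1, c(1, 1, 1))  # single point on m5's 2nd atom
  s <- field_settings(sigma_min_comfa = 0)
  raw <- vapply(mols, function(m) comfa_fields(m, g2, s)$electrostatic,
                numeric(1))
  excl <- vapply(mols, function(m) comfa_fields(m, g2, s)$excluded, logical(1))
  expect_identical(excl, c(rep(FALSE, 4), TRUE))
  s2 <- field_settings(sigma_min_comfa = 1e-6)
  dm <- build_descriptor_matrix(mols, g2, "comfa_electrostatic", s2)
  expect_equal(dm$X[5, 1], mean(raw[1:4]), tolerance = 1e-12)

  # surviving columns concentrate where substitution varies: brute-force
  # locate the max-variance columns and check they are retained
  ser <- get_series(1)
  gg <- build_grid(ser$molecules, spacing = 3.0, margin = 3.0)
  dm2 <- build_descriptor_matrix(ser$molecules, gg, "comsia_S")
  blocks <- t(vapply(ser$molecules, function(m) {
    comsia_fields(m, gg, field_settings(), "S")$comsia_S
  }, numeric(n_grid_points(gg))))
  sds <- apply(blocks, 2, sd)
  top <- order(-sds)[1:10]
  kept <- dm2$col_meta$grid_index[dm2$mask] + 1L
  expect_true(all(top %in% kept))
})

test_that("CoMSIA lattice values vary smoothly (no caps or jumps)", {
  ser <- get_series(1)
  m <- ser$molecules[[1]]
  g1 <- field_grid(c(-2, 0, 0), 1.0, c(9, 1, 1))
  g2 <- field_grid(c(-2, 0, 0), 0.5, c(17, 1, 1))
  v1 <- comsia_fields(m, g1, kinds = "S")$comsia_S
  v2 <- comsia_fields(m, g2, kinds = "S")$comsia_S
  expect_equal(v2[seq(1, 17, 2)], v1, tolerance = 1e-10)
  # halved spacing: neighbour differences shrink, no new extremes appear
  expect_lte(max(abs(diff(v2))), max(abs(diff(v1))) + 1e-9)
  expect_lte(max(abs(v2)), max(abs(v1)) + abs(diff(range(v1))))
})

test_that("OpenDX export writes a well-formed scalar grid", {
  g <- field_grid(c(0, 0, 0), 2.0, c(2, 3, 2))
  vals <- seq_len(n_grid_points(g)) / 10
  p <- withr::local_tempfile(fileext = ".dx")
  write_dx(vals, g, p)
  lines <- readLines(p)
  expect_match(lines[1], "counts 2 3 2")
  data_lines <- lines[8:(8 + ceiling(12 / 3) - 1)]
  nums <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  # z-fastest reordering: first value is (0,0,0), second is (0,0,1)
  arr <- array(vals, dim = g$npoints)
  expect_equal(nums[1:2], c(arr[1, 1, 1], arr[1, 1, 2]), tolerance = 1e-9)
  expect_equal(sort(nums), sort(vals), tolerance = 1e-9)
})
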