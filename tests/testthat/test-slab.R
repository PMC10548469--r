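test_that("surface alignment puts the Miller plane in the xy-plane", {
  cub <- make_sc_lj(a = 4)
  al <- surface_aligned_cell(cub, c(0, 0, 1))
  expect_equal(cell_volume(al$cell), 64, tolerance = 1e-10)
  expect_equal(d_spacing(al$cell, c(0, 0, 1)), 4, tolerance = 1e-10)

  al110 <- surface_aligned_cell(cub, c(1, 1, 0))
  B <- cell_basis(al110$cell)
  # both in-plane vectors perpendicular to the +z normal
  expect_equal(unname(B[3, 1]), 0, tolerance = 1e-10)
  expect_equal(unname(B[3, 2]), 0, tolerance = 1e-10)
  expect_equal(d_spacing(al110$cell, c(0, 0, 1)), 4 / sqrt(2),
               tolerance = 1e-10)
  expect_equal(cell_volume(al110$cell), 64, tolerance = 1e-10)
  expect_equal(nrow(expand_structure(al110)$atoms), 1)
})

test_that("alignment preserves volume and atom content on random faces", {
  set.seed(21)
  di <- make_diatomic_molecular(cell = c(6, 7, 9), charges = c(0.1, -0.1))
  v0 <- cell_volume(di$cell)
  n0 <- nrow(expand_structure(di)$atoms)
  for (hkl in list(c(1, 0, 0), c(0, 1, 1), c(1, 1, 1), c(2, 1, 0))) {
    al <- surface_aligned_cell(di, hkl)
    expect_equal(cell_volume(al$cell), v0, tolerance = 1e-8)
    expect_equal(nrow(expand_structure(al)$atoms), n0)
    B <- cell_basis(al$cell)
    expect_lt(max(abs(B[3, 1:2])), 1e-9)
    expect_equal(d_spacing(al$cell, c(0, 0, 1)),
                 d_spacing(di$cell, hkl), tolerance = 1e-9)
  }
})

test_that("lattice energy reproduces the simple-cubic hand count", {
  sc <- make_sc_lj(a = 3.5, D0 = 0.2)
  p <- toy_ff_params(sc, cutoff = 4.0)    # nearest neighbors only
  e <- lattice_energy(sc, p, radius = 5)
  expect_equal(as.numeric(e), -3 * 0.2, tolerance = 1e-12)
  # gas-phase limit: cutoff below the nearest-neighbor distance
  pfar <- toy_ff_params(sc, cutoff = 3.0)
  expect_equal(as.numeric(lattice_energy(sc, pfar, radius = 5)), 0)
})

test_that("rock-salt lattice sum recovers the Madelung constant", {
  rs <- make_rocksalt(a = 5.64, q = 1)
  p <- toy_ff_params(rs, cutoff = 1e6)
  e <- lattice_energy(rs, p, radius = 14, summation = "cells")
  M <- -as.numeric(e) / 4 / (332.0637 / (5.64 / 2))
  expect_equal(M, 1.7476, tolerance = 0.01)
  # sign symmetry: swapping all charges leaves the energy unchanged
  rs2 <- make_rocksalt(a = 5.64, q = 1)
  rs2$sites$charge <- -rs2$sites$charge
  rs2$expanded$atoms$charge <- -rs2$expanded$atoms$charge
  e2 <- lattice_energy(rs2, p, radius = 14, summation = "cells")
  expect_equal(as.numeric(e2), as.numeric(e), tolerance = 1e-12)
})

test_that("attachment energy partitions the sc-LJ lattice energy exactly", {
  sc <- make_sc_lj(a = 3.5, D0 = 0.2)
  p <- toy_ff_params(sc, cutoff = 4.0)
  t0 <- attachment_energy(sc, c(0, 0, 1), 0, p, radius = 5)
  expect_equal(t0$E_slice, -2 * 0.2, tolerance = 1e-12)
  expect_equal(t0$E_att, -1 * 0.2, tolerance = 1e-12)
  expect_equal(t0$E_latt, -3 * 0.2, tolerance = 1e-12)
  expect_lt(abs(t0$identity_gap), 1e-12)
  expect_error(attachment_energy(sc, c(0, 0, 1), 1.2, p), "offset")
})

test_that("E_latt = E_slice + E_att for every face and offset tested", {
  sc <- make_sc_lj(a = 3.5, D0 = 0.2)
  psc <- toy_ff_params(sc, cutoff = 6)
  di <- make_diatomic_molecular(cell = c(6, 6, 9), charges = c(0.15, -0.15))
  pdi <- toy_ff_params(di, cutoff = 8)
  for (case in list(list(st = sc, p = psc), list(st = di, p = pdi))) {
    for (hkl in list(c(0, 0, 1), c(0, 1, 0))) {
      al <- surface_aligned_cell(case$st, hkl)
      for (off in c(0, 0.3, 0.7)) {
        t <- attachment_energy(al, hkl, off, case$p, radius = 10)
        expect_equal(t$E_slice + t$E_att, t$E_latt, tolerance = 1e-6)
      }
    }
  }
})

test_that("|E_att| <= |E_latt| for an all-attractive toy crystal", {
  sc <- make_sc_lj(a = 3.5, D0 = 0.2)
  p <- toy_ff_params(sc, cutoff = 6)
  for (hkl in list(c(0, 0, 1), c(0, 1, 1), c(1, 1, 1))) {
    t <- attachment_energy(sc, hkl, 0, p, radius = 9)
    expect_lte(abs(t$E_att), abs(t$E_latt) + 1e-12)
  }
})

test_that("termination scan enumerates ten offsets and matches a fine-grid oracle", {
  di <- make_diatomic_molecular(cell = c(6, 6, 14), z = 0.1, second_z = 0.35,
                                charges = c(0.1, -0.1))
  p <- toy_ff_params(di, cutoff = 13)
  scn <- scan_terminations(di, c(0, 0, 1), 0.1, p, radius = 14)
  expect_equal(nrow(scn$terminations), 10)
  expect_equal(scn$terminations$offset, seq(0, 0.9, by = 0.1))
  expect_equal(sum(scn$terminations$selected), 1)
  # partition identity at every offset
  expect_lt(max(abs(scn$terminations$E_slice + scn$terminations$E_att -
                    scn$terminations$E_latt)), 1e-9)
  # the coarse selection achieves the fine-scan optimum |E_att|
  fine <- scan_terminations(di, c(0, 0, 1), 0.01, p, radius = 14)
  expect_equal(abs(scn$selected$E_att), abs(fine$selected$E_att),
               tolerance = 1e-9)
  expect_error(scan_terminations(di, c(0, 0, 1), 0.13, p), "integer")
})

test_that("single-atom bases tie all offsets and break to the smallest", {
  sc <- make_sc_lj(a = 3.5, D0 = 0.2)
  p <- toy_ff_params(sc, cutoff = 4)
  scn <- scan_terminations(sc, c(0, 0, 1), 0.1, p, radius = 5)
  expect_lt(diff(range(scn$terminations$E_att)), 1e-10)
  expect_equal(scn$selected$offset, 0)
})

test_that("BFDH ranks faces by d-spacing with symmetry families", {
  cub <- make_sc_lj(a = 4)
  f <- bfdh_faces(cub, 3)
  expect_equal(as.integer(f[1, c("h", "k", "l")]), c(1L, 0L, 0L))
  expect_equal(f$multiplicity[1], 6)

  ortho <- crystal_structure(unit_cell(3, 4, 5),
    data.frame(label = "X1", element = "X", fx = 0, fy = 0, fz = 0,
               charge = 0, type = "X_sc"))
  f2 <- bfdh_faces(ortho, 4)
  expect_equal(f2$d_eff[1:2], c(5, 4))
  expect_equal(as.integer(f2[1, c("h", "k", "l")]), c(0L, 0L, 1L))
  expect_equal(as.integer(f2[2, c("h", "k", "l")]), c(0L, 1L, 0L))

  # monoclinic carrier-like cell: (0 1 0) with b = 21.54 dominates
  lmh <- crystal_structure(unit_cell(4.783, 21.54, 7.7599, 90, 105.911, 90),
    data.frame(label = "X1", element = "X", fx = 0.1, fy = 0.1, fz = 0.1,
               charge = 0, type = "X_sc"),
    ops = list(parse_symop("x,y,z"), parse_symop("-x,y+1/2,-z")))
  f3 <- bfdh_faces(lmh, 5)
  expect_equal(as.integer(f3[1, c("h", "k", "l")]), c(0L, 1L, 0L))
  expect_equal(f3$d_eff[1], 21.54, tolerance = 1e-6)
})

test_that("BFDH centering extinctions replace forbidden faces by allowed multiples", {
  # body-centered toy lattice: (1 0 0) is extinct, effective spacing a/2
  bcc <- crystal_structure(unit_cell(4, 4, 4),
    data.frame(label = "X1", element = "X", fx = 0, fy = 0, fz = 0,
               charge = 0, type = "X_sc"),
    ops = list(parse_symop("x,y,z"), parse_symop("x+1/2,y+1/2,z+1/2")))
  f <- bfdh_faces(bcc, 2)
  i100 <- which(f$h == 1 & f$k == 0 & f$l == 0)
  i110 <- which(f$h == 1 & f$k == 1 & f$l == 0)
  expect_equal(f$d_eff[i110], 4 / sqrt(2), tolerance = 1e-9)  # allowed
  if (length(i100) > 0) expect_equal(f$d_eff[i100], 2, tolerance = 1e-9)
  expect_equal(as.integer(f[1, c("h", "k", "l")]), c(1L, 1L, 0L))
})

test_that("slab construction counts, layers and first-layer probes behave", {
  sc <- make_sc_lj(a = 4)
  s1 <- build_slab(sc, c(0, 0, 1), 0, repeats = c(2, 2), layers = 1)
  expect_equal(n_atoms(s1), 4)
  s2 <- build_slab(sc, c(0, 0, 1), 0, repeats = c(2, 2), layers = 2)
  expect_equal(n_atoms(s2), 8)
  expect_equal(s1$area, 64)   # (4x4) in-plane cell x 2x2 repeats
  expect_error(build_slab(sc, c(0, 0, 1), 0, repeats = c(0, 2), layers = 1),
               ">= 1")
  # all atoms below the cut plane, within one layer of it
  expect_true(all(s1$atoms$z < s1$offset * s1$d_hkl + 1e-9))
  expect_true(all(s1$atoms$z >= s1$offset * s1$d_hkl - s1$d_hkl - 1e-9))

  # molecular slab: first molecular layer only, units never cut
  di <- make_diatomic_molecular(cell = c(6, 6, 14), z = 0.1, second_z = 0.35,
                                charges = c(0.1, -0.1))
  p <- toy_ff_params(di, cutoff = 13)
  scn <- scan_terminations(di, c(0, 0, 1), 0.1, p, radius = 14)
  probe <- build_slab(di, c(0, 0, 1), scn$selected, repeats = c(2, 2),
                      layers = 1)
  expect_equal(n_atoms(probe) %% 2, 0)       # whole diatomics only
  units <- split(probe$atoms$z, probe$atoms$unit)
  expect_true(all(vapply(units, length, integer(1)) == 2))
  zspan <- max(probe$atoms$z) - min(probe$atoms$z)
  expect_lte(zspan, probe$d_hkl + 1e-6)
})

test_that("rugosity is 1 for flat atomic planes and >= 1 always", {
  p <- ff_params(extra = data.frame(type = "F_t", D0 = 0.1, R0 = 3.0),
                 cutoff = 12)
  # dense flat square lattice: fluctuations far below atom radius
  gridxy <- expand.grid(x = seq(0, 10, by = 0.5), y = seq(0, 10, by = 0.5))
  flat <- body(data.frame(element = "X", x = gridxy$x, y = gridxy$y, z = 0,
                          charge = 0, type = "F_t"))
  r <- rugosity(flat, p, grid_resolution = 0.2)
  expect_gte(r, 1)
  expect_equal(as.numeric(r), 1, tolerance = 0.02)

  # any slab: >= 1
  di <- make_diatomic_molecular(cell = c(6, 6, 9))
  pd <- toy_ff_params(di)
  sl <- build_slab(di, c(0, 0, 1), 0, repeats = c(3, 3), layers = 1)
  expect_gte(as.numeric(rugosity(sl, pd, 0.25)), 1)
  expect_error(rugosity(sl, pd, 0), "grid_resolution")
})

test_that("rugosity of a two-level step matches the analytic profile area", {
  # ridge step: two dense plateaus z = 0 and z = h, uniform along y.
  # The height map is flat on each plateau with a quarter-cylinder roll of
  # radius r at the upper edge and a vertical drop of (h - r); its area is
  # W * integral sqrt(1 + p'(x)^2) dx, computed here by fine 1D quadrature
  # of the known envelope profile.
  h <- 2; rad <- 1.5   # R0 = 3
  p <- ff_params(extra = data.frame(type = "F_t", D0 = 0.1, R0 = 2 * rad),
                 cutoff = 12)
  xy <- expand.grid(x = seq(0, 20, by = 0.25), y = seq(0, 10, by = 0.25))
  z <- ifelse(xy$x >= 10, h, 0)
  stepb <- body(data.frame(element = "X", x = xy$x, y = xy$y, z = z,
                           charge = 0, type = "F_t"))
  rug <- rugosity(stepb, p, grid_resolution = 0.1)

  # analytic envelope profile along x (upper plateau edge at x = 10)
  prof <- function(x) {
    ifelse(x >= 10 - rad & x < 10,
           pmax(rad, h + sqrt(pmax(rad^2 - (x - 10)^2, 0))),
           ifelse(x >= 10, h + rad, rad))
  }
  xs <- seq(0, 20, by = 0.001)
  ps <- prof(xs)
  arclen <- sum(sqrt(diff(xs)^2 + diff(ps)^2))
  expected <- arclen / 20
  expect_equal(as.numeric(rug), expected, tolerance = 0.02)
})
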