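test_that("grid construction covers the inflated box and excludes clashes", {
  host <- atom_body(0, 0, 0)
  cfg <- search_config("molecule-molecule", spacing = 1, extents = 5,
                       angle_step = 90, clash_distance = 0)
  g <- build_grid(host, cfg)
  expect_equal(nrow(g), 11^3)
  expect_equal(attr(g, "n_excluded"), 0)

  cfg2 <- search_config("molecule-molecule", spacing = 1, extents = 5,
                        angle_step = 90, clash_distance = 0.5)
  g2 <- build_grid(host, cfg2)
  expect_equal(attr(g2, "n_excluded"), 1)        # only the host position
  expect_false(any(rowSums(abs(g2)) == 0))

  expect_error(build_grid(host, search_config("molecule-molecule",
    spacing = 1, extents = 1, angle_step = 90, clash_distance = 10)),
    "empty")
})

test_that("surface-mode grids sit strictly above the exposed face", {
  sc <- make_sc_lj(a = 4)
  sl <- build_slab(sc, c(0, 0, 1), 0, repeats = c(3, 3), layers = 2)
  cfg <- search_config("molecule-surface", spacing = 1, extents = 4,
                       angle_step = 120, clash_distance = 0)
  g <- build_grid(sl, cfg)
  expect_true(all(g[, 3] > max(sl$atoms$z)))
})

test_that("the LJ dimer search finds -D0 at R0, rotation-invariantly", {
  p <- ff_params(extra = data.frame(type = "X_sc", D0 = 0.2, R0 = 3.0),
                 cutoff = 12)
  host <- atom_body(0, 0, 0)
  probe <- atom_body(0, 0, 0, label = "probe")
  cfg <- search_config("molecule-molecule", spacing = 1, extents = 4,
                       angle_step = 90, clash_distance = 0, top_n = 80)
  res <- systematic_search(host, probe, cfg, p)
  expect_equal(res$poses$total[1], -0.2, tolerance = 1e-12)
  expect_equal(sqrt(sum(res$poses[1, c("tx", "ty", "tz")]^2)), 3)
  # spherically symmetric probe: identical energy across all rotations of
  # the winning grid point
  win <- res$poses$grid_index[1]
  same <- res$poses[res$poses$grid_index == win, ]
  expect_equal(nrow(same), 64)                    # 4^3 rotation triples
  expect_lt(diff(range(same$total)), 1e-14)
})

test_that("ranked output equals the independent brute-force enumerator", {
  set.seed(31)
  p <- toy_types_params()
  for (rep in 1:4) {
    host <- random_body(3, c("T_a", "T_b", "T_c"))
    probe <- random_body(2, c("T_a", "T_c"))
    cfg <- search_config("molecule-molecule", spacing = 2.0, extents = 3,
                         angle_step = 120, clash_distance = 0,
                         top_n = 10000)
    res <- systematic_search(host, probe, cfg, p)
    ref <- brute_force_search(host, probe, cfg, p)
    expect_equal(nrow(res$poses), nrow(ref))
    expect_equal(res$poses$total, ref$total, tolerance = 1e-12)
    expect_equal(res$poses$dispersive, ref$dispersive, tolerance = 1e-12)
    expect_equal(res$poses$electrostatic, ref$electrostatic,
                 tolerance = 1e-12)
    gap <- diff(ref$total) > 1e-12
    sep <- c(TRUE, gap) & c(gap, TRUE)
    expect_equal(res$poses$grid_index[sep], ref$gi[sep])
    expect_equal(res$poses$rot_index[sep], ref$ri[sep])
  }
})

test_that("search results are deterministic and clash counts reconcile", {
  set.seed(32)
  p <- toy_types_params()
  host <- random_body(4, c("T_a", "T_b"))
  probe <- random_body(3, c("T_b", "T_c"))
  cfg <- search_config("molecule-molecule", spacing = 1.5, extents = 3,
                       angle_step = 120, top_n = 25)
  r1 <- systematic_search(host, probe, cfg, p)
  r2 <- systematic_search(host, probe, cfg, p)
  expect_identical(r1$poses, r2$poses)
  expect_identical(r1$histogram, r2$histogram)
  expect_equal(r1$stats$n_scored + r1$stats$n_clash_skipped,
               r1$stats$n_poses)
  # ranking ascending, length capped at top_n
  expect_lte(nrow(r1$poses), 25)
  expect_true(all(diff(r1$poses$total) >= 0))
})

test_that("halving grid spacing and angle step never worsens the best energy", {
  set.seed(33)
  p <- toy_types_params()
  host <- random_body(3, c("T_a", "T_b"))
  probe <- random_body(2, c("T_b", "T_c"))
  best <- c()
  for (lev in 0:2) {
    cfg <- search_config("molecule-molecule", spacing = 2 / 2^lev,
                         extents = 3, angle_step = 120 / 2^lev,
                         clash_distance = 0, top_n = 1)
    best <- c(best, systematic_search(host, probe, cfg, p)$poses$total[1])
  }
  expect_true(all(diff(best) <= 1e-12))
})

test_that("per-atom normalization divides every component consistently", {
  e <- energy_breakdown(dispersive = -6, electrostatic = -3, hbond = -1)
  n <- normalize_per_atom(e, 5)
  expect_equal(n$total, -2)
  expect_equal(n$dispersive, -1.2)
  expect_equal(n$total, n$dispersive + n$electrostatic + n$hbond,
               tolerance = 1e-12)
  expect_equal(normalize_per_atom(e, 1)$total, e$total)
  expect_error(normalize_per_atom(e, 0), ">= 1")
  # search results carry the same normalization
  p <- ff_params(extra = data.frame(type = "X_sc", D0 = 0.2, R0 = 3.0),
                 cutoff = 12)
  host <- atom_body(0, 0, 0)
  probe <- body(data.frame(element = "X", x = c(0, 1.2), y = 0, z = 0,
                           charge = 0, type = "X_sc"), "diatomic")
  cfg <- search_config("molecule-molecule", spacing = 2, extents = 4,
                       angle_step = 180, clash_distance = 0)
  res <- systematic_search(host, probe, cfg, p)
  expect_equal(res$poses$total_per_atom * res$probe_atoms, res$poses$total,
               tolerance = 1e-9)
})

test_that("pose energies match a direct body evaluation at the same placement", {
  set.seed(34)
  p <- toy_types_params()
  host <- random_body(4, c("T_a", "T_b"))
  probe <- random_body(3, c("T_b", "T_c"))
  cfg <- search_config("molecule-molecule", spacing = 2, extents = 3,
                       angle_step = 120, clash_distance = 0, top_n = 3)
  res <- systematic_search(host, probe, cfg, p)
  for (k in 1:3) {
    ps <- res$poses[k, ]
    R <- synthsearch:::.rot_zyx(ps$a1, ps$a2, ps$a3)
    P0 <- as.matrix(probe$atoms[, c("x", "y", "z")])
    P0 <- sweep(P0, 2, colMeans(P0))
    PX <- sweep(P0 %*% t(R), 2, c(ps$tx, ps$ty, ps$tz), "+")
    moved <- probe
    moved$atoms$x <- PX[, 1]; moved$atoms$y <- PX[, 2]; moved$atoms$z <- PX[, 3]
    expect_equal(body_body_energy(host, moved, p)$total, ps$total,
                 tolerance = 1e-9)
  }
})

test_that("the pair matrix schedules, deduplicates and mirrors near-symmetric pairs", {
  set.seed(35)
  p <- toy_types_params()
  A <- random_body(2, c("T_a", "T_b"), label = "A")
  B <- random_body(2, c("T_b", "T_c"), label = "B")
  bodies <- list(A = A, B = B)
  cfg <- search_config("molecule-molecule", spacing = 1.5, extents = 4,
                       angle_step = 120, clash_distance = 0)

  # the 4 + 8 + 4 layout of a two-faces-per-material surface-surface
  # campaign: every ordered combination of two A faces and two B faces
  faces <- c("A", "A", "B", "B")   # stand-ins for A{001}, A{010}, B{010}, B{011}
  specs <- expand.grid(host = c("A", "B"), probe = c("A", "B"),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(specs), 4)
  # single self pair
  one <- pair_matrix(data.frame(host = "A", probe = "A"), bodies, cfg, p)
  expect_equal(length(one$results), 1)
  # duplicates collapse with a warning
  expect_warning(
    two <- pair_matrix(data.frame(host = c("A", "A"), probe = c("A", "A")),
                       bodies, cfg, p),
    "duplicate")
  expect_equal(length(two$results), 1)
  expect_error(pair_matrix(data.frame(host = "A", probe = "Z"), bodies,
                           cfg, p), "Z")

  # both orderings of a finite pair on symmetric grids agree closely
  mat <- pair_matrix(specs, bodies, cfg, p)
  tab <- mat$table
  ab <- tab$best_total[tab$host == "A" & tab$probe == "B"]
  ba <- tab$best_total[tab$host == "B" & tab$probe == "A"]
  expect_equal(ab, ba, tolerance = 0.15)
})

test_that("a Table-1-style 16-search campaign is scheduled in full", {
  specs <- rbind(
    expand.grid(host = c("API{001}", "API{010}"),
                probe = c("API{001}", "API{010}"),
                stringsAsFactors = FALSE),                 # 4 cohesive API
    data.frame(host = c("API{001}", "EXC{010}", "API{001}", "EXC{011}",
                        "API{010}", "EXC{010}", "API{010}", "EXC{011}"),
               probe = c("EXC{010}", "API{001}", "EXC{011}", "API{001}",
                         "EXC{010}", "API{010}", "EXC{011}", "API{010}")),
    expand.grid(host = c("EXC{010}", "EXC{011}"),
                probe = c("EXC{010}", "EXC{011}"),
                stringsAsFactors = FALSE))                 # 4 cohesive EXC
  expect_equal(nrow(specs), 16)
  set.seed(36)
  p <- toy_types_params()
  bods <- list()
  for (nm in c("API{001}", "API{010}", "EXC{010}", "EXC{011}")) {
    bods[[nm]] <- random_body(2, c("T_a", "T_b"), label = nm)
  }
  cfg <- search_config("molecule-molecule", spacing = 3, extents = 3,
                       angle_step = 180, clash_distance = 0)
  mat <- pair_matrix(specs, bods, cfg, p)
  expect_equal(length(mat$results), 16)
  expect_equal(nrow(mat$table), 16)
})

test_that("an oversized probe is rejected", {
  p <- toy_types_params()
  host <- atom_body(0, 0, 0, type = "T_a")
  big <- body(data.frame(element = "X", x = seq(0, 30, by = 5), y = 0, z = 0,
                         charge = 0, type = "T_a"), "rod")
  cfg <- search_config("molecule-molecule", spacing = 2, extents = 2,
                       angle_step = 180)
  expect_error(systematic_search(host, big, cfg, p), "larger")
})
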