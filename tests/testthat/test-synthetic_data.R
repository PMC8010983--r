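test_that("flat bilayer plants its thickness, area and leaflets exactly at zero noise", {
  mb <- make_flat_bilayer(nx = 10, ny = 10, thickness = 38, z_noise = 0, seed = 1)
  tp <- thickness_profile(mb$frame, mb$topology)
  expect_true(all(abs(tp$thickness - 38) < 1e-9))
  hf <- height_field(mb$frame, mb$topology)
  expect_equal(surface_area(hf), prod(mb$frame$box[1:2]))
  lf <- assign_leaflets(mb$frame, mb$topology)
  heads <- select_atoms(mb$topology, role = "lipid_head")
  expect_setequal(lf$upper, heads[mb$frame$coords[heads, 3] > 0])
})

test_that("generators are pure functions of their seed", {
  a <- make_flat_bilayer(nx = 6, ny = 6, z_noise = 1, seed = 7)
  b <- make_flat_bilayer(nx = 6, ny = 6, z_noise = 1, seed = 7)
  expect_identical(a$frame$coords, b$frame$coords)
  c1 <- make_planted_clusters(2, c(3, 4), seed = 5, jitter = 0.2)
  c2 <- make_planted_clusters(2, c(3, 4), seed = 5, jitter = 0.2)
  expect_identical(c1$frame$coords, c2$frame$coords)
  expect_warning(make_flat_bilayer(nx = 4, ny = 4, thickness = 3, z_noise = 2),
                 "interpenetrate")
})

test_that("noisy flat bilayer reproduces its planted thickness within sampling error", {
  mb <- make_flat_bilayer(nx = 16, ny = 16, thickness = 38, z_noise = 1, seed = 1)
  tp <- thickness_profile(mb$frame, mb$topology, bin = 8)
  # mean thickness estimator: SE = sqrt(2) * sigma / sqrt(N heads)
  se <- sqrt(2) * 1 / sqrt(16 * 16)
  expect_lt(abs(mean(tp$thickness) - 38), 3 * se)
})

test_that("bent bilayer degenerates to flat at zero amplitude and validates the wavelength", {
  fl <- make_flat_bilayer(nx = 6, ny = 6, z_noise = 0, lz_pad = 30)
  bt <- make_bent_bilayer(amplitude = 0, wavelength = 48, nx = 6, ny = 6,
                          z_noise = 0)
  expect_equal(bt$frame$coords, fl$frame$coords, ignore_attr = TRUE)
  expect_error(make_bent_bilayer(amplitude = 5, wavelength = 37, nx = 6, ny = 6),
               "invalid geometry")
})

test_that("bent bilayer attaches quadrature ground truth for area and bending", {
  bb <- make_bent_bilayer(amplitude = 5, wavelength = 96, nx = 24, ny = 12,
                          lattice = 4)
  orc <- sinusoid_oracles(5, 96, bb$frame$box[2])
  expect_equal(bb$truth$area, orc$area, tolerance = 1e-8)
  expect_equal(bb$truth$bend_per_kc, orc$bend_per_kc, tolerance = 1e-8)
})

test_that("planted clusters give exactly the planted partition and reject bad gaps", {
  pc <- make_planted_clusters(3, c(5, 10, 15), seed = 1)
  cs <- find_clusters(pc$frame, pc$topology)
  expect_equal(sort(cs$sizes), c(5, 10, 15))
  expect_error(make_planted_clusters(2, c(3, 3), intra_spacing = 2, inter_gap = 6),
               "invalid geometry")
})

test_that("ellipsoid and rod clouds carry the closed-form shape ground truth", {
  pe <- make_planted_clusters(1, 60, atoms_per_molecule = 20L,
                              intra_spacing = 1.5, shape = "ellipsoid",
                              semiaxes = c(20, 10, 10), seed = 2)
  expect_equal(pe$truth$expected_kappa, sqrt(0.4))
  sh <- cluster_shape(pe$frame, pe$topology,
                      unique(pe$topology$atoms$molecule_id))
  expect_equal(sh$kappa, sqrt(0.4), tolerance = 0.01)
  pr <- make_planted_clusters(1, 40, atoms_per_molecule = 10L,
                              intra_spacing = 1.5, shape = "rod", aspect = 20,
                              seed = 3)
  shr <- cluster_shape(pr$frame, pr$topology,
                       unique(pr$topology$atoms$molecule_id))
  expect_lt(shr$kappa, 0.2)
})

test_that("biased window samples recover the Gaussian limit for a flat PMF", {
  ds <- suppressWarnings(sample_biased_windows(function(x) 0, centers = c(10),
                                               k = 20, n_per_window = 50000L,
                                               seed = 4))
  s <- ds$windows[[1]]$samples
  kT <- sim_constants(310)$kT
  expect_equal(mean(s), 10, tolerance = 0.01)
  expect_equal(stats::var(s), kT / 20, tolerance = 0.02)
  # a single draw per window is a valid (noisy) dataset and WHAM still runs
  ds1 <- suppressWarnings(sample_biased_windows(double_well,
                                                centers = seq(45, 60, 1),
                                                k = 2, n_per_window = 1L,
                                                seed = 5))
  expect_s3_class(wham_solve(ds1), "WhamResult")
})

test_that("scripted hydrogen-bond trajectories record their realized occupancy", {
  tr1 <- make_hbond_script(20, n_pairs = 2L, occupancy = 1, seed = 1)
  expect_equal(tr1$truth$realized, c(1, 1))
  tr0 <- make_hbond_script(20, n_pairs = 2L, occupancy = 0, seed = 1)
  expect_equal(tr0$truth$realized, c(0, 0))
  tr <- make_hbond_script(1000, n_pairs = 3L, occupancy = 0.4, seed = 7)
  expect_equal(tr$truth$realized, colMeans(tr$truth$bonded))
  expect_error(make_hbond_script(5, n_pairs = 1L, occupancy = 1.2), "occupancy")
})
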