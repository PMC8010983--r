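test_that("flat membrane: exact thickness, planar area, zero bending energy", {
  mb <- make_flat_bilayer(nx = 10, ny = 10, thickness = 38, z_noise = 0)
  hf <- height_field(mb$frame, mb$topology)
  expect_true(all(abs(hf$thickness - 38) < 1e-9))
  expect_equal(surface_area(hf), prod(mb$frame$box[1:2]))
  expect_true(all(abs(hf$H) < 1e-12))
  expect_equal(bending_energy(hf)$F_bend, 0)
  tp <- thickness_profile(mb$frame, mb$topology, axis = "y", bin = 8)
  expect_true(all(abs(tp$thickness - 38) < 1e-9))
})

test_that("leaflet assignment matches generator labels, bent or flat", {
  bb <- make_bent_bilayer(amplitude = 5, wavelength = 96, nx = 12, ny = 6)
  lf <- assign_leaflets(bb$frame, bb$topology)
  heads <- select_atoms(bb$topology, role = "lipid_head")
  mols <- bb$topology$atoms$molecule_id[heads]
  want_upper <- heads[bb$truth$leaflet[mols] == "upper"]
  expect_setequal(lf$upper, want_upper)
  expect_false(any(lf$uncovered))
})

test_that("a single-leaflet sheet flags every node as uncovered", {
  mb <- make_flat_bilayer(nx = 6, ny = 6, z_noise = 0.2, seed = 1)
  heads <- select_atoms(mb$topology, role = "lipid_head")
  upper_only <- heads[mb$frame$coords[heads, 3] > 0]
  lf <- assign_leaflets(mb$frame, mb$topology, head_sel = upper_only)
  expect_true(all(lf$uncovered))
})

test_that("a planted indentation shows up in the thickness profile", {
  mb <- make_flat_bilayer(nx = 12, ny = 12, thickness = 38, z_noise = 0)
  co <- mb$frame$coords
  heads <- select_atoms(mb$topology, role = "lipid_head")
  zone <- co[, 2] > 32 & co[, 2] <= 64 & co[, 3] > 0   # upper leaflet band
  co[zone, 3] <- co[zone, 3] - 10
  fr <- particle_frame(co, mb$frame$box)
  tp <- thickness_profile(fr, mb$topology, axis = "y", bin = 8)
  inz <- tp$center > 32 & tp$center <= 64
  expect_true(all(abs(tp$thickness[inz] - 28) < 1e-9))
  expect_true(all(abs(tp$thickness[!inz] - 38) < 1e-9))
})

test_that("per-bin thickness noise propagates as sqrt(2) sigma / sqrt(N)", {
  reps <- vapply(1:40, function(s) {
    mb <- make_flat_bilayer(nx = 12, ny = 12, thickness = 38, z_noise = 1,
                            seed = s)
    thickness_profile(mb$frame, mb$topology, axis = "y", bin = 96)$thickness
  }, numeric(1))
  # one bin holding all 144 lipids per leaflet
  expect_equal(stats::sd(reps), sqrt(2) * 1 / sqrt(144), tolerance = 0.35)
})

test_that("sinusoid area and bending match quadrature oracles within 1%", {
  A <- 5; L <- 96; box <- c(96, 48, 100)
  orc <- sinusoid_oracles(A, L, box[2])
  hf <- synthetic_height_field(function(x, y) A * sin(2 * pi * x / L), box,
                               spacing = 8)
  expect_equal(surface_area(hf), orc$area, tolerance = 0.01)
  expect_equal(bending_energy(hf, k_c = 1)$F_bend, orc$bend_per_kc,
               tolerance = 0.01)
  # curvature against the closed form H(x) everywhere, crest included
  hf2 <- synthetic_height_field(function(x, y) A * sin(2 * pi * x / L), box,
                                spacing = 2)
  k <- 2 * pi / L
  Hc <- function(x) -A * k^2 * sin(k * x) / (2 * (1 + (A * k * cos(k * x))^2)^1.5)
  expect_equal(hf2$H[, 1], Hc(hf2$x), tolerance = 1e-3, ignore_attr = TRUE)
  # at the crest itself z_x = 0, so H reduces to z_xx / 2
  expect_equal(Hc(L / 4), -A * k^2 / 2)
})

test_that("grid refinement converges for smooth surfaces", {
  A <- 5; L <- 96; box <- c(96, 48, 100)
  zf <- function(x, y) A * sin(2 * pi * x / L)
  a1 <- surface_area(synthetic_height_field(zf, box, spacing = 8))
  a2 <- surface_area(synthetic_height_field(zf, box, spacing = 4))
  expect_lt(abs(a2 / a1 - 1), 0.002)
  f1 <- bending_energy(synthetic_height_field(zf, box, spacing = 8), k_c = 1)$F_bend
  f2 <- bending_energy(synthetic_height_field(zf, box, spacing = 4), k_c = 1)$F_bend
  expect_lt(abs(f2 / f1 - 1), 0.005)
})

test_that("bent-bilayer particle fixture recovers analytic area and bending", {
  bb <- make_bent_bilayer(amplitude = 5, wavelength = 96, nx = 24, ny = 12,
                          lattice = 4)
  hf <- height_field(bb$frame, bb$topology, spacing = 8)
  expect_equal(surface_area(hf), bb$truth$area, tolerance = 0.005)
  expect_equal(bending_energy(hf, k_c = 1)$F_bend, bb$truth$bend_per_kc,
               tolerance = 0.05)
})

test_that("sphere test mesh gives the closed-form 8 pi k_c at any radius", {
  for (R in c(10, 30, 100)) {
    sm <- sphere_test_mesh(R)
    expect_equal(bending_energy(sm, k_c = 1)$F_bend, 8 * pi, tolerance = 1e-9)
    expect_equal(sum(sm$dA), 4 * pi * R^2, tolerance = 1e-9)
  }
})

test_that("bending energy is linear in k_c, non-negative, translation invariant", {
  bb <- make_bent_bilayer(amplitude = 4, wavelength = 48, nx = 12, ny = 6)
  hf <- height_field(bb$frame, bb$topology, spacing = 8)
  f1 <- bending_energy(hf, k_c = 10)$F_bend
  f2 <- bending_energy(hf, k_c = 20)$F_bend
  expect_equal(f2, 2 * f1)
  expect_gte(f1, 0)
  expect_error(bending_energy(hf, k_c = -1), "positive")
  # rigid in-plane translation
  co <- bb$frame$coords
  co[, 1] <- (co[, 1] + 13.7) %% bb$frame$box[1]
  hft <- height_field(particle_frame(co, bb$frame$box), bb$topology, spacing = 8)
  expect_equal(surface_area(hft), surface_area(hf), tolerance = 1e-6)
  expect_equal(bending_energy(hft, k_c = 10)$F_bend, f1, tolerance = 1e-6)
})
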