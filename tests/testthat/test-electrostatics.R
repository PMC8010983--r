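ion_system <- function(pos, q, box = c(20, 20, 20)) {
  n <- length(q)
  top <- system_topology(mass = rep(12, n), charge = q,
                         molecule_id = seq_len(n), role = rep("ion", n))
  list(topology = top, frame = particle_frame(matrix(pos, ncol = 3), box))
}

test_that("charge smearing conserves total charge and handles empty systems", {
  sys <- ion_system(rbind(c(7, 10, 10), c(13, 10, 10)), c(1, -1))
  cg <- smear_charges(sys$frame, sys$topology, spacing = 0.5, sigma = 1)
  expect_lt(abs(cg$total_charge), 1e-12)
  cg1 <- smear_charges(sys$frame, sys$topology, spacing = 0.5, sigma = 1, sel = 1L)
  expect_equal(cg1$total_charge, 1, tolerance = 1e-9)
  none <- ion_system(c(5, 5, 5), 0)
  cg0 <- smear_charges(none$frame, none$topology)
  expect_true(all(cg0$rho == 0))
  expect_warning(smear_charges(sys$frame, sys$topology, spacing = 2, sigma = 1),
                 "aliased")
  expect_error(smear_charges(sys$frame, sys$topology, sigma = -1), "positive")
})

test_that("zero density gives zero potential; dipole potential is antisymmetric", {
  none <- ion_system(c(5, 5, 5), 0)
  pg0 <- solve_poisson_periodic(smear_charges(none$frame, none$topology))
  expect_true(all(pg0$phi == 0))

  sys <- ion_system(rbind(c(7, 10, 10), c(13, 10, 10)), c(1, -1))
  pg <- solve_poisson_periodic(smear_charges(sys$frame, sys$topology,
                                             spacing = 0.5, sigma = 1))
  expect_lt(abs(mean(pg$phi)), 1e-12)           # zero-k mode removed
  # inversion through the dipole centre (10,10,10) flips the sign
  set.seed(1)
  pr <- matrix(runif(30, 2, 18), ncol = 3)
  v1 <- potential_at(pg, pr)
  v2 <- potential_at(pg, sweep(-pr, 2, c(20, 20, 20), "+"))
  expect_equal(v2, -v1, tolerance = 1e-6)
})

test_that("the spectral solve matches the direct Ewald sum to well under 0.1%", {
  box <- c(20, 20, 20)
  pos <- rbind(c(7, 10, 10), c(13, 10, 10)); q <- c(1, -1)
  sys <- ion_system(pos, q, box)
  pg <- solve_poisson_periodic(smear_charges(sys$frame, sys$topology,
                                             spacing = 0.5, sigma = 1))
  probes <- rbind(c(5, 10, 10), c(10, 14, 10), c(3, 3, 3), c(16, 10, 10),
                  c(10, 6, 13), c(14, 14, 14))
  num <- potential_at(pg, probes)
  ref <- ewald_reference_potential(q, pos, box, sg = 1, probes)
  expect_lt(max(abs(num - ref)) / max(abs(ref)), 1e-3)
})

test_that("a net charge is neutralized by a uniform background, matching Ewald", {
  box <- c(20, 20, 20)
  pos <- matrix(c(10, 10, 10), 1); q <- 1
  sys <- ion_system(pos, q, box)
  expect_warning(pg <- solve_poisson_periodic(
    smear_charges(sys$frame, sys$topology, spacing = 0.5, sigma = 1)),
    "neutralizing background")
  probes <- rbind(c(5, 10, 10), c(3, 3, 3), c(14, 10, 10))
  ref <- ewald_reference_potential(q, pos, box, sg = 1, probes)
  expect_lt(max(abs(potential_at(pg, probes) - ref)) / max(abs(ref)), 1e-3)
})

test_that("the solver is linear and translation-equivariant on the grid", {
  box <- c(16, 16, 16)
  a <- ion_system(rbind(c(4, 8, 8), c(12, 8, 8)), c(1, -1), box)
  b <- ion_system(rbind(c(8, 4, 8), c(8, 12, 8)), c(0.5, -0.5), box)
  both <- ion_system(rbind(c(4, 8, 8), c(12, 8, 8), c(8, 4, 8), c(8, 12, 8)),
                     c(1, -1, 0.5, -0.5), box)
  solve1 <- function(s) solve_poisson_periodic(
    smear_charges(s$frame, s$topology, spacing = 0.5, sigma = 1))
  expect_equal(solve1(both)$phi, solve1(a)$phi + solve1(b)$phi,
               tolerance = 1e-10)
  # shift by exactly one grid cell along x
  sh <- ion_system(rbind(c(4.5, 8, 8), c(12.5, 8, 8)), c(1, -1), box)
  pa <- solve1(a)$phi; ps <- solve1(sh)$phi
  n <- dim(pa)[1]
  rolled <- pa[c(n, 1:(n - 1)), , ]
  expect_equal(ps, rolled, tolerance = 1e-9)
})

test_that("slice maps average slabs and frames correctly", {
  box <- c(16, 16, 16)
  sys <- ion_system(rbind(c(4, 8, 8), c(12, 8, 8)), c(1, -1), box)
  pg <- solve_poisson_periodic(smear_charges(sys$frame, sys$topology,
                                             spacing = 1, sigma = 1.2))
  full <- slice_map(pg, axis = "z", slab = box[3])
  expect_equal(full$map, apply(pg$phi, c(1, 2), mean), tolerance = 1e-12)
  two <- slice_map(list(pg, pg), axis = "z", slab = 4)
  one <- slice_map(pg, axis = "z", slab = 4)
  expect_equal(two$map, one$map)
  expect_error(slice_map(pg, axis = "z", offset = 100, slab = 2), "outside")
})

test_that("the planted surface dipole makes the membrane positive against the water", {
  mb <- make_flat_bilayer(nx = 8, ny = 8, z_noise = 0, lz_pad = 13)
  # membrane centred at z = 0: shift into [0, Lz) for the grid
  co <- mb$frame$coords; box <- mb$frame$box
  co[, 3] <- co[, 3] + box[3] / 2
  fr <- particle_frame(co, box)
  pg <- solve_poisson_periodic(smear_charges(fr, mb$topology,
                                             spacing = 1, sigma = 1.5))
  prof <- apply(pg$phi, 3, mean)                 # z-profile of the potential
  zs <- (seq_len(dim(pg$phi)[3]) - 1L) * pg$spacing[3]
  membrane <- which(abs(zs - box[3] / 2) < 16)
  water <- which(zs < 6 | zs > box[3] - 6)
  expect_gt(mean(prof[membrane]), mean(prof[water]))
  # the same structure shows in a slab-averaged slice map through the box
  sl <- slice_map(pg, axis = "y", slab = box[2])
  zprof <- colMeans(sl$map)
  expect_gt(mean(zprof[membrane]), mean(zprof[water]))
})
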