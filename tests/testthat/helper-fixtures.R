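# shared fixtures and independent oracles, all built in code at test time

# 12 icosahedron vertices: an exactly spherically symmetric equal-mass set
icosahedron_system <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(cbind(0, c(1, 1, -1, -1), c(phi, -phi, phi, -phi)),
             cbind(c(1, 1, -1, -1), c(phi, -phi, phi, -phi), 0),
             cbind(c(phi, -phi, phi, -phi), 0, c(1, 1, -1, -1)))
  top <- system_topology(mass = rep(1, 12), molecule_id = rep(1L, 12),
                         role = rep("drug", 12))
  list(topology = top,
       frame = particle_frame(v + 50, c(100, 100, 100)))
}

# double-well PMF: minima at 40 and 64 A, 3 kcal/mol barrier at 52 A
double_well <- function(x) 3 * (((x - 52) / 12)^2 - 1)^2

# random multi-molecule frame for cluster oracle comparisons
random_molecule_frame <- function(n_molecules, atoms_per_molecule = 3L,
                                  box = c(40, 40, 40), seed = 1) {
  set.seed(seed)
  com <- cbind(runif(n_molecules, 0, box[1]), runif(n_molecules, 0, box[2]),
               runif(n_molecules, 0, box[3]))
  coords <- do.call(rbind, lapply(seq_len(n_molecules), function(m)
    sweep(matrix(rnorm(atoms_per_molecule * 3, 0, 1), ncol = 3), 2,
          com[m, ], "+")))
  n <- n_molecules * atoms_per_molecule
  top <- system_topology(mass = rep(12, n),
                         molecule_id = rep(seq_len(n_molecules),
                                           each = atoms_per_molecule),
                         role = rep("drug", n))
  list(topology = top, frame = particle_frame(coords, box))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Independent Ewald-sum reference for the periodic potential of Gaussian
# charges (width sg): short-range erf-difference over images, direct
# reciprocal sum with splitting width ss, tinfoil boundary, box mean removed
# to match the spectral solver's zero-mode convention. Output in volts.
ewald_reference_potential <- function(charges, pos, box, sg, probes, ss = 2.0) {
  V <- prod(box)
  probes <- matrix(probes, ncol = 3L)
  phi <- numeric(nrow(probes))
  for (j in seq_along(charges)) {
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      d <- sweep(probes, 2, pos[j, ] + c(ix, iy, iz) * box)
      r <- sqrt(rowSums(d^2))
      term <- ifelse(r < 1e-9, sqrt(2 / pi) * (1 / sg - 1 / ss),
                     (erf(r / (sqrt(2) * sg)) - erf(r / (sqrt(2) * ss))) /
                       pmax(r, 1e-9))
      phi <- phi + charges[j] * term
    }
  }
  mmax <- ceiling(sqrt(2 * 34) / ss * max(box) / (2 * pi))
  ms <- as.matrix(expand.grid(-mmax:mmax, -mmax:mmax, -mmax:mmax))
  ms <- ms[rowSums(ms^2) > 0, , drop = FALSE]
  kx <- 2 * pi * ms[, 1] / box[1]; ky <- 2 * pi * ms[, 2] / box[2]
  kz <- 2 * pi * ms[, 3] / box[3]
  k2 <- kx^2 + ky^2 + kz^2
  keep <- ss^2 * k2 / 2 < 34
  kx <- kx[keep]; ky <- ky[keep]; kz <- kz[keep]; k2 <- k2[keep]
  Sk <- vapply(seq_along(k2), function(i)
    sum(charges * exp(-1i * (kx[i] * pos[, 1] + ky[i] * pos[, 2] +
                               kz[i] * pos[, 3]))), complex(1))
  for (p in seq_len(nrow(probes))) {
    ph <- exp(1i * (kx * probes[p, 1] + ky * probes[p, 2] + kz * probes[p, 3]))
    phi[p] <- phi[p] + Re(sum(4 * pi / (V * k2) * exp(-ss^2 * k2 / 2) * Sk * ph))
  }
  (phi - sum(charges) * 2 * pi * (ss^2 - sg^2) / V) * 14.3996
}

# quadrature oracles for the sinusoidal mid-surface z = A sin(2 pi x / L)
sinusoid_oracles <- function(A, L, Ly) {
  zx <- function(x) A * (2 * pi / L) * cos(2 * pi * x / L)
  zxx <- function(x) -A * (2 * pi / L)^2 * sin(2 * pi * x / L)
  H <- function(x) zxx(x) / (2 * (1 + zx(x)^2)^(3 / 2))
  list(area = Ly * stats::integrate(function(x) sqrt(1 + zx(x)^2), 0, L,
                                    rel.tol = 1e-12)$value,
       bend_per_kc = Ly * stats::integrate(function(x)
         0.5 * (2 * H(x))^2 * sqrt(1 + zx(x)^2), 0, L,
         rel.tol = 1e-12)$value)
}

# single donor-H-acceptor triplet at a controlled D-A distance and D-H-A angle
hb_system <- function(d_da, angle_deg) {
  th <- (180 - angle_deg) * pi / 180
  u <- c(cos(th), sin(th), 0)
  tpos <- max(Re(polyroot(c(1 - d_da^2, 2 * u[1], 1))))
  A <- c(1, 0, 0) + tpos * u
  top <- system_topology(mass = c(14, 1, 16), charge = c(-0.3, 0.3, -0.5),
                         molecule_id = c(1L, 1L, 2L),
                         residue_name = c("LYS", "LYS", "POPC"),
                         role = c("peptide", "peptide", "lipid_head"),
                         is_donor_heavy = c(TRUE, FALSE, FALSE),
                         is_polar_hydrogen = c(FALSE, TRUE, FALSE),
                         is_acceptor = c(FALSE, FALSE, TRUE),
                         donor_of = c(NA, 1L, NA))
  fr <- particle_frame(rbind(c(0, 0, 0), c(1, 0, 0), A) + 25, c(50, 50, 50))
  list(topology = top, frame = fr)
}
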