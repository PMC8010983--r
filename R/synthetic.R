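#' Synthetic flat bilayer with labelled head and tail particles
#'
#' Builds a coarse toy bilayer: each lipid is three particles (one
#' `lipid_head`, two `lipid_tail`) on an nx-by-ny lattice per leaflet, head
#' planes at +/- thickness/2. Head particles carry -0.5 e and the adjacent
#' tail particle +0.5 e, a surface dipole pointing inward on both leaflets
#' that leaves the membrane interior electrostatically positive relative to
#' the surrounding space (a toy membrane dipole potential); heads are
#' flagged H-bond acceptors.
#' Ground truth (planted thickness, planar area, per-molecule leaflet labels)
#' is attached as `$truth`.
#'
#' @param nx,ny lipids per leaflet along x and y (>= 2).
#' @param lattice in-plane lattice constant (angstrom).
#' @param thickness head-to-head distance (angstrom); the study membrane is
#'   about 38 A thick.
#' @param z_noise Gaussian sigma added to every particle z (angstrom).
#' @param seed RNG seed; output is a pure function of the arguments.
#' @param lz_pad solvent clearance added above and below (angstrom).
#' @return list with `topology`, `frame`, `truth`.
#' @export
make_flat_bilayer <- function(nx = 12, ny = 12, lattice = 8, thickness = 38,
                              z_noise = 0.5, seed = 1, lz_pad = 21) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  if (thickness <= 0) stop("thickness must be positive")
  if (z_noise < 0) stop("z_noise must be >= 0")
  if (thickness <= 2 * z_noise)
    warning("thickness <= 2*z_noise: leaflets may interpenetrate")
  box <- c(nx * lattice, ny * lattice, thickness + 2 * lz_pad)
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  xy <- cbind(g$i * lattice + lattice / 2, g$j * lattice + lattice / 2)
  n_lip_leaf <- nrow(xy)

  build_leaflet <- function(sign) {
    zc <- 0                              # membrane mid-plane at z = 0
    zs <- c(thickness / 2, thickness / 4, thickness / 12) * sign
    co <- do.call(rbind, lapply(seq_len(n_lip_leaf), function(l)
      cbind(rep(xy[l, 1], 3), rep(xy[l, 2], 3), zc + zs)))
    co
  }
  coords <- rbind(build_leaflet(+1), build_leaflet(-1))
  n_lip <- 2L * n_lip_leaf
  set.seed(seed)
  if (z_noise > 0) coords[, 3] <- coords[, 3] + stats::rnorm(nrow(coords), 0, z_noise)

  role <- rep(c("lipid_head", "lipid_tail", "lipid_tail"), n_lip)
  top <- system_topology(
    mass = rep(c(94.97, 60, 60), n_lip),
    charge = rep(c(-0.5, 0.5, 0), n_lip),
    molecule_id = rep(seq_len(n_lip), each = 3L),
    residue_name = rep("POPC", 3L * n_lip),
    role = role,
    is_acceptor = role == "lipid_head",
    atom_name = rep(c("P", "C1", "C2"), n_lip)
  )
  frame <- particle_frame(coords, box, time = 0, index = 0L)
  truth <- list(kind = "flat_bilayer", thickness = thickness,
                area = box[1] * box[2],
                leaflet = rep(c("upper", "lower"), each = n_lip_leaf),
                n_lipids = n_lip, z_noise = z_noise)
  list(topology = top, frame = frame, truth = truth)
}

#' Synthetic sinusoidally bent bilayer with analytic ground truth
#'
#' Mid-surface z(x) = amplitude * sin(2*pi*x / wavelength), constant
#' thickness measured along the local surface normal. The wavelength must
#' divide the box length so the sheet is periodically continuous. Attached
#' ground truth: mid-surface area and Helfrich bending energy per unit
#' bending rigidity, both computed by 1D quadrature of the closed-form
#' integrands.
#'
#' @inheritParams make_flat_bilayer
#' @param amplitude sine amplitude (angstrom); 0 degenerates to the flat case.
#' @param wavelength sine wavelength (angstrom).
#' @return list with `topology`, `frame`, `truth` (`area`, `bend_per_kc`).
#' @export
make_bent_bilayer <- function(amplitude, wavelength, nx = 12, ny = 12,
                              lattice = 8, thickness = 38, z_noise = 0,
                              seed = 1, lz_pad = 30) {
  box_x <- nx * lattice
  ncyc <- box_x / wavelength
  if (abs(ncyc - round(ncyc)) > 1e-8)
    stop("invalid geometry: wavelength must divide the box length Lx = ", box_x)
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2")
  kx <- 2 * pi / wavelength
  zmid <- function(x) amplitude * sin(kx * x)
  zx   <- function(x) amplitude * kx * cos(kx * x)
  zxx  <- function(x) -amplitude * kx^2 * sin(kx * x)

  box <- c(box_x, ny * lattice, thickness + 2 * amplitude + 2 * lz_pad)
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  xs <- g$i * lattice + lattice / 2
  ys <- g$j * lattice + lattice / 2
  n_lip_leaf <- length(xs)

  build_leaflet <- function(sign) {
    zs_off <- c(thickness / 2, thickness / 4, thickness / 12) * sign
    nrm <- cbind(-zx(xs), 0, 1) / sqrt(1 + zx(xs)^2)
    do.call(rbind, lapply(seq_len(n_lip_leaf), function(l) {
      base <- c(xs[l], ys[l], zmid(xs[l]))
      t(vapply(zs_off, function(h) base + h * c(nrm[l, 1], 0, nrm[l, 3]),
               numeric(3)))
    }))
  }
  coords <- rbind(build_leaflet(+1), build_leaflet(-1))
  n_lip <- 2L * n_lip_leaf
  set.seed(seed)
  if (z_noise > 0) coords[, 3] <- coords[, 3] + stats::rnorm(nrow(coords), 0, z_noise)

  role <- rep(c("lipid_head", "lipid_tail", "lipid_tail"), n_lip)
  top <- system_topology(
    mass = rep(c(94.97, 60, 60), n_lip),
    charge = rep(c(-0.5, 0.5, 0), n_lip),
    molecule_id = rep(seq_len(n_lip), each = 3L),
    residue_name = rep("POPC", 3L * n_lip),
    role = role,
    is_acceptor = role == "lipid_head",
    atom_name = rep(c("P", "C1", "C2"), n_lip)
  )
  frame <- particle_frame(coords, box, time = 0, index = 0L)

  # quadrature oracles on the closed-form mid-surface
  area <- box[2] * stats::integrate(function(x) sqrt(1 + zx(x)^2),
                                    0, box[1], subdivisions = 2000L,
                                    rel.tol = 1e-10)$value
  Hfun <- function(x) zxx(x) / (2 * (1 + zx(x)^2)^(3 / 2))
  bend_per_kc <- box[2] * stats::integrate(function(x)
    0.5 * (2 * Hfun(x))^2 * sqrt(1 + zx(x)^2),
    0, box[1], subdivisions = 2000L, rel.tol = 1e-10)$value

  truth <- list(kind = "bent_bilayer", thickness = thickness,
                amplitude = amplitude, wavelength = wavelength,
                area = area, bend_per_kc = bend_per_kc,
                leaflet = rep(c("upper", "lower"), each = n_lip_leaf),
                zmid = zmid, n_lipids = n_lip)
  list(topology = top, frame = frame, truth = truth)
}

# radially sorted cubic-lattice fill of an ellipsoid; connected at spacing h
ellipsoid_lattice <- function(n_points, semiaxes, h) {
  vol_per_pt <- (4 / 3) * pi * prod(semiaxes) / n_points
  scale0 <- 1
  repeat {
    ax <- semiaxes * scale0
    rng <- lapply(ax, function(a) seq(-ceiling(a / h) * h, ceiling(a / h) * h, by = h))
    g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    r2 <- (g[, 1] / ax[1])^2 + (g[, 2] / ax[2])^2 + (g[, 3] / ax[3])^2
    inside <- which(r2 <= 1)
    if (length(inside) >= n_points) {
      ord <- inside[order(r2[inside])]
      return(g[ord[seq_len(n_points)], , drop = FALSE])
    }
    scale0 <- scale0 * 1.15
  }
}

#' Synthetic multi-molecule system with planted contact clusters
#'
#' Places `n_clusters` groups of drug-role molecules so that the 4.5-angstrom
#' contact graph has exactly the planted components: atoms within a cluster
#' sit on a cubic lattice of spacing `intra_spacing` (guaranteeing
#' connectivity), and clusters are separated by `inter_gap`, which must
#' exceed the contact cutoff plus the lattice spacing.
#'
#' @param n_clusters number of planted clusters.
#' @param molecules_per_cluster integer vector of length `n_clusters`.
#' @param atoms_per_molecule atoms in each molecule.
#' @param intra_spacing lattice spacing inside a cluster (angstrom).
#' @param inter_gap minimum separation between cluster extents (angstrom);
#'   must exceed 4.5 + intra_spacing.
#' @param shape `"blob"` (sphere), `"rod"` (elongated ellipsoid of the given
#'   `aspect`), or `"ellipsoid"` with `semiaxes` giving the a:b:c ratio.
#' @param semiaxes length-3 semi-axis ratio for `shape = "ellipsoid"`.
#' @param aspect long/short axis ratio for `shape = "rod"`.
#' @param with_donors if TRUE each molecule gains an amide-like N-H donor
#'   pair next to its first atom (for hydrogen-bond pipelines).
#' @param seed RNG seed (reserved for jitter; lattice fill is deterministic).
#' @param jitter uniform coordinate jitter half-width (angstrom).
#' @return list with `topology`, `frame`, `truth` (`sizes`, `membership`,
#'   `expected_kappa` where closed-form).
#' @export
make_planted_clusters <- function(n_clusters, molecules_per_cluster,
                                  atoms_per_molecule = 4L, intra_spacing = 2,
                                  inter_gap = 20, shape = c("blob", "rod", "ellipsoid"),
                                  semiaxes = c(1, 1, 1), aspect = 20,
                                  with_donors = FALSE, seed = 1, jitter = 0) {
  shape <- match.arg(shape)
  if (length(molecules_per_cluster) != n_clusters)
    stop("molecules_per_cluster must have length n_clusters")
  if (inter_gap <= 4.5 + intra_spacing)
    stop("invalid geometry: inter_gap must exceed 4.5 + intra_spacing so clusters cannot merge")
  ax <- switch(shape,
    blob = c(1, 1, 1),
    rod = c(aspect, 1, 1),
    ellipsoid = {
      if (length(semiaxes) != 3L || any(semiaxes <= 0)) stop("semiaxes must be 3 positive numbers")
      semiaxes
    })
  set.seed(seed)
  clouds <- lapply(molecules_per_cluster, function(m)
    ellipsoid_lattice(m * atoms_per_molecule, ax / max(ax), intra_spacing / max(ax)))
  # scale each cloud so lattice spacing is intra_spacing in the longest axis
  clouds <- lapply(clouds, function(cl) cl * max(ax))
  if (jitter > 0)
    clouds <- lapply(clouds, function(cl)
      cl + matrix(stats::runif(length(cl), -jitter, jitter), nrow(cl)))

  # place clusters along x with inter_gap between bounding boxes
  xoff <- 0; margin <- inter_gap
  placed <- list()
  for (cl in clouds) {
    cl[, 1] <- cl[, 1] - min(cl[, 1]) + xoff + margin
    placed[[length(placed) + 1L]] <- cl
    xoff <- max(cl[, 1]) + inter_gap
  }
  all_xy <- do.call(rbind, placed)
  span_yz <- apply(all_xy[, 2:3, drop = FALSE], 2, function(v) diff(range(v)))
  box <- c(xoff + margin, span_yz[1] + 2 * inter_gap, span_yz[2] + 2 * inter_gap)
  coords <- all_xy
  coords[, 2] <- coords[, 2] - min(coords[, 2]) + inter_gap
  coords[, 3] <- coords[, 3] - min(coords[, 3]) + inter_gap

  n_mol_tot <- sum(molecules_per_cluster)
  mol_id <- unlist(lapply(seq_len(n_clusters), function(c) {
    prev <- sum(molecules_per_cluster[seq_len(c - 1L)])
    rep(prev + seq_len(molecules_per_cluster[c]), each = atoms_per_molecule)
  }))
  membership <- rep(seq_len(n_clusters), molecules_per_cluster)

  n_at <- nrow(coords)
  mass <- rep(12.011, n_at); charge <- rep(0, n_at)
  role <- rep("drug", n_at)
  donor_heavy <- rep(FALSE, n_at); polar_h <- rep(FALSE, n_at)
  donor_of <- rep(NA_integer_, n_at); aname <- rep("C", n_at)

  if (with_donors) {
    first_atom <- match(seq_len(n_mol_tot), mol_id)
    extra <- do.call(rbind, lapply(first_atom, function(i)
      rbind(coords[i, ] + c(0, 0, 1.2), coords[i, ] + c(0, 0, 2.2))))
    nd <- length(first_atom)
    coords <- rbind(coords, extra)
    mass <- c(mass, rep(c(14.007, 1.008), nd))
    charge <- c(charge, rep(c(-0.3, 0.3), nd))
    role <- c(role, rep("peptide", 2L * nd))
    donor_heavy <- c(donor_heavy, rep(c(TRUE, FALSE), nd))
    polar_h <- c(polar_h, rep(c(FALSE, TRUE), nd))
    donor_of <- c(donor_of, as.integer(rbind(NA_integer_, n_at + 2L * seq_len(nd) - 1L)))
    aname <- c(aname, rep(c("N", "HN"), nd))
    mol_id <- c(mol_id, rep(mol_id[first_atom], each = 2L))
  }

  top <- system_topology(
    mass = mass, charge = charge, molecule_id = mol_id,
    residue_name = rep("DA", length(mass)), role = role,
    is_donor_heavy = donor_heavy, is_polar_hydrogen = polar_h,
    donor_of = donor_of, atom_name = aname
  )
  frame <- particle_frame(coords, box, time = 0, index = 0L)
  kappa <- {
    s <- sort(ax, decreasing = TRUE)
    sqrt((s[2]^2 + s[3]^2) / (s[1]^2 + s[2]^2))
  }
  truth <- list(kind = "planted_clusters", sizes = molecules_per_cluster,
                membership = membership, shape = shape,
                expected_kappa = kappa, n_molecules = n_mol_tot)
  list(topology = top, frame = frame, truth = truth)
}

#' Draw umbrella-window samples from a known PMF under harmonic biases
#'
#' For window i with center c_i and spring constant k, samples are drawn from
#' p_i(xi) proportional to exp(-(W(xi) + k/2 (xi - c_i)^2) / kT) by exact
#' inverse-CDF sampling on a fine grid (piecewise-uniform within bins).
#' The input PMF is attached as ground truth so a WHAM solve can be scored
#' against it.
#'
#' @param pmf function(xi) -> kcal/mol, or a 2-column data.frame (xi, w)
#'   interpolated linearly.
#' @param centers window centers (angstrom), e.g. [generate_windows()].
#' @param k spring constant (kcal mol-1 A-2); the study used 20.
#' @param temperature kelvin.
#' @param n_per_window samples per window (>= 1).
#' @param seed RNG seed; output deterministic per seed.
#' @param n_grid grid resolution for the inverse CDF.
#' @param half logical: bias is (k/2)(xi-c)^2 when TRUE (default), k(xi-c)^2
#'   otherwise.
#' @return an [umbrella_dataset()] with `$truth` holding the tabulated PMF.
#' @export
sample_biased_windows <- function(pmf, centers, k = 20, temperature = 310,
                                  n_per_window = 1000L, seed = 1,
                                  n_grid = 2000L, half = TRUE) {
  if (n_per_window < 1L) stop("n_per_window must be >= 1")
  if (k <= 0) stop("spring constant must be positive")
  wfun <- if (is.function(pmf)) pmf else {
    pmf <- as.data.frame(pmf)
    stats::approxfun(pmf[[1]], pmf[[2]], rule = 2)
  }
  const <- sim_constants(temperature)
  sigma <- sqrt(const$kT / k)
  lo <- min(centers) - 5 * sigma; hi <- max(centers) + 5 * sigma
  grid <- seq(lo, hi, length.out = n_grid + 1L)   # bin edges
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  w_mid <- wfun(mid)
  set.seed(seed)
  windows <- lapply(centers, function(ci) {
    u <- harmonic_bias(ci, k, mid, half = half)
    loge <- -(w_mid + u) / const$kT
    p <- exp(loge - max(loge))
    if (!any(is.finite(p)) || sum(p) <= 0)
      stop("degenerate window at center ", ci, ": biased density underflows")
    cdf <- c(0, cumsum(p) / sum(p))
    r <- stats::runif(n_per_window)
    bin <- findInterval(r, cdf, rightmost.closed = TRUE)
    bin[bin < 1L] <- 1L; bin[bin > n_grid] <- n_grid
    frac <- (r - cdf[bin]) / pmax(cdf[bin + 1L] - cdf[bin], .Machine$double.xmin)
    xi <- grid[bin] + frac * diff(grid)[bin]
    list(center = ci, k = k, samples = xi, half = half)
  })
  ds <- umbrella_dataset(windows, temperature = temperature)
  ds$truth <- list(grid = mid, w = w_mid, pmf = wfun)
  ds
}

#' Scripted hydrogen-bond trajectory with known occupancy
#'
#' Each donor/acceptor pair is placed in bonded geometry (donor-acceptor
#' 2.8 A, D-H-A angle 170 deg) with the stated probability per frame, else in
#' broken geometry (5 A). The realized Bernoulli fractions are recorded in
#' `$truth$realized`, so downstream occupancy estimates can be compared
#' exactly.
#'
#' @param n_frames number of frames.
#' @param n_pairs number of independent donor/acceptor pairs, or a character
#'   vector of residue labels for the donors (its length sets the count).
#' @param occupancy target bond probability per pair (scalar or per pair).
#' @param seed RNG seed.
#' @return [md_trajectory()] with `$truth` (`realized`, `bonded` matrix,
#'   `pair_labels`).
#' @export
make_hbond_script <- function(n_frames, n_pairs = 3L, occupancy = 0.5, seed = 1) {
  labels <- if (is.character(n_pairs)) n_pairs else
    sprintf("K%02d", seq_len(n_pairs))
  np <- length(labels)
  occupancy <- rep_len(occupancy, np)
  if (any(occupancy < 0 | occupancy > 1)) stop("occupancy must be in [0, 1]")

  # per-pair template geometry: D at origin, H at +x; A_bonded solves
  # |D-A| = 2.8 with D-H-A angle 170 deg
  u <- c(cos(10 * pi / 180), sin(10 * pi / 180), 0)
  tq <- polyroot(c(1 - 2.8^2, 2 * u[1], 1))
  tpos <- Re(tq[abs(Im(tq)) < 1e-9 & Re(tq) > 0][1])
  A_bond <- c(1, 0, 0) + tpos * u
  A_off <- c(5, 0, 0)

  spacing <- 25
  origins <- cbind((seq_len(np) - 1L) * spacing + spacing / 2, spacing / 2, spacing / 2)
  box <- c(np * spacing, spacing, spacing)

  top <- system_topology(
    mass = rep(c(14.007, 1.008, 15.999), np),
    charge = rep(c(-0.3, 0.3, -0.5), np),
    molecule_id = rep(seq_len(2L * np), rep(c(2L, 1L), np)),
    residue_name = as.vector(t(cbind(labels, labels, sprintf("PO%02d", seq_len(np))))),
    role = rep(c("peptide", "peptide", "lipid_head"), np),
    is_donor_heavy = rep(c(TRUE, FALSE, FALSE), np),
    is_polar_hydrogen = rep(c(FALSE, TRUE, FALSE), np),
    is_acceptor = rep(c(FALSE, FALSE, TRUE), np),
    donor_of = as.integer(rbind(NA, 3L * seq_len(np) - 2L, NA)),
    atom_name = rep(c("N", "HN", "O"), np)
  )
  set.seed(seed)
  bonded <- matrix(stats::runif(n_frames * np) < rep(occupancy, each = n_frames),
                   n_frames, np)
  frames <- lapply(seq_len(n_frames), function(f) {
    co <- matrix(NA_real_, 3L * np, 3L)
    for (p in seq_len(np)) {
      base <- origins[p, ]
      a <- if (bonded[f, p]) A_bond else A_off
      co[3L * p - 2L, ] <- base
      co[3L * p - 1L, ] <- base + c(1, 0, 0)
      co[3L * p, ] <- base + a
    }
    particle_frame(co, box, time = (f - 1L) * 0.1, index = f - 1L)
  })
  traj <- md_trajectory(top, frames)
  traj$truth <- list(kind = "hbond_script", realized = colMeans(bonded),
                     bonded = bonded, pair_labels = labels,
                     target_occupancy = occupancy)
  traj
}

#' Composite drug-amphiphile / membrane synthetic trajectory
#'
#' A flat bilayer plus planted drug clusters hovering above it at controlled
#' closest-approach distances, with one scripted N-H donor on the lowest
#' cluster hydrogen-bonded to a head-group acceptor. Used by the end-to-end
#' pipeline tests.
#'
#' @param seed RNG seed.
#' @param n_frames frames to emit (small per-atom jitter between frames).
#' @param cluster_sizes molecules per planted cluster.
#' @param dz_planted closest-approach distance of each cluster from the
#'   membrane centre of mass (angstrom).
#' @param jitter per-frame per-atom Gaussian jitter sigma (angstrom).
#' @return [md_trajectory()] with `$truth`.
#' @export
make_da_membrane_composite <- function(seed = 1, n_frames = 5L,
                                       cluster_sizes = c(5L, 8L, 12L),
                                       dz_planted = c(24, 32, 40),
                                       jitter = 0.05) {
  stopifnot(length(dz_planted) == length(cluster_sizes))
  mem <- make_flat_bilayer(nx = 12, ny = 12, lattice = 8, thickness = 38,
                           z_noise = 0.3, seed = seed)
  box <- mem$frame$box
  # recentre membrane z to box middle for a strictly positive coordinate range
  zshift <- box[3] / 2
  mem$frame$coords[, 3] <- mem$frame$coords[, 3] + zshift

  nclu <- length(cluster_sizes)
  clu <- make_planted_clusters(nclu, cluster_sizes, atoms_per_molecule = 4L,
                               intra_spacing = 2, inter_gap = 22,
                               shape = "blob", seed = seed + 1L)
  cco <- clu$frame$coords
  # spread clusters across x, set each cluster's lowest atom at its planted dz
  memb <- clu$truth$membership
  mol2clu <- memb[clu$topology$atoms$molecule_id]
  targ_x <- (seq_len(nclu) - 0.5) * box[1] / nclu
  for (c in seq_len(nclu)) {
    idx <- which(mol2clu == c)
    cco[idx, 1] <- cco[idx, 1] - mean(range(cco[idx, 1])) + targ_x[c]
    cco[idx, 2] <- cco[idx, 2] - mean(range(cco[idx, 2])) + box[2] / 2
    cco[idx, 3] <- cco[idx, 3] - min(cco[idx, 3]) + zshift + dz_planted[c]
  }

  mem_at <- mem$topology$atoms
  clu_at <- clu$topology$atoms
  clu_at$molecule_id <- clu_at$molecule_id + max(mem_at$molecule_id)

  # scripted H-bond: donor N-H under the first atom of cluster 1, aimed at
  # the nearest head-group acceptor straight below it
  head_idx <- which(mem_at$role == "lipid_head" &
                    mem$frame$coords[, 3] > zshift)     # upper leaflet
  anchor_atom <- which(mol2clu == 1)[1]
  hx <- mem$frame$coords[head_idx, 1:2, drop = FALSE]
  tgt <- head_idx[which.min((hx[, 1] - cco[anchor_atom, 1])^2 +
                            (hx[, 2] - cco[anchor_atom, 2])^2)]
  apos <- mem$frame$coords[tgt, ]
  dpos <- apos + c(0, 0, 2.8)    # donor heavy 2.8 A above acceptor, linear H
  hpos <- apos + c(0, 0, 1.8)
  don <- data.frame(mass = c(14.007, 1.008), charge = c(-0.3, 0.3),
                    molecule_id = rep(max(clu_at$molecule_id) + 1L, 2L),
                    residue_name = "K517", role = "peptide",
                    is_donor_heavy = c(TRUE, FALSE),
                    is_polar_hydrogen = c(FALSE, TRUE),
                    is_acceptor = FALSE,
                    donor_of = c(NA_integer_, nrow(mem_at) + nrow(clu_at) + 1L),
                    atom_name = c("N", "HN"), stringsAsFactors = FALSE)
  if (is.null(mem_at$atom_name)) mem_at$atom_name <- "X"
  if (is.null(clu_at$atom_name)) clu_at$atom_name <- "C"
  atoms <- rbind(mem_at, clu_at, don)
  top <- do.call(system_topology, c(as.list(atoms[setdiff(names(atoms), "atom_name")]),
                                    list(atom_name = atoms$atom_name)))
  coords0 <- rbind(mem$frame$coords, cco, rbind(dpos, hpos))

  set.seed(seed + 2L)
  frames <- lapply(seq_len(n_frames), function(f) {
    co <- coords0
    if (jitter > 0 && f > 1L)
      co <- co + matrix(stats::rnorm(length(co), 0, jitter), nrow(co))
    particle_frame(co, box, time = (f - 1L) * 0.1, index = f - 1L)
  })
  traj <- md_trajectory(top, frames)
  traj$truth <- list(kind = "da_membrane_composite",
                     cluster_sizes = cluster_sizes, dz_planted = dz_planted,
                     membrane_thickness = 38, membrane_area = box[1] * box[2],
                     membrane_z = zshift, jitter = jitter,
                     n_membrane_atoms = nrow(mem_at),
                     hbond_pair = c(donor_res = "K517", acceptor_res = "POPC"))
  traj
}
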