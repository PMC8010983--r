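#' Closest-approach distance of a cluster from the membrane centre of mass
#'
#' d_z is measured from the cluster atom closest to the membrane (along the
#' membrane normal, taken as z) to the membrane centre of mass:
#' min over cluster atoms of |z_atom - z_COM(membrane)|.
#'
#' @param frame a [particle_frame()].
#' @param topology a [system_topology()].
#' @param cluster molecule ids of the cluster (or atom indices, `by = "atom"`).
#' @param membrane_sel atom indices of the membrane (default: lipid roles).
#' @param by how to interpret `cluster`.
#' @return d_z in angstrom.
#' @export
dz_closest <- function(frame, topology, cluster,
                       membrane_sel = select_atoms(topology,
                                                   role = c("lipid_head", "lipid_tail")),
                       by = c("molecule", "atom")) {
  by <- match.arg(by)
  if (length(membrane_sel) == 0L) stop("empty membrane selection")
  idx <- if (by == "molecule")
    which(topology$atoms$molecule_id %in% cluster) else as.integer(cluster)
  if (length(idx) == 0L) stop("empty cluster selection")
  zc <- center_of_mass(frame, topology, membrane_sel)[3]
  min(abs(frame$coords[idx, 3] - zc))
}

#' Two-dimensional free-energy surface by Boltzmann inversion
#'
#' Histograms the samples on a 2D grid and converts occupancy to free energy
#' with Delta G = -R T ln(P / P_max), so the most probable bin sits at
#' exactly 0 kcal/mol and every occupied bin is non-negative. Empty bins are
#' undefined (NA), not infinite.
#'
#' @param samples data.frame or 2-column matrix: normalized cluster size in
#'   (0, 1] and d_z (angstrom), one row per cluster per frame.
#' @param bins length-2 integer bin counts (default 50 x 50).
#' @param temperature kelvin.
#' @param size_range,dz_range axis ranges; defaults (0, 1] and (0, max(d_z)).
#' @return object of class `Landscape2D`: list with `size_edges`, `dz_edges`,
#'   `P` (counts / total), `dG` (kcal/mol, NA where empty), `temperature`,
#'   `n_samples`.
#' @export
free_energy_surface <- function(samples, bins = c(50L, 50L), temperature = 310,
                                size_range = NULL, dz_range = NULL) {
  samples <- as.matrix(as.data.frame(samples)[, 1:2])
  if (nrow(samples) < 1L) stop("need at least one sample")
  if (temperature <= 0) stop("temperature must be positive")
  bins <- rep_len(as.integer(bins), 2L)
  if (is.null(size_range)) size_range <- c(0, 1)
  if (is.null(dz_range)) dz_range <- c(0, max(samples[, 2]))
  se <- seq(size_range[1], size_range[2], length.out = bins[1] + 1L)
  de <- seq(dz_range[1], dz_range[2], length.out = bins[2] + 1L)
  ix <- findInterval(samples[, 1], se, rightmost.closed = TRUE, left.open = TRUE)
  iy <- findInterval(samples[, 2], de, rightmost.closed = TRUE, left.open = TRUE)
  ok <- ix >= 1L & ix <= bins[1] & iy >= 1L & iy <= bins[2]
  if (!any(ok)) stop("empty landscape: all samples outside the bin ranges")
  counts <- matrix(0, bins[1], bins[2])
  tab <- table(factor(ix[ok], levels = seq_len(bins[1])),
               factor(iy[ok], levels = seq_len(bins[2])))
  counts[] <- as.numeric(tab)
  P <- counts / sum(counts)
  const <- sim_constants(temperature)
  dG <- matrix(NA_real_, bins[1], bins[2])
  occ <- counts > 0
  dG[occ] <- -const$R * temperature * log(P[occ] / max(P))
  dG[occ][dG[occ] == 0] <- 0           # normalise -0 at the modal bin
  structure(list(size_edges = se, dz_edges = de, counts = counts, P = P,
                 dG = dG, temperature = temperature, n_samples = sum(ok)),
            class = "Landscape2D")
}

#' @export
print.Landscape2D <- function(x, ...) {
  occ <- sum(!is.na(x$dG))
  cat(sprintf("Landscape2D: %d x %d bins (%d occupied), %d samples, T = %g K\n",
              nrow(x$dG), ncol(x$dG), occ, x$n_samples, x$temperature))
  cat(sprintf("  Delta G range over occupied bins: [0, %.3f] kcal/mol\n",
              max(x$dG, na.rm = TRUE)))
  invisible(x)
}

#' @param dG_max colour-scale cap (kcal/mol) for plotting.
#' @rdname free_energy_surface
#' @export
plot.Landscape2D <- function(x, dG_max = NULL, ...) {
  z <- x$dG
  if (!is.null(dG_max)) z[z > dG_max] <- dG_max
  xm <- (x$size_edges[-1] + x$size_edges[-length(x$size_edges)]) / 2
  ym <- (x$dz_edges[-1] + x$dz_edges[-length(x$dz_edges)]) / 2
  graphics::image(xm, ym, z, xlab = "normalized cluster size",
                  ylab = expression(d[z] ~ "(" * ring(A) * ")"),
                  col = grDevices::hcl.colors(50, "viridis"), ...)
  invisible(x)
}

#' Per-cluster-per-frame landscape samples from a trajectory
#'
#' Convenience driver: clusters every frame, computes each cluster's
#' normalized size and d_z, and returns the sample table that
#' [free_energy_surface()] consumes.
#'
#' @param traj an [md_trajectory()].
#' @param sel drug-atom selection (default drug role).
#' @param membrane_sel membrane atom selection.
#' @param r_cutoff contact cutoff (angstrom).
#' @param frames optional integer subset of frames (time window).
#' @return data.frame with `frame`, `normalized_size`, `dz`.
#' @export
landscape_samples <- function(traj, sel = NULL,
                              membrane_sel = select_atoms(traj$topology,
                                                          role = c("lipid_head", "lipid_tail")),
                              r_cutoff = 4.5, frames = NULL) {
  if (is.null(frames)) frames <- seq_along(traj$frames)
  rows <- lapply(frames, function(fi) {
    fr <- traj$frames[[fi]]
    cs <- find_clusters(fr, traj$topology, sel = sel, r_cutoff = r_cutoff)
    do.call(rbind, lapply(seq_along(cs$clusters), function(i)
      data.frame(frame = fr$index,
                 normalized_size = cs$normalized_sizes[i],
                 dz = dz_closest(fr, traj$topology, cs$clusters[[i]],
                                 membrane_sel = membrane_sel))))
  })
  do.call(rbind, rows)
}
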