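#' Default bending rigidity
#'
#' No measured rigidity is assumed; the default is 30 k_B T at 310 K
#' (about 18.5 kcal/mol), a textbook value for a fluid phosphatidylcholine
#' bilayer. All bending energies should be reported together with the k_c
#' they used.
#' @param temperature kelvin.
#' @return k_c in kcal/mol.
#' @export
kc_default <- function(temperature = 310) 30 * sim_constants(temperature)$kT

#' Assign head-group atoms to upper and lower leaflets
#'
#' Two-pass assignment robust to bending: first a global split about the
#' mid-point of the head z-range, then a refinement against the local
#' mid-surface estimated on an (x, y) grid. Grid nodes where either leaflet
#' is missing, or where the apparent leaflet separation falls below
#' `min_separation`, are flagged uncovered (a single-leaflet sheet flags
#' every node).
#'
#' @param frame a [particle_frame()].
#' @param topology a [system_topology()].
#' @param head_sel head-group atom indices (default role `lipid_head`).
#' @param spacing grid spacing for the local refinement (angstrom).
#' @param min_separation minimal credible leaflet separation (angstrom).
#' @return list with `upper`, `lower` (atom index vectors), `uncovered`
#'   (logical matrix over grid nodes), `grid` (node coordinates).
#' @export
assign_leaflets <- function(frame, topology,
                            head_sel = select_atoms(topology, role = "lipid_head"),
                            spacing = 12, min_separation = 5) {
  if (length(head_sel) == 0L) stop("empty head selection")
  x <- frame$coords[head_sel, , drop = FALSE]
  box <- frame$box
  zmid_g <- mean(range(x[, 3]))
  up <- x[, 3] >= zmid_g
  nx <- max(1L, round(box[1] / spacing)); ny <- max(1L, round(box[2] / spacing))
  ij <- cbind(pmin(floor((x[, 1] %% box[1]) / (box[1] / nx)), nx - 1L),
              pmin(floor((x[, 2] %% box[2]) / (box[2] / ny)), ny - 1L))
  node <- ij[, 1] + nx * ij[, 2] + 1L
  for (pass in 1:2) {
    mid_loc <- rep(zmid_g, nx * ny)
    for (k in unique(node)) {
      zu <- x[node == k & up, 3]; zl <- x[node == k & !up, 3]
      if (length(zu) && length(zl)) mid_loc[k] <- (mean(zu) + mean(zl)) / 2
    }
    up <- x[, 3] >= mid_loc[node]
  }
  unc <- matrix(TRUE, nx, ny)
  sep <- matrix(NA_real_, nx, ny)
  for (k in unique(node)) {
    zu <- x[node == k & up, 3]; zl <- x[node == k & !up, 3]
    if (length(zu) && length(zl)) {
      s <- mean(zu) - mean(zl)
      sep[((k - 1L) %% nx) + 1L, ((k - 1L) %/% nx) + 1L] <- s
      if (s >= min_separation)
        unc[((k - 1L) %% nx) + 1L, ((k - 1L) %/% nx) + 1L] <- FALSE
    }
  }
  list(upper = head_sel[up], lower = head_sel[!up], uncovered = unc,
       separation = sep, grid = list(nx = nx, ny = ny))
}

#' Gridded membrane mid-surface (height field)
#'
#' Bins head-group atoms on an (x, y) grid, averages leaflet heights per
#' node, and derives mid-surface height, thickness, metric area elements and
#' mean curvature. Isolated empty nodes are filled by linear interpolation of
#' their periodic neighbours; larger holes stay unoccupied.
#'
#' @inheritParams assign_leaflets
#' @param spacing grid node spacing (angstrom).
#' @return object of class `HeightField`: list with `x`, `y` (node centres),
#'   `zmid`, `upper`, `lower`, `thickness`, `H` (mean curvature, 1/angstrom),
#'   `dA` (metric area elements, angstrom^2), `occupied` (logical),
#'   `spacing` (c(sx, sy)), `box`.
#' @export
height_field <- function(frame, topology,
                         head_sel = select_atoms(topology, role = "lipid_head"),
                         spacing = 8) {
  lf <- assign_leaflets(frame, topology, head_sel)
  box <- frame$box
  nx <- max(2L, round(box[1] / spacing)); ny <- max(2L, round(box[2] / spacing))
  sx <- box[1] / nx; sy <- box[2] / ny
  bin_mean <- function(idx) {
    z <- matrix(NA_real_, nx, ny)
    if (!length(idx)) return(z)
    xx <- frame$coords[idx, , drop = FALSE]
    i <- pmin(floor((xx[, 1] %% box[1]) / sx), nx - 1L) + 1L
    j <- pmin(floor((xx[, 2] %% box[2]) / sy), ny - 1L) + 1L
    key <- i + nx * (j - 1L)
    means <- tapply(xx[, 3], key, mean)
    z[as.integer(names(means))] <- means
    z
  }
  zu <- bin_mean(lf$upper); zl <- bin_mean(lf$lower)
  fill_single <- function(z) {
    holes <- which(is.na(z), arr.ind = TRUE)
    if (!nrow(holes)) return(z)
    zf <- z
    for (r in seq_len(nrow(holes))) {
      i <- holes[r, 1]; j <- holes[r, 2]
      nb <- c(z[(i %% nx) + 1L, j], z[((i - 2L) %% nx) + 1L, j],
              z[i, (j %% ny) + 1L], z[i, ((j - 2L) %% ny) + 1L])
      if (sum(!is.na(nb)) >= 3L) zf[i, j] <- mean(nb, na.rm = TRUE)
    }
    zf
  }
  zu <- fill_single(zu); zl <- fill_single(zl)
  occ <- !is.na(zu) & !is.na(zl)
  zmid <- (zu + zl) / 2
  hf <- structure(list(x = (seq_len(nx) - 0.5) * sx, y = (seq_len(ny) - 0.5) * sy,
                       zmid = zmid, upper = zu, lower = zl,
                       thickness = zu - zl, occupied = occ,
                       spacing = c(sx, sy), box = box),
                  class = "HeightField")
  hf$H <- mean_curvature(hf)
  hf$dA <- area_elements(hf)
  hf
}

#' @export
print.HeightField <- function(x, ...) {
  cat(sprintf("HeightField: %d x %d nodes (%.1f x %.1f A spacing), %d%% occupied\n",
              length(x$x), length(x$y), x$spacing[1], x$spacing[2],
              round(100 * mean(x$occupied))))
  if (any(x$occupied))
    cat(sprintf("  thickness %.2f +/- %.2f A\n",
                mean(x$thickness[x$occupied]), stats::sd(x$thickness[x$occupied])))
  invisible(x)
}

pshift <- function(M, di, dj) {
  n <- nrow(M); m <- ncol(M)
  M[((seq_len(n) - 1L + di) %% n) + 1L, ((seq_len(m) - 1L + dj) %% m) + 1L,
    drop = FALSE]
}

# periodic central-difference first/second derivatives, 4th order when the
# grid has >= 5 nodes in that direction (2nd order otherwise)
fd_d1 <- function(z, h, dim) {
  s <- function(d) if (dim == 1L) pshift(z, d, 0) else pshift(z, 0, d)
  if ((if (dim == 1L) nrow(z) else ncol(z)) >= 5L)
    (8 * (s(1) - s(-1)) - (s(2) - s(-2))) / (12 * h)
  else (s(1) - s(-1)) / (2 * h)
}
fd_d2 <- function(z, h, dim) {
  s <- function(d) if (dim == 1L) pshift(z, d, 0) else pshift(z, 0, d)
  if ((if (dim == 1L) nrow(z) else ncol(z)) >= 5L)
    (-s(2) + 16 * s(1) - 30 * z + 16 * s(-1) - s(-2)) / (12 * h^2)
  else (s(1) - 2 * z + s(-1)) / h^2
}

#' Mean curvature of a height field (Monge gauge)
#'
#' H = ((1 + z_x^2) z_yy - 2 z_x z_y z_xy + (1 + z_y^2) z_xx) /
#' (2 (1 + z_x^2 + z_y^2)^(3/2)) with central differences and periodic
#' boundaries. Nodes whose finite-difference stencil touches a hole give NA.
#' Overhanging membranes (surface folding past vertical) are outside the
#' Monge-gauge description.
#'
#' @param hf a `HeightField`.
#' @return matrix of H per node (1/angstrom).
#' @export
mean_curvature <- function(hf) {
  z <- hf$zmid; sx <- hf$spacing[1]; sy <- hf$spacing[2]
  zx <- fd_d1(z, sx, 1L); zy <- fd_d1(z, sy, 2L)
  zxx <- fd_d2(z, sx, 1L); zyy <- fd_d2(z, sy, 2L)
  zxy <- fd_d1(fd_d1(z, sx, 1L), sy, 2L)
  ((1 + zx^2) * zyy - 2 * zx * zy * zxy + (1 + zy^2) * zxx) /
    (2 * (1 + zx^2 + zy^2)^(3 / 2))
}

area_elements <- function(hf) {
  z <- hf$zmid; sx <- hf$spacing[1]; sy <- hf$spacing[2]
  zx <- fd_d1(z, sx, 1L); zy <- fd_d1(z, sy, 2L)
  sqrt(1 + zx^2 + zy^2) * sx * sy
}

#' Height field sampled from an analytic surface
#'
#' Evaluates z(x, y) exactly at the grid nodes — the clean test bed for the
#' discrete area/curvature/bending operators, free of the head-binning noise
#' of a particle fixture.
#'
#' @param zfun function(x, y) -> height (angstrom), periodic over the box.
#' @param box length-3 box (only x and y used).
#' @param spacing grid node spacing (angstrom).
#' @param thickness constant thickness to attach (angstrom).
#' @return a `HeightField`.
#' @export
synthetic_height_field <- function(zfun, box, spacing = 8, thickness = 38) {
  nx <- max(2L, round(box[1] / spacing)); ny <- max(2L, round(box[2] / spacing))
  sx <- box[1] / nx; sy <- box[2] / ny
  x <- (seq_len(nx) - 0.5) * sx; y <- (seq_len(ny) - 0.5) * sy
  zmid <- outer(x, y, zfun)
  hf <- structure(list(x = x, y = y, zmid = zmid,
                       upper = zmid + thickness / 2, lower = zmid - thickness / 2,
                       thickness = matrix(thickness, nx, ny),
                       occupied = matrix(TRUE, nx, ny),
                       spacing = c(sx, sy), box = box),
                  class = "HeightField")
  hf$H <- mean_curvature(hf)
  hf$dA <- area_elements(hf)
  hf
}

#' Mid-surface area by triangulation
#'
#' Each grid cell (periodic wrap at the edges) is split into two triangles;
#' the sum of triangle areas over cells with all corners occupied is
#' returned. A flat field gives exactly Lx * Ly.
#'
#' @param hf a `HeightField`.
#' @return area in angstrom^2.
#' @export
surface_area <- function(hf) {
  if (sum(hf$occupied) < 4L) stop("need at least 4 occupied nodes")
  z <- hf$zmid; sx <- hf$spacing[1]; sy <- hf$spacing[2]
  z10 <- pshift(z, 1, 0); z01 <- pshift(z, 0, 1); z11 <- pshift(z, 1, 1)
  tri_area <- function(dz1, dz2, e1, e2) {
    # triangle with in-plane edge vectors e1, e2 and height differences dz
    # cross product of (e1x, e1y, dz1) and (e2x, e2y, dz2)
    cx <- e1[2] * dz2 - dz1 * e2[2]
    cy <- dz1 * e2[1] - e1[1] * dz2
    cz <- e1[1] * e2[2] - e1[2] * e2[1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  a1 <- tri_area(z10 - z, z01 - z, c(sx, 0), c(0, sy))
  a2 <- tri_area(z11 - z10, z01 - z11, c(0, sy), c(-sx, 0))
  ok <- hf$occupied & pshift(hf$occupied, 1, 0) & pshift(hf$occupied, 0, 1) &
    pshift(hf$occupied, 1, 1)
  sum((a1 + a2)[ok])
}

#' Membrane thickness profile along one axis
#'
#' Head atoms are split into leaflets and binned along the chosen axis
#' (averaging over the transverse direction); per-bin thickness is the mean
#' upper height minus the mean lower height. Empty bins give NA.
#'
#' @inheritParams assign_leaflets
#' @param axis `"x"` or `"y"`.
#' @param bin bin width (angstrom).
#' @return data.frame with `center` (bin centre, angstrom) and `thickness`.
#' @export
thickness_profile <- function(frame, topology,
                              head_sel = select_atoms(topology, role = "lipid_head"),
                              axis = c("y", "x"), bin = 8) {
  axis <- match.arg(axis)
  ax <- if (axis == "x") 1L else 2L
  lf <- assign_leaflets(frame, topology, head_sel)
  L <- frame$box[ax]
  nb <- max(1L, round(L / bin)); w <- L / nb
  bin_of <- function(idx) pmin(floor((frame$coords[idx, ax] %% L) / w), nb - 1L) + 1L
  zu <- tapply(frame$coords[lf$upper, 3], factor(bin_of(lf$upper), levels = seq_len(nb)), mean)
  zl <- tapply(frame$coords[lf$lower, 3], factor(bin_of(lf$lower), levels = seq_len(nb)), mean)
  data.frame(center = (seq_len(nb) - 0.5) * w,
             thickness = as.numeric(zu) - as.numeric(zl))
}

#' Helfrich bending energy of a surface
#'
#' F_bend = (k_c / 2) * sum over nodes of (2 H)^2 dA. Accepts a
#' `HeightField` or any list with per-node `H` and `dA` (e.g.
#' [sphere_test_mesh()], for which F = 8 pi k_c independent of radius).
#'
#' @param surface a `HeightField` or list with `H` and `dA`.
#' @param k_c bending rigidity (kcal/mol); default [kc_default()].
#' @return list with `F_bend` (kcal/mol) and the `k_c` used.
#' @export
bending_energy <- function(surface, k_c = kc_default()) {
  if (k_c <= 0) stop("k_c must be positive")
  H <- surface$H; dA <- surface$dA
  ok <- is.finite(H) & is.finite(dA)
  if (!is.null(surface$occupied)) ok <- ok & surface$occupied
  list(F_bend = (k_c / 2) * sum((2 * H[ok])^2 * dA[ok]), k_c = k_c)
}

#' Parametric sphere mesh (curvature test harness)
#'
#' A closed sphere sampled on a latitude/longitude grid, bypassing the Monge
#' gauge: every node carries the exact H = 1/R, and the patch areas
#' dA = R^2 dphi (cos(theta_k) - cos(theta_k+1)) sum exactly to 4 pi R^2, so
#' [bending_energy()] returns 8 pi k_c up to floating-point error.
#'
#' @param radius sphere radius (angstrom).
#' @param n_theta,n_phi grid resolution.
#' @return list with `H`, `dA` (classes it as a surface for [bending_energy()]).
#' @export
sphere_test_mesh <- function(radius, n_theta = 40L, n_phi = 80L) {
  th <- seq(0, pi, length.out = n_theta + 1L)
  dphi <- 2 * pi / n_phi
  dA_band <- radius^2 * dphi * (cos(th[-length(th)]) - cos(th[-1]))
  dA <- matrix(rep(dA_band, n_phi), n_theta, n_phi)
  list(H = matrix(1 / radius, n_theta, n_phi), dA = dA, radius = radius)
}
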