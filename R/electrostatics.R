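#' Gaussian-smeared charge density on a periodic grid
#'
#' Each partial charge is deposited as a periodic Gaussian of width
#' `sigma` (the smoothed-potential convention of grid electrostatics
#' plugins); each atom's deposited kernel is renormalized on the grid so the
#' integrated density equals the summed charge to machine precision. Grid
#' dimensions are forced even for the spectral solver.
#'
#' @param frame a [particle_frame()].
#' @param topology a [system_topology()] with charges.
#' @param spacing target grid spacing (angstrom); actual spacing divides the
#'   box exactly.
#' @param sigma Gaussian smearing width (angstrom), > 0.
#' @param sel atoms to deposit (default: all with non-zero charge).
#' @return object of class `ChargeGrid`: list with `rho` (3D array, e/A^3),
#'   `box`, `spacing` (length 3), `sigma`, `total_charge`.
#' @export
smear_charges <- function(frame, topology, spacing = 1.0, sigma = 1.0,
                          sel = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (sigma < spacing)
    warning("sigma below the grid spacing: density will be aliased")
  box <- frame$box
  dims <- pmax(4L, 2L * ceiling(box / spacing / 2))   # even
  h <- box / dims
  rho <- array(0, dims)
  q <- topology$atoms$charge
  if (is.null(sel)) sel <- which(q != 0)
  cut <- ceiling(5 * sigma / h)                        # deposit to 5 sigma
  full <- any(2L * cut + 1L >= dims)                   # kernel spans the box
  axes <- lapply(1:3, function(d) (seq_len(dims[d]) - 1L) * h[d])
  for (ia in sel) {
    r0 <- frame$coords[ia, ] %% box
    if (full) {
      # min-image Gaussian over the whole (small) grid
      w <- lapply(1:3, function(d) {
        x <- axes[[d]] - r0[d]
        x <- x - box[d] * round(x / box[d])
        exp(-x^2 / (2 * sigma^2))
      })
      ker <- outer(outer(w[[1]], w[[2]]), w[[3]])
      rho <- rho + ker * (q[ia] / (sum(ker) * prod(h)))
      next
    }
    w <- vector("list", 3L); idx <- vector("list", 3L)
    for (d in 1:3) {
      i0 <- round(r0[d] / h[d])
      ii <- (i0 - cut[d]):(i0 + cut[d])
      x <- ii * h[d] - r0[d]
      idx[[d]] <- (ii %% dims[d]) + 1L
      w[[d]] <- exp(-x^2 / (2 * sigma^2))
    }
    ker <- outer(outer(w[[1]], w[[2]]), w[[3]])
    ker <- ker * (q[ia] / (sum(ker) * prod(h)))        # exact normalization
    ix <- idx[[1]]; iy <- idx[[2]]; iz <- idx[[3]]     # wrapped, no repeats
    for (kz in seq_along(iz))
      rho[ix, iy, iz[kz]] <- rho[ix, iy, iz[kz]] + ker[, , kz]
  }
  structure(list(rho = rho, box = box, spacing = h, sigma = sigma,
                 total_charge = sum(rho) * prod(h)),
            class = "ChargeGrid")
}

#' Spectral periodic Poisson solve
#'
#' Solves nabla^2 phi = -4 pi rho (Gaussian units; charge in e, length in
#' angstrom) by FFT: phi(k) = 4 pi rho(k) / k^2, with the k = 0 mode set to
#' zero — equivalent to a uniform neutralizing background, so non-neutral
#' systems are handled with a warning and the box-average potential is
#' exactly zero. Output is converted to volts.
#'
#' @param density a `ChargeGrid` from [smear_charges()].
#' @return object of class `PotentialGrid`: list with `phi` (3D array,
#'   volts), `box`, `spacing`, `sigma`, `frames_averaged = 1`.
#' @export
solve_poisson_periodic <- function(density) {
  stopifnot(inherits(density, "ChargeGrid"))
  if (abs(density$total_charge) > 1e-6)
    warning(sprintf("net charge %.4g e: applying uniform neutralizing background",
                    density$total_charge))
  dims <- dim(density$rho)
  box <- density$box
  kvec <- lapply(1:3, function(d) {
    m <- c(0:(dims[d] %/% 2), -((dims[d] - dims[d] %/% 2 - 1):1))
    2 * pi * m / box[d]
  })
  k2 <- outer(outer(kvec[[1]]^2, kvec[[2]]^2, "+"), kvec[[3]]^2, "+")
  rhok <- stats::fft(density$rho)
  phik <- array(0i, dims)
  nz <- k2 > 0
  phik[nz] <- 4 * pi * rhok[nz] / k2[nz]
  phi <- Re(stats::fft(phik, inverse = TRUE)) / prod(dims)
  phi <- phi * sim_constants()$coulomb_to_volt
  structure(list(phi = phi, box = box, spacing = density$spacing,
                 sigma = density$sigma, frames_averaged = 1L),
            class = "PotentialGrid")
}

#' @export
print.PotentialGrid <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("PotentialGrid: %d x %d x %d nodes, %d frame(s), phi in [%.3g, %.3g] V\n",
              d[1], d[2], d[3], x$frames_averaged, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Electrostatic potential at arbitrary points (trilinear interpolation)
#' @param grid a `PotentialGrid`.
#' @param points n x 3 matrix of positions (angstrom).
#' @return potential in volts at each point.
#' @export
potential_at <- function(grid, points) {
  points <- matrix(points, ncol = 3L)
  dims <- dim(grid$phi); h <- grid$spacing
  vapply(seq_len(nrow(points)), function(r) {
    u <- (points[r, ] %% grid$box) / h
    i0 <- floor(u); f <- u - i0
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      ii <- (i0 + c(dx, dy, dz)) %% dims + 1L
      v <- v + w * grid$phi[ii[1], ii[2], ii[3]]
    }
    v
  }, numeric(1))
}

#' Slab-averaged 2D potential slice, averaged over frames
#'
#' Averages the per-frame 3D potential grids, then averages the nodes whose
#' coordinate along `axis` falls inside the slab, producing the 2D map of a
#' slice through the simulation box.
#'
#' @param grids a `PotentialGrid` or list of them (identical dimensions).
#' @param axis `"x"`, `"y"`, or `"z"` (slab normal).
#' @param offset slab centre along `axis` (angstrom); default box centre.
#' @param slab slab width (angstrom).
#' @return object of class `PotentialSlice`: list with `map` (2D matrix,
#'   volts), `u`, `v` (node coordinates of the in-plane axes), `axis`,
#'   `offset`, `slab`.
#' @export
slice_map <- function(grids, axis = c("z", "x", "y"), offset = NULL, slab = 10) {
  axis <- match.arg(axis)
  if (inherits(grids, "PotentialGrid")) grids <- list(grids)
  phi <- Reduce(`+`, lapply(grids, `[[`, "phi")) / length(grids)
  g1 <- grids[[1]]
  ax <- match(axis, c("x", "y", "z"))
  L <- g1$box[ax]
  if (is.null(offset)) offset <- L / 2
  coord <- (seq_len(dim(phi)[ax]) - 1L) * g1$spacing[ax]
  lo <- offset - slab / 2; hi <- offset + slab / 2
  if (hi <= 0 || lo >= L) stop("slab lies outside the box")
  inside <- ((coord - lo) %% L) <= ((hi - lo) %% L) | slab >= L
  if (!any(inside)) stop("slab contains no grid planes")
  keep <- which(inside)
  m <- switch(axis,
              x = apply(phi[keep, , , drop = FALSE], c(2, 3), mean),
              y = apply(phi[, keep, , drop = FALSE], c(1, 3), mean),
              z = apply(phi[, , keep, drop = FALSE], c(1, 2), mean))
  plane <- setdiff(1:3, ax)
  structure(list(map = m,
                 u = (seq_len(dim(phi)[plane[1]]) - 1L) * g1$spacing[plane[1]],
                 v = (seq_len(dim(phi)[plane[2]]) - 1L) * g1$spacing[plane[2]],
                 axis = axis, offset = offset, slab = slab,
                 frames_averaged = length(grids)),
            class = "PotentialSlice")
}

#' @export
plot.PotentialSlice <- function(x, ...) {
  lim <- max(abs(x$map))
  graphics::image(x$u, x$v, x$map, zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(51, "Blue-Red 3", rev = TRUE),
                  xlab = "(A)", ylab = "(A)", ...)
  invisible(x)
}
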