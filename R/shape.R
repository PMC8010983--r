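#' Principal gyration radii and sphericity index of a cluster
#'
#' The inertia tensor is taken about the cluster centre of mass with atomic
#' masses, I = sum_i m_i (|r_i|^2 Id - r_i r_i^T). Principal moments
#' I1 <= I2 <= I3 come from its eigen-decomposition; the principal gyration
#' radii follow the I = m R^2 convention, R_k = sqrt(I_k / m) with m the
#' total cluster mass, and the sphericity index is kappa = R_min / R_max:
#' close to 1 for a spherical aggregate, approaching 0 for a rod. A cluster
#' whose smallest moment vanishes (collinear atoms) is reported with
#' kappa = 0 and `degenerate = TRUE`; clusters under 4 atoms carry a
#' `small_cluster` flag but are not excluded.
#'
#' @param frame a [particle_frame()].
#' @param topology a [system_topology()].
#' @param cluster molecule ids forming the cluster (e.g. one element of a
#'   `ClusterSet$clusters`), or atom indices if `by = "atom"`.
#' @param by interpret `cluster` as `"molecule"` ids (default) or `"atom"`
#'   indices.
#' @return object of class `ClusterShape`: list with `inertia` (amu A^2),
#'   `moments` (ascending), `gyration_radii` (R1 <= R2 <= R3, angstrom),
#'   `mass_amu`, `mass_g`, `kappa`, `degenerate`, `small_cluster`, `axes`
#'   (principal axes, columns matching `moments`).
#' @export
cluster_shape <- function(frame, topology, cluster, by = c("molecule", "atom")) {
  by <- match.arg(by)
  idx <- if (by == "molecule")
    which(topology$atoms$molecule_id %in% cluster) else as.integer(cluster)
  if (length(idx) < 2L) stop("cluster needs at least 2 atoms")
  m <- topology$atoms$mass[idx]
  if (any(m <= 0)) stop("cluster atoms must have positive mass")
  x <- frame$coords[idx, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  xc <- sweep(x, 2, com)
  I <- matrix(0, 3, 3)
  I[1, 1] <- sum(m * (xc[, 2]^2 + xc[, 3]^2))
  I[2, 2] <- sum(m * (xc[, 1]^2 + xc[, 3]^2))
  I[3, 3] <- sum(m * (xc[, 1]^2 + xc[, 2]^2))
  # off-diagonals: I_ab = -sum m x_a x_b
  I[1, 2] <- I[2, 1] <- -sum(m * xc[, 1] * xc[, 2])
  I[1, 3] <- I[3, 1] <- -sum(m * xc[, 1] * xc[, 3])
  I[2, 3] <- I[3, 2] <- -sum(m * xc[, 2] * xc[, 3])
  eg <- eigen(I, symmetric = TRUE)
  mom <- rev(eg$values)            # ascending
  axes <- eg$vectors[, 3:1, drop = FALSE]
  mom[mom < 0 & mom > -1e-9 * max(abs(mom))] <- 0   # numerical floor
  mtot <- sum(m)
  R <- sqrt(pmax(mom, 0) / mtot)
  degenerate <- mom[1] <= 1e-12 * max(mom[3], 1)
  kappa <- if (degenerate) 0 else R[1] / R[3]
  structure(list(inertia = I, moments = mom, gyration_radii = R,
                 mass_amu = mtot, mass_g = mtot * 1.66053906660e-24,
                 kappa = kappa, degenerate = degenerate,
                 small_cluster = length(idx) < 4L, axes = axes,
                 n_atoms = length(idx)),
            class = "ClusterShape")
}

#' @export
print.ClusterShape <- function(x, ...) {
  cat(sprintf("ClusterShape: %d atoms, mass %.1f amu\n", x$n_atoms, x$mass_amu))
  cat(sprintf("  R = (%.3f, %.3f, %.3f) A, kappa = %.4f%s%s\n",
              x$gyration_radii[1], x$gyration_radii[2], x$gyration_radii[3],
              x$kappa, if (x$degenerate) " [degenerate]" else "",
              if (x$small_cluster) " [small cluster]" else ""))
  invisible(x)
}

#' Shapes of all clusters in a ClusterSet
#'
#' @param frame,topology as in [cluster_shape()].
#' @param clusters a `ClusterSet` from [find_clusters()].
#' @return data.frame: cluster id, size, normalized size, R1..R3, kappa, flags.
#' @export
cluster_shapes <- function(frame, topology, clusters) {
  rows <- lapply(seq_along(clusters$clusters), function(i) {
    sh <- cluster_shape(frame, topology, clusters$clusters[[i]])
    data.frame(cluster = i, n_molecules = clusters$sizes[i],
               normalized_size = clusters$normalized_sizes[i],
               R1 = sh$gyration_radii[1], R2 = sh$gyration_radii[2],
               R3 = sh$gyration_radii[3], kappa = sh$kappa,
               degenerate = sh$degenerate, small_cluster = sh$small_cluster)
  })
  do.call(rbind, rows)
}

#' Sphericity-versus-size linear regression with 95% confidence band
#'
#' Ordinary least squares of the sphericity index on normalized cluster
#' size, with t-based 95% confidence intervals on slope and intercept and a
#' pointwise confidence band. The sign of the slope distinguishes aggregates
#' that elongate as they grow (negative) from ones that round up (positive).
#'
#' @param data data.frame with columns `normalized_size` and `kappa` (or the
#'   first two columns used in that order).
#' @return object of class `RegressionResult`: list with `slope`,
#'   `intercept`, `conf` (2x2 matrix of 95% CIs), `band`
#'   (data.frame x, fit, lwr, upr), and the underlying `lm` fit.
#' @export
sphericity_vs_size <- function(data) {
  data <- as.data.frame(data)
  x <- if ("normalized_size" %in% names(data)) data$normalized_size else data[[1]]
  y <- if ("kappa" %in% names(data)) data$kappa else data[[2]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 points")
  if (length(unique(x)) < 2L) stop("rank deficiency: all abscissae identical")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  perfect <- all(abs(stats::residuals(fit)) < 1e-12 * max(1, diff(range(y))))
  conf <- if (perfect) cbind(cf, cf) else suppressWarnings(stats::confint(fit, level = 0.95))
  xs <- seq(min(x), max(x), length.out = 50L)
  pr <- suppressWarnings(stats::predict(fit, newdata = data.frame(x = xs),
                                        interval = "confidence", level = 0.95))
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 conf = conf,
                 band = data.frame(x = xs, fit = pr[, "fit"],
                                   lwr = pr[, "lwr"], upr = pr[, "upr"]),
                 fit = fit, n = length(x)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): kappa = %.4f %+.4f * size\n",
              x$n, x$intercept, x$slope))
  cat(sprintf("  95%% CI slope     [%.4f, %.4f]\n", x$conf[2, 1], x$conf[2, 2]))
  cat(sprintf("  95%% CI intercept [%.4f, %.4f]\n", x$conf[1, 1], x$conf[1, 2]))
  invisible(x)
}

#' @export
plot.RegressionResult <- function(x, ...) {
  md <- stats::model.frame(x$fit)
  graphics::plot(md$x, md$y, xlab = "normalized cluster size",
                 ylab = "sphericity index", ...)
  graphics::lines(x$band$x, x$band$fit)
  graphics::lines(x$band$x, x$band$lwr, lty = 2)
  graphics::lines(x$band$x, x$band$upr, lty = 2)
  invisible(x)
}
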