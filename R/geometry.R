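#' Minimum-image displacement vectors (orthorhombic box)
#'
#' @param d numeric matrix (n x 3) of raw displacement vectors, or a length-3
#'   vector.
#' @param box length-3 numeric, orthorhombic box edge lengths (angstrom).
#' @return displacements wrapped into `[-L/2, L/2)` per component.
#' @keywords internal
min_image <- function(d, box) {
  check_box(box)
  if (is.null(dim(d))) d <- matrix(d, ncol = 3L)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

check_box <- function(box) {
  if (!is.numeric(box) || length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
    stop("invalid box: need 3 positive orthorhombic edge lengths")
  invisible(box)
}

#' Minimum-image distance under periodic boundary conditions
#'
#' Shortest distance between two points over all periodic images of an
#' orthorhombic box. Triclinic cells are not supported.
#'
#' @param a,b length-3 numeric positions (angstrom).
#' @param box length-3 numeric box edge lengths (angstrom).
#' @return distance in angstrom.
#' @examples
#' minimum_image_distance(c(1, 0, 0), c(99, 0, 0), c(100, 100, 100))  # 2
#' @export
minimum_image_distance <- function(a, b, box) {
  if (length(a) != 3L || length(b) != 3L)
    stop("a and b must be length-3 positions")
  sqrt(sum(min_image(a - b, box)^2))
}

#' All minimum-image distances between two coordinate sets
#'
#' @param xa,xb coordinate matrices (na x 3, nb x 3).
#' @param box box edge lengths.
#' @return na x nb matrix of distances.
#' @keywords internal
pair_distances <- function(xa, xb, box) {
  check_box(box)
  na <- nrow(xa); nb <- nrow(xb)
  d2 <- matrix(0, na, nb)
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' Mass-weighted center of mass of a selection
#'
#' Coordinates are used as given (no periodic unwrapping); generators in this
#' package emit whole molecules unwrapped, so the plain mass-weighted mean is
#' exact for them.
#'
#' @param frame a [particle_frame()].
#' @param topology a [system_topology()].
#' @param sel integer atom indices (1-based), e.g. from [select_atoms()].
#' @return length-3 numeric position (angstrom).
#' @export
center_of_mass <- function(frame, topology, sel = seq_len(n_atoms(topology))) {
  sel <- as.integer(sel)
  if (length(sel) == 0L) stop("empty selection")
  m <- topology$atoms$mass[sel]
  if (any(!is.finite(m)) || any(m <= 0)) stop("all masses must be positive")
  x <- frame$coords[sel, , drop = FALSE]
  colSums(x * m) / sum(m)
}
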