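#' Nanocluster detection by the contact-distance rule
#'
#' Molecules are grouped into nanoclusters as the connected components of the
#' contact graph whose edges join molecules having any pair of selected atoms
#' within `r_cutoff` under the minimum-image convention. The default cutoff
#' of 4.5 angstrom is the aggregation criterion used throughout the package;
#' the distance test is inclusive (d <= cutoff counts as contact). Hydrogens
#' are excluded from contact detection by default.
#'
#' Contacts are found with a periodic cell list (cells at least one cutoff
#' wide); [contact_graph_oracle()] is the quadratic reference implementation
#' the cell list is validated against.
#'
#' @param frame a [particle_frame()].
#' @param topology a [system_topology()].
#' @param sel atom indices to consider (default: drug-role atoms).
#' @param r_cutoff contact distance (angstrom), > 0.
#' @param heavy_only drop hydrogens (mass < 1.5 amu) before contact search.
#' @return object of class `ClusterSet`: list with `clusters` (list of sorted
#'   molecule-id vectors, ordered by smallest member), `sizes`,
#'   `normalized_sizes`, `n_molecules`, `r_cutoff`, `frame_index`.
#' @export
find_clusters <- function(frame, topology, sel = NULL, r_cutoff = 4.5,
                          heavy_only = TRUE) {
  if (!is.numeric(r_cutoff) || r_cutoff <= 0) stop("invalid parameter: r_cutoff must be > 0")
  if (is.null(sel)) sel <- select_atoms(topology, role = "drug")
  if (heavy_only) sel <- sel[topology$atoms$mass[sel] >= 1.5]
  if (length(sel) == 0L) stop("selection resolves no atoms")
  mol <- topology$atoms$molecule_id[sel]
  mols <- sort(unique(mol))
  edges <- contact_edges_celllist(frame$coords[sel, , drop = FALSE],
                                  mol, frame$box, r_cutoff)
  comps <- molecule_components(mols, edges)
  cluster_set(comps, mols, r_cutoff, frame$index)
}

cluster_set <- function(comps, mols, r_cutoff, frame_index) {
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  sizes <- lengths(comps)
  structure(list(clusters = comps, sizes = sizes,
                 normalized_sizes = sizes / length(mols),
                 n_molecules = length(mols), r_cutoff = r_cutoff,
                 frame_index = frame_index),
            class = "ClusterSet")
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet (frame %d): %d molecules in %d clusters, r_cutoff %.2f A\n",
              x$frame_index, x$n_molecules, length(x$clusters), x$r_cutoff))
  cat("sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

# connected components over molecule ids given molecule-level contact edges
molecule_components <- function(mols, edges) {
  g <- igraph::make_empty_graph(n = length(mols), directed = FALSE)
  if (nrow(edges)) {
    ei <- cbind(match(edges[, 1], mols), match(edges[, 2], mols))
    g <- igraph::add_edges(g, t(ei))
  }
  cm <- igraph::components(g)$membership
  lapply(seq_len(max(cm)), function(c) sort(mols[cm == c]))
}

# periodic cell list: returns unique molecule-id contact pairs (m1 < m2)
contact_edges_celllist <- function(x, mol, box, rc) {
  n <- nrow(x)
  ncell <- pmax(1L, floor(box / rc))
  if (any(ncell < 3L))  # too few cells for unambiguous half-neighbour sweep
    return(contact_edges_brute(x, mol, box, rc))
  w <- box / ncell
  xw <- sweep(x, 2, box, "%%")                       # wrap into [0, L)
  ci <- floor(sweep(xw, 2, w, "/"))
  ci <- pmin(ci, matrix(rep(ncell - 1L, each = n), n))  # guard fp edge
  key <- ci[, 1] + ncell[1] * (ci[, 2] + ncell[2] * ci[, 3])
  cells <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[(offs[, 3] > 0) | (offs[, 3] == 0 & offs[, 2] > 0) |
               (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] >= 0), , drop = FALSE]
  res <- vector("list", length(cells) * nrow(offs)); ri <- 0L
  cell_xyz <- function(k) {
    k <- as.integer(k)
    c(k %% ncell[1], (k %/% ncell[1]) %% ncell[2], k %/% (ncell[1] * ncell[2]))
  }
  for (ck in names(cells)) {
    ia <- cells[[ck]]
    cc <- cell_xyz(ck)
    for (o in seq_len(nrow(offs))) {
      nb <- (cc + offs[o, ]) %% ncell
      nk <- as.character(nb[1] + ncell[1] * (nb[2] + ncell[2] * nb[3]))
      ib <- cells[[nk]]
      if (is.null(ib)) next
      same <- nk == ck
      d <- pair_distances(x[ia, , drop = FALSE], x[ib, , drop = FALSE], box)
      hit <- which(d <= rc, arr.ind = TRUE)
      if (same) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      if (!nrow(hit)) next
      m1 <- mol[ia[hit[, 1]]]; m2 <- mol[ib[hit[, 2]]]
      keep <- m1 != m2
      if (!any(keep)) next
      ri <- ri + 1L
      res[[ri]] <- cbind(pmin(m1[keep], m2[keep]), pmax(m1[keep], m2[keep]))
    }
  }
  if (ri == 0L) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, res[seq_len(ri)]))
}

contact_edges_brute <- function(x, mol, box, rc) {
  n <- nrow(x)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  d <- pair_distances(x, x, box)
  hit <- which(d <= rc, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  m1 <- mol[hit[, 1]]; m2 <- mol[hit[, 2]]
  keep <- m1 != m2
  unique(cbind(pmin(m1[keep], m2[keep]), pmax(m1[keep], m2[keep])))
}

#' Quadratic contact-graph reference (test oracle)
#'
#' All-pairs minimum-image distance check; returns the molecule-level edge
#' list. Slower than the cell list in [find_clusters()] but independent of
#' it, so the two must agree exactly.
#'
#' @inheritParams find_clusters
#' @return 2-column matrix of molecule-id pairs (m1 < m2).
#' @export
contact_graph_oracle <- function(frame, topology, sel = NULL, r_cutoff = 4.5,
                                 heavy_only = TRUE) {
  if (is.null(sel)) sel <- select_atoms(topology, role = "drug")
  if (heavy_only) sel <- sel[topology$atoms$mass[sel] >= 1.5]
  if (length(sel) == 0L) return(matrix(integer(0), 0, 2))
  contact_edges_brute(frame$coords[sel, , drop = FALSE],
                      topology$atoms$molecule_id[sel], frame$box, r_cutoff)
}

#' Clusters found by the brute-force oracle
#' @inheritParams find_clusters
#' @export
find_clusters_oracle <- function(frame, topology, sel = NULL, r_cutoff = 4.5,
                                 heavy_only = TRUE) {
  if (is.null(sel)) sel <- select_atoms(topology, role = "drug")
  selh <- if (heavy_only) sel[topology$atoms$mass[sel] >= 1.5] else sel
  mols <- sort(unique(topology$atoms$molecule_id[selh]))
  edges <- contact_graph_oracle(frame, topology, sel, r_cutoff, heavy_only)
  cluster_set(molecule_components(mols, edges), mols, r_cutoff, frame$index)
}

#' Per-frame cluster-size statistics over a trajectory
#'
#' For each frame: number of clusters, number-weighted mean cluster size
#' (optionally the mass-weighted mean, i.e. the expected size of the cluster
#' a random molecule belongs to), quartiles, extrema and box-plot outliers
#' (beyond 1.5 x IQR from the quartiles).
#'
#' @param traj an [md_trajectory()].
#' @param sel atom indices (default drug-role atoms).
#' @param r_cutoff contact cutoff (angstrom).
#' @param weighting `"number"` (default) or `"mass"` for the mean size.
#' @return object of class `ClusterStats`: data.frame with one row per frame
#'   plus attributes `sizes` (list of per-frame size vectors),
#'   `cluster_sets`, and `outliers`.
#' @export
cluster_timeseries <- function(traj, sel = NULL, r_cutoff = 4.5,
                               weighting = c("number", "mass")) {
  weighting <- match.arg(weighting)
  if (!length(traj$frames)) stop("need at least one frame")
  sets <- lapply(traj$frames, find_clusters, topology = traj$topology,
                 sel = sel, r_cutoff = r_cutoff)
  rows <- lapply(sets, function(cs) {
    s <- as.numeric(cs$sizes)
    q <- stats::quantile(s, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    out <- s[s < q[1] - 1.5 * iqr | s > q[3] + 1.5 * iqr]
    mean_size <- if (weighting == "number") mean(s) else sum(s^2) / sum(s)
    data.frame(frame = cs$frame_index, n_clusters = length(s),
               mean_size = mean_size, q25 = q[1], median = q[2], q75 = q[3],
               min = min(s), max = max(s), n_outliers = length(out),
               max_normalized = max(cs$normalized_sizes))
  })
  df <- do.call(rbind, rows)
  attr(df, "sizes") <- lapply(sets, function(cs) as.numeric(cs$sizes))
  attr(df, "outliers") <- lapply(sets, function(cs) {
    s <- as.numeric(cs$sizes)
    q <- stats::quantile(s, c(0.25, 0.75), names = FALSE)
    s[s < q[1] - 1.5 * (q[2] - q[1]) | s > q[2] + 1.5 * (q[2] - q[1])]
  })
  attr(df, "cluster_sets") <- sets
  class(df) <- c("ClusterStats", "data.frame")
  df
}

#' @export
print.ClusterStats <- function(x, ...) {
  cat(sprintf("ClusterStats: %d frames\n", nrow(x)))
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
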