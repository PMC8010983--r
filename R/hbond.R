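#' Geometric hydrogen-bond detection between two groups
#'
#' A donor-H...acceptor triplet is a hydrogen bond when the donor-heavy-atom
#' to acceptor distance (minimum image) is at most `d_cut` and the
#' D-H-A angle is at least `angle_cut` (180 degrees = linear). The defaults,
#' 3.0 angstrom and 120 degrees, are the criteria used for the study
#' systems. Only bonds crossing the two groups are reported (donor in one
#' group, acceptor in the other); intra-group bonds are excluded.
#'
#' @param frame a [particle_frame()].
#' @param topology a [system_topology()] with donor/acceptor annotation.
#' @param group_a,group_b atom index vectors for the two groups.
#' @param d_cut donor-acceptor distance cutoff (angstrom).
#' @param angle_cut D-H-A angle cutoff (degrees).
#' @return data.frame with one row per bond: `donor`, `hydrogen`, `acceptor`
#'   (atom indices), `donor_res`, `acceptor_res`, `distance`, `angle`.
#' @export
detect_hbonds <- function(frame, topology, group_a, group_b,
                          d_cut = 3.0, angle_cut = 120) {
  a <- topology$atoms
  if (!any(a$is_polar_hydrogen))
    stop("configuration error: topology has no donor map (no polar hydrogens flagged)")
  res <- rbind(
    hbond_one_direction(frame, a, group_a, group_b, d_cut, angle_cut),
    hbond_one_direction(frame, a, group_b, group_a, d_cut, angle_cut)
  )
  res[order(res$donor, res$acceptor), , drop = FALSE]
}

hbond_one_direction <- function(frame, a, gd, ga, d_cut, angle_cut) {
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), donor_res = character(0),
                      acceptor_res = character(0), distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  hyd <- gd[a$is_polar_hydrogen[gd]]
  hyd <- hyd[a$donor_of[hyd] %in% gd]          # donor heavy must be in-group
  acc <- ga[a$is_acceptor[ga]]
  if (!length(hyd) || !length(acc)) return(empty)
  don <- a$donor_of[hyd]
  x <- frame$coords; box <- frame$box
  dda <- pair_distances(x[don, , drop = FALSE], x[acc, , drop = FALSE], box)
  hit <- which(dda <= d_cut, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  hd <- min_image(x[don[hit[, 1]], , drop = FALSE] - x[hyd[hit[, 1]], , drop = FALSE], box)
  ha <- min_image(x[acc[hit[, 2]], , drop = FALSE] - x[hyd[hit[, 1]], , drop = FALSE], box)
  cosang <- rowSums(hd * ha) /
    (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  keep <- ang >= angle_cut
  if (!any(keep)) return(empty)
  hit <- hit[keep, , drop = FALSE]
  data.frame(donor = don[hit[, 1]], hydrogen = hyd[hit[, 1]],
             acceptor = acc[hit[, 2]],
             donor_res = a$residue_name[don[hit[, 1]]],
             acceptor_res = a$residue_name[acc[hit[, 2]]],
             distance = dda[hit], angle = ang[keep],
             stringsAsFactors = FALSE)
}

#' Per-frame hydrogen-bond counts with trailing running average
#'
#' Counts bonds between the two groups in every frame and smooths with a
#' trailing mean over the previous `window` frames (the first window-1
#' frames average over the history available so far).
#'
#' @param traj an [md_trajectory()].
#' @inheritParams detect_hbonds
#' @param window running-average width in frames (default 100).
#' @return data.frame with `frame`, `time`, `count`, `running_mean`, plus a
#'   `bonds` attribute (list of per-frame bond tables).
#' @export
hbond_series <- function(traj, group_a, group_b, d_cut = 3.0, angle_cut = 120,
                         window = 100L) {
  if (!length(traj$frames)) stop("need at least one frame")
  tabs <- lapply(traj$frames, detect_hbonds, topology = traj$topology,
                 group_a = group_a, group_b = group_b,
                 d_cut = d_cut, angle_cut = angle_cut)
  counts <- vapply(tabs, nrow, integer(1))
  cs <- cumsum(counts)
  n <- length(counts)
  run <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    run[i] <- (cs[i] - if (lo > 1L) cs[lo - 1L] else 0) / (i - lo + 1L)
  }
  out <- data.frame(frame = vapply(traj$frames, `[[`, integer(1), "index"),
                    time = vapply(traj$frames, `[[`, numeric(1), "time"),
                    count = counts, running_mean = run)
  attr(out, "bonds") <- tabs
  out
}

#' Residue-pair hydrogen-bond occupancy and episode lifetimes
#'
#' A residue pair counts as bonded in a frame when at least one atom-level
#' hydrogen bond exists between the two residues. Occupancy is the fraction
#' of frames bonded (order-invariant); the longest contiguous bonded episode
#' is also reported (order-sensitive). Pairs never bonded are absent.
#'
#' @inheritParams hbond_series
#' @return object of class `OccupancyTable`: data.frame sorted by descending
#'   occupancy with `donor_res`, `acceptor_res`, `occupancy`,
#'   `longest_episode` (frames), `n_frames_bonded`.
#' @export
occupancy_lifetimes <- function(traj, group_a, group_b, d_cut = 3.0,
                                angle_cut = 120) {
  tabs <- lapply(traj$frames, detect_hbonds, topology = traj$topology,
                 group_a = group_a, group_b = group_b,
                 d_cut = d_cut, angle_cut = angle_cut)
  nf <- length(tabs)
  keys <- lapply(tabs, function(tb)
    unique(paste(tb$donor_res, tb$acceptor_res, sep = "\r")))
  all_keys <- unique(unlist(keys))
  if (!length(all_keys)) {
    out <- data.frame(donor_res = character(0), acceptor_res = character(0),
                      occupancy = numeric(0), longest_episode = integer(0),
                      n_frames_bonded = integer(0), stringsAsFactors = FALSE)
    class(out) <- c("OccupancyTable", "data.frame")
    return(out)
  }
  pres <- vapply(keys, function(k) all_keys %in% k,
                 logical(length(all_keys)))
  pres <- matrix(pres, nrow = length(all_keys))
  longest <- apply(pres, 1, function(v) {
    r <- rle(v)
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  })
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  out <- data.frame(donor_res = vapply(parts, `[`, "", 1),
                    acceptor_res = vapply(parts, `[`, "", 2),
                    occupancy = rowSums(pres) / nf,
                    longest_episode = as.integer(longest),
                    n_frames_bonded = as.integer(rowSums(pres)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occupancy, out$donor_res, out$acceptor_res), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("OccupancyTable", "data.frame")
  out
}

#' @export
print.OccupancyTable <- function(x, ...) {
  cat(sprintf("OccupancyTable: %d residue pairs\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 15))
  invisible(x)
}
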