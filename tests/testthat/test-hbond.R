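test_that("bond geometry criteria accept and reject as specified", {
  ok <- hb_system(2.8, 180)
  hb <- detect_hbonds(ok$frame, ok$topology, 1:2, 3L)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 2.8, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)

  far <- hb_system(3.5, 180)
  expect_equal(nrow(detect_hbonds(far$frame, far$topology, 1:2, 3L)), 0L)
  bent <- hb_system(2.8, 100)
  expect_equal(nrow(detect_hbonds(bent$frame, bent$topology, 1:2, 3L)), 0L)
  # inclusive boundary: cutoffs set to the exact measured geometry still match
  edge <- hb_system(3.0, 120)
  all_hb <- detect_hbonds(edge$frame, edge$topology, 1:2, 3L,
                          d_cut = 10, angle_cut = 0)
  expect_equal(nrow(detect_hbonds(edge$frame, edge$topology, 1:2, 3L,
                                  d_cut = all_hb$distance,
                                  angle_cut = all_hb$angle)), 1L)

  nod <- system_topology(mass = c(12, 16), molecule_id = 1:2,
                         is_acceptor = c(FALSE, TRUE))
  frn <- particle_frame(rbind(c(0, 0, 0), c(2, 0, 0)), c(10, 10, 10))
  expect_error(detect_hbonds(frn, nod, 1L, 2L), "configuration error")
})

test_that("tightening either cutoff never adds bonds", {
  set.seed(1)
  for (rep in 1:10) {
    d <- runif(1, 2.2, 4); a <- runif(1, 90, 180)
    sys <- hb_system(d, a)
    n <- function(dc, ac) nrow(detect_hbonds(sys$frame, sys$topology, 1:2, 3L,
                                             d_cut = dc, angle_cut = ac))
    expect_lte(n(2.5, 120), n(3.5, 120))
    expect_lte(n(3.0, 150), n(3.0, 120))
  }
})

test_that("detection matches an explicit triplet-loop oracle on scripted frames", {
  tr <- make_hbond_script(10, n_pairs = 4L, occupancy = 0.5, seed = 2)
  a <- tr$topology$atoms
  gall <- seq_len(nrow(a))
  pep <- which(a$role == "peptide"); lip <- which(a$role == "lipid_head")
  for (f in tr$frames) {
    got <- detect_hbonds(f, tr$topology, pep, lip)
    # oracle: loop every (H, acceptor) pair directly
    want <- 0L
    for (h in which(a$is_polar_hydrogen)) for (ac in which(a$is_acceptor)) {
      d <- a$donor_of[h]
      in_groups <- (d %in% pep && ac %in% lip) || (d %in% lip && ac %in% pep)
      if (!in_groups) next
      dda <- minimum_image_distance(f$coords[d, ], f$coords[ac, ], f$box)
      v1 <- f$coords[d, ] - f$coords[h, ]
      v2 <- f$coords[ac, ] - f$coords[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      if (dda <= 3.0 && ang >= 120) want <- want + 1L
    }
    expect_equal(nrow(got), want)
  }
})

test_that("per-frame counts and the trailing running average behave", {
  tr <- make_hbond_script(200, n_pairs = 5L, occupancy = 1, seed = 3)
  a <- tr$topology$atoms
  pep <- which(a$role == "peptide"); lip <- which(a$role == "lipid_head")
  hs <- hbond_series(tr, pep, lip, window = 100L)
  expect_true(all(hs$count == 5))
  expect_true(all(hs$running_mean == 5))

  # scripted alternation 0/10 converges to 5
  tr2 <- make_hbond_script(2, n_pairs = 10L, occupancy = 1, seed = 4)
  off <- make_hbond_script(1, n_pairs = 10L, occupancy = 0, seed = 4)
  frames <- rep(list(tr2$frames[[1]], off$frames[[1]]), 100)
  alt <- md_trajectory(tr2$topology, frames)
  a2 <- tr2$topology$atoms
  pep2 <- which(a2$role == "peptide"); lip2 <- which(a2$role == "lipid_head")
  hs2 <- hbond_series(alt, pep2, lip2, window = 100L)
  expect_equal(hs2$count[1:4], c(10, 0, 10, 0))
  expect_equal(hs2$running_mean[200], 5, tolerance = 1e-9)

  # mean count equals realized occupancy times the pair count, exactly
  tr3 <- make_hbond_script(500, n_pairs = 4L, occupancy = 0.4, seed = 5)
  a3 <- tr3$topology$atoms
  hs3 <- hbond_series(tr3, which(a3$role == "peptide"),
                      which(a3$role == "lipid_head"))
  expect_equal(mean(hs3$count), sum(tr3$truth$realized))
})

test_that("occupancy lifetimes equal the generator's realized fractions", {
  tr <- make_hbond_script(300, n_pairs = 3L, occupancy = c(0.3, 0.6, 0.9),
                          seed = 6)
  a <- tr$topology$atoms
  pep <- which(a$role == "peptide"); lip <- which(a$role == "lipid_head")
  occ <- occupancy_lifetimes(tr, pep, lip)
  got <- occ$occupancy[match(tr$truth$pair_labels, occ$donor_res)]
  expect_equal(got, tr$truth$realized)
  expect_true(all(diff(occ$occupancy) <= 0))   # sorted descending
  # longest episode from the recorded Bernoulli draws
  for (p in 1:3) {
    r <- rle(tr$truth$bonded[, p])
    want <- max(c(0, r$lengths[r$values]))
    expect_equal(occ$longest_episode[occ$donor_res == tr$truth$pair_labels[p]],
                 want)
  }
  # never-bonded pairs are absent
  tr0 <- make_hbond_script(50, n_pairs = 2L, occupancy = c(0.5, 0), seed = 7)
  occ0 <- occupancy_lifetimes(tr0, pep[1:4], lip[1:2])
  expect_false(tr0$truth$pair_labels[2] %in% occ0$donor_res)
})

test_that("occupancy is frame-order invariant but episodes are not", {
  tr <- make_hbond_script(60, n_pairs = 2L, occupancy = 0.5, seed = 8)
  a <- tr$topology$atoms
  pep <- which(a$role == "peptide"); lip <- which(a$role == "lipid_head")
  occ1 <- occupancy_lifetimes(tr, pep, lip)
  set.seed(9)
  shuf <- md_trajectory(tr$topology, tr$frames[sample(60)])
  occ2 <- occupancy_lifetimes(shuf, pep, lip)
  expect_equal(occ1$occupancy, occ2$occupancy)
  # same frames sorted bonded-first maximises the episode length
  ord <- order(-tr$truth$bonded[, 1])
  sorted <- md_trajectory(tr$topology, tr$frames[ord])
  occ3 <- occupancy_lifetimes(sorted, pep, lip)
  lab <- tr$truth$pair_labels[1]
  expect_gte(occ3$longest_episode[occ3$donor_res == lab],
             occ1$longest_episode[occ1$donor_res == lab])
})
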