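test_that("window layouts reproduce inclusive arithmetic sequences", {
  w38 <- generate_windows(70.5, 33.5, 1)
  expect_length(w38, 38L)
  expect_equal(w38[1], 70.5); expect_equal(w38[38], 33.5)
  w49 <- generate_windows(84.5, 36.5, 1)
  expect_length(w49, 49L)
  expect_error(generate_windows(10, 10, 1), "differ")
  expect_length(generate_windows(10, 11, 1), 2L)
  expect_error(generate_windows(0, 1, 0.3), "integer multiple")
  expect_error(generate_windows(0, 1, -1), "positive")
})

test_that("harmonic bias follows the half-k-squared convention and its flag", {
  expect_equal(harmonic_bias(10, 20, 10), 0)
  expect_equal(harmonic_bias(10, 20, 11), 10)
  expect_equal(harmonic_bias(10, 20, 9), harmonic_bias(10, 20, 11))
  expect_equal(harmonic_bias(10, 20, 11, half = FALSE), 20)
})

test_that("single unbiased window reduces to the histogram log, and duplication is a no-op", {
  set.seed(1)
  s <- rnorm(20000, 50, 2)
  # near-zero spring constant approximates an unbiased window
  ds <- suppressWarnings(umbrella_dataset(list(list(center = 50, k = 1e-9,
                                                    samples = s))))
  grid <- seq(40, 60, by = 0.5)
  res <- wham_solve(ds, grid = grid)
  kT <- sim_constants(310)$kT
  h <- hist(s, breaks = grid, plot = FALSE)$counts
  want <- -kT * log(h / sum(h))
  want <- want - min(want[h > 0])
  expect_equal(res$pmf[h > 0], want[h > 0], tolerance = 1e-6)

  dup <- suppressWarnings(umbrella_dataset(list(
    list(center = 50, k = 1e-9, samples = s),
    list(center = 50, k = 1e-9, samples = s))))
  res2 <- wham_solve(dup, grid = grid)
  expect_equal(res2$pmf, res$pmf, tolerance = 1e-9)
})

test_that("raw samples and a pre-binned histogram give identical results", {
  ctr <- seq(45, 58, by = 1)
  ds <- suppressWarnings(sample_biased_windows(double_well, ctr, k = 5,
                                               n_per_window = 2000L, seed = 2))
  grid <- seq(42, 61, by = 0.2)
  res_s <- wham_solve(ds, grid = grid)
  wins_h <- lapply(ds$windows, function(w) {
    h <- hist(w$samples[w$samples >= min(grid) & w$samples <= max(grid)],
              breaks = grid, plot = FALSE)
    list(center = w$center, k = w$k,
         hist = list(breaks = grid, counts = h$counts))
  })
  res_h <- wham_solve(suppressWarnings(umbrella_dataset(wins_h)), grid = grid)
  expect_equal(res_h$pmf, res_s$pmf, tolerance = 1e-9)
  expect_equal(res_h$F, res_s$F, tolerance = 1e-9)
})

test_that("WHAM recovers a planted double well and anchoring is a constant shift", {
  ctr <- generate_windows(70.5, 33.5, 1)
  ds <- suppressWarnings(sample_biased_windows(double_well, ctr, k = 20,
                                               n_per_window = 2000L, seed = 11))
  res <- wham_solve(ds)
  expect_true(res$converged)
  # reproduces the two wells and the barrier to within the stitching noise
  expect_lt(pmf_rms_error(res, double_well, xi_range = c(33.5, 70.5)), 0.6)
  prof_far <- pmf_profile(res)
  expect_equal(prof_far$pmf[which.max(prof_far$xi[!is.na(prof_far$pmf)])], 0)
  prof_a <- pmf_profile(res, anchor = 52)
  d <- prof_a$pmf - prof_far$pmf
  expect_lt(diff(range(d, na.rm = TRUE)), 1e-12)
})

test_that("a monotone repulsive PMF is recovered as monotone within noise", {
  ctr <- generate_windows(60.5, 40.5, 1)
  repulsive <- function(x) 0.25 * (60.5 - x)
  ds <- suppressWarnings(sample_biased_windows(repulsive, ctr, k = 20,
                                               n_per_window = 3000L, seed = 13))
  res <- wham_solve(ds)
  prof <- pmf_profile(res)
  ok <- !is.na(prof$pmf) & res$counts >= 50
  fit <- stats::lm(prof$pmf[ok] ~ prof$xi[ok])
  expect_equal(unname(stats::coef(fit)[2]), -0.25, tolerance = 0.15)
  # decreasing on average: smoothed differences mostly negative in xi, and
  # the near end sits clearly above the far end
  sm <- stats::filter(prof$pmf[ok], rep(1 / 9, 9), sides = 2)
  expect_gt(mean(diff(stats::na.omit(as.vector(sm))) < 0, na.rm = TRUE), 0.75)
  xi_ok <- prof$xi[ok]; pmf_ok <- prof$pmf[ok]
  expect_gt(mean(pmf_ok[rank(xi_ok) <= 5]) - mean(pmf_ok[rank(-xi_ok) <= 5]), 3)
})

test_that("disconnected window groups are rejected", {
  ds <- suppressWarnings(umbrella_dataset(list(
    list(center = 10, k = 20, samples = rnorm(100, 10, 0.2)),
    list(center = 500, k = 20, samples = rnorm(100, 500, 0.2)))))
  expect_error(wham_solve(ds, grid = seq(5, 505, by = 0.2)), "disconnected")
})

test_that("the WHAM gauge is fixed: PMF invariant to window order and seed-stable", {
  ctr <- seq(48, 56, 1)
  ds <- suppressWarnings(sample_biased_windows(double_well, ctr, k = 5,
                                               n_per_window = 1000L, seed = 3))
  res1 <- wham_solve(ds)
  ds_rev <- suppressWarnings(umbrella_dataset(rev(ds$windows)))
  res2 <- wham_solve(ds_rev, grid = res1$grid)
  expect_equal(res1$pmf, res2$pmf, tolerance = 1e-9)
  res3 <- wham_solve(ds)
  expect_identical(res1$pmf, res3$pmf)   # deterministic
})

test_that("umbrella datasets validate windows and warn on non-overlap", {
  expect_error(umbrella_dataset(list()), "at least one")
  expect_error(umbrella_dataset(list(list(center = 1, k = -2, samples = 1:5))),
               "positive spring")
  expect_error(umbrella_dataset(list(list(center = 1, k = 2))), "samples or")
  expect_warning(umbrella_dataset(list(
    list(center = 0, k = 20, samples = c(0, 0.1)),
    list(center = 5, k = 20, samples = c(5, 5.1)))), "overlap")
})

test_that("window sample files round trip through the exchange layout", {
  dir <- withr::local_tempdir()
  ctr <- c(49, 50, 51)
  ds <- suppressWarnings(sample_biased_windows(double_well, ctr, k = 2,
                                               n_per_window = 500L, seed = 4))
  meta <- file.path(dir, "windows.meta")
  lines <- "# T 310"
  for (i in seq_along(ctr)) {
    f <- sprintf("win%02d.dat", i)
    utils::write.table(data.frame(t = seq_along(ds$windows[[i]]$samples) * 0.01,
                                  xi = ds$windows[[i]]$samples),
                       file.path(dir, f), row.names = FALSE, col.names = FALSE)
    lines <- c(lines, sprintf("%s %.2f %.1f", f, ctr[i], 2))
  }
  writeLines(lines, meta)
  rd <- suppressWarnings(read_umbrella_windows(meta))
  expect_equal(rd$temperature, 310)
  expect_length(rd$windows, 3L)
  r1 <- wham_solve(rd)
  r2 <- wham_solve(ds, grid = r1$grid)
  expect_equal(r1$pmf, r2$pmf, tolerance = 1e-6)
})
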