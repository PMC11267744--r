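## Streamline length, fibre-ODF tracking and null tractography.

test_that("streamline length sums Euclidean segments", {
  expect_equal(streamline_length(rbind(c(0, 0, 0), c(1, 0, 0))), 1)
  pts <- cbind(seq(0, 10, by = 0.2), 0, 0)   # 51 collinear points
  expect_equal(streamline_length(pts), 10)
  set.seed(1)
  poly <- matrix(rnorm(30), ncol = 3)
  oracle <- sum(vapply(1:9, function(i)
    as.numeric(dist(poly[i:(i + 1), ])), numeric(1)))
  expect_equal(streamline_length(poly), oracle, tolerance = 1e-9)
  expect_error(streamline_length(matrix(0, 1, 3)), "at least 2")
})

test_that("tracking parameter invariants are enforced", {
  p <- tracking_params()
  expect_equal(p$step_size, 0.2)
  expect_equal(p$max_angle, 30)
  expect_equal(p$amplitude_threshold, 0.1)
  expect_equal(c(p$min_length, p$max_length), c(3, 120))
  expect_equal(p$seeds_per_voxel_axis, 4L)
  expect_error(tracking_params(step_size = 0), "step_size")
  expect_error(tracking_params(min_length = 200), "min_length")
})

## single-direction delta ODF on a uniform grid
delta_field <- function(dir_idx = 1, dims = c(20, 20, 20), subdiv = 2) {
  dirs <- sphere_directions(subdiv)
  amp <- array(0.01, dim = c(dims, nrow(dirs)))
  amp[, , , dir_idx] <- 1
  ai <- safmap:::antipode_index(dirs)[dir_idx]
  amp[, , , ai] <- 1
  odf_field(amp, dirs, origin = c(0, 0, 0), voxel_size = 1)
}

test_that("a delta ODF yields straight streamlines with zero turning", {
  fld <- delta_field(dir_idx = 3)
  tg <- track_odf(fld, matrix(c(10, 10, 10), 1),
                  tracking_params(rng_seed = 2, seeds_per_voxel_axis = 2))
  expect_gt(length(tg$streamlines), 0)
  for (s in tg$streamlines) {
    steps <- diff(s)
    steps <- steps / sqrt(rowSums(steps^2))
    expect_lt(max(acos(pmin(1, steps %*% steps[1, ])) * 180 / pi), 1e-6)
  }
})

test_that("sub-threshold amplitudes yield no streamlines and seeds are counted", {
  dirs <- sphere_directions(1)
  amp <- array(0.05, dim = c(8, 8, 8, nrow(dirs)))
  fld <- odf_field(amp, dirs, c(0, 0, 0), 1)
  sm <- rbind(c(2, 2, 2), c(5, 5, 5), c(6, 3, 4))
  tg <- track_odf(fld, sm, tracking_params(rng_seed = 1))
  expect_length(tg$streamlines, 0)
  expect_equal(attr(tg, "seeds_attempted"), 3 * 64)   # 4x4x4 per voxel
  expect_error(track_odf(fld, matrix(numeric(0), 0, 3)), "empty seed mask")
})

test_that("tracked streamlines satisfy the step, angle and length invariants", {
  fld <- delta_field(dir_idx = 5)
  fld$amplitudes[, , , ] <- 0.5    # isotropic above threshold
  p <- tracking_params(rng_seed = 3)
  tg <- track_odf(fld, rbind(c(10, 10, 10), c(8, 12, 9)), p)
  nulls <- track_null(list(mask = array(TRUE, dim(fld$amplitudes)[1:3]),
                           origin = fld$origin, voxel_size = 1),
                      rbind(c(10, 10, 10)), p, repeats = 2)
  check <- function(tg) {
    expect_gt(length(tg$streamlines), 0)
    for (s in tg$streamlines) {
      st <- diff(s)
      len <- sqrt(rowSums(st^2))
      expect_lt(max(abs(len - 0.2)), 1e-6)
      u <- st / len
      ca <- rowSums(u[-1, , drop = FALSE] * u[-nrow(u), , drop = FALSE])
      expect_true(all(acos(pmin(1, ca)) * 180 / pi <= 30 + 1e-6))
    }
    expect_true(all(tg$lengths >= 3 & tg$lengths <= 120))
  }
  check(tg)
  for (n in nulls) check(n)
})

test_that("null tractography is repeated, deterministic, and mask confined", {
  mask <- array(TRUE, c(16, 16, 8))
  grid <- list(mask = mask, origin = c(0, 0, 0), voxel_size = 1)
  p <- tracking_params(rng_seed = 9, seeds_per_voxel_axis = 2)
  seeds <- rbind(c(8, 8, 4), c(4, 10, 5))
  reps <- track_null(grid, seeds, p, repeats = 10)
  expect_length(reps, 10)
  reps2 <- track_null(grid, seeds, p, repeats = 10)
  expect_identical(lapply(reps, `[[`, "streamlines"),
                   lapply(reps2, `[[`, "streamlines"))
  ## distinct repeats differ
  expect_false(identical(reps[[1]]$streamlines, reps[[2]]$streamlines))
  ## confinement: all points stay inside the masked box (within half a voxel)
  for (tg in reps[1:3]) for (s in tg$streamlines) {
    expect_true(all(s >= -0.75 & s[, 1] <= 15.75))
  }
  expect_error(track_null(list(mask = array(FALSE, c(4, 4, 4)),
                               origin = c(0, 0, 0), voxel_size = 1),
                          rbind(c(2, 2, 2)), p), "empty white-matter mask")
})

test_that("null endpoints are left/right symmetric in a symmetric slab", {
  mask <- array(TRUE, c(30, 20, 6))
  grid <- list(mask = mask, origin = c(0, 0, 0), voxel_size = 1)
  p <- tracking_params(rng_seed = 4, seeds_per_voxel_axis = 4)
  ## seeds on the symmetry plane x = 14.5 (between voxels 15 and 16)
  seeds <- as.matrix(expand.grid(x = 15:16, y = 5:14, z = 3))
  reps <- track_null(grid, seeds, p, repeats = 2)
  ends <- do.call(rbind, lapply(reps, function(tg)
    do.call(rbind, lapply(tg$streamlines, function(s) s[c(1, nrow(s)), ]))))
  left <- sum(ends[, 1] < 14.5); right <- sum(ends[, 1] > 14.5)
  expect_lt(abs(left - right) / (left + right), 0.05)
})

test_that("the null tracker reproduces the length bias", {
  ## end-to-end displacements of random walks: short separations are hit
  ## far more often than long ones
  mask <- array(TRUE, c(40, 20, 6))
  grid <- list(mask = mask, origin = c(0, 0, 0), voxel_size = 1)
  p <- tracking_params(rng_seed = 8, seeds_per_voxel_axis = 2)
  reps <- track_null(grid, as.matrix(expand.grid(x = c(10, 20, 30),
                                                 y = c(5, 10, 15), z = 3)),
                     p, repeats = 2)
  disp <- unlist(lapply(reps, function(tg)
    vapply(tg$streamlines, function(s)
      sqrt(sum((s[1, ] - s[nrow(s), ])^2)), numeric(1))))
  expect_gt(sum(disp < 10), 2 * sum(disp > 20))
})
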