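## SNR computation, phase-map smoothing and sub-area segmentation.

test_that("SNR passes the gate for a strong periodic response and is scale invariant", {
  set.seed(1)
  n <- 64; k <- 8
  t <- seq_len(n)
  strong <- 10 * sin(2 * pi * k * t / n) + rnorm(n, 0, 0.5)
  expect_gte(compute_snr(strong, k), 5)
  noise <- rnorm(n)
  expect_lt(compute_snr(noise, k), 5)
  x <- rnorm(n) + sin(2 * pi * k * t / n)
  expect_equal(compute_snr(2 * x, k), compute_snr(x, k), tolerance = 1e-12)
  expect_equal(compute_snr(0.001 * x, k), compute_snr(x, k), tolerance = 1e-9)
})

test_that("SNR matches a direct discrete Fourier sum oracle", {
  set.seed(3)
  n <- 48; k <- 5
  x <- rnorm(n)
  ## oracle: spectrum by explicit DFT sums, one-sided without DC
  dft <- vapply(1:(floor(n / 2) - 1), function(f)
    abs(sum(x * exp(-2i * pi * f * (0:(n - 1)) / n))), numeric(1))
  oracle <- dft[k] / sd(dft[-k])
  expect_equal(compute_snr(x, k), oracle, tolerance = 1e-10)
  oracle_incl <- dft[k] / sd(dft)
  expect_equal(compute_snr(x, k, exclude_stimulus_bin = FALSE), oracle_incl,
               tolerance = 1e-10)
})

test_that("SNR rejects invalid inputs", {
  expect_error(compute_snr(rep(1, 32), 4), "standard deviation")
  expect_error(compute_snr(rnorm(6), 1), "length")
  expect_error(compute_snr(rnorm(32), 16), "Nyquist")
})

test_that("circular mean wraps correctly", {
  expect_equal(circular_mean(c(350, 10)), 0)
  expect_equal(circular_mean(c(90, 180)), 135)
  expect_true(is.na(circular_mean(c(0, 180))))   # antipodal, undefined
})

test_that("smoothing is the identity for constant maps and zero iterations", {
  w <- small_world()
  nv <- nrow(w$mesh$vertices)
  const <- rep(42, nv)
  snr <- rep(10, nv)
  expect_equal(smooth_phase_map(w$mesh, const, snr, iterations = 4), const,
               tolerance = 1e-12)
  x <- runif(nv, 0, 360)
  expect_identical(smooth_phase_map(w$mesh, x, snr, iterations = 0), x)
})

test_that("one smoothing pass averages the closed 1-ring: star example", {
  ## centre vertex 1 with four leaves; fan of four triangles
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0.2), c(0, -1, 0.2))
  tri <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2))
  star <- surface_mesh(v, tri)
  phase <- c(10, 20, 20, 20, 20)
  out <- smooth_phase_map(star, phase, rep(10, 5), iterations = 1)
  expect_equal(out[1], mean(c(10, 20, 20, 20, 20)))   # = 18
})

test_that("unreliable vertices never contribute but still receive values", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  tri <- rbind(c(1, 2, 3), c(1, 3, 4), c(1, 4, 5), c(1, 5, 2))
  star <- surface_mesh(v, tri)
  phase <- c(1000, 20, 20, 20, 20)
  snr <- c(1, 10, 10, 10, 10)     # centre unreliable
  out <- smooth_phase_map(star, phase, snr, iterations = 1)
  expect_equal(out[1], 20)        # receives the reliable neighbours' mean
  expect_equal(out[2], 20)        # 1000 never contaminates the leaves
})

test_that("circular smoothing averages phases on the circle", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  tri <- rbind(c(1, 2, 3))
  m3 <- surface_mesh(v, tri)
  out <- smooth_phase_map(m3, c(350, 10, 0), rep(10, 3), iterations = 1,
                          circular = TRUE)
  expect_equal(out[1], 0, tolerance = 1e-9)
})

test_that("linear smoothing never increases the value range", {
  w <- small_world()
  nv <- nrow(w$mesh$vertices)
  set.seed(5)
  x <- runif(nv, 0, 100)
  snr <- ifelse(runif(nv) < 0.2, 1, 10)
  prev <- x
  for (it in 1:5) {
    cur <- smooth_phase_map(w$mesh, prev, snr, iterations = 1)
    expect_lte(diff(range(cur)), diff(range(prev)) + 1e-12)
    prev <- cur
  }
})

test_that("noiseless segmentation reproduces the eccentricity cut points", {
  w <- small_world()
  cuts <- w$parc$ecc_cuts$V1
  expect_equal(unname(cuts["cut1"]), 0.89 + (6 - 0.89) / 3, tolerance = 1e-9)
  expect_equal(unname(cuts["cut2"]), 0.89 + 2 * (6 - 0.89) / 3, tolerance = 1e-9)
  ## with a 0-6 degree span the cuts are at 2 and 4 degrees
  map06 <- make_retinotopy(w$mesh, w$labels, 0, 0, 2, ecc_range = c(0, 6))
  p06 <- segment_subareas(w$mesh, w$labels, map06)
  expect_equal(unname(p06$ecc_cuts$V2[c("cut1", "cut2")]), c(2, 4),
               tolerance = 1e-9)
})

test_that("sub-areas partition each area's reliable vertices", {
  w <- small_world()
  all_assigned <- unlist(w$parc$sets)
  expect_false(anyDuplicated(all_assigned) > 0)
  reliable <- which(w$map$snr >= 5)
  expect_setequal(all_assigned, reliable)
  ## uniform eccentricity: equal bin occupancy to within one vertex
  occ <- lengths(w$parc$sets)
  expect_lte(diff(range(occ)), 1)
})

test_that("segmentation fails on degenerate input", {
  w <- small_world()
  one_hemi <- w$map
  one_hemi$polar_angle <- rep(200, length(one_hemi$polar_angle))  # all dorsal
  expect_error(segment_subareas(w$mesh, w$labels, one_hemi), "hemifield")
  starved <- w$map
  starved$snr[w$labels$v2] <- 1
  expect_error(segment_subareas(w$mesh, w$labels, starved), "reliable vertices")
})

test_that("segmentation commutes with vertex relabelling", {
  mesh <- make_mesh(12, 18, 1, seed = 3)
  labels <- make_area_labels(mesh)
  map <- make_retinotopy(mesh, labels, 0, 0, 4)
  parc <- segment_subareas(mesh, labels, map)
  set.seed(9)
  perm <- sample(nrow(mesh$vertices))          # new index of old vertex i
  inv <- order(perm)
  mesh2 <- surface_mesh(mesh$vertices[inv, ],
                        matrix(perm[mesh$triangles], ncol = 3))
  labels2 <- lapply(labels, function(v) sort(perm[v]))
  map2 <- list(eccentricity = map$eccentricity[inv],
               polar_angle = map$polar_angle[inv], snr = map$snr[inv])
  parc2 <- segment_subareas(mesh2, labels2, map2)
  for (k in 1:18)
    expect_setequal(parc2$sets[[k]], perm[parc$sets[[k]]])
})
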