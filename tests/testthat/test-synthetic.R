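## Synthetic cortex generators: retinotopy, planted tractograms, ODF fields.

test_that("synthetic retinotopy spans the mapped eccentricity range", {
  w <- small_world()
  expect_equal(min(w$map$eccentricity), 0.89)
  expect_equal(max(w$map$eccentricity), 6)
  expect_true(all(w$map$polar_angle >= 0 & w$map$polar_angle < 360))
  expect_true(all(w$map$snr >= 0))
})

test_that("exactly the requested fraction of vertices is low-SNR", {
  w <- small_world()
  nv <- nrow(w$mesh$vertices)
  map <- make_retinotopy(w$mesh, w$labels, 0, 0.2, seed = 9)
  expect_equal(sum(map$snr < 5), floor(0.2 * nv))
  expect_true(all(map$snr[map$snr >= 5] >= 5))
})

test_that("generators are deterministic and labels stay disjoint", {
  w <- small_world()
  expect_identical(make_retinotopy(w$mesh, w$labels, 5, 0.1, seed = 3),
                   make_retinotopy(w$mesh, w$labels, 5, 0.1, seed = 3))
  expect_false(anyDuplicated(unlist(w$labels)) > 0)
  expect_error(make_retinotopy(w$mesh, list(v1 = w$labels$v1, v2 = w$labels$v2,
                                            v3 = w$labels$v3[-1]), 0, 0, 1),
               "cover")
})

test_that("noiseless phase maps are nearly fixed points of smoothing", {
  w <- small_world()
  sm_e <- smooth_phase_map(w$mesh, w$map$eccentricity, w$map$snr, 5, 4)
  sm_a <- smooth_phase_map(w$mesh, w$map$polar_angle, w$map$snr, 5, 4,
                           circular = TRUE)
  ## the eccentricity gradient is linear everywhere, so it is (nearly) a
  ## fixed point; the polar-angle triangle wave is linear within strips
  ## but kinks at the meridians, where diffusion rounds the reversals
  expect_lt(max(abs(sm_e - w$map$eccentricity)), 0.2)
  d_ang <- abs(sm_a - w$map$polar_angle)
  d_ang <- pmin(d_ang, 360 - d_ang)
  expect_lt(max(d_ang), 20)
  expect_lt(stats::median(d_ang), 5)
  ## hemifield membership survives smoothing for nearly all vertices
  hemi0 <- w$map$polar_angle > 0 & w$map$polar_angle < 180
  hemi1 <- sm_a > 0 & sm_a < 180
  expect_gte(mean(hemi0 == hemi1), 0.95)
  ## segmentation of the smoothed maps equals the noiseless segmentation
  parc_sm <- segment_subareas(w$mesh, w$labels,
                              list(eccentricity = sm_e, polar_angle = sm_a,
                                   snr = w$map$snr))
  same <- mapply(setequal, parc_sm$sets, w$parc$sets)
  expect_gte(mean(unlist(lapply(1:18, function(k)
    length(intersect(parc_sm$sets[[k]], w$parc$sets[[k]])) /
      length(w$parc$sets[[k]])))), 0.95)
})

test_that("planted tractograms honour counts, lengths and truth bookkeeping", {
  w <- small_world()
  pl <- make_planted_tractogram(w$parc, w$mesh, 40, 12, 10, seed = 5)
  expect_length(pl$tractogram$streamlines, 62)
  expect_true(all(pl$tractogram$lengths >= 3 & pl$tractogram$lengths <= 120))
  expect_equal(table(pl$truth$kind)[["retinotopic"]], 40)
  expect_equal(table(pl$truth$kind)[["intra"]], 10)
  expect_true(all(pl$truth$subarea_i >= 1 & pl$truth$subarea_j <= 18))
  expect_true(all(pl$truth$subarea_i <= pl$truth$subarea_j))
  info <- subarea_table()
  ret <- pl$truth[pl$truth$kind == "retinotopic", ]
  expect_true(all(info$number[ret$subarea_i] == info$number[ret$subarea_j]))
  expect_true(all(info$area[ret$subarea_i] != info$area[ret$subarea_j]))
  intra <- pl$truth[pl$truth$kind == "intra", ]
  expect_true(all(info$area[intra$subarea_i] == info$area[intra$subarea_j]))
  expect_true(all(intra$subarea_i != intra$subarea_j))
  expect_equal(attr(pl$truth, "retinotopic_fraction"), 40 / 62)
  expect_identical(make_planted_tractogram(w$parc, w$mesh, 5, 2, 1, seed = 8),
                   make_planted_tractogram(w$parc, w$mesh, 5, 2, 1, seed = 8))
})

test_that("planted percentage split follows the planted counts exactly", {
  ## 78 retinotopic vs 22 non-retinotopic inter-area streamlines: counting
  ## the truth table reproduces the 78 / 22 split and ratio
  w <- small_world()
  pl <- make_planted_tractogram(w$parc, w$mesh, 78, 22, 0, seed = 13)
  cm <- build_count_matrix(fake_assignments(pl$truth$subarea_i,
                                            pl$truth$subarea_j))
  pm <- percent_matrix(cm)
  r <- overall_retinotopic_ratio(pm)
  expect_equal(r$retinotopic, 78)
  expect_equal(r$nonretinotopic, 22)
  expect_equal(r$ratio, 78 / 22)
})

test_that("an all-retinotopic tractogram has maximal retinotopic order", {
  w <- small_world()
  pl <- make_planted_tractogram(w$parc, w$mesh, 100, 0, 0, seed = 21)
  cm <- build_count_matrix(fake_assignments(pl$truth$subarea_i,
                                            pl$truth$subarea_j))
  r <- overall_retinotopic_ratio(percent_matrix(cm))
  expect_identical(r$ratio, Inf)
  expect_equal(r$retinotopic, 100)
})

test_that("planted generation fails on an empty sub-area", {
  w <- small_world()
  broken <- w$parc
  broken$subarea_of[broken$sets[[4]]] <- NA   # erase V1v4
  broken$sets[[4]] <- integer(0)
  expect_error(make_planted_tractogram(broken, w$mesh, 10, 0, 0, seed = 1),
               "empty sub-area")
})

test_that("ODF field mask equals the amplitude-threshold rule", {
  w <- small_world()
  fld <- make_odf_field(w$mesh, voxel_size = 1.5, n_directions = 42)
  maxamp <- apply(fld$amplitudes, 1:3, max)
  expect_identical(fld$wm_mask, maxamp > 0.1)
  expect_true(all(fld$amplitudes >= 0))
  ## sub-threshold baseline and no bundles: empty mask
  lo <- make_odf_field(w$mesh, voxel_size = 2, n_directions = 12,
                       base_amplitude = 0.05)
  expect_false(any(lo$wm_mask))
})

test_that("bundle ODF peaks align with the bundle tangent", {
  mesh <- make_mesh(18, 24, 0, seed = 1)
  labels <- make_area_labels(mesh)
  map <- make_retinotopy(mesh, labels, 0, 0, 1)
  parc <- segment_subareas(mesh, labels, map)
  fld <- make_odf_field(mesh, bundles = list(c("V1d2", "V3d2")),
                        voxel_size = 1, parcellation = parc,
                        n_directions = 642)
  path <- attr(fld, "bundle_paths")[[1]]
  dims <- dim(fld$amplitudes)[1:3]
  checked <- 0
  np <- nrow(path$points)
  for (q in seq(ceiling(np / 3), floor(2 * np / 3), by = 2)) {
    ijk <- round((path$points[q, ] - fld$origin) / fld$voxel_size)
    if (any(ijk < 0) || any(ijk > dims - 1)) next
    centre <- fld$origin + ijk * fld$voxel_size
    ## the dominant contribution comes from the path point nearest the
    ## voxel centre; compare against that tangent
    qn <- which.min(rowSums(sweep(path$points, 2, centre)^2))
    amps <- fld$amplitudes[ijk[1] + 1, ijk[2] + 1, ijk[3] + 1, ]
    peak_dir <- fld$directions[which.max(amps), ]
    ang <- acos(min(1, abs(sum(peak_dir * path$tangents[qn, ])))) * 180 / pi
    expect_lt(ang, 10)
    checked <- checked + 1
  }
  expect_gte(checked, 5)
  expect_error(make_odf_field(mesh, bundles = list(c(1, 99)),
                              parcellation = parc, n_directions = 12),
               "unknown sub-area")
})
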