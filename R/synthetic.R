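## Synthetic cortex: area labels, retinotopy maps, planted U-fibre
## tractograms and fibre-ODF fields.  These generators produce every input
## the analysis pipeline consumes, with the statistical structure the
## analysis assumes, under explicit seeds.

## The six hemifield strips of the flattened early visual cortex, stacked
## along y in their anatomical (mirrored) order around V1:
## V3d | V2d | V1d | V1v | V2v | V3v.  Polar angle runs as a triangle wave
## across the stack, hitting the vertical meridian (270 / 90 deg) at the
## V1/V2 borders and outer V3 edges and the horizontal meridian (180 deg)
## at the V2/V3 borders and the middle of V1.
strip_table <- function() {
  data.frame(area = c("V3", "V2", "V1", "V1", "V2", "V3"),
             hemifield = c("dorsal", "dorsal", "dorsal",
                           "ventral", "ventral", "ventral"),
             angle_from = c(270, 180, 270, 180, 90, 180),
             angle_to = c(180, 270, 180, 90, 180, 90))
}

strip_of_row <- function(n_rows) {
  cuts <- floor(seq_len(5) * n_rows / 6)
  findInterval(seq_len(n_rows) - 1L, cuts) + 1L
}

#' Split a sheet mesh into V1/V2/V3 bands in flatmap order
#'
#' Areas are laid out as parallel row bands along the y axis in the
#' mirrored stacking of flattened early visual cortex,
#' V3d | V2d | V1d | V1v | V2v | V3v, so that each V1/V2 and V2/V3 border
#' is shared by anatomically adjacent strips (retinotopically
#' corresponding nearest-neighbour sub-areas share borders, and V1 and V3
#' are next-neighbours separated by V2).  Labels are pairwise disjoint and
#' together cover the mesh.
#'
#' @param mesh A mesh from [make_mesh()].
#' @return List with integer vertex-index vectors `v1`, `v2`, `v3`.
#' @export
make_area_labels <- function(mesh) {
  n_rows <- attr(mesh, "n_rows"); n_cols <- attr(mesh, "n_cols")
  if (is.null(n_rows)) stop("mesh lacks grid attributes; use make_mesh()")
  strips <- strip_table()
  strip_of <- strip_of_row(n_rows)[rep(seq_len(n_rows), each = n_cols)]
  area_of <- strips$area[strip_of]
  list(v1 = which(area_of == "V1"),
       v2 = which(area_of == "V2"),
       v3 = which(area_of == "V3"))
}

#' Generate a synthetic retinotopic map
#'
#' Eccentricity increases linearly along the x (column) axis over
#' `ecc_range` (default 0.89-6 degrees, the mapped range of the emulated
#' experiment).  Polar angle runs as a continuous triangle wave along the
#' y axis across the six hemifield strips (V3d to V3v), reversing
#' direction at every areal border (mirror representations): the vertical
#' meridian (270/90 degrees) lies at the V1/V2 borders, the horizontal
#' meridian (180) at the V2/V3 borders and the middle of V1, so each area
#' contains both an upper-field (ventral) and a lower-field (dorsal) half.
#' Independent Gaussian phase noise of `noise_sd` degrees is added to both
#' maps (polar angle wrapped to \[0, 360)).  A random `low_snr_fraction` of
#' vertices (exactly `floor(fraction * n)`) receives SNR below 5; all
#' others receive SNR of at least 5.
#'
#' @param mesh A mesh from [make_mesh()].
#' @param labels Area labels covering the mesh (see [make_area_labels()]).
#' @param noise_sd Phase noise standard deviation in degrees.
#' @param low_snr_fraction Fraction of vertices with unreliable signal
#'   (in \[0, 1)).
#' @param seed Integer seed.
#' @param ecc_range Eccentricity range in degrees of visual angle.
#' @return List of class `retinotopic_map` with per-vertex `eccentricity`,
#'   `polar_angle` and `snr` vectors.
#' @export
make_retinotopy <- function(mesh, labels, noise_sd = 0,
                            low_snr_fraction = 0, seed = 1L,
                            ecc_range = c(0.89, 6)) {
  stopifnot(low_snr_fraction >= 0, low_snr_fraction < 1, noise_sd >= 0)
  nv <- nrow(mesh$vertices)
  check_labels(labels, nv)
  if (length(unique(c(labels$v1, labels$v2, labels$v3))) != nv)
    stop("labels do not cover the mesh")
  rng <- make_rng(seed)
  x <- mesh$vertices[, 1]; y <- mesh$vertices[, 2]
  ecc <- ecc_range[1] +
    (x - min(x)) / max(max(x) - min(x), .Machine$double.eps) * diff(ecc_range)
  n_rows <- attr(mesh, "n_rows"); n_cols <- attr(mesh, "n_cols")
  if (is.null(n_rows)) stop("mesh lacks grid attributes; use make_mesh()")
  strips <- strip_table()
  strip_of <- strip_of_row(n_rows)
  row_of <- rep(seq_len(n_rows), each = n_cols)
  ang <- numeric(nv)
  for (s in 1:6) {
    rows <- which(strip_of == s)
    verts <- which(row_of %in% rows)
    rl <- match(row_of[verts], rows)               # local row, 1..L
    t <- (rl - 0.5) / length(rows)                 # strictly inside (0, 1)
    ang[verts] <- strips$angle_from[s] +
      (strips$angle_to[s] - strips$angle_from[s]) * t
  }
  if (noise_sd > 0) {
    ecc <- pmax(0, ecc + rng$rnorm(nv, 0, noise_sd))
    ang <- (ang + rng$rnorm(nv, 0, noise_sd)) %% 360
  }
  snr <- rng$runif(nv, 6, 25)
  n_low <- floor(low_snr_fraction * nv)
  if (n_low > 0) {
    low <- rng$sample_int(nv, n_low)
    snr[low] <- rng$runif(n_low, 0.5, 4.5)
  }
  structure(list(eccentricity = ecc, polar_angle = ang %% 360, snr = snr),
            class = "retinotopic_map")
}

## Triangles of the mesh fully interior to each sub-area (all three
## vertices in the sub-area's set): endpoints planted on these triangles
## resolve unambiguously under the termination-vertex subset rule.
subarea_interior_triangles <- function(parcellation, mesh) {
  tri <- mesh$triangles
  s1 <- parcellation$subarea_of[tri[, 1]]
  s2 <- parcellation$subarea_of[tri[, 2]]
  s3 <- parcellation$subarea_of[tri[, 3]]
  inside <- !is.na(s1) & s1 == s2 & s1 == s3
  lapply(seq_len(18), function(k) which(inside & s1 == k))
}

subarea_centroids <- function(parcellation, mesh) {
  t(vapply(parcellation$sets, function(vs) {
    if (!length(vs)) rep(NA_real_, 3)
    else colMeans(mesh$vertices[vs, , drop = FALSE])
  }, numeric(3)))
}

## 18x18 matrix of minimum vertex-to-vertex distances between sub-area
## vertex sets (0 on the diagonal); border-sharing pairs score ~ one edge
## length.  Used to weight noise-pair sampling towards border-proximal
## pairs, the misassignment mechanism of gyral bias.
subarea_min_distances <- function(parcellation, mesh) {
  v <- mesh$vertices
  d <- matrix(Inf, 18, 18)
  diag(d) <- 0
  for (i in 1:17) for (j in (i + 1):18) {
    vi <- parcellation$sets[[i]]; vj <- parcellation$sets[[j]]
    if (!length(vi) || !length(vj)) next
    ## min over the cross pairwise distances, blockwise
    m <- Inf
    for (start in seq(1, length(vi), by = 200)) {
      blk <- vi[start:min(length(vi), start + 199)]
      dd <- outer(v[blk, 1], v[vj, 1], "-")^2 +
        outer(v[blk, 2], v[vj, 2], "-")^2 +
        outer(v[blk, 3], v[vj, 3], "-")^2
      m <- min(m, min(dd))
    }
    d[i, j] <- d[j, i] <- sqrt(m)
  }
  d
}

## Cubic-Bezier U-arc between two cortical endpoints, dipping into the
## white matter (against the outward normals), resampled to ~equal spacing.
u_arc <- function(p1, n1, p2, n2, dip, spacing = 0.25) {
  c1 <- p1 - dip * n1
  c2 <- p2 - dip * n2
  t <- seq(0, 1, length.out = 400)
  bez <- outer((1 - t)^3, p1) + outer(3 * (1 - t)^2 * t, c1) +
    outer(3 * (1 - t) * t^2, c2) + outer(t^3, p2)
  seg <- sqrt(rowSums(diff(bez)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  s_out <- seq(0, L, by = spacing)
  if (s_out[length(s_out)] < L) s_out <- c(s_out, L)
  pts <- vapply(1:3, function(d) stats::approx(cum, bez[, d], xout = s_out)$y,
                numeric(length(s_out)))
  pts
}

#' Plant a ground-truth U-fibre tractogram
#'
#' Generates U-shaped streamlines whose two ends terminate just inside the
#' cortex (0.4 mm above the grey/white interface) at triangles fully
#' interior to the intended sub-areas, recording the intended sub-area
#' pair per streamline.  Three populations are planted: retinotopic
#' streamlines connect equal-numbered sub-areas of two different areas
#' (uniform over the 18 such pairs); non-retinotopic streamlines connect
#' unequal-numbered sub-areas of two different areas; intra-area
#' streamlines connect two different sub-areas of the same area.
#' Non-retinotopic and intra-area pairs are sampled with probability
#' decaying exponentially with the minimum distance between the two
#' sub-areas' vertex sets (`noise_length_scale`), so noise concentrates on
#' border-proximal pairs: this emulates termination misassignment by gyral
#' bias and tractography dispersion, which displace streamline endpoints
#' locally across sub-area borders.  All lengths fall in 3-120 mm.
#'
#' @param parcellation A [segment_subareas()] result.
#' @param mesh The mesh the parcellation lives on.
#' @param n_retinotopic,n_nonretinotopic,n_intra Streamline counts (>= 0).
#' @param seed Integer seed.
#' @param thickness Cortical thickness in mm (sets the arc dip).
#' @param noise_length_scale Exponential decay length (mm) for
#'   border-proximity noise-pair sampling.
#' @return List with `tractogram` (class `tractogram`) and `truth`, a data
#'   frame with columns `streamline`, `subarea_i`, `subarea_j` (1-18,
#'   i <= j) and `kind` (`"retinotopic"`, `"nonretinotopic"`, `"intra"`),
#'   plus the planted retinotopic fraction as attribute
#'   `retinotopic_fraction`.
#' @export
make_planted_tractogram <- function(parcellation, mesh, n_retinotopic,
                                    n_nonretinotopic = 0, n_intra = 0,
                                    seed = 1L, thickness = 2.5,
                                    noise_length_scale = 2) {
  stopifnot(n_retinotopic >= 0, n_nonretinotopic >= 0, n_intra >= 0)
  itri <- subarea_interior_triangles(parcellation, mesh)
  if (any(lengths(itri) == 0))
    stop("empty sub-area (no interior triangle): ",
         paste(parcellation$info$name[lengths(itri) == 0], collapse = ", "))
  cen <- subarea_centroids(parcellation, mesh)
  mind <- subarea_min_distances(parcellation, mesh)
  rng <- make_rng(seed)
  info <- parcellation$info
  area_pairs <- list(c(1L, 2L), c(2L, 3L), c(1L, 3L))

  sample_pair <- function(kind) {
    if (kind == "retinotopic") {
      ap <- area_pairs[[rng$sample_int(3, 1)]]
      k <- rng$sample_int(6, 1)
      c((ap[1] - 1L) * 6L + k, (ap[2] - 1L) * 6L + k)
    } else {
      ## all inter-area non-matching pairs (noise) or within-area pairs
      ## (intra), weighted by border proximity
      combos <- expand.grid(i = 1:18, j = 1:18)
      combos <- combos[combos$i < combos$j, ]
      ai <- info$area[combos$i]; aj <- info$area[combos$j]
      ni <- info$number[combos$i]; nj <- info$number[combos$j]
      sel <- if (kind == "nonretinotopic") ai != aj & ni != nj else ai == aj
      combos <- combos[sel, ]
      w <- exp(-mind[cbind(combos$i, combos$j)] / noise_length_scale)
      pick <- rng$sample_int(nrow(combos), 1, prob = w)
      c(combos$i[pick], combos$j[pick])
    }
  }

  endpoint_on <- function(k) {
    t_id <- itri[[k]][rng$sample_int(length(itri[[k]]), 1)]
    tri <- mesh$triangles[t_id, ]
    p <- colMeans(mesh$vertices[tri, , drop = FALSE])
    n <- mesh$normals[t_id, ]
    list(p = p + 0.4 * n, n = n)
  }

  kinds <- c(rep("retinotopic", n_retinotopic),
             rep("nonretinotopic", n_nonretinotopic),
             rep("intra", n_intra))
  n <- length(kinds)
  streamlines <- vector("list", n)
  truth <- data.frame(streamline = seq_len(n),
                      subarea_i = integer(n), subarea_j = integer(n),
                      kind = kinds, stringsAsFactors = FALSE)
  for (s in seq_len(n)) {
    pr <- sample_pair(kinds[s])
    e1 <- endpoint_on(pr[1]); e2 <- endpoint_on(pr[2])
    dist <- sqrt(sum((e1$p - e2$p)^2))
    dip <- max(2 * thickness + 1.5, 0.25 * dist)
    pts <- u_arc(e1$p, e1$n, e2$p, e2$n, dip)
    L <- streamline_length(pts)
    if (L < 3) {                       # deepen very short arcs
      pts <- u_arc(e1$p, e1$n, e2$p, e2$n, dip + 3)
      L <- streamline_length(pts)
    }
    if (L < 3 || L > 120)
      stop("planted streamline length ", round(L, 2), " mm outside 3-120 mm")
    streamlines[[s]] <- pts
    truth$subarea_i[s] <- min(pr); truth$subarea_j[s] <- max(pr)
  }
  tg <- tractogram(streamlines, provenance = "planted")
  attr(truth, "retinotopic_fraction") <- if (n) n_retinotopic / n else NA_real_
  list(tractogram = tg, truth = truth)
}

#' Construct a fibre-ODF field object
#'
#' Container for per-voxel ODF amplitudes sampled on a fixed direction
#' set, with a voxel-centre affine (0-based indices) and a white-matter
#' mask defined, as in the tracking pipeline, as the voxels whose maximum
#' amplitude exceeds `threshold`.
#'
#' @param amplitudes 4-D array (nx, ny, nz, n_directions) of non-negative
#'   amplitudes.
#' @param directions Unit direction matrix (n_directions x 3).
#' @param origin mm coordinates of the centre of voxel (0, 0, 0).
#' @param voxel_size Isotropic voxel edge in mm.
#' @param threshold Amplitude threshold defining the mask (default 0.1).
#' @return Object of class `odf_field` with elements `amplitudes`,
#'   `directions`, `origin`, `voxel_size`, `threshold`, `wm_mask` (logical
#'   3-D array) and `affine`.
#' @export
odf_field <- function(amplitudes, directions, origin, voxel_size,
                      threshold = 0.1) {
  stopifnot(length(dim(amplitudes)) == 4, nrow(directions) == dim(amplitudes)[4],
            voxel_size > 0, all(amplitudes >= 0))
  maxamp <- apply(amplitudes, 1:3, max)
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- origin
  structure(list(amplitudes = amplitudes, directions = directions,
                 origin = origin, voxel_size = voxel_size,
                 threshold = threshold, wm_mask = maxamp > threshold,
                 affine = affine),
            class = "odf_field")
}

#' Generate a synthetic fibre-ODF field under a cortical sheet
#'
#' Builds a voxel grid covering the mesh, assigns a uniform (isotropic)
#' baseline amplitude to the slab extending from `wm_depth` mm below the
#' grey/white interface up through the cortical ribbon (`thickness` mm
#' above it) and a negligible amplitude outside, and superimposes, for
#' each requested bundle, amplitudes sharply peaked along the tangent of a
#' U-arc connecting the two sub-area centroids.  The white-matter mask is
#' the set of voxels whose maximum amplitude exceeds `threshold`; with the
#' default baseline (0.3) it equals the slab, and with
#' `base_amplitude <= threshold` and no bundles it is empty.
#'
#' @param mesh A mesh from [make_mesh()].
#' @param bundles List of length-2 vectors of sub-area indices (1-18) or
#'   sub-area names; may be empty.
#' @param voxel_size Isotropic voxel size in mm.
#' @param seed Integer seed (reserved; the field is deterministic).
#' @param parcellation Required when `bundles` is non-empty.
#' @param n_directions One of 12, 42, 162, 642.
#' @param base_amplitude Isotropic baseline inside the slab.
#' @param peak_amplitude Peak bundle amplitude.
#' @param thickness Cortical ribbon thickness in mm.
#' @param wm_depth White-matter slab depth below the interface in mm.
#' @param threshold Mask amplitude threshold (default 0.1).
#' @return An [odf_field()]; bundle centre-lines and tangents are attached
#'   as attribute `bundle_paths` for diagnostics.
#' @export
make_odf_field <- function(mesh, bundles = list(), voxel_size = 1, seed = 1L,
                           parcellation = NULL, n_directions = 162,
                           base_amplitude = 0.3, peak_amplitude = 1,
                           thickness = 2.5, wm_depth = 8, threshold = 0.1) {
  stopifnot(voxel_size > 0)
  subdiv <- match(n_directions, c(12, 42, 162, 642)) - 1L
  if (is.na(subdiv)) stop("n_directions must be one of 12, 42, 162, 642")
  dirs <- sphere_directions(subdiv)
  v <- mesh$vertices
  margin <- 2
  origin <- c(min(v[, 1]) - margin, min(v[, 2]) - margin,
              min(v[, 3]) - wm_depth - margin)
  top <- c(max(v[, 1]) + margin, max(v[, 2]) + margin,
           max(v[, 3]) + thickness + margin)
  dims <- pmax(2L, as.integer(ceiling((top - origin) / voxel_size)) + 1L)
  centres <- as.matrix(expand.grid(
    x = origin[1] + (seq_len(dims[1]) - 1) * voxel_size,
    y = origin[2] + (seq_len(dims[2]) - 1) * voxel_size,
    z = origin[3] + (seq_len(dims[3]) - 1) * voxel_size))
  nt <- nearest_triangle(centres, mesh)
  in_slab <- nt$height >= -wm_depth & nt$height <= thickness
  amp <- array(0.02, dim = c(dims, nrow(dirs)))
  base <- array(ifelse(in_slab, base_amplitude, 0.02), dim = dims)
  for (d in seq_len(nrow(dirs))) amp[, , , d] <- base

  paths <- list()
  if (length(bundles)) {
    if (is.null(parcellation))
      stop("parcellation is required when planting bundles")
    cen <- subarea_centroids(parcellation, mesh)
    nms <- parcellation$info$name
    resolve <- function(x) {
      if (is.character(x)) x <- match(x, nms)
      x <- as.integer(x)
      if (anyNA(x) || any(x < 1) || any(x > 18))
        stop("bundle references an unknown sub-area")
      x
    }
    ## endpoint normals from the nearest mesh vertex to each centroid
    for (b in seq_along(bundles)) {
      pr <- resolve(bundles[[b]])
      if (length(pr) != 2) stop("each bundle must be a pair of sub-areas")
      nearv <- function(p) which.min(rowSums(sweep(v, 2, p)^2))
      p1 <- cen[pr[1], ]; p2 <- cen[pr[2], ]
      n1 <- mesh$vertex_normals[nearv(p1), ]
      n2 <- mesh$vertex_normals[nearv(p2), ]
      dist <- sqrt(sum((p1 - p2)^2))
      dip <- max(2 * thickness + 1.5, 0.25 * dist)
      pts <- u_arc(p1 - 0.5 * n1, n1, p2 - 0.5 * n2, n2, dip, spacing = 0.5)
      tang <- diff(pts)
      tang <- tang / sqrt(rowSums(tang^2))
      mid <- (pts[-1, , drop = FALSE] + pts[-nrow(pts), , drop = FALSE]) / 2
      paths[[b]] <- list(points = mid, tangents = tang)
      rad <- 2
      for (q in seq_len(nrow(mid))) {
        ijk0 <- floor((mid[q, ] - rad - origin) / voxel_size)
        ijk1 <- ceiling((mid[q, ] + rad - origin) / voxel_size)
        ijk0 <- pmax(ijk0, 0); ijk1 <- pmin(ijk1, dims - 1L)
        if (any(ijk0 > ijk1)) next
        gx <- ijk0[1]:ijk1[1]; gy <- ijk0[2]:ijk1[2]; gz <- ijk0[3]:ijk1[3]
        loc <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
        pos <- sweep(loc * voxel_size, 2, origin, "+")
        d2 <- rowSums(sweep(pos, 2, mid[q, ])^2)
        wsp <- exp(-d2 / (2 * 1.0^2))
        keep <- wsp > 1e-3
        if (!any(keep)) next
        ang_w <- abs(dirs %*% tang[q, ])^40
        contrib <- outer(wsp[keep], as.vector(ang_w)) * peak_amplitude * 0.5
        lin <- 1L + loc[keep, 1] + dims[1] * (loc[keep, 2] + dims[2] * loc[keep, 3])
        nvox_block <- prod(dims)
        for (d in seq_len(nrow(dirs))) {
          ii <- lin + (d - 1L) * nvox_block
          amp[ii] <- pmax(amp[ii], 0.02 + contrib[, d])
        }
      }
    }
  }
  fld <- odf_field(amp, dirs, origin, voxel_size, threshold)
  attr(fld, "bundle_paths") <- paths
  fld
}

#' Simulate per-hemisphere count matrices from a Poisson null
#'
#' Draws symmetric 18x18 count matrices whose element (i, j) is Poisson
#' with the mean given by the corresponding element of `mu` (a single
#' matrix recycled over hemispheres, or a list with one matrix per
#' hemisphere).  Used to study the calibration of the Poisson sum test
#' under a true null.
#'
#' @param mu 18x18 mean matrix (or list of them, one per hemisphere).
#' @param n_hemispheres Number of hemispheres.
#' @param seed Integer seed.
#' @return List of `n_hemispheres` integer count matrices (symmetric, zero
#'   diagonal).
#' @export
simulate_count_matrices <- function(mu, n_hemispheres, seed = 1L) {
  if (!is.list(mu)) mu <- rep(list(mu), n_hemispheres)
  stopifnot(length(mu) == n_hemispheres)
  rng <- make_rng(seed)
  ut <- upper.tri(mu[[1]])
  lapply(mu, function(m) {
    stopifnot(all(dim(m) == c(18, 18)), all(m >= 0))
    out <- matrix(0L, 18, 18, dimnames = dimnames(m))
    out[ut] <- rng$rpois(sum(ut), m[ut])
    out + t(out)
  })
}
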