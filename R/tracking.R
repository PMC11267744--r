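## Simplified probabilistic fibre-ODF tractography and isotropic-field
## null tractography.  Propagation is discretised on the ODF direction
## set: successive step directions are drawn from the cone of set members
## within the curvature threshold of the previous direction, weighted by
## ODF amplitude (fibre tracking) or uniformly (null tracking).  All
## walkers advance in lock-step so the engine is fully vectorised.

#' Tracking parameter set
#'
#' Defaults follow the standard sub-millimetre SAF protocol: curvature
#' threshold 30 degrees per step, seed/tracking amplitude threshold 0.1,
#' step size 0.2 mm, retained streamline lengths 3-120 mm, and 4x4x4
#' regularly spaced seed points per seed voxel.
#'
#' @param step_size Step length in mm (> 0).
#' @param max_angle Maximum angle between successive steps, degrees.
#' @param amplitude_threshold Minimum ODF amplitude for seeding/tracking.
#' @param min_length,max_length Retained length window in mm.
#' @param seeds_per_voxel_axis Seeds per voxel along each axis.
#' @param rng_seed Integer seed.
#' @return List of class `tracking_params`.
#' @export
tracking_params <- function(step_size = 0.2, max_angle = 30,
                            amplitude_threshold = 0.1,
                            min_length = 3, max_length = 120,
                            seeds_per_voxel_axis = 4, rng_seed = 1L) {
  stopifnot(step_size > 0, max_angle > 0, max_angle < 90,
            min_length < max_length, min_length >= 0,
            seeds_per_voxel_axis >= 1)
  structure(list(step_size = step_size, max_angle = max_angle,
                 amplitude_threshold = amplitude_threshold,
                 min_length = min_length, max_length = max_length,
                 seeds_per_voxel_axis = as.integer(seeds_per_voxel_axis),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' Tractogram container
#'
#' @param streamlines List of n x 3 point matrices (mm).
#' @param provenance Character scalar, e.g. `"odf"`, `"null"`, `"planted"`.
#' @return List of class `tractogram` with `streamlines`, `provenance` and
#'   per-streamline `lengths` (mm).
#' @export
tractogram <- function(streamlines, provenance = "odf") {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    stopifnot(ncol(s) == 3, nrow(s) >= 2)
    unname(s)
  })
  structure(list(streamlines = streamlines, provenance = provenance,
                 lengths = vapply(streamlines, streamline_length, numeric(1))),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram (%s): %d streamlines, lengths %.1f-%.1f mm\n",
              x$provenance, length(x$streamlines),
              if (length(x$lengths)) min(x$lengths) else NA,
              if (length(x$lengths)) max(x$lengths) else NA))
  invisible(x)
}

#' Streamline arc length
#'
#' Sum of Euclidean segment lengths along an ordered point sequence.
#'
#' @param points n x 3 matrix with n >= 2.
#' @return Length in mm.
#' @export
streamline_length <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("a streamline needs at least 2 points")
  sum(sqrt(rowSums(diff(points)^2)))
}

## mm -> continuous voxel coordinates (0-based, voxel-centre convention)
vox_coord <- function(points, origin, voxel_size) {
  sweep(points, 2, origin) / voxel_size
}

## Trilinear gather of a 3-D array `vol` at continuous voxel coords (n x 3);
## coordinates outside the grid return `fill`.
trilinear <- function(vol, f, fill = 0) {
  dims <- dim(vol)
  n <- nrow(f)
  i0 <- floor(f)
  w <- f - i0
  out <- numeric(n)
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= dims[1] - 2 & i0[, 2] <= dims[2] - 2 & i0[, 3] <= dims[3] - 2
  ## points in the outer half-voxel shell: clamp to the boundary sample
  edge <- !ok & f[, 1] > -0.5 & f[, 2] > -0.5 & f[, 3] > -0.5 &
    f[, 1] < dims[1] - 0.5 & f[, 2] < dims[2] - 0.5 & f[, 3] < dims[3] - 0.5
  out[!ok & !edge] <- fill
  if (any(edge)) {
    ii <- pmin(pmax(round(f[edge, , drop = FALSE]), 0), rep(dims - 1, each = sum(edge)))
    out[edge] <- vol[1L + ii[, 1] + dims[1] * (ii[, 2] + dims[2] * ii[, 3])]
  }
  if (any(ok)) {
    i0k <- i0[ok, , drop = FALSE]; wk <- w[ok, , drop = FALSE]
    acc <- numeric(sum(ok))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) wk[, 1] else 1 - wk[, 1]) *
        (if (dy) wk[, 2] else 1 - wk[, 2]) *
        (if (dz) wk[, 3] else 1 - wk[, 3])
      lin <- 1L + (i0k[, 1] + dx) + dims[1] * ((i0k[, 2] + dy) + dims[2] * (i0k[, 3] + dz))
      acc <- acc + wt * vol[lin]
    }
    out[ok] <- acc
  }
  out
}

## Trilinear ODF amplitude at points (n x 3 voxel coords) for a matrix of
## candidate direction indices (n x k, NA allowed).  Returns n x k.
amp_interp <- function(field, f, dir_idx) {
  dims <- dim(field$amplitudes)[1:3]
  nvox <- prod(dims)
  n <- nrow(f); k <- ncol(dir_idx)
  i0 <- floor(f)
  w <- f - i0
  ok <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= dims[1] - 2 & i0[, 2] <= dims[2] - 2 & i0[, 3] <= dims[3] - 2
  out <- matrix(0, n, k)
  if (!any(ok)) return(out)
  i0k <- i0[ok, , drop = FALSE]; wk <- w[ok, , drop = FALSE]
  d_ok <- dir_idx[ok, , drop = FALSE]
  base <- matrix(0, sum(ok), k)
  dvalid <- !is.na(d_ok)
  doff <- (d_ok - 1L) * nvox
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) wk[, 1] else 1 - wk[, 1]) *
      (if (dy) wk[, 2] else 1 - wk[, 2]) *
      (if (dz) wk[, 3] else 1 - wk[, 3])
    lin <- 1L + (i0k[, 1] + dx) + dims[1] * ((i0k[, 2] + dy) + dims[2] * (i0k[, 3] + dz))
    idx <- matrix(lin, sum(ok), k) + doff
    vals <- matrix(0, sum(ok), k)
    vals[dvalid] <- field$amplitudes[idx[dvalid]]
    base <- base + wt * vals
  }
  out[ok, ] <- base
  out
}

## Lock-step propagation of N walkers.  `choose_next(points, dir_idx, rng)`
## returns the next direction index per walker (NA terminates).  Returns a
## list of per-walker point matrices (seed first).
propagate_walkers <- function(pos0, dir0, dirs, step_size, max_steps,
                              choose_next, rng) {
  n <- nrow(pos0)
  hist <- array(NA_real_, c(max_steps + 1L, n, 3))
  hist[1, , ] <- pos0
  alive <- !is.na(dir0)
  dir_idx <- dir0
  nsteps <- integer(n)
  pos <- pos0
  for (s in seq_len(max_steps)) {
    if (!any(alive)) break
    ia <- which(alive)
    ## the first step follows the seed direction itself (so the two
    ## bidirectional halves join with zero turning); later steps sample
    ## from the cone of the previous direction
    nd <- choose_next(pos[ia, , drop = FALSE], dir_idx[ia], rng,
                      fixed = s == 1L)
    stopok <- is.na(nd)
    keep <- ia[!stopok]
    alive[ia[stopok]] <- FALSE
    if (!length(keep)) next
    dir_idx[keep] <- nd[!stopok]
    pos[keep, ] <- pos[keep, , drop = FALSE] +
      step_size * dirs[dir_idx[keep], , drop = FALSE]
    hist[s + 1L, keep, ] <- pos[keep, , drop = FALSE]
    nsteps[keep] <- s
  }
  lapply(seq_len(n), function(w) {
    k <- nsteps[w]
    matrix(hist[seq_len(k + 1L), w, ], k + 1L, 3)
  })
}

seed_points_in_voxels <- function(voxels, origin, voxel_size, per_axis) {
  offs <- ((seq_len(per_axis) - 0.5) / per_axis - 0.5) * voxel_size
  grid <- as.matrix(expand.grid(x = offs, y = offs, z = offs))
  centres <- sweep((voxels - 1) * voxel_size, 2, origin, "+")
  pts <- matrix(NA_real_, nrow(centres) * nrow(grid), 3)
  for (g in seq_len(nrow(grid)))
    pts[seq(g, by = nrow(grid), length.out = nrow(centres)), ] <-
      sweep(centres, 2, grid[g, ], "+")
  pts
}

assemble_bidirectional <- function(fwd, bwd, step_size, params, provenance) {
  keep <- list()
  for (w in seq_along(fwd)) {
    f <- fwd[[w]]; b <- bwd[[w]]
    pts <- rbind(b[rev(seq_len(nrow(b)))[-nrow(b)], , drop = FALSE], f)
    if (nrow(pts) < 2) next
    len <- (nrow(pts) - 1) * step_size
    if (len >= params$min_length && len <= params$max_length)
      keep[[length(keep) + 1L]] <- pts
  }
  if (!length(keep))
    structure(list(streamlines = list(), provenance = provenance,
                   lengths = numeric(0)), class = "tractogram")
  else tractogram(keep, provenance = provenance)
}

#' Probabilistic fibre-ODF tractography
#'
#' Seeds `seeds_per_voxel_axis`^3 regularly spaced points in every seed
#' voxel and propagates each seed bidirectionally.  At each step the next
#' direction is drawn from the ODF direction set among directions within
#' `max_angle` of the previous direction whose trilinearly interpolated
#' amplitude at the current point exceeds `amplitude_threshold`, with
#' probability proportional to amplitude; the initial direction is drawn
#' from all admissible directions and the second half starts from its
#' antipode.  A walker terminates when no admissible direction remains or
#' it leaves the volume; each half is capped at half the maximum length.
#' Streamlines outside the `[min_length, max_length]` window are
#' discarded.
#'
#' @param field An [odf_field()].
#' @param seed_mask Logical 3-D array over the field grid, or an n x 3
#'   matrix of 1-based voxel indices.
#' @param params A [tracking_params()].
#' @return A [tractogram()] with provenance `"odf"`.
#' @export
track_odf <- function(field, seed_mask, params = tracking_params()) {
  voxels <- seed_voxel_matrix(seed_mask, dim(field$amplitudes)[1:3])
  if (!nrow(voxels)) stop("empty seed mask")
  rng <- make_rng(params$rng_seed)
  dirs <- field$directions
  cone <- cone_neighbours(dirs, params$max_angle)
  anti <- antipode_index(dirs)
  pts <- seed_points_in_voxels(voxels, field$origin, field$voxel_size,
                               params$seeds_per_voxel_axis)
  n <- nrow(pts)
  f <- vox_coord(pts, field$origin, field$voxel_size)
  all_dirs <- matrix(rep(seq_len(nrow(dirs)), each = n), n)
  amps <- amp_interp(field, f, all_dirs)
  amps[amps <= params$amplitude_threshold] <- NA
  d0 <- gumbel_pick(log(amps), rng)

  choose_next <- function(points, dir_idx, rng, fixed = FALSE) {
    cand <- if (fixed) matrix(dir_idx, ncol = 1)
            else cone[dir_idx, , drop = FALSE]
    fa <- vox_coord(points, field$origin, field$voxel_size)
    a <- amp_interp(field, fa, cand)
    a[is.na(cand) | a <= params$amplitude_threshold] <- NA
    pick <- gumbel_pick(log(a), rng)
    ifelse(is.na(pick), NA_integer_, cand[cbind(seq_len(nrow(cand)), pick)])
  }
  half_steps <- floor(params$max_length / params$step_size / 2)
  fwd <- propagate_walkers(pts, d0, dirs, params$step_size, half_steps,
                           choose_next, rng)
  bwd <- propagate_walkers(pts, ifelse(is.na(d0), NA_integer_, anti[d0]),
                           dirs, params$step_size, half_steps,
                           choose_next, rng)
  tg <- assemble_bidirectional(fwd, bwd, params$step_size, params, "odf")
  attr(tg, "seeds_attempted") <- n
  tg
}

#' Null-distribution tractography in an isotropic field
#'
#' Identical propagation mechanics to [track_odf()], but the next
#' direction is drawn uniformly from the cone of set directions within
#' `max_angle` of the previous one (the initial direction uniformly from
#' the whole set), and propagation is confined to the white-matter mask
#' (trilinear mask value >= 0.5): candidate steps leaving the mask are
#' inadmissible and a walker with no admissible step terminates.  The
#' procedure is repeated `repeats` times with seeds derived from
#' `params$rng_seed`, and the same length window is applied.
#'
#' @param wm_mask An [odf_field()] (its `wm_mask` and grid are used) or a
#'   list with elements `mask` (logical 3-D array), `origin`, `voxel_size`.
#' @param seed_mask As in [track_odf()].
#' @param params A [tracking_params()].
#' @param repeats Number of independent repetitions (default 10).
#' @param directions Optional unit direction matrix; defaults to the
#'   field's direction set or a 162-direction icosphere.
#' @return List of `repeats` [tractogram()]s with provenance `"null"`.
#' @export
track_null <- function(wm_mask, seed_mask, params = tracking_params(),
                       repeats = 10, directions = NULL) {
  if (inherits(wm_mask, "odf_field")) {
    grid <- list(mask = wm_mask$wm_mask, origin = wm_mask$origin,
                 voxel_size = wm_mask$voxel_size)
    if (is.null(directions)) directions <- wm_mask$directions
  } else grid <- wm_mask
  if (is.null(directions)) directions <- sphere_directions(2)
  maskvol <- array(as.numeric(grid$mask), dim = dim(grid$mask))
  if (!any(grid$mask)) stop("empty white-matter mask")
  voxels <- seed_voxel_matrix(seed_mask, dim(maskvol))
  if (!nrow(voxels)) stop("empty seed mask")
  stopifnot(repeats >= 1)
  dirs <- directions
  cone <- cone_neighbours(dirs, params$max_angle)
  anti <- antipode_index(dirs)
  ndir <- nrow(dirs)
  half_steps <- floor(params$max_length / params$step_size / 2)
  pts <- seed_points_in_voxels(voxels, grid$origin, grid$voxel_size,
                               params$seeds_per_voxel_axis)
  n <- nrow(pts)
  inmask0 <- trilinear(maskvol, vox_coord(pts, grid$origin, grid$voxel_size)) >= 0.5

  choose_next <- function(points, dir_idx, rng, fixed = FALSE) {
    cand <- if (fixed) matrix(dir_idx, ncol = 1)
            else cone[dir_idx, , drop = FALSE]
    k <- ncol(cand)
    nn <- nrow(cand)
    new_f <- vox_coord(
      points[rep(seq_len(nn), k), , drop = FALSE] +
        params$step_size * dirs[ifelse(is.na(cand), 1L, cand), , drop = FALSE],
      grid$origin, grid$voxel_size)
    okmask <- matrix(trilinear(maskvol, new_f) >= 0.5, nn, k)
    score <- matrix(NA_real_, nn, k)
    score[okmask & !is.na(cand)] <- 0
    pick <- gumbel_pick(score, rng)
    ifelse(is.na(pick), NA_integer_, cand[cbind(seq_len(nn), pick)])
  }

  lapply(seq_len(repeats), function(r) {
    rng <- make_rng(params$rng_seed + r - 1L)
    d0 <- rep(NA_integer_, n)
    d0[inmask0] <- rng$sample_int(ndir, sum(inmask0), replace = TRUE)
    fwd <- propagate_walkers(pts, d0, dirs, params$step_size, half_steps,
                             choose_next, rng)
    bwd <- propagate_walkers(pts, ifelse(is.na(d0), NA_integer_, anti[d0]),
                             dirs, params$step_size, half_steps,
                             choose_next, rng)
    tg <- assemble_bidirectional(fwd, bwd, params$step_size, params, "null")
    attr(tg, "seeds_attempted") <- n
    tg
  })
}

seed_voxel_matrix <- function(seed_mask, dims) {
  if (is.array(seed_mask) || is.matrix(seed_mask) && is.logical(seed_mask)) {
    if (is.logical(seed_mask) && length(dim(seed_mask)) == 3) {
      stopifnot(all(dim(seed_mask) == dims))
      return(which(seed_mask, arr.ind = TRUE))
    }
  }
  m <- as.matrix(seed_mask)
  stopifnot(ncol(m) == 3)
  storage.mode(m) <- "integer"
  if (any(m < 1) || any(m > rep(dims, each = nrow(m))))
    stop("seed voxel index out of range")
  m
}

## Vectorised categorical sampling: one draw per row of a log-weight
## matrix (NA = inadmissible) via the Gumbel-max trick.  Returns the
## picked column per row, NA where no column is admissible.
gumbel_pick <- function(logw, rng) {
  n <- nrow(logw); k <- ncol(logw)
  g <- -log(-log(rng$runif(n * k)))
  score <- logw + matrix(g, n, k)
  score[is.na(logw)] <- -Inf
  pick <- max.col(score, ties.method = "first")
  none <- !is.finite(score[cbind(seq_len(n), pick)])
  pick[none] <- NA_integer_
  pick
}
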