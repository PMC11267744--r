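## Triangular surface meshes representing the cortical grey/white interface.

#' Construct a surface mesh object
#'
#' Builds the internal `surface_mesh` representation from a vertex matrix
#' and a triangle index matrix, deriving the vertex adjacency (1-ring) and
#' consistently oriented triangle normals.  Triangles are re-wound so that
#' normals point towards positive z ("outward", from white matter into
#' cortex) wherever the normal has a z component; meshes produced by
#' [make_mesh()] always satisfy this.
#'
#' @param vertices Numeric matrix (n x 3) of coordinates in mm.
#' @param triangles Integer matrix (m x 3) of 1-based vertex indices.
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `triangles`, `adjacency` (list of sorted 1-ring neighbour indices),
#'   `normals` (per-triangle unit normals) and `vertex_normals`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, nrow(vertices) >= 3, nrow(triangles) >= 1)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range")
  ## orient: flip winding where the normal points to -z
  n <- triangle_normals(vertices, triangles)
  flip <- n[, 3] < 0
  if (any(flip))
    triangles[flip, ] <- triangles[flip, c(1L, 3L, 2L)]
  n <- triangle_normals(vertices, triangles)

  ## manifold check: each undirected edge in at most two triangles
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (any(table(ekey) > 2))
    stop("mesh is not a 2-manifold patch: an edge is shared by > 2 triangles")

  adj <- vector("list", nrow(vertices))
  eu <- e[!duplicated(ekey), , drop = FALSE]
  for (r in seq_len(nrow(eu))) {
    a <- eu[r, 1]; b <- eu[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))

  vn <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    idx <- triangles[, k]
    vn[, 1] <- vn[, 1] + tapply_sum(n[, 1], idx, nrow(vertices))
    vn[, 2] <- vn[, 2] + tapply_sum(n[, 2], idx, nrow(vertices))
    vn[, 3] <- vn[, 3] + tapply_sum(n[, 3], idx, nrow(vertices))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn <- vn / len

  structure(
    list(vertices = vertices, triangles = triangles, adjacency = adj,
         normals = n, vertex_normals = vn),
    class = "surface_mesh")
}

tapply_sum <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

triangle_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(n^2))
  if (any(len == 0)) stop("degenerate (zero-area) triangle in mesh")
  n / len
}

#' Generate a folded rectangular cortical sheet
#'
#' Emulates a patch of cortex at the grey/white interface as a regular
#' `n_rows` x `n_cols` vertex grid (1 mm spacing by default) folded
#' sinusoidally along the row (y) axis, so that gyral crowns and sulcal
#' fundi exist and run orthogonally to the eccentricity (column / x) axis.
#' The fold phase is randomised from `seed` so area borders fall at varying
#' positions relative to crowns and fundi; the output is deterministic for
#' a given seed.
#'
#' @param n_rows,n_cols Grid dimensions (both >= 4).
#' @param fold_amplitude Peak-to-midline fold height in mm (0 gives a plane).
#' @param seed Integer seed controlling the fold phase.
#' @param spacing Vertex spacing in mm.
#' @param fold_wavelength Fold wavelength along y in mm.
#' @return A [surface_mesh()] with `n_rows * n_cols` vertices and
#'   `2 * (n_rows - 1) * (n_cols - 1)` triangles, plus attributes `n_rows`,
#'   `n_cols` used by the synthetic generators.
#' @export
make_mesh <- function(n_rows, n_cols, fold_amplitude = 0, seed = 1L,
                      spacing = 1, fold_wavelength = 12) {
  if (n_rows < 4 || n_cols < 4)
    stop("degenerate mesh dimensions: need n_rows >= 4 and n_cols >= 4")
  stopifnot(spacing > 0, fold_wavelength > 0, fold_amplitude >= 0)
  phase <- local({
    rng <- make_rng(seed)
    rng$runif(1, 0, 2 * pi)
  })
  ij <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  x <- (ij$col - 1) * spacing
  y <- (ij$row - 1) * spacing
  z <- fold_amplitude * sin(2 * pi * y / fold_wavelength + phase)
  vid <- function(r, c) (r - 1L) * n_cols + c
  r <- rep(seq_len(n_rows - 1L), each = n_cols - 1L)
  c_ <- rep(seq_len(n_cols - 1L), times = n_rows - 1L)
  tri <- rbind(
    cbind(vid(r, c_), vid(r, c_ + 1L), vid(r + 1L, c_)),
    cbind(vid(r + 1L, c_), vid(r, c_ + 1L), vid(r + 1L, c_ + 1L)))
  m <- surface_mesh(cbind(x, y, z), tri)
  attr(m, "n_rows") <- as.integer(n_rows)
  attr(m, "n_cols") <- as.integer(n_cols)
  attr(m, "spacing") <- spacing
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

## Isolated RNG stream: all generators take explicit seeds and never touch
## (or depend on) the global .Random.seed.
make_rng <- function(seed) {
  seed <- as.integer(seed)
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    rpois = function(n, lambda) with_state(rpois(n, lambda)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      with_state(sample(x, size, replace, prob)),
    sample_int = function(n, size, replace = FALSE, prob = NULL)
      with_state(sample.int(n, size, replace, prob)))
}
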