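## Unit-sphere direction sets used to represent ODF amplitudes and to
## discretise streamline propagation directions.

#' Unit direction set from an subdivided icosahedron
#'
#' Returns an antipodally symmetric set of unit vectors obtained by
#' repeatedly subdividing the regular icosahedron and re-projecting onto the
#' sphere.  0, 1, 2 and 3 subdivisions give 12, 42, 162 and 642 directions.
#'
#' @param subdivisions Number of 4-to-1 triangle subdivisions (0 to 4).
#' @return Numeric matrix with one unit row vector per direction.
#' @export
sphere_directions <- function(subdivisions = 2) {
  stopifnot(subdivisions >= 0, subdivisions <= 4)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- unique(rbind(
      cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1])))
    keys <- edge_key(edges[, 1], edges[, 2])
    keep <- !duplicated(keys)
    edges <- edges[keep, , drop = FALSE]
    keys <- keys[keep]
    mid <- (v[edges[, 1], ] + v[edges[, 2], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    mid_idx <- stats::setNames(nrow(v) + seq_len(nrow(mid)), keys)
    v <- rbind(v, mid)
    m12 <- mid_idx[edge_key(f[, 1], f[, 2])]
    m23 <- mid_idx[edge_key(f[, 2], f[, 3])]
    m31 <- mid_idx[edge_key(f[, 3], f[, 1])]
    f <- rbind(
      cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
      cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  dimnames(v) <- NULL
  v
}

## Index of the antipodal partner of each direction (exact for the
## icosphere, which is symmetric under point inversion).
antipode_index <- function(dirs) {
  m <- dirs %*% t(-dirs)
  idx <- max.col(m)
  stopifnot(all(rowSums((dirs + dirs[idx, , drop = FALSE])^2) < 1e-12))
  idx
}

## For each direction, the indices of all directions (self included) within
## `max_angle` degrees.  Returned as a padded integer matrix with NA fill,
## suitable for vectorised per-walker candidate gathering.
cone_neighbours <- function(dirs, max_angle) {
  cosmax <- cos(max_angle * pi / 180)
  g <- dirs %*% t(dirs)
  lst <- apply(g >= cosmax - 1e-12, 1, which, simplify = FALSE)
  k <- max(lengths(lst))
  m <- matrix(NA_integer_, nrow(dirs), k)
  for (i in seq_along(lst)) m[i, seq_along(lst[[i]])] <- lst[[i]]
  m
}
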