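## Assignment of streamlines to ordered sub-area pairs: the intracortical
## length filter, termination-vertex lookup on the grey/white interface
## mesh, and the termination-vertex subset rule.

#' Cortical ribbon model
#'
#' The ribbon is the shell between the grey/white interface mesh and a
#' surface offset by `thickness` mm along the outward normals.  A point is
#' inside the cortex when its signed height along the nearest
#' inner-triangle normal lies in `[0, thickness]` and it sits (to within
#' `lateral_slack`) over that triangle rather than beyond the patch edge.
#'
#' @param mesh Inner (grey/white) [surface_mesh()].
#' @param thickness Cortical thickness in mm (> 0).
#' @param lateral_slack Tolerated lateral excess in mm when testing
#'   membership over curved or edge triangles.
#' @return Object of class `cortical_ribbon`.
#' @export
cortical_ribbon <- function(mesh, thickness = 2.5, lateral_slack = 0.8) {
  stopifnot(inherits(mesh, "surface_mesh"), thickness > 0)
  structure(list(mesh = mesh, thickness = thickness,
                 lateral_slack = lateral_slack,
                 index = build_triangle_index(mesh)),
            class = "cortical_ribbon")
}

## Classify points against the ribbon.  A cheap per-cell z-range prefilter
## skips the exact nearest-triangle query for points that cannot be inside
## the shell; `triangle`/`dist` are only populated for points that passed.
ribbon_classify <- function(points, ribbon) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  idx <- ribbon$index
  cells <- index_cell_of(idx, points)
  zlo <- idx$zmin[cells] - ribbon$lateral_slack
  zhi <- idx$zmax[cells] + ribbon$thickness + ribbon$lateral_slack
  maybe <- is.finite(zlo) & points[, 3] >= zlo & points[, 3] <= zhi
  inside <- rep(FALSE, n)
  height <- rep(NA_real_, n)
  tri <- rep(NA_integer_, n)
  dist <- rep(NA_real_, n)
  if (any(maybe)) {
    nt <- nearest_triangle(points[maybe, , drop = FALSE], ribbon$mesh, idx)
    h <- nt$height
    lat2 <- pmax(nt$dist2 - h^2, 0)
    ins <- h >= 0 & h <= ribbon$thickness & lat2 <= ribbon$lateral_slack^2
    inside[maybe] <- ins
    height[maybe] <- h
    tri[maybe] <- nt$triangle
    dist[maybe] <- sqrt(nt$dist2)
  }
  list(inside = inside, height = height, triangle = tri, dist = dist)
}

#' Intracortical length fraction of a streamline
#'
#' Fraction of a streamline's arc length running inside the cortical
#' ribbon: the sum of lengths of segments whose midpoint is inside,
#' divided by the total length.  Streamlines with fraction above 0.8 are
#' removed downstream to avoid bias from intracortical fibre pathways.
#'
#' @param streamline n x 3 point matrix.
#' @param ribbon A [cortical_ribbon()].
#' @return Fraction in \[0, 1\].
#' @export
intracortical_fraction <- function(streamline, ribbon) {
  streamline <- as.matrix(streamline)
  if (nrow(streamline) < 2) stop("a streamline needs at least 2 points")
  seg <- sqrt(rowSums(diff(streamline)^2))
  if (sum(seg) == 0) stop("zero-length streamline")
  mid <- (streamline[-1, , drop = FALSE] +
            streamline[-nrow(streamline), , drop = FALSE]) / 2
  cls <- ribbon_classify(mid, ribbon)
  sum(seg[cls$inside]) / sum(seg)
}

#' Locate termination vertices of a streamline
#'
#' The two terminations are the first and the last streamline point lying
#' inside the cortical ribbon; each termination's "surrounding vertices"
#' are the three vertices of the nearest triangle of the inner surface.
#' An end is unresolved when no point of the streamline lies inside the
#' cortex or the nearest-triangle distance exceeds `tol`.  Exact distance
#' ties are broken towards the lowest triangle index.
#'
#' @param streamline n x 3 point matrix.
#' @param ribbon A [cortical_ribbon()].
#' @param tol Maximum point-to-triangle distance in mm (default 2).
#' @return List with `end1`, `end2` (integer vertex triples or `NULL`),
#'   `triangles` (the two triangle indices or `NA`) and `resolved`
#'   (logical scalar).
#' @export
locate_end_vertices <- function(streamline, ribbon, tol = 2) {
  streamline <- as.matrix(streamline)
  cls <- ribbon_classify(streamline, ribbon)
  ins <- which(cls$inside)
  if (!length(ins))
    return(list(end1 = NULL, end2 = NULL,
                triangles = c(NA_integer_, NA_integer_), resolved = FALSE))
  i1 <- ins[1]; i2 <- ins[length(ins)]
  ok <- cls$dist[c(i1, i2)] <= tol
  if (!all(ok))
    return(list(end1 = NULL, end2 = NULL,
                triangles = c(NA_integer_, NA_integer_), resolved = FALSE))
  t1 <- cls$triangle[i1]; t2 <- cls$triangle[i2]
  list(end1 = ribbon$mesh$triangles[t1, ],
       end2 = ribbon$mesh$triangles[t2, ],
       triangles = c(t1, t2), resolved = TRUE)
}

#' Assign a located streamline to a sub-area pair
#'
#' Applies the subset rule: an end belongs to the sub-area whose vertex
#' set contains all three surrounding vertices; if no single sub-area
#' contains the triple (the triangle straddles a border or unreliable
#' cortex) the streamline is rejected.  The pair is normalised so that
#' `subarea_i <= subarea_j`.
#'
#' @param end1,end2 Integer vertex triples from [locate_end_vertices()].
#' @param parcellation A [segment_subareas()] result.
#' @return List with `status` (`"accepted"` or `"straddles_border"`) and
#'   `subarea_i`, `subarea_j` (1-18, or `NA` when rejected).
#' @export
assign_connection <- function(end1, end2, parcellation) {
  sub_of <- parcellation$subarea_of
  one <- function(tripl) {
    s <- sub_of[tripl]
    if (anyNA(s) || length(unique(s)) != 1L) NA_integer_ else s[1]
  }
  a <- one(end1); b <- one(end2)
  if (is.na(a) || is.na(b))
    list(status = "straddles_border", subarea_i = NA_integer_,
         subarea_j = NA_integer_)
  else
    list(status = "accepted", subarea_i = min(a, b), subarea_j = max(a, b))
}

#' Assign every streamline of a tractogram to a sub-area pair
#'
#' Runs the intracortical filter (reject when the intracortical fraction
#' exceeds `max_intracortical`), locates termination vertices, and applies
#' the subset rule, for all streamlines at once.
#'
#' @param tract A [tractogram()].
#' @param ribbon A [cortical_ribbon()].
#' @param parcellation A [segment_subareas()] result.
#' @param max_intracortical Rejection threshold on the intracortical
#'   fraction (default 0.8).
#' @param tol Termination distance tolerance in mm (default 2).
#' @return Data frame with one row per streamline: `streamline`, `status`
#'   (`accepted`, `too_intracortical`, `unresolved`, `straddles_border`),
#'   `subarea_i`, `subarea_j`, `length_mm`, `intracortical`, and the end
#'   vertex triples `end1_v1..3`, `end2_v1..3`.
#' @export
assign_streamlines <- function(tract, ribbon, parcellation,
                               max_intracortical = 0.8, tol = 2) {
  sl <- tract$streamlines
  ns <- length(sl)
  out <- data.frame(
    streamline = seq_len(ns),
    status = rep(NA_character_, ns),
    subarea_i = rep(NA_integer_, ns), subarea_j = rep(NA_integer_, ns),
    length_mm = tract$lengths,
    intracortical = rep(NA_real_, ns),
    end1_v1 = NA_integer_, end1_v2 = NA_integer_, end1_v3 = NA_integer_,
    end2_v1 = NA_integer_, end2_v2 = NA_integer_, end2_v3 = NA_integer_,
    stringsAsFactors = FALSE)
  if (!ns) return(out)

  npts <- vapply(sl, nrow, integer(1))
  allpts <- do.call(rbind, sl)
  sid <- rep(seq_len(ns), npts)

  ## segment midpoints for the intracortical fraction
  first_of <- cumsum(c(1L, npts[-ns]))
  is_last <- seq_len(nrow(allpts)) %in% (first_of + npts - 1L)
  midpts <- (allpts[!is_last, , drop = FALSE] +
               allpts[-which(seq_len(nrow(allpts)) %in% first_of), , drop = FALSE]) / 2
  mid_sid <- sid[!is_last]
  seglen <- sqrt(rowSums((allpts[-which(seq_len(nrow(allpts)) %in% first_of), ,
                                 drop = FALSE] -
                            allpts[!is_last, , drop = FALSE])^2))
  mid_cls <- ribbon_classify(midpts, ribbon)
  tot <- tapply_sum(seglen, mid_sid, ns)
  inl <- tapply_sum(seglen * mid_cls$inside, mid_sid, ns)
  frac <- ifelse(tot > 0, inl / tot, 0)
  out$intracortical <- frac
  reject_ic <- frac > max_intracortical
  out$status[reject_ic] <- "too_intracortical"

  kept <- which(!reject_ic)
  if (!length(kept)) return(out)
  keep_pt <- sid %in% kept
  cls <- ribbon_classify(allpts[keep_pt, , drop = FALSE], ribbon)
  sid_k <- sid[keep_pt]
  rows_by_sl <- split(seq_along(sid_k), sid_k)   # names = streamline id

  ## first and last inside-ribbon point per kept streamline
  t1 <- rep(NA_integer_, ns); t2 <- rep(NA_integer_, ns)
  d1 <- rep(NA_real_, ns); d2 <- rep(NA_real_, ns)
  for (nm in names(rows_by_sl)) {
    s <- as.integer(nm)
    rows <- rows_by_sl[[nm]]
    ins <- rows[cls$inside[rows]]
    if (length(ins)) {
      t1[s] <- cls$triangle[ins[1]];  d1[s] <- cls$dist[ins[1]]
      t2[s] <- cls$triangle[ins[length(ins)]]
      d2[s] <- cls$dist[ins[length(ins)]]
    }
  }
  unres <- !reject_ic & (is.na(t1) | d1 > tol | d2 > tol)
  out$status[unres] <- "unresolved"

  res <- which(!reject_ic & !unres)
  if (length(res)) {
    tri <- ribbon$mesh$triangles
    e1 <- tri[t1[res], , drop = FALSE]
    e2 <- tri[t2[res], , drop = FALSE]
    out$end1_v1[res] <- e1[, 1]; out$end1_v2[res] <- e1[, 2]
    out$end1_v3[res] <- e1[, 3]
    out$end2_v1[res] <- e2[, 1]; out$end2_v2[res] <- e2[, 2]
    out$end2_v3[res] <- e2[, 3]
    sub_of <- parcellation$subarea_of
    ## subset rule, vectorised: the triple must map to one sub-area
    sub1 <- cbind(sub_of[e1[, 1]], sub_of[e1[, 2]], sub_of[e1[, 3]])
    sub2 <- cbind(sub_of[e2[, 1]], sub_of[e2[, 2]], sub_of[e2[, 3]])
    ok1 <- rowSums(is.na(sub1)) == 0 & sub1[, 1] == sub1[, 2] &
      sub1[, 1] == sub1[, 3]
    ok2 <- rowSums(is.na(sub2)) == 0 & sub2[, 1] == sub2[, 2] &
      sub2[, 1] == sub2[, 3]
    ok1[is.na(ok1)] <- FALSE
    ok2[is.na(ok2)] <- FALSE
    acc <- ok1 & ok2
    out$status[res[!acc]] <- "straddles_border"
    out$status[res[acc]] <- "accepted"
    out$subarea_i[res[acc]] <- pmin(sub1[acc, 1], sub2[acc, 1])
    out$subarea_j[res[acc]] <- pmax(sub1[acc, 1], sub2[acc, 1])
  }
  out
}
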