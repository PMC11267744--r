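## 18x18 connectivity matrices (counts, percent, closeness), 6x6 inter-area
## blocks and the retinotopic-order ratio.

subarea_names <- function() subarea_table()$name

empty_matrix <- function(mode = "integer") {
  nm <- subarea_names()
  matrix(if (mode == "integer") 0L else 0, 18, 18, dimnames = list(nm, nm))
}

#' Build the 18x18 streamline-count matrix
#'
#' Element (i, j) = (j, i) counts the accepted streamlines assigned to the
#' sub-area pair (i, j).  The diagonal (self connections, within one
#' sub-area) is forced to zero.
#'
#' @param assignments Data frame from [assign_streamlines()] (one
#'   hemisphere).
#' @return Symmetric integer matrix with zero diagonal, class
#'   `count_matrix`.
#' @export
build_count_matrix <- function(assignments) {
  m <- empty_matrix()
  acc <- assignments[!is.na(assignments$status) &
                       assignments$status == "accepted", , drop = FALSE]
  if (nrow(acc)) {
    i <- pmin(acc$subarea_i, acc$subarea_j)
    j <- pmax(acc$subarea_i, acc$subarea_j)
    tab <- table(factor(i, 1:18), factor(j, 1:18))
    m <- m + matrix(as.integer(tab), 18, 18, dimnames = dimnames(m))
    m <- m + t(m) - diag(diag(m))
  }
  diag(m) <- 0L
  class(m) <- c("count_matrix", class(m))
  m
}

#' Percent connectivity matrix
#'
#' Each unique off-diagonal element is the number of streamlines detected
#' between that pair of sub-areas divided by the total number detected
#' between all pairs (self connections excluded), times 100.  The
#' off-diagonal upper-triangle sums to 100.
#'
#' @param counts A symmetric count matrix with zero diagonal.
#' @return Symmetric numeric percent matrix with zero diagonal.
#' @export
percent_matrix <- function(counts) {
  m <- unclass(as.matrix(counts))
  stopifnot(all(dim(m) == 18), isTRUE(all.equal(m, t(m))), all(diag(m) == 0))
  if (any(m < 0)) stop("negative counts")
  total <- sum(m[upper.tri(m)])
  if (total == 0) stop("all-zero count matrix: percent matrix undefined")
  100 * m / total
}

#' Closeness matrix from streamline lengths
#'
#' Element (i, j) is the mean of the reciprocal lengths (1/mm) of all
#' accepted streamlines connecting sub-areas i and j — a proxy for the
#' anatomical proximity of the connected patches.  Elements with no
#' connecting streamline are `NA` (undefined), so an element is positive
#' exactly where the count is positive.
#'
#' @param assignments Data frame from [assign_streamlines()].
#' @return Symmetric numeric matrix (1/mm) with `NA` where undefined.
#' @export
closeness_matrix <- function(assignments) {
  acc <- assignments[!is.na(assignments$status) &
                       assignments$status == "accepted", , drop = FALSE]
  if (nrow(acc) && any(acc$length_mm <= 0)) stop("non-positive streamline length")
  m <- empty_matrix("double")
  m[] <- NA_real_
  if (nrow(acc)) {
    i <- pmin(acc$subarea_i, acc$subarea_j)
    j <- pmax(acc$subarea_i, acc$subarea_j)
    key <- (i - 1L) * 18L + j
    means <- tapply(1 / acc$length_mm, key, mean)
    ki <- (as.integer(names(means)) - 1L) %/% 18L + 1L
    kj <- (as.integer(names(means)) - 1L) %% 18L + 1L
    m[cbind(ki, kj)] <- means
    m[cbind(kj, ki)] <- means
  }
  diag(m) <- NA_real_
  m
}

#' Group-average of percent connectivity matrices
#'
#' Element-wise arithmetic mean across hemispheres; preserves symmetry and
#' the off-diagonal sum of 100.
#'
#' @param matrices Non-empty list of equally sized matrices.
#' @return The mean matrix.
#' @export
group_average <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  d <- dim(matrices[[1]])
  if (!all(vapply(matrices, function(m) all(dim(m) == d), logical(1))))
    stop("matrices differ in shape")
  Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
}

#' Extract a 6x6 inter- or intra-area block
#'
#' @param m 18x18 matrix ordered as [subarea_table()].
#' @param area_row,area_col `"V1"`, `"V2"` or `"V3"`.
#' @return The 6x6 block (rows = `area_row` sub-areas 1-6).
#' @export
subarea_block <- function(m, area_row, area_col) {
  ai <- match(area_row, c("V1", "V2", "V3"))
  aj <- match(area_col, c("V1", "V2", "V3"))
  stopifnot(!is.na(ai), !is.na(aj))
  m[(ai - 1) * 6 + 1:6, (aj - 1) * 6 + 1:6]
}

#' Retinotopic-order ratio of a 6x6 inter-area block
#'
#' In an inter-area block the six diagonal elements are the retinotopic
#' connections (equal sub-area numbers) and the thirty off-diagonal
#' elements the non-retinotopic ones.  The ratio of total retinotopic to
#' non-retinotopic percent connectivity indexes the retinotopic
#' organisation; it is scale invariant.
#'
#' @param block 6x6 non-negative matrix (percent connectivity).
#' @return List with `retinotopic`, `nonretinotopic` (the two sums),
#'   `ratio` and `ratio_1dp` (rounded to 1 decimal as conventionally
#'   reported).  The ratio is `Inf` when the off-diagonal sum is zero but
#'   the diagonal is not.
#' @export
retinotopic_ratio <- function(block) {
  block <- as.matrix(block)
  stopifnot(all(dim(block) == 6))
  if (any(block < 0)) stop("negative block elements")
  r <- sum(diag(block))
  nr <- sum(block) - r
  if (r == 0 && nr == 0) stop("all-zero block: ratio undefined")
  ratio <- if (nr == 0) Inf else r / nr
  list(retinotopic = r, nonretinotopic = nr, ratio = ratio,
       ratio_1dp = round(ratio, 1))
}

#' Overall inter-area retinotopic-order ratio
#'
#' Pools the three inter-area blocks (V1-V2, V2-V3, V1-V3) of an 18x18
#' percent matrix: retinotopic = sum of the three block diagonals,
#' non-retinotopic = sum of the three block off-diagonals.
#'
#' @param m 18x18 percent connectivity matrix.
#' @return As [retinotopic_ratio()].
#' @export
overall_retinotopic_ratio <- function(m) {
  pairs <- list(c("V1", "V2"), c("V2", "V3"), c("V1", "V3"))
  r <- 0; nr <- 0
  for (p in pairs) {
    b <- subarea_block(m, p[1], p[2])
    r <- r + sum(diag(b))
    nr <- nr + sum(b) - sum(diag(b))
  }
  if (r == 0 && nr == 0) stop("all-zero inter-area blocks: ratio undefined")
  ratio <- if (nr == 0) Inf else r / nr
  list(retinotopic = r, nonretinotopic = nr, ratio = ratio,
       ratio_1dp = round(ratio, 1))
}
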