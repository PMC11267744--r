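## Phase-map SNR, surface smoothing and segmentation of V1/V2/V3 into the
## 18 retinotopic sub-areas (3 areas x dorsal/ventral x 3 eccentricity bins).

#' Names and metadata of the 18 retinotopic sub-areas
#'
#' Sub-areas are ordered V1 then V2 then V3; within each area the six
#' sub-areas are numbered 1-6 with 1-3 dorsal and 4-6 ventral, and the
#' eccentricity bin increasing foveal to peripheral within each hemifield
#' (so numbers 1 and 4 share the foveal bin, 2 and 5 the middle bin, 3 and
#' 6 the peripheral bin).  Retinotopic correspondence between two areas
#' pairs equal numbers.
#'
#' @return Data frame with columns `name` (e.g. `"V1d1"`, `"V3v6"`),
#'   `area`, `hemifield` (`"dorsal"`/`"ventral"`), `number` (1-6) and
#'   `ecc_bin` (1-3).
#' @export
subarea_table <- function() {
  data.frame(
    name = paste0(rep(c("V1", "V2", "V3"), each = 6),
                  rep(c("d1", "d2", "d3", "v4", "v5", "v6"), 3)),
    area = rep(c("V1", "V2", "V3"), each = 6),
    hemifield = rep(rep(c("dorsal", "ventral"), each = 3), 3),
    number = rep(1:6, 3),
    ecc_bin = rep(c(1:3, 1:3), 3),
    stringsAsFactors = FALSE)
}

#' Signal-to-noise ratio of a periodic fMRI response
#'
#' SNR of a phase-encoded retinotopy time series: the magnitude of the
#' discrete Fourier spectrum at the stimulus frequency divided by the
#' standard deviation of the (one-sided, DC-excluded) amplitude spectrum.
#' By default the stimulus bin itself is excluded from the spectrum
#' standard deviation, so the denominator estimates the noise floor; set
#' `exclude_stimulus_bin = FALSE` to include it.  The ratio is invariant
#' under positive rescaling of the series.
#'
#' @param timeseries Numeric vector (length >= 8) or matrix with one row
#'   per vertex.
#' @param stimulus_frequency_index Index of the stimulus frequency in
#'   cycles per run (1 = one cycle over the whole series); must lie below
#'   the Nyquist index.
#' @param exclude_stimulus_bin Exclude the stimulus bin from the spectrum
#'   standard deviation (default `TRUE`).
#' @return Numeric vector of non-negative SNR values, one per row.
#' @export
compute_snr <- function(timeseries, stimulus_frequency_index,
                        exclude_stimulus_bin = TRUE) {
  x <- if (is.matrix(timeseries)) timeseries else matrix(timeseries, nrow = 1)
  n <- ncol(x)
  if (n < 8) stop("time series must have length >= 8")
  k <- as.integer(stimulus_frequency_index)
  if (k <= 0 || k >= floor(n / 2))
    stop("stimulus frequency index must lie strictly between 0 and the Nyquist index")
  spec <- abs(stats::mvfft(t(x)))          # n x nvert, bins 0..n-1
  side <- spec[2:(floor(n / 2)), , drop = FALSE]   # one-sided, DC excluded
  sig <- side[k, ]
  noise_rows <- if (exclude_stimulus_bin) setdiff(seq_len(nrow(side)), k)
                else seq_len(nrow(side))
  sds <- apply(side[noise_rows, , drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stop("zero spectrum standard deviation (constant or purely periodic series)")
  unname(sig / sds)
}

#' Circular mean of angles in degrees
#'
#' Unit-vector (resultant) mean; e.g. the circular mean of 350 and 10
#' degrees is 0, not 180.  Returns values in \[0, 360).
#'
#' @param theta Angles in degrees.
#' @param w Optional non-negative weights.
#' @return Mean angle in degrees, or `NA` if the resultant is (numerically)
#'   zero.
#' @export
circular_mean <- function(theta, w = NULL) {
  r <- theta * pi / 180
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * sin(r)); c_ <- sum(w * cos(r))
  if (sqrt(s^2 + c_^2) < 1e-12 * max(sum(w), 1)) return(NA_real_)
  wrap360(atan2(s, c_) * 180 / pi)
}

## wrap to [0, 360), mapping values within rounding error of 360 to 0
wrap360 <- function(x) {
  x <- x %% 360
  x[x >= 360 - 1e-9] <- 0
  x
}

#' Smooth a phase map on the cortical surface with an SNR gate
#'
#' Iteratively replaces each vertex value by the mean over its 1-ring
#' neighbourhood (centre vertex included) restricted to vertices whose SNR
#' meets the threshold, so only vertices with reliable functional signal
#' contribute.  Vertices with no reliable vertex in their neighbourhood
#' keep their current value.  Low-SNR vertices receive smoothed values from
#' reliable neighbours but never contribute their own.  Polar-angle maps
#' should be smoothed circularly (`circular = TRUE`, unit-vector mean);
#' eccentricity linearly.
#'
#' @param mesh A [surface_mesh()].
#' @param phase Per-vertex phase values in degrees.
#' @param snr Per-vertex SNR.
#' @param snr_threshold Reliability gate (default 5).
#' @param iterations Number of smoothing passes (default 4).
#' @param circular Use the circular mean (for polar angle).
#' @return Smoothed per-vertex phase vector.
#' @export
smooth_phase_map <- function(mesh, phase, snr, snr_threshold = 5,
                             iterations = 4, circular = FALSE) {
  nv <- nrow(mesh$vertices)
  stopifnot(length(phase) == nv, length(snr) == nv, iterations >= 0)
  reliable <- snr >= snr_threshold
  ## flat neighbourhood structure for vectorised averaging
  nb <- mesh$adjacency
  centre <- rep(seq_len(nv), lengths(nb) + 1L)
  member <- unlist(lapply(seq_len(nv), function(i) c(i, nb[[i]])))
  use <- reliable[member]
  centre_u <- centre[use]
  member_u <- member[use]
  x <- phase
  for (it in seq_len(iterations)) {
    if (!length(member_u)) break
    if (circular) {
      r <- x[member_u] * pi / 180
      s <- tapply_sum(sin(r), centre_u, nv)
      c_ <- tapply_sum(cos(r), centre_u, nv)
      res <- sqrt(s^2 + c_^2)
      newx <- wrap360(atan2(s, c_) * 180 / pi)
      has <- res > 1e-12
    } else {
      s <- tapply_sum(x[member_u], centre_u, nv)
      cnt <- tapply_sum(rep(1, length(member_u)), centre_u, nv)
      has <- cnt > 0
      newx <- ifelse(has, s / pmax(cnt, 1), x)
    }
    x <- ifelse(has, newx, x)
  }
  x
}

#' Segment V1, V2 and V3 into 18 retinotopic sub-areas
#'
#' Within each area, vertices with reliable retinotopy (SNR at or above the
#' threshold) are first split into dorsal and ventral sets by the smoothed
#' polar angle — the upper visual hemifield, polar angle strictly inside
#' (0, 180) degrees, maps to ventral cortex; boundary (meridian) values go
#' to the dorsal set.  Eccentricity is then min-max normalised to \[0, 1\]
#' over that area's reliable vertices and cut at 1/3 and 2/3, giving three
#' bins equally spaced in the visual-field domain (for a 0-6 degree span
#' these correspond approximately to 0-2, 2-4 and 4-6 degrees).  Bins are
#' lower-inclusive, `[lo, hi)`, with the last bin closed.  Vertices below
#' the SNR threshold are omitted from the parcellation entirely.
#'
#' @param mesh A [surface_mesh()].
#' @param labels List with disjoint integer vertex-index vectors `v1`,
#'   `v2`, `v3`.
#' @param map List with per-vertex `eccentricity`, `polar_angle` (smoothed)
#'   and `snr` vectors.
#' @param snr_threshold SNR gate (default 5).
#' @param allow_empty_hemifield If `FALSE` (default), an area whose
#'   reliable vertices all fall in one hemifield is an error.
#' @return Object of class `subarea_parcellation`: list with `sets` (named
#'   list of 18 vertex-index vectors ordered as [subarea_table()]), `info`
#'   (the metadata table), `subarea_of` (per-vertex sub-area index 1-18 or
#'   `NA`), and `ecc_cuts` (per-area raw eccentricity cut values).
#' @export
segment_subareas <- function(mesh, labels, map, snr_threshold = 5,
                             allow_empty_hemifield = FALSE) {
  nv <- nrow(mesh$vertices)
  stopifnot(length(map$eccentricity) == nv, length(map$polar_angle) == nv,
            length(map$snr) == nv)
  check_labels(labels, nv)
  info <- subarea_table()
  sets <- stats::setNames(vector("list", 18), info$name)
  subarea_of <- rep(NA_integer_, nv)
  ecc_cuts <- list()
  for (ai in 1:3) {
    area <- c("V1", "V2", "V3")[ai]
    verts <- labels[[c("v1", "v2", "v3")[ai]]]
    incl <- verts[map$snr[verts] >= snr_threshold]
    if (length(incl) < 6)
      stop(sprintf("%s has %d reliable vertices; need at least 6",
                   area, length(incl)))
    ang <- map$polar_angle[incl] %% 360
    ventral <- ang > 0 & ang < 180          # upper visual field
    if (!allow_empty_hemifield && (all(ventral) || !any(ventral)))
      stop(sprintf("%s: all reliable vertices fall in one hemifield", area))
    ecc <- map$eccentricity[incl]
    lo <- min(ecc); hi <- max(ecc)
    if (hi <= lo)
      stop(sprintf("%s: eccentricity has no spread; cannot bin", area))
    en <- (ecc - lo) / (hi - lo)
    bin <- ifelse(en < 1 / 3, 1L, ifelse(en < 2 / 3, 2L, 3L))
    ecc_cuts[[area]] <- c(lo = lo, cut1 = lo + (hi - lo) / 3,
                          cut2 = lo + 2 * (hi - lo) / 3, hi = hi)
    for (h in 1:2) {     # 1 = dorsal, 2 = ventral
      inh <- if (h == 1) !ventral else ventral
      for (b in 1:3) {
        k <- (ai - 1L) * 6L + (h - 1L) * 3L + b
        vs <- sort(incl[inh & bin == b])
        sets[[k]] <- vs
        subarea_of[vs] <- k
      }
    }
  }
  structure(list(sets = sets, info = info, subarea_of = subarea_of,
                 ecc_cuts = ecc_cuts),
            class = "subarea_parcellation")
}

check_labels <- function(labels, nv) {
  for (nm in c("v1", "v2", "v3"))
    if (!length(labels[[nm]])) stop("area label ", nm, " is empty")
  all_v <- c(labels$v1, labels$v2, labels$v3)
  if (anyDuplicated(all_v)) stop("V1/V2/V3 labels overlap")
  if (any(all_v < 1) || any(all_v > nv)) stop("label vertex index out of range")
  invisible(TRUE)
}

#' @export
print.subarea_parcellation <- function(x, ...) {
  cat("subarea_parcellation: 18 sub-areas,",
      sum(lengths(x$sets)), "vertices included\n")
  print(stats::setNames(lengths(x$sets), x$info$name))
  invisible(x)
}
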