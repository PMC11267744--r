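## Readers and writers for the interchange formats: TCK tractograms
## (MRtrix track format), ASCII PLY meshes, per-vertex scalar CSV,
## parcellation CSV/JSON, connectivity-matrix CSV and NIfTI volumes.

#' Write a tractogram as a TCK file
#'
#' Writes the MRtrix track format: a text header followed by binary
#' little-endian coordinate triplets, streamlines separated by NaN
#' triplets and the file terminated by an Inf triplet.  `"Float32LE"`
#' (the format's standard datatype) round-trips coordinates at single
#' precision; `"Float64LE"` round-trips exactly.
#'
#' @param tract A [tractogram()].
#' @param path Output file path.
#' @param datatype `"Float32LE"` or `"Float64LE"`.
#' @return `path`, invisibly.
#' @export
write_tck <- function(tract, path, datatype = c("Float32LE", "Float64LE")) {
  datatype <- match.arg(datatype)
  sl <- tract$streamlines
  header_for <- function(offset) {
    paste0("mrtrix tracks\n",
           "datatype: ", datatype, "\n",
           "count: ", length(sl), "\n",
           "provenance: ", tract$provenance, "\n",
           "file: . ", offset, "\n",
           "END\n")
  }
  off <- nchar(header_for(0), type = "bytes")
  while (nchar(header_for(off), type = "bytes") != off)
    off <- nchar(header_for(off), type = "bytes")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header_for(off), con, eos = NULL)
  size <- if (datatype == "Float32LE") 4L else 8L
  for (s in sl) {
    writeBin(as.numeric(t(s)), con, size = size, endian = "little")
    writeBin(rep(NaN, 3), con, size = size, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = size, endian = "little")
  invisible(path)
}

#' Read a TCK tractogram
#'
#' @param path TCK file written by [write_tck()] or MRtrix (Float32LE or
#'   Float64LE datatypes).
#' @return A [tractogram()]; the header's `provenance` field is restored
#'   when present.
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file")
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("unterminated TCK header")
    if (ln == "END") break
    kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[[kv[1]]] <- kv[2]
  }
  datatype <- fields[["datatype"]]
  if (!datatype %in% c("Float32LE", "Float64LE"))
    stop("unsupported TCK datatype: ", datatype)
  size <- if (datatype == "Float32LE") 4L else 8L
  offset <- as.integer(sub("^\\. ", "", fields[["file"]]))
  seek(con, offset)
  nbytes <- file.size(path) - offset
  raw <- readBin(con, "double", n = nbytes / size, size = size,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  isnan <- is.nan(m[, 1])
  isinf <- is.infinite(m[, 1])
  breaks <- which(isnan | isinf)
  starts <- c(1, head(breaks, -1) + 1)
  sl <- list()
  for (k in seq_along(breaks)) {
    if (breaks[k] > starts[k])
      sl[[length(sl) + 1L]] <- m[starts[k]:(breaks[k] - 1), , drop = FALSE]
  }
  tractogram(sl, provenance = fields[["provenance"]] %||% "odf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a surface mesh as ASCII PLY
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property double x", "property double y", "property double z",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$triangles - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' Read an ASCII PLY surface mesh
#'
#' @param path PLY file with vertex x/y/z and triangular faces.
#' @return A [surface_mesh()].
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2])) stop("not an ASCII PLY file")
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  v <- do.call(rbind, lapply(lines[hdr_end + seq_len(nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  f <- do.call(rbind, lapply(lines[hdr_end + nv + seq_len(nf)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (x[1] != 3L) stop("non-triangular face in PLY")
    x[2:4] + 1L
  }))
  surface_mesh(v, f)
}

#' Write per-vertex scalars as CSV
#'
#' Two columns: 0-based `vertex_index` and `value`.
#'
#' @param values Numeric per-vertex vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vertex_scalars <- function(values, path) {
  utils::write.csv(data.frame(vertex_index = seq_along(values) - 1L,
                              value = values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read per-vertex scalars from CSV
#' @param path CSV written by [write_vertex_scalars()].
#' @return Numeric vector ordered by vertex index.
#' @export
read_vertex_scalars <- function(path) {
  d <- utils::read.csv(path)
  d$value[order(d$vertex_index)]
}

#' Write a sub-area parcellation as CSV plus JSON metadata
#'
#' The CSV holds 0-based `vertex_index` and `subarea_index` (0-17, the
#' order of [subarea_table()]); the JSON holds per-sub-area area,
#' hemifield and eccentricity bin plus the raw eccentricity cut values.
#'
#' @param parcellation A [segment_subareas()] result.
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_parcellation <- function(parcellation, csv_path, json_path = NULL) {
  keep <- which(!is.na(parcellation$subarea_of))
  utils::write.csv(data.frame(
    vertex_index = keep - 1L,
    subarea_index = parcellation$subarea_of[keep] - 1L),
    csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(subareas = parcellation$info, ecc_cuts = parcellation$ecc_cuts),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(csv_path)
}

#' Write a connectivity matrix as CSV with sub-area headers
#' @param m 18x18 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  m <- as.matrix(m)
  dimnames(m) <- list(subarea_names(), subarea_names())
  utils::write.csv(m, path, row.names = TRUE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Numeric matrix with sub-area dimnames.
#' @export
read_matrix_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Write a 3-D volume (e.g. a mask) as NIfTI
#'
#' @param vol 3-D array (logical arrays are written as 0/1).
#' @param path Output `.nii` or `.nii.gz` path.
#' @param origin mm coordinates of voxel (0, 0, 0); with `voxel_size`
#'   this defines the voxel-centre affine.
#' @param voxel_size Isotropic voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(vol, path, origin = c(0, 0, 0), voxel_size = 1) {
  a <- array(as.numeric(vol), dim = dim(vol))
  affine <- diag(c(voxel_size, voxel_size, voxel_size, 1))
  affine[1:3, 4] <- origin
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @param path NIfTI file.
#' @return List with `data` (array), `origin`, `voxel_size`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  dat <- array(as.numeric(img), dim = dim(img))
  list(data = dat, origin = as.numeric(aff[1:3, 4]),
       voxel_size = as.numeric(aff[1, 1]))
}
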