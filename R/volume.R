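#' 4D volume series
#'
#' Container for a 4D EPI (or single-volume anatomical/mask) dataset on a
#' regular grid: the intensity array, voxel sizes, repetition time, an
#' orientation code, and run-break information for multi-run acquisitions.
#'
#' @param data Numeric array with 3 or 4 dimensions (x, y, z\[, t\]); a 3D
#'   array is promoted to a single-volume series.
#' @param voxdims Numeric length-3 vector of voxel edge lengths in mm.
#' @param tr Repetition time in seconds (sampling interval of the series).
#' @param orient Three-letter axis-direction code (e.g. `"RAS"`), one letter
#'   per array axis.
#' @param run_lengths Integer vector of per-run volume counts summing to the
#'   number of time points; default a single run.
#' @param raw_range Length-2 stored-unit (unscaled) data range, kept so that
#'   integer-saturation checks see the values as written on disk.
#' @param affine Optional 4x4 voxel-to-world matrix (mm); used only to report
#'   world coordinates, never for resampling.
#'
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, voxdims = c(1, 1, 1), tr = 1,
                          orient = "RAS", run_lengths = NULL,
                          raw_range = NULL, affine = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("'data' must have 3 or 4 dimensions, got ", length(dim(data)))
  voxdims <- as.numeric(voxdims)
  if (length(voxdims) != 3L || any(!is.finite(voxdims)) || any(voxdims <= 0))
    stop("'voxdims' must be 3 positive numbers (mm)")
  nt <- dim(data)[4L]
  if (is.null(run_lengths)) run_lengths <- nt
  run_lengths <- as.integer(run_lengths)
  if (any(run_lengths <= 0L) || sum(run_lengths) != nt)
    stop("'run_lengths' must be positive and sum to the number of volumes (", nt, ")")
  if (is.null(raw_range)) raw_range <- suppressWarnings(range(data, na.rm = TRUE))
  structure(
    list(data = data, voxdims = voxdims, tr = as.numeric(tr),
         orient = toupper(orient), run_lengths = run_lengths,
         raw_range = as.numeric(raw_range), affine = affine),
    class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d x %d  vox %.3g x %.3g x %.3g mm  TR %.3g s  [%s]\n",
              d[1], d[2], d[3], d[4], x$voxdims[1], x$voxdims[2], x$voxdims[3],
              x$tr, x$orient))
  cat(sprintf("  runs: %s | stored range [%.6g, %.6g]\n",
              paste(x$run_lengths, collapse = ", "),
              x$raw_range[1], x$raw_range[2]))
  invisible(x)
}

#' Number of time points of a volume series
#' @param vol A `volume_series`.
#' @return Integer count of volumes.
#' @export
n_timepoints <- function(vol) dim(vol$data)[4L]

#' Read a NIfTI-1 dataset as a volume series
#'
#' Reads a 3D or 4D NIfTI-1 file (`.nii` / `.nii.gz`). Any `scl_slope` /
#' `scl_inter` header scaling is applied to the returned intensities, and the
#' stored-unit (unscaled) data range is retained in `raw_range` so that
#' acquisition checks (e.g. 12-bit saturation at 4095) see on-disk values.
#'
#' @param path Path to the NIfTI file.
#' @param tr Optional repetition time (s) overriding the header value; also
#'   used when the header TR is missing or zero.
#' @param run_lengths Optional per-run volume counts (default: single run).
#' @return A [volume_series()].
#' @export
read_volume4d <- function(path, tr = NULL, run_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  nd <- hdr$dim[1L]
  if (nd > 4L) stop("dataset has ", nd, " dimensions; only 3D/4D supported: ", path)
  dm <- dim(img)
  if (length(dm) < 3L) dm <- c(dm, rep(1L, 3L - length(dm)))
  dat <- array(as.vector(img), dim = dm)
  hdr_tr <- if (nd >= 4L) hdr$pixdim[5L] else 0
  eff_tr <- if (!is.null(tr)) tr else if (is.finite(hdr_tr) && hdr_tr > 0) hdr_tr else 1
  slope <- hdr$scl_slope
  inter <- hdr$scl_inter
  rng <- suppressWarnings(range(dat, na.rm = TRUE))
  raw_rng <- if (is.finite(slope) && slope != 0) (rng - inter) / slope else rng
  vd <- abs(hdr$pixdim[2:4])
  vd[!is.finite(vd) | vd == 0] <- 1   # degenerate axes of low-dim files
  volume_series(dat,
                voxdims = vd,
                tr = eff_tr,
                orient = RNifti::orientation(img),
                run_lengths = run_lengths,
                raw_range = raw_rng,
                affine = unclass(RNifti::xform(img)))
}

#' Write a volume series (or 3D array) as NIfTI-1
#'
#' @param vol A `volume_series`, or a plain 3D/4D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxdims,tr Grid metadata used when `vol` is a bare array.
#' @param datatype NIfTI storage type (RNifti name, e.g. `"float"`, `"int16"`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path, voxdims = c(1, 1, 1), tr = 1,
                         datatype = "float") {
  if (inherits(vol, "volume_series")) {
    dat <- vol$data
    if (dim(dat)[4L] == 1L) dim(dat) <- dim(dat)[1:3]
    voxdims <- vol$voxdims
    tr <- vol$tr
  } else {
    dat <- vol
  }
  img <- RNifti::asNifti(dat)
  pd <- if (length(dim(dat)) == 4L) c(voxdims, tr) else voxdims
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# Drop the time axis of a one-volume series; error if t > 1.
vol3d <- function(vol) {
  if (inherits(vol, "volume_series")) {
    if (dim(vol$data)[4L] != 1L) stop("expected a single-volume series")
    array(vol$data, dim = dim(vol$data)[1:3])
  } else if (length(dim(vol)) == 3L) {
    vol
  } else stop("expected a 3D array or single-volume series")
}

# Coerce mask input (array or volume_series) to logical 3D array.
as_mask <- function(mask, dims = NULL) {
  m <- if (inherits(mask, "volume_series")) vol3d(mask) else mask
  if (length(dim(m)) != 3L) stop("mask must be 3D")
  if (!is.null(dims) && !identical(dim(m), as.integer(dims[1:3])))
    stop("mask grid ", paste(dim(m), collapse = "x"),
         " does not match data grid ", paste(dims[1:3], collapse = "x"))
  m != 0 & !is.na(m)
}

# Extract in-mask voxel time series as a V x T matrix.
masked_matrix <- function(vol, mask) {
  d <- dim(vol$data)
  m <- as_mask(mask, d)
  idx <- which(m)
  if (length(idx) == 0L) stop("mask is empty")
  mat <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4L])[idx, , drop = FALSE]
  attr(mat, "voxel_index") <- idx
  mat
}

# Map linear voxel indices to 1-based (i,j,k) triples.
ijk_of <- function(idx, dims) {
  k <- (idx - 1L) %/% (dims[1L] * dims[2L])
  r <- (idx - 1L) %% (dims[1L] * dims[2L])
  cbind(i = r %% dims[1L] + 1L, j = r %/% dims[1L] + 1L, k = k + 1L)
}

# Voxel (i,j,k) [1-based] to world mm via the affine; identity-scaled fallback.
ijk_to_xyz <- function(ijk, affine = NULL, voxdims = c(1, 1, 1)) {
  ijk <- matrix(ijk, ncol = 3L)
  if (is.null(affine)) {
    sweep(ijk - 1, 2, voxdims, `*`)
  } else {
    t(affine %*% rbind(t(ijk - 1), 1))[, 1:3, drop = FALSE]
  }
}
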