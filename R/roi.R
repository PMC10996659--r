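#' Erosion depth of a binary ROI
#'
#' Depth of each ROI voxel under repeated 6-neighbor (face-adjacent) erosion:
#' a voxel removed by the k-th erosion pass has depth k, so boundary voxels
#' (including voxels on the grid edge — out-of-grid counts as background)
#' have depth 1. This equals the city-block (L1) distance to the nearest
#' background voxel and is computed by sequential per-axis distance sweeps.
#' The maximum depth (`Dvox`) shrinks as an ROI thins, which is how poor
#' coverage shows up in the ROI table.
#'
#' @param roi_mask 3D binary array (nonempty).
#' @return List with `depth` (3D integer array, 0 outside the ROI) and
#'   `max_depth`.
#' @export
roi_depth <- function(roi_mask) {
  m <- as_mask(roi_mask)
  if (!any(m)) stop("ROI mask is empty")
  d <- dim(m)
  big <- sum(d) + 3
  dist <- array(big, dim = d)
  dist[!m] <- 0
  # out-of-grid is background: seed a value of 1 at in-mask border voxels by
  # sweeping over a zero-padded array
  pd <- d + 2L
  pad <- array(0, dim = pd)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- dist
  pad[pad == 0] <- 0
  # forward/backward 1D sweeps along each axis give the exact L1 transform
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(pad, perm)
    da <- dim(a)
    mat <- matrix(a, nrow = da[1L])
    for (i in 2:da[1L]) mat[i, ] <- pmin(mat[i, ], mat[i - 1L, ] + 1)
    for (i in (da[1L] - 1L):1L) mat[i, ] <- pmin(mat[i, ], mat[i + 1L, ] + 1)
    a <- array(mat, dim = da)
    pad <- aperm(a, order(perm))
  }
  depth <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  depth[!m] <- 0L
  list(depth = depth, max_depth = max(depth))
}

#' Per-ROI TSNR and shape table
#'
#' For every distinct nonzero label in an integer atlas volume: voxel count
#' (`Nvox`), count of zero-valued statistic voxels (`Nzer`), the five-number
#' summary of the statistic over nonzero voxels (`Tmin`, `T25`, `Tmed`,
#' `T75`, `Tmax`; linear-interpolation quantiles), the maximum erosion depth
#' (`Dvox`), and the (i, j, k) and world (x, y, z mm) coordinates of a
#' maximum-depth voxel (ties broken by smallest i, j, k lexicographically).
#' An ROI with no nonzero statistic voxels reports zero quantiles and a
#' severe warning.
#'
#' @param tsnr A [stat_volume()] (typically TSNR) or 3D array.
#' @param atlas Integer-labeled 3D array (or single-volume series) on the
#'   same grid; 0 = background.
#' @param labels Optional named translation `value -> name` (named character
#'   vector, names = atlas values).
#' @param affine Optional 4x4 voxel-to-world matrix for the mm coordinates.
#' @param voxdims Voxel sizes used when `affine` is absent.
#' @return A tibble with one row per ROI.
#' @export
roi_table <- function(tsnr, atlas, labels = NULL, affine = NULL,
                      voxdims = c(1, 1, 1)) {
  tv <- if (inherits(tsnr, "stat_volume")) tsnr$data else tsnr
  at <- vol3d(atlas)
  if (!identical(dim(tv), dim(at))) stop("atlas grid does not match statistic grid")
  vals <- sort(unique(at[at != 0]))
  if (length(vals) == 0L) stop("atlas has no nonzero labels")
  rows <- lapply(vals, function(v) {
    roi <- at == v
    tvals <- tv[roi]
    nvox <- sum(roi)
    nzer <- sum(tvals == 0)
    nz <- tvals[tvals != 0]
    q <- if (length(nz) > 0L)
      stats::quantile(nz, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    else rep(0, 5L)
    dep <- roi_depth(roi)
    peak_idx <- which(dep$depth == dep$max_depth)
    ijk <- ijk_of(peak_idx, dim(at))
    ord <- order(ijk[, 1L], ijk[, 2L], ijk[, 3L])
    pk <- ijk[ord[1L], ]
    xyz <- ijk_to_xyz(pk, affine, voxdims)
    nm <- if (!is.null(labels) && !is.na(labels[as.character(v)]))
      labels[[as.character(v)]] else as.character(v)
    tibble::tibble(label = nm, value = v, Nvox = nvox, Nzer = nzer,
                   Tmin = q[1L], T25 = q[2L], Tmed = q[3L], T75 = q[4L],
                   Tmax = q[5L], Dvox = dep$max_depth,
                   i = pk[["i"]], j = pk[["j"]], k = pk[["k"]],
                   x = xyz[1L], y = xyz[2L], z = xyz[3L])
  })
  do.call(rbind, rows)
}

#' Default grading thresholds for the ROI table
#' @return Named list of threshold vectors used by [roi_warn()].
#' @export
roi_warn_config <- function() {
  list(
    nzer_frac = c(mild = 0.05, medium = 0.25, severe = 0.75),
    nvox_small = c(mild = 20, medium = 10, severe = 5),   # warn when below
    dvox_small = c(mild = 3, medium = 2, severe = 1),     # warn when below
    t75_low = c(mild = 100, medium = 50, severe = 25),    # warn when below
    slope_high = c(mild = 0.3, medium = 0.6, severe = 1.0)
  )
}

#' Graded warnings for ROI-table rows
#'
#' Grades each quality-relevant cell of an ROI table: fraction of
#' zero-statistic voxels (rising is bad), small voxel count, small erosion
#' depth, low T75, and a high spread slope `(T75 - T25) / Tmed` (an
#' undefined slope at `Tmed = 0` is severe).
#'
#' @param table A tibble from [roi_table()].
#' @param config Threshold list as returned by [roi_warn_config()].
#' @return The table with added columns `warn_nzer`, `warn_nvox`,
#'   `warn_dvox`, `warn_t75`, `warn_slope`, and `warn_max`.
#' @export
roi_warn <- function(table, config = roi_warn_config()) {
  below <- function(v, thr) {
    if (v < thr[["severe"]]) "severe" else if (v < thr[["medium"]]) "medium"
    else if (v < thr[["mild"]]) "mild" else "none"
  }
  n <- nrow(table)
  wz <- wn <- wd <- wt <- ws <- character(n)
  for (r in seq_len(n)) {
    row <- table[r, ]
    wz[r] <- grade_level(row$Nzer / row$Nvox, config$nzer_frac)
    wn[r] <- below(row$Nvox, config$nvox_small)
    wd[r] <- below(row$Dvox, config$dvox_small + 1)  # strict "below" on counts
    wt[r] <- below(row$T75, config$t75_low)
    ws[r] <- if (row$Tmed == 0) "severe"
             else grade_level((row$T75 - row$T25) / row$Tmed, config$slope_high)
    if (row$Nzer == row$Nvox) wz[r] <- "severe"
  }
  table$warn_nzer <- wz; table$warn_nvox <- wn; table$warn_dvox <- wd
  table$warn_t75 <- wt; table$warn_slope <- ws
  table$warn_max <- vapply(seq_len(n), function(r)
    aggregate_warns(as.list(c(wz[r], wn[r], wd[r], wt[r], ws[r])))$level,
    character(1L))
  table
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks are defined to overlap
#' perfectly (value 1, with a `"both_empty"` note attribute).
#'
#' @param a,b 3D binary arrays (or single-volume series) on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
mask_dice <- function(a, b) {
  ma <- as_mask(a); mb <- as_mask(b)
  if (!identical(dim(ma), dim(mb))) stop("masks must share a grid")
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0L) return(structure(1, note = "both_empty"))
  2 * sum(ma & mb) / (na + nb)
}
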