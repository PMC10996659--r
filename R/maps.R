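#' Statistic volume
#'
#' A 3D map derived from a time series (TSNR, correlation, radial
#' correlation), tagged with its kind and processing stage.
#'
#' @param data 3D numeric array.
#' @param kind One of `"tsnr"`, `"corr"`, `"radcor"`.
#' @param stage Free-form stage tag (e.g. `"volreg"`, `"regress"`).
#' @param mask Logical 3D array the statistic was computed within (optional).
#' @param ... Extra scalar attributes stored on the object (e.g. display
#'   defaults, zero-variance counters).
#' @return An object of class `stat_volume`.
#' @export
stat_volume <- function(data, kind = c("tsnr", "corr", "radcor"),
                        stage = "", mask = NULL, ...) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3L) stop("stat_volume data must be 3D")
  extra <- list(...)
  structure(c(list(data = data, kind = kind, stage = stage, mask = mask), extra),
            class = "stat_volume")
}

#' @export
print.stat_volume <- function(x, ...) {
  v <- if (is.null(x$mask)) x$data else x$data[x$mask]
  cat(sprintf("<stat_volume> %s%s  %s  range [%.4g, %.4g], median %.4g\n",
              x$kind, if (nzchar(x$stage)) paste0("/", x$stage) else "",
              paste(dim(x$data), collapse = "x"),
              min(v), max(v), stats::median(v)))
  invisible(x)
}

#' Remove per-run polynomial trends from row time series
#'
#' Fits and removes a polynomial of the given order (Legendre-style
#' orthogonal basis including the constant term) independently within each
#' run, for every row of a V x T matrix.
#'
#' @param y V x T numeric matrix (rows are voxel series), or a length-T vector.
#' @param order Polynomial order (0 = mean removal).
#' @param run_lengths Per-run column counts summing to T.
#' @return Residual matrix of the same shape (vector in, vector out).
#' @export
detrend_poly <- function(y, order = 2L, run_lengths = NULL) {
  vec_in <- is.null(dim(y))
  y <- if (vec_in) matrix(y, nrow = 1L) else as.matrix(y)
  nt <- ncol(y)
  if (order < 0L) stop("order must be >= 0")
  if (is.null(run_lengths)) run_lengths <- nt
  if (sum(run_lengths) != nt) stop("run_lengths must sum to ", nt)
  off <- 0L
  for (rl in run_lengths) {
    if (rl < order + 2L)
      stop("run of length ", rl, " too short for polynomial order ", order)
    cols <- off + seq_len(rl)
    x <- seq(-1, 1, length.out = rl)
    basis <- cbind(rep(1 / sqrt(rl), rl),
                   if (order >= 1L) stats::poly(x, degree = order))
    q <- qr.Q(qr(basis))
    yr <- y[, cols, drop = FALSE]
    y[, cols] <- yr - (yr %*% q) %*% t(q)
    off <- off + rl
  }
  if (vec_in) drop(y) else y
}

#' Temporal signal-to-noise ratio map
#'
#' Per voxel, mean of the signal series divided by the standard deviation of
#' the noise series. Voxels whose noise series has zero variance are set to 0
#' and counted (`n_zero_sd` attribute). Two conventional stages:
#' [tsnr_volreg()] uses the full series as signal and its own detrended
#' residual as noise; [tsnr_regress()] pairs the full series with supplied
#' regression residuals.
#'
#' @param signal A [volume_series()]: the "signal" series.
#' @param noise A [volume_series()] on the same grid/T: the "noise" series.
#' @param mask 3D binary mask.
#' @param stage Stage tag recorded on the result.
#' @return A [stat_volume()] of kind `"tsnr"` (0 outside the mask).
#' @export
tsnr_map <- function(signal, noise, mask, stage = "") {
  if (!identical(dim(signal$data), dim(noise$data)))
    stop("signal and noise grids differ")
  nt <- n_timepoints(signal)
  if (nt < 2L) stop("need at least 2 time points")
  m <- as_mask(mask, dim(signal$data))
  s <- masked_matrix(signal, m)
  n <- masked_matrix(noise, m)
  mu <- rowMeans(s)
  sdv <- sqrt(rowSums((n - rowMeans(n))^2) / (nt - 1L))
  tsnr <- ifelse(sdv > 0, mu / sdv, 0)
  out <- array(0, dim = dim(signal$data)[1:3])
  out[m] <- tsnr
  stat_volume(out, kind = "tsnr", stage = stage, mask = m,
              n_zero_sd = sum(sdv == 0))
}

#' @rdname tsnr_map
#' @param vol A [volume_series()].
#' @param order Detrending polynomial order for the volreg-stage noise.
#' @export
tsnr_volreg <- function(vol, mask, order = 2L) {
  m <- as_mask(mask, dim(vol$data))
  noise <- vol
  d <- dim(vol$data)
  y <- matrix(vol$data, nrow = prod(d[1:3]), ncol = d[4L])
  idx <- which(m)
  y[idx, ] <- detrend_poly(y[idx, , drop = FALSE], order = order,
                           run_lengths = vol$run_lengths)
  noise$data <- array(y, dim = d)
  tsnr_map(vol, noise, m, stage = "volreg")
}

#' @rdname tsnr_map
#' @param errts A [volume_series()] of regression residuals.
#' @export
tsnr_regress <- function(vol, errts, mask) {
  tsnr_map(vol, errts, mask, stage = "regress")
}

#' Global correlation (GCOR)
#'
#' Average over all in-mask voxel pairs (self-pairs included) of the Pearson
#' correlation of their time series, computed as the squared Euclidean norm
#' of the mean of the demeaned, unit-normalized series. Zero-variance voxels
#' are excluded.
#'
#' @param vol A [volume_series()] or a V x T matrix.
#' @param mask 3D binary mask (ignored for matrix input).
#' @return Scalar in \[0, 1\].
#' @export
gcor <- function(vol, mask = NULL) {
  y <- if (inherits(vol, "volume_series")) masked_matrix(vol, mask) else as.matrix(vol)
  y <- y - rowMeans(y)
  nrm <- sqrt(rowSums(y^2))
  ok <- nrm > 0
  if (sum(ok) < 2L) stop("fewer than 2 voxels with nonzero variance")
  u <- y[ok, , drop = FALSE] / nrm[ok]
  sum(colMeans(u)^2)
}

# Pearson r between corresponding rows of two V x T matrices; 0 where either
# row has zero variance.
rowwise_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  ifelse(den > 0, num / den, 0)
}

#' Whole-brain residual correlation map (corr_brain)
#'
#' Correlation of each in-mask voxel's residual time series with the average
#' residual series over the whole mask. The result carries the customary
#' display defaults (transparent thresholding at |r| = 0.3, color range 0.6).
#'
#' @param errts A [volume_series()] of residuals.
#' @param mask 3D binary mask.
#' @return A [stat_volume()] of kind `"corr"`.
#' @export
corr_brain <- function(errts, mask) {
  m <- as_mask(mask, dim(errts$data))
  y <- masked_matrix(errts, m)
  gm <- colMeans(y)
  if (stats::sd(gm) == 0) stop("global mean residual has zero variance")
  r <- rowwise_cor(y, matrix(gm, nrow = nrow(y), ncol = ncol(y), byrow = TRUE))
  out <- array(0, dim = dim(errts$data)[1:3])
  out[m] <- r
  stat_volume(out, kind = "corr", stage = "regress", mask = m,
              display_thr = 0.3, display_range = 0.6)
}

# Separable truncated-Gaussian weight matrix along one axis (n grid points,
# spacing vox mm): W[a,b] = exp(-(d/sigma)^2/2) for |d| <= 3 sigma, else 0.
gauss_band <- function(n, vox, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), `-`)) * vox
  w <- exp(-0.5 * (d / sigma)^2)
  w[d > 3 * sigma] <- 0
  w
}

# Apply per-axis weight matrices to a 3D array (tensor contraction).
smooth3d <- function(a, wx, wy, wz) {
  d <- dim(a)
  m <- wx %*% matrix(a, nrow = d[1L])                      # x
  a <- array(m, dim = d)
  a <- aperm(a, c(2L, 1L, 3L))
  m <- wy %*% matrix(a, nrow = d[2L])                      # y
  a <- aperm(array(m, dim = d[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  a <- aperm(a, c(3L, 1L, 2L))
  m <- wz %*% matrix(a, nrow = d[3L])                      # z
  aperm(array(m, dim = d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

#' Radial correlation map
#'
#' Per voxel, the Pearson correlation between its time series and a
#' Gaussian-weighted average of the in-mask series in a large neighborhood
#' around it (FWHM 20 mm by default; sigma = FWHM / 2.3548). Weights are a
#' product of per-axis Gaussians, each truncated at 3 sigma, normalized over
#' in-mask voxels; the center voxel is included. Large coherent patches of
#' high radial correlation indicate coil artifacts or motion patterns.
#'
#' @param vol A [volume_series()].
#' @param mask 3D binary mask.
#' @param fwhm_mm Full width at half maximum of the Gaussian weighting, mm.
#' @return A [stat_volume()] of kind `"radcor"`.
#' @export
radial_correlate <- function(vol, mask, fwhm_mm = 20) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be positive")
  sigma <- fwhm_mm / 2.3548
  d <- dim(vol$data)
  m <- as_mask(mask, d)
  if (!any(m)) stop("mask is empty")
  wx <- gauss_band(d[1L], vol$voxdims[1L], sigma)
  wy <- gauss_band(d[2L], vol$voxdims[2L], sigma)
  wz <- gauss_band(d[3L], vol$voxdims[3L], sigma)
  mnum <- m * 1
  den <- smooth3d(mnum, wx, wy, wz)
  nt <- d[4L]
  idx <- which(m)
  nb <- matrix(0, nrow = length(idx), ncol = nt)
  for (t in seq_len(nt)) {
    vt <- vol$data[, , , t] * mnum
    st <- smooth3d(vt, wx, wy, wz)
    nb[, t] <- st[idx] / den[idx]
  }
  y <- matrix(vol$data, nrow = prod(d[1:3]))[idx, , drop = FALSE]
  r <- rowwise_cor(y, nb)
  out <- array(0, dim = d[1:3])
  out[idx] <- r
  stat_volume(out, kind = "radcor", stage = "", mask = m, fwhm_mm = fwhm_mm)
}

#' Seed-based correlation map
#'
#' Averages the series of all in-mask voxels within `seed_radius_mm` of the
#' seed voxel (radius 0 selects the seed alone) and correlates every in-mask
#' voxel's series with that seed series.
#'
#' @param vol A [volume_series()].
#' @param mask 3D binary mask.
#' @param seed_ijk 1-based (i, j, k) voxel index of the seed.
#' @param seed_radius_mm Averaging radius around the seed, mm.
#' @return A [stat_volume()] of kind `"corr"`.
#' @export
seed_corr <- function(vol, mask, seed_ijk, seed_radius_mm = 0) {
  d <- dim(vol$data)
  if (any(seed_ijk < 1L) || any(seed_ijk > d[1:3]))
    stop("seed voxel outside the grid")
  m <- as_mask(mask, d)
  if (!m[seed_ijk[1L], seed_ijk[2L], seed_ijk[3L]])
    stop("seed voxel is outside the mask")
  idx <- which(m)
  ijk <- ijk_of(idx, d)
  dist <- sqrt(colSums((t(ijk) - as.numeric(seed_ijk))^2 * vol$voxdims^2))
  sel <- dist <= seed_radius_mm + 1e-9
  y <- matrix(vol$data, nrow = prod(d[1:3]))[idx, , drop = FALSE]
  seed_series <- colMeans(y[sel, , drop = FALSE])
  r <- rowwise_cor(y, matrix(seed_series, nrow = nrow(y), ncol = ncol(y),
                             byrow = TRUE))
  out <- array(0, dim = d[1:3])
  out[idx] <- r
  stat_volume(out, kind = "corr", stage = "seed", mask = m,
              seed_ijk = seed_ijk, seed_radius_mm = seed_radius_mm)
}

#' Grayplot (carpet plot) matrix
#'
#' Builds the 2D matrix of Z-scored voxel time series (one row per mask
#' voxel, one column per volume): each series is detrended (quadratic per
#' run), Z-scored, and clipped at the two-sided normal tail quantile for
#' `clip_p` (about 3.29 for p = 0.001). In `"similarity"` mode rows are
#' ordered by decreasing |r| with the first principal component of the
#' standardized masked data (ties broken by voxel index); the PC sign is
#' fixed so its correlation with the mean masked series is nonnegative.
#'
#' @param vol A [volume_series()] or a V x T matrix of voxel series.
#' @param mask 3D binary mask (ignored for matrix input).
#' @param order_mode `"similarity"` or `"unsorted"`.
#' @param clip_p Two-sided tail probability for the Z clip.
#' @param detrend_order Polynomial order removed before Z-scoring.
#' @param enorm,outliers Optional per-volume series attached for display.
#' @return An object of class `grayplot_matrix`: `values` (V x T, |Z| <=
#'   `clip`), `row_order` (voxel indices in display order), `clip`, and any
#'   attached display series.
#' @export
grayplot <- function(vol, mask = NULL, order_mode = c("similarity", "unsorted"),
                     clip_p = 0.001, detrend_order = 2L,
                     enorm = NULL, outliers = NULL) {
  order_mode <- match.arg(order_mode)
  is_vs <- inherits(vol, "volume_series")
  y <- if (is_vs) masked_matrix(vol, mask) else as.matrix(vol)
  run_lengths <- if (is_vs) vol$run_lengths else ncol(y)
  vox_idx <- attr(y, "voxel_index")
  if (is.null(vox_idx)) vox_idx <- seq_len(nrow(y))
  z <- detrend_poly(y, order = detrend_order, run_lengths = run_lengths)
  sdv <- sqrt(rowSums(z^2) / (ncol(z) - 1L))
  nz <- sdv > 1e-8 * (rowMeans(abs(y)) + 1)   # numerically constant => zero row
  z[nz, ] <- z[nz, , drop = FALSE] / sdv[nz]
  z[!nz, ] <- 0
  clip <- stats::qnorm(1 - clip_p / 2)
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  ord <- seq_len(nrow(z))
  if (order_mode == "similarity" && sum(nz) >= 2L) {
    sv <- svd(z[nz, , drop = FALSE], nu = 0L, nv = 1L)
    pc1 <- sv$v[, 1L]
    mean_series <- colMeans(z[nz, , drop = FALSE])
    if (stats::sd(mean_series) > 0 && stats::cor(pc1, mean_series) < 0) pc1 <- -pc1
    r <- rowwise_cor(z, matrix(pc1, nrow = nrow(z), ncol = ncol(z), byrow = TRUE))
    ord <- order(-abs(r), seq_len(nrow(z)))
  }
  structure(list(values = z[ord, , drop = FALSE],
                 row_order = vox_idx[ord],
                 clip = clip, order_mode = order_mode,
                 enorm = enorm, outliers = outliers,
                 run_lengths = run_lengths),
            class = "grayplot_matrix")
}

#' @export
print.grayplot_matrix <- function(x, ...) {
  cat(sprintf("<grayplot_matrix> %d voxels x %d volumes, clip %.4f, %s order\n",
              nrow(x$values), ncol(x$values), x$clip, x$order_mode))
  invisible(x)
}

#' Write a grayplot matrix as plain text
#' @param gp A `grayplot_matrix`.
#' @param path Output path (rows = voxels, whitespace-separated).
#' @return The path, invisibly.
#' @export
write_grayplot_matrix <- function(gp, path) {
  write_table_1d(gp$values, path,
                 comments = sprintf("grayplot: clip %.6g, order %s",
                                    gp$clip, gp$order_mode))
}
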