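#' Graded warning levels
#'
#' QC warnings are graded on the ordered scale
#' `none < undecided < mild < medium < severe`.
#'
#' @param level One of `"none"`, `"undecided"`, `"mild"`, `"medium"`,
#'   `"severe"`.
#' @param message Optional message attached to the warning.
#' @return An object of class `warn_level`.
#' @export
warn_level <- function(level = "none", message = "") {
  level <- match.arg(level, warn_levels())
  structure(list(level = level, message = message), class = "warn_level")
}

#' @rdname warn_level
#' @return `warn_levels()` returns the ordered level vocabulary.
#' @export
warn_levels <- function() c("none", "undecided", "mild", "medium", "severe")

#' @export
print.warn_level <- function(x, ...) {
  cat(sprintf("<warn_level> %s%s\n", x$level,
              if (nzchar(x$message)) paste0(": ", x$message) else ""))
  invisible(x)
}

#' Aggregate warnings to the maximum level
#'
#' @param warns List of `warn_level` objects (or level strings). An empty
#'   list aggregates to `"none"`.
#' @return A `warn_level` at the maximum of the inputs.
#' @export
aggregate_warns <- function(warns) {
  if (length(warns) == 0L) return(warn_level("none"))
  levs <- vapply(warns, function(w)
    if (inherits(w, "warn_level")) w$level else as.character(w), character(1L))
  ranks <- match(levs, warn_levels())
  top <- which.max(ranks)
  msg <- if (inherits(warns[[top]], "warn_level")) warns[[top]]$message else ""
  warn_level(levs[top], msg)
}

#' Local Pearson correlation (LPC) alignment cost
#'
#' The mask is partitioned into non-overlapping cubic blocks of
#' `block_vox`^3 voxels; within each block holding at least `min_vox`
#' in-mask voxels (and nonzero variance in both images) the signed Pearson
#' correlation `r_b` between the two images is computed. The cost is the
#' negated weighted mean `-sum(w_b r_b) / sum(w_b)` with `w_b` the block's
#' in-mask voxel count, so lower is better: identical images score -1,
#' sign-flipped images +1.
#'
#' @param u,v 3D arrays (or single-volume series) on the same grid.
#' @param mask 3D binary mask.
#' @param block_vox Block edge length in voxels.
#' @param min_vox Minimum in-mask voxels for a block to count.
#' @return Scalar cost in \[-1, 1\].
#' @export
lpc_cost <- function(u, v, mask, block_vox = 5L, min_vox = 8L) {
  u <- vol3d(u); v <- vol3d(v)
  if (!identical(dim(u), dim(v))) stop("volumes must share a grid")
  m <- as_mask(mask, dim(u))
  idx <- which(m)
  if (length(idx) == 0L) stop("mask is empty")
  d <- dim(u)
  ijk <- ijk_of(idx, d)
  block <- paste((ijk[, 1L] - 1L) %/% block_vox,
                 (ijk[, 2L] - 1L) %/% block_vox,
                 (ijk[, 3L] - 1L) %/% block_vox)
  uu <- u[idx]; vv <- v[idx]
  n <- tapply(uu, block, length)
  su <- tapply(uu, block, sum);  sv <- tapply(vv, block, sum)
  suu <- tapply(uu^2, block, sum); svv <- tapply(vv^2, block, sum)
  suv <- tapply(uu * vv, block, sum)
  num <- suv - su * sv / n
  varu <- suu - su^2 / n
  varv <- svv - sv^2 / n
  ok <- n >= min_vox & varu > 0 & varv > 0
  if (!any(ok)) stop("no valid blocks (mask too sparse or constant images)")
  r <- num[ok] / sqrt(varu[ok] * varv[ok])
  w <- n[ok]
  -sum(w * r) / sum(w)
}

# Reverse an array along the left-right axis given an orientation code.
lr_axis <- function(orient) {
  ax <- which(strsplit(toupper(orient), "")[[1L]] %in% c("L", "R"))
  if (length(ax) != 1L) stop("cannot identify the left-right axis in orientation '",
                             orient, "'")
  ax
}

flip_lr <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx))
}

#' Left-right flip check
#'
#' Tests whether the EPI and anatomical volumes agree on left versus right
#' by comparing the local-Pearson-correlation cost of the pair "as is"
#' against the cost after mirroring the anatomical across the left-right
#' axis (identified from the orientation code). Inputs must already share a
#' grid; no registration is performed. A clearly lower mirrored cost means
#' the data are likely stored left-right flipped.
#'
#' @param epi_ref 3D EPI reference volume (array or single-volume series).
#' @param anat 3D anatomical volume on the same grid.
#' @param mask 3D binary mask.
#' @param orient Orientation code used to find the left-right axis.
#' @param tie_tol Cost difference below which the result is `"ambiguous"`.
#' @param block_vox LPC block size, voxels.
#' @return List with `cost_asis`, `cost_flipped`, and `guess`
#'   (`"NO_FLIP"`, `"DO_FLIP"`, or `"ambiguous"`).
#' @export
flip_check <- function(epi_ref, anat, mask, orient = "RAS", tie_tol = 0.01,
                       block_vox = 5L) {
  a <- vol3d(anat)
  ax <- lr_axis(orient)
  cost_asis <- lpc_cost(epi_ref, a, mask, block_vox = block_vox)
  cost_flipped <- lpc_cost(epi_ref, flip_lr(a, ax), mask, block_vox = block_vox)
  guess <- if (cost_flipped < cost_asis - tie_tol) "DO_FLIP"
           else if (cost_asis < cost_flipped - tie_tol) "NO_FLIP"
           else "ambiguous"
  list(cost_asis = cost_asis, cost_flipped = cost_flipped, guess = guess)
}

#' Detect through-plane variance lines
#'
#' Scanner (coil/spike) problems can produce narrow columns of artifactually
#' high temporal variance running orthogonal to the slice planes (the third
#' voxel axis by convention). Each voxel's series is detrended (quadratic
#' per run) and scaled to percent of its mean; a per-column score is the
#' 90th percentile of the in-mask temporal standard deviations along the
#' slice axis, and a column is a candidate when its score is at least
#' `ratio_thresh` times the median score in its in-plane neighborhood.
#' Adjacent candidates are merged, reporting the peak.
#'
#' @param vol A [volume_series()].
#' @param mask 3D binary mask covering at least 2 slices along the slice axis.
#' @param ratio_thresh Detection threshold on the score / neighborhood-median
#'   ratio.
#' @param detrend_order Polynomial order removed per run before the variance
#'   is measured.
#' @param nbhd In-plane neighborhood edge length (voxels) for the median
#'   normalization.
#' @return A tibble with one row per detected line: `i`, `j` (1-based
#'   in-plane voxel indices of the peak), `score` (variance ratio), and
#'   world `x`, `y`, `z` (mm, at the column's mid-mask slice).
#' @export
variance_lines <- function(vol, mask, ratio_thresh = 3.0, detrend_order = 2L,
                           nbhd = 11L) {
  d <- dim(vol$data)
  m <- as_mask(mask, d)
  ijk_all <- ijk_of(which(m), d)
  if (length(unique(ijk_all[, 3L])) < 2L)
    stop("mask must cover at least 2 slices along the slice axis")
  y <- masked_matrix(vol, m)
  res <- detrend_poly(y, order = detrend_order, run_lengths = vol$run_lengths)
  mu <- rowMeans(y)
  sdv <- sqrt(rowSums(res^2) / (ncol(res) - 1L))
  sd_pct <- ifelse(abs(mu) > 1e-8, 100 * sdv / abs(mu), 0)
  # per in-plane column: 90th percentile of sd over in-mask slices
  col_id <- (ijk_all[, 2L] - 1L) * d[1L] + ijk_all[, 1L]
  score <- matrix(NA_real_, d[1L], d[2L])
  agg <- tapply(sd_pct, col_id, stats::quantile, probs = 0.9, names = FALSE,
                type = 7)
  cid <- as.integer(names(agg))
  score[cbind((cid - 1L) %% d[1L] + 1L, (cid - 1L) %/% d[1L] + 1L)] <- agg
  half <- nbhd %/% 2L
  cand <- which(!is.na(score), arr.ind = TRUE)
  ratio <- rep(NA_real_, nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    wi <- max(1L, i - half):min(d[1L], i + half)
    wj <- max(1L, j - half):min(d[2L], j + half)
    med <- stats::median(score[wi, wj], na.rm = TRUE)
    if (is.finite(med) && med > 0) ratio[r] <- score[i, j] / med
  }
  hits <- which(!is.na(ratio) & ratio >= ratio_thresh)
  empty <- tibble::tibble(i = integer(), j = integer(), score = numeric(),
                          x = numeric(), y = numeric(), z = numeric())
  if (length(hits) == 0L) return(empty)
  # merge 8-adjacent candidate columns, keep the peak-ratio voxel of each
  hij <- cand[hits, , drop = FALSE]
  hratio <- ratio[hits]
  comp <- seq_along(hits)
  repeat {
    changed <- FALSE
    for (a in seq_along(hits)) for (b in seq_along(hits)) {
      if (comp[a] != comp[b] &&
          max(abs(hij[a, ] - hij[b, ])) <= 1L) {
        comp[comp == comp[b]] <- comp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  rows <- lapply(unique(comp), function(cc) {
    sel <- which(comp == cc)
    peak <- sel[which.max(hratio[sel])]
    i <- hij[peak, 1L]; j <- hij[peak, 2L]
    kz <- ijk_all[col_id == (j - 1L) * d[1L] + i, 3L]
    kmid <- round(stats::median(kz))
    xyz <- ijk_to_xyz(c(i, j, kmid), vol$affine, vol$voxdims)
    tibble::tibble(i = as.integer(i), j = as.integer(j),
                   score = hratio[peak],
                   x = xyz[1L], y = xyz[2L], z = xyz[3L])
  })
  out <- do.call(rbind, rows)
  out[order(-out$score), ]
}

#' Raw intensity range check
#'
#' Inspects the stored-unit (unscaled) minimum and maximum of a dataset.
#' Negative values can indicate acquisition or conversion problems; a
#' maximum of exactly 4095 suggests saturation of a 12-bit intensity signal.
#'
#' @param vol A [volume_series()] (uses its retained `raw_range`).
#' @return List with `min`, `max`, `flags` (character vector, possibly
#'   empty: `"negative_min"`, `"saturation"`), and `warn` (a [warn_level()]).
#' @export
data_range_check <- function(vol) {
  rng <- vol$raw_range
  flags <- character(0L)
  if (rng[1L] < 0) flags <- c(flags, "negative_min")
  if (rng[2L] == 4095) flags <- c(flags, "saturation")
  warn <- if (length(flags) > 0L)
    warn_level("mild", paste(flags, collapse = ", ")) else warn_level("none")
  list(min = rng[1L], max = rng[2L], flags = flags, warn = warn)
}

#' Default mapping from check outcomes to warning levels
#'
#' @return Named list used by [qc_run()]: flip guesses, variance lines,
#'   pre-steady-state and intensity-range outcomes mapped onto
#'   [warn_level()] grades.
#' @export
qc_warn_config <- function() {
  list(
    flip = c(DO_FLIP = "severe", ambiguous = "undecided", NO_FLIP = "none"),
    variance_lines_any = "medium",
    pre_steady_any = "medium",
    range_flag = "mild",
    censor_fraction = c(mild = 0.05, medium = 0.1, severe = 0.2)
  )
}
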