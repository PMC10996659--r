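# Independent brute-force oracles used to validate the vectorized
# implementations, plus small fixture builders. Everything here is
# deliberately written as plain loops over definitions.

# Mean of the full V x V Pearson correlation matrix, self-pairs included.
oracle_gcor <- function(y) {
  cm <- stats::cor(t(y))
  mean(cm)
}

# Per-voxel outlier detection: linear fit per run, sort-based median/MAD.
oracle_outlier_fractions <- function(y, run_lengths, alpha = 0.01) {
  nt <- ncol(y)
  k <- stats::qnorm(1 - alpha / 2)
  out <- matrix(FALSE, nrow(y), nt)
  for (v in seq_len(nrow(y))) {
    res <- numeric(nt)
    off <- 0L
    for (rl in run_lengths) {
      idx <- off + seq_len(rl)
      fit <- stats::lm.fit(cbind(1, seq_len(rl)), y[v, idx])
      res[idx] <- fit$residuals
      off <- off + rl
    }
    med <- sort(res)[c(ceiling(nt / 2), floor(nt / 2) + 1)]
    med <- mean(med)
    ad <- abs(res - med)
    smad <- sort(ad)[c(ceiling(nt / 2), floor(nt / 2) + 1)]
    thr <- k * 1.4826 * mean(smad)
    out[v, ] <- abs(res) > thr
  }
  colSums(out) / nrow(y)
}

# Signed block-wise Pearson cost by explicit block loops.
oracle_lpc <- function(u, v, mask, block_vox = 5L, min_vox = 8L) {
  d <- dim(u)
  num <- 0; den <- 0
  for (bi in seq(1L, d[1L], by = block_vox))
    for (bj in seq(1L, d[2L], by = block_vox))
      for (bk in seq(1L, d[3L], by = block_vox)) {
        ii <- bi:min(bi + block_vox - 1L, d[1L])
        jj <- bj:min(bj + block_vox - 1L, d[2L])
        kk <- bk:min(bk + block_vox - 1L, d[3L])
        m <- mask[ii, jj, kk]
        if (sum(m) < min_vox) next
        uu <- u[ii, jj, kk][m]
        vv <- v[ii, jj, kk][m]
        if (stats::sd(uu) == 0 || stats::sd(vv) == 0) next
        r <- stats::cor(uu, vv)
        num <- num + sum(m) * r
        den <- den + sum(m)
      }
  -num / den
}

# Repeated 6-neighbor erosion; depth = pass at which a voxel is removed.
oracle_roi_depth <- function(m) {
  d <- dim(m)
  depth <- array(0L, dim = d)
  cur <- m
  pass <- 0L
  while (any(cur)) {
    pass <- pass + 1L
    pad <- array(FALSE, dim = d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- cur
    keep <- array(TRUE, dim = d)
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      nb <- pad[2:(d[1] + 1) + sh[1], 2:(d[2] + 1) + sh[2],
                2:(d[3] + 1) + sh[3]]
      keep <- keep & nb
    }
    removed <- cur & !keep
    depth[removed] <- pass
    cur <- cur & keep
  }
  depth
}

# Dense direct-summation radial correlation: explicit per-pair separable
# truncated-Gaussian weights over in-mask voxels.
oracle_radcor <- function(vol, mask, fwhm_mm) {
  sigma <- fwhm_mm / 2.3548
  d <- dim(vol$data)
  idx <- which(mask)
  ijk <- cbind((idx - 1) %% d[1] + 1,
               ((idx - 1) %/% d[1]) %% d[2] + 1,
               (idx - 1) %/% (d[1] * d[2]) + 1)
  y <- matrix(vol$data, nrow = prod(d[1:3]))[idx, , drop = FALSE]
  w1 <- function(delta_mm) {
    w <- exp(-0.5 * (delta_mm / sigma)^2)
    w[abs(delta_mm) > 3 * sigma] <- 0
    w
  }
  r <- numeric(length(idx))
  for (a in seq_along(idx)) {
    w <- w1((ijk[, 1] - ijk[a, 1]) * vol$voxdims[1]) *
         w1((ijk[, 2] - ijk[a, 2]) * vol$voxdims[2]) *
         w1((ijk[, 3] - ijk[a, 3]) * vol$voxdims[3])
    nbhd <- colSums(w * y) / sum(w)
    r[a] <- stats::cor(y[a, ], nbhd)
  }
  out <- array(0, dim = d[1:3])
  out[idx] <- r
  out
}

# Small volume_series from an array with 3 mm voxels.
tiny_vol <- function(arr, tr = 2, run_lengths = NULL) {
  volume_series(arr, voxdims = c(3, 3, 3), tr = tr, run_lengths = run_lengths)
}

# Ellipsoid mask for a given grid.
ellipsoid_mask <- function(d, frac = 0.9) {
  cx <- (d + 1) / 2
  gi <- (seq_len(d[1]) - cx[1]) / (d[1] / 2 * frac)
  gj <- (seq_len(d[2]) - cx[2]) / (d[2] / 2 * frac)
  gk <- (seq_len(d[3]) - cx[3]) / (d[3] / 2 * frac)
  outer(outer(gi^2, gj^2, `+`), gk^2, `+`) <= 1
}

# Colon-format review fixture with representative printed quantities.
write_review_fixture <- function(path, subject = "FT",
                                 censor_fraction = 0.012397,
                                 gcor_val = 0.0622461) {
  writeLines(c(
    paste0("subject ID : ", subject),
    "num runs found : 1",
    "num TRs per run : 242",
    "num TRs per run (censored) : 3",
    "fraction censored per run : 0.0123967",
    "TRs total (uncensored) : 242",
    "TRs total : 239",
    "degrees of freedom used : 13",
    "degrees of freedom left : 226",
    "final DF fraction : 0.933884",
    "TRs censored : 3",
    paste0("censor fraction : ", censor_fraction),
    "num regs of interest : 2",
    "num TRs per stim (orig) : 136 210",
    "num TRs censored per stim : 2 0",
    "fraction TRs censored : 0.015 0.000",
    "TSNR average : 191.52",
    paste0("global correlation (GCOR) : ", gcor_val),
    "anat/EPI mask Dice coef : 0.919111",
    "maximum F-stat (masked) : 84.3675",
    "AFNI version : AFNI_23.1.10",
    "flip guess : NO_FLIP"
  ), path)
  path
}
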