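#' Specification for a synthetic EPI phantom
#'
#' Describes a deterministic 4D phantom: an ellipsoidal "brain" of baseline
#' intensity with slow polynomial drift and Gaussian noise, plus any of the
#' artifact classes the QC detectors look for — motion spikes (mirrored in
#' the motion-parameter table and as integer-voxel shifts of the affected
#' volumes), through-plane variance lines, a spatially coherent "bad coil"
#' patch sharing one latent signal, a global signal component, block-design
#' task activation, elevated pre-steady-state initial volumes, and optional
#' left-right mirroring of the anatomical.
#'
#' Defaults describe a small desk-scale acquisition: 24 x 24 x 16 voxels at
#' 3 mm isotropic, TR 2 s, one 200-volume run, baseline 1000 with noise
#' standard deviation 10 (1% of baseline) and a gentle linear+quadratic
#' drift.
#'
#' @param dims Grid size (3 integers).
#' @param voxdims Voxel sizes, mm.
#' @param tr Repetition time, s.
#' @param run_lengths Volumes per run.
#' @param baseline Baseline in-brain intensity.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param drift Polynomial drift coefficients (intensity units) for the
#'   order-1, order-2, ... Legendre terms, applied per run.
#' @param mask_axes Ellipsoid semi-axes as fractions of the grid half-sizes.
#' @param seed Integer RNG seed; identical spec + seed gives identical data.
#' @param motion_spikes List `(times, magnitudes)`: volume indices receiving
#'   a one-TR motion excursion of the given size (mm).
#' @param variance_lines List `(ij, gain)`: `ij` an n x 2 matrix of in-plane
#'   voxel indices; extra noise of sd `gain * noise_sd` along each column.
#' @param coil_patch List `(octant, sd)`: octant 1..8 receives a shared
#'   latent series of the given sd.
#' @param global_signal List `(sd)`: common series added to every mask voxel.
#' @param task List `(onsets_s, durations_s, effect_pct)`: block design with
#'   percent-signal-change activation in a planted spherical region.
#' @param presteady List `(n, excess)`: first `n` volumes of each run scaled
#'   by `1 + excess`.
#' @param lr_flip Mirror the anatomical volume left-right (plants a flipped
#'   dataset).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(24L, 24L, 16L), voxdims = c(3, 3, 3),
                         tr = 2, run_lengths = 200L, baseline = 1000,
                         noise_sd = 10, drift = c(10, -4),
                         mask_axes = c(0.9, 0.9, 0.9), seed = 42L,
                         motion_spikes = NULL, variance_lines = NULL,
                         coil_patch = NULL, global_signal = NULL,
                         task = NULL, presteady = NULL, lr_flip = FALSE) {
  nt <- sum(run_lengths)
  stopifnot(length(dims) == 3L, all(dims >= 4L), all(voxdims > 0), tr > 0,
            baseline > 0, noise_sd >= 0)
  if (!is.null(motion_spikes)) {
    stopifnot(length(motion_spikes$times) == length(motion_spikes$magnitudes),
              all(motion_spikes$times >= 1L), all(motion_spikes$times <= nt))
  }
  if (!is.null(variance_lines)) {
    ij <- matrix(variance_lines$ij, ncol = 2L)
    stopifnot(all(ij[, 1L] >= 1L & ij[, 1L] <= dims[1L]),
              all(ij[, 2L] >= 1L & ij[, 2L] <= dims[2L]))
  }
  structure(list(dims = as.integer(dims), voxdims = voxdims, tr = tr,
                 run_lengths = as.integer(run_lengths), baseline = baseline,
                 noise_sd = noise_sd, drift = drift, mask_axes = mask_axes,
                 seed = as.integer(seed), motion_spikes = motion_spikes,
                 variance_lines = variance_lines, coil_patch = coil_patch,
                 global_signal = global_signal, task = task,
                 presteady = presteady, lr_flip = isTRUE(lr_flip)),
            class = "phantom_spec")
}

# Normalized ellipsoid radius^2 and structural profile of the phantom brain.
phantom_geometry <- function(spec) {
  d <- spec$dims
  cx <- (d + 1) / 2
  gi <- (seq_len(d[1L]) - cx[1L]) / (d[1L] / 2 * spec$mask_axes[1L])
  gj <- (seq_len(d[2L]) - cx[2L]) / (d[2L] / 2 * spec$mask_axes[2L])
  gk <- (seq_len(d[3L]) - cx[3L]) / (d[3L] / 2 * spec$mask_axes[3L])
  rho2 <- outer(outer(gi^2, gj^2, `+`), gk^2, `+`)
  mask <- rho2 <= 1
  # asymmetric structure: radial falloff + left-right gradient + a bright
  # blob in the left half, so flip checks have something to detect
  xfrac <- array(rep((seq_len(d[1L]) - 1) / (d[1L] - 1), d[2L] * d[3L]), dim = d)
  blob_c <- c(round(d[1L] * 0.3), round(d[2L] * 0.55), round(d[3L] * 0.5))
  bi <- (seq_len(d[1L]) - blob_c[1L]) / 3
  bj <- (seq_len(d[2L]) - blob_c[2L]) / 3
  bk <- (seq_len(d[3L]) - blob_c[3L]) / 3
  blob <- exp(-0.5 * outer(outer(bi^2, bj^2, `+`), bk^2, `+`))
  struct <- (1 - 0.35 * rho2) + 0.25 * xfrac + 0.8 * blob
  struct[!mask] <- 0
  list(mask = mask, struct = struct, rho2 = rho2)
}

#' Generate a synthetic EPI phantom
#'
#' Realizes a [phantom_spec()]: reproducible from its seed, with every
#' injected artifact echoed back in a ground-truth record. Motion spikes
#' appear both as one-TR steps in the motion-parameter table and as
#' integer-voxel in-plane shifts of the affected volumes (no interpolation,
#' so the image effect and the parameter-table truth are exactly
#' consistent).
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `vol` ([volume_series()]), `mask` (3D logical),
#'   `anat` (3D array), `epi_ref` (temporal-mean 3D array), `motion`
#'   (T x 6 matrix), `ideal` (T x S matrix of task regressors, or NULL),
#'   `atlas` (integer 3D array of 4 quadrant ROIs), and `truth` (list of
#'   injected-artifact parameters and expected detector outcomes).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$dims
  nt <- sum(spec$run_lengths)
  geo <- phantom_geometry(spec)
  mask <- geo$mask
  base3d <- spec$baseline * (0.55 + 0.45 * geo$struct)
  base3d[!mask] <- 0.08 * spec$baseline   # dim positive "air" floor
  nv <- prod(d)
  dat <- array(stats::rnorm(nv * nt, sd = spec$noise_sd) + as.vector(base3d),
               dim = c(d, nt))
  # slow polynomial drift, identical across the brain, per run
  if (length(spec$drift) > 0L && any(spec$drift != 0)) {
    off <- 0L
    for (rl in spec$run_lengths) {
      x <- seq(-1, 1, length.out = rl)
      basis <- stats::poly(x, degree = length(spec$drift))
      dr <- as.vector(basis %*% (spec$drift * sqrt(rl)))
      for (t in seq_len(rl))
        dat[, , , off + t] <- dat[, , , off + t] + dr[t] * mask
      off <- off + rl
    }
  }
  truth <- list(seed = spec$seed, run_lengths = spec$run_lengths)
  if (!is.null(spec$global_signal)) {
    g <- stats::rnorm(nt, sd = spec$global_signal$sd)
    for (t in seq_len(nt)) dat[, , , t] <- dat[, , , t] + g[t] * mask
    truth$global_signal_sd <- spec$global_signal$sd
    truth$gcor_expected <- spec$global_signal$sd^2 /
      (spec$global_signal$sd^2 + spec$noise_sd^2)
  }
  if (!is.null(spec$coil_patch)) {
    oct <- spec$coil_patch$octant
    half <- lapply(1:3, function(ax) {
      lohi <- bitwAnd(bitwShiftR(oct - 1L, ax - 1L), 1L)
      if (lohi == 0L) seq_len(d[ax] %/% 2L) else (d[ax] %/% 2L + 1L):d[ax]
    })
    patch <- array(FALSE, dim = d)
    patch[half[[1L]], half[[2L]], half[[3L]]] <- TRUE
    patch <- patch & mask
    l <- stats::rnorm(nt, sd = spec$coil_patch$sd)
    for (t in seq_len(nt)) dat[, , , t] <- dat[, , , t] + l[t] * patch
    truth$coil_patch_voxels <- which(patch)
  }
  ideal <- NULL
  if (!is.null(spec$task)) {
    tt <- (seq_len(nt) - 1) * spec$tr
    box <- rep(0, nt)
    for (s in seq_along(spec$task$onsets_s)) {
      on <- spec$task$onsets_s[s]
      box[tt >= on & tt < on + spec$task$durations_s[s]] <- 1
    }
    ideal <- matrix(box, ncol = 1L, dimnames = list(NULL, "task"))
    ctr <- round(d * c(0.65, 0.4, 0.5))
    ri <- (seq_len(d[1L]) - ctr[1L])^2
    rj <- (seq_len(d[2L]) - ctr[2L])^2
    rk <- (seq_len(d[3L]) - ctr[3L])^2
    region <- outer(outer(ri, rj, `+`), rk, `+`) <= 3^2 & mask
    amp <- spec$task$effect_pct / 100 * spec$baseline
    for (t in which(box > 0)) dat[, , , t] <- dat[, , , t] + amp * region
    truth$task_voxels <- which(region)
    truth$task_regressor <- box
  }
  if (!is.null(spec$variance_lines)) {
    ij <- matrix(spec$variance_lines$ij, ncol = 2L)
    gain <- rep(spec$variance_lines$gain, length.out = nrow(ij))
    for (r in seq_len(nrow(ij))) {
      extra <- matrix(stats::rnorm(d[3L] * nt, sd = gain[r] * spec$noise_sd),
                      nrow = d[3L])
      dat[ij[r, 1L], ij[r, 2L], , ] <-
        dat[ij[r, 1L], ij[r, 2L], , ] + extra
    }
    truth$line_ij <- ij
    truth$line_gain <- gain
  }
  if (!is.null(spec$presteady)) {
    off <- 0L
    flagged <- integer(0L)
    for (rl in spec$run_lengths) {
      npre <- min(spec$presteady$n, rl)
      for (t in seq_len(npre))
        dat[, , , off + t] <- dat[, , , off + t] * (1 + spec$presteady$excess)
      flagged <- c(flagged, off + seq_len(npre))
      off <- off + rl
    }
    truth$presteady_indices <- flagged
  }
  motion <- matrix(0, nrow = nt, ncol = 6L,
                   dimnames = list(NULL, c("roll", "pitch", "yaw",
                                           "dS", "dL", "dP")))
  if (!is.null(spec$motion_spikes)) {
    run_start <- cumsum(c(1L, spec$run_lengths[-length(spec$run_lengths)]))
    run_end <- cumsum(spec$run_lengths)
    exceed <- integer(0L)
    for (s in seq_along(spec$motion_spikes$times)) {
      t0 <- spec$motion_spikes$times[s]
      mag <- spec$motion_spikes$magnitudes[s]
      motion[t0, "dL"] <- motion[t0, "dL"] + mag
      shift <- round(mag / spec$voxdims[2L])
      if (shift != 0) {
        v <- dat[, , , t0]
        idx <- ((seq_len(d[2L]) - 1L - shift) %% d[2L]) + 1L
        dat[, , , t0] <- v[, idx, ]
      }
      run <- findInterval(t0, run_start)
      exceed <- c(exceed, t0)
      if (t0 + 1L <= run_end[run]) exceed <- c(exceed, t0 + 1L)
    }
    exceed <- sort(unique(exceed))
    prev <- setdiff(exceed[exceed - 1L >= 1L & !(exceed %in% run_start)] - 1L,
                    exceed)
    truth$spike_times <- spec$motion_spikes$times
    truth$enorm_exceed_indices <- exceed
    truth$censor_indices_with_prev <- sort(unique(c(exceed, prev)))
  }
  anat <- 500 * (0.5 + geo$struct)
  anat[!mask] <- 40
  if (spec$lr_flip) anat <- flip_lr(anat, 1L)
  truth$lr_flip <- spec$lr_flip
  epi_ref <- apply(dat, 1:3, mean)
  atlas <- array(0L, dim = d)
  ci <- d[1L] %/% 2L; cj <- d[2L] %/% 2L
  qlab <- array(1L, dim = d)
  qlab[(ci + 1L):d[1L], , ] <- qlab[(ci + 1L):d[1L], , ] + 1L
  qlab[, (cj + 1L):d[2L], ] <- qlab[, (cj + 1L):d[2L], ] + 2L
  atlas[mask] <- qlab[mask]
  vol <- volume_series(dat, voxdims = spec$voxdims, tr = spec$tr,
                       orient = "RAS", run_lengths = spec$run_lengths)
  list(vol = vol, mask = mask, anat = anat, epi_ref = epi_ref,
       motion = motion, ideal = ideal, atlas = atlas, truth = truth)
}

#' Write a phantom as an on-disk fixture bundle
#'
#' Writes the standard files every QC entry point consumes: `epi.nii`,
#' `anat.nii`, `mask.nii`, `atlas.nii`, `motion.1D`, optional `ideal.1D`,
#' and `truth.json` (the ground-truth record). Uncompressed NIfTI is used so
#' repeated writes of the same phantom are byte-identical.
#'
#' @param ph Result of [make_phantom()].
#' @param dir Output directory (created).
#' @return The directory path, invisibly.
#' @export
write_fixture_bundle <- function(ph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(ph$vol, file.path(dir, "epi.nii"))
  write_volume(ph$anat, file.path(dir, "anat.nii"),
               voxdims = ph$vol$voxdims)
  write_volume(ph$mask * 1, file.path(dir, "mask.nii"),
               voxdims = ph$vol$voxdims, datatype = "uint8")
  write_volume(ph$atlas, file.path(dir, "atlas.nii"),
               voxdims = ph$vol$voxdims, datatype = "int16")
  write_table_1d(ph$motion, file.path(dir, "motion.1D"),
                 comments = "roll pitch yaw dS dL dP")
  if (!is.null(ph$ideal))
    write_table_1d(ph$ideal, file.path(dir, "ideal.1D"),
                   comments = paste(colnames(ph$ideal), collapse = " "))
  tr_meta <- list(tr = ph$vol$tr, run_lengths = as.list(ph$vol$run_lengths))
  jsonlite::write_json(c(tr_meta, ph$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
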