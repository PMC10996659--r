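#' Run the full per-subject QC pipeline on a fixture bundle
#'
#' Consumes a directory in the layout written by [write_fixture_bundle()]
#' (`epi.nii[.gz]` required; `anat`, `mask`, `atlas`, `motion.1D`,
#' `ideal.1D` optional — a missing mask is replaced by a light automask of
#' the mean EPI) and produces a self-contained QC report directory plus the
#' standard side files: the review dictionary (colon text and JSON), the
#' censor 1D file, and the variance-line table. The run is deterministic:
#' rebuilding from the same inputs yields byte-identical output.
#'
#' @param bundle_dir Input directory.
#' @param outdir Output QC directory.
#' @param subject Subject id used in file names.
#' @param enorm_limit,outlier_limit Censor limits.
#' @param seed_radius_mm Radius for the seed-correlation display map.
#' @return Invisibly, a list with the `review` dictionary and key results
#'   (`censor`, `ledger`, `warns`, paths).
#' @export
qc_run <- function(bundle_dir, outdir, subject = "subj",
                   enorm_limit = 0.3, outlier_limit = 0.1,
                   seed_radius_mm = 6) {
  find1 <- function(stem) {
    for (ext in c(".nii", ".nii.gz")) {
      p <- file.path(bundle_dir, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
    NULL
  }
  epi_path <- find1("epi")
  if (is.null(epi_path)) stop("no epi.nii[.gz] in ", bundle_dir)
  run_lengths <- NULL
  tr <- NULL
  truth_path <- file.path(bundle_dir, "truth.json")
  if (file.exists(truth_path)) {
    meta <- jsonlite::fromJSON(truth_path)
    if (!is.null(meta$run_lengths)) run_lengths <- unlist(meta$run_lengths)
    if (!is.null(meta$tr)) tr <- meta$tr
  }
  vol <- read_volume4d(epi_path, tr = tr, run_lengths = run_lengths)
  d3 <- dim(vol$data)[1:3]
  mask_path <- find1("mask")
  mask <- if (!is.null(mask_path)) as_mask(vol3d(read_volume4d(mask_path)), d3)
          else automask(apply(vol$data, 1:3, mean))
  anat <- if (!is.null(find1("anat"))) vol3d(read_volume4d(find1("anat")))
  atlas <- if (!is.null(find1("atlas"))) vol3d(read_volume4d(find1("atlas")))
  motion_path <- file.path(bundle_dir, "motion.1D")
  motion <- if (file.exists(motion_path)) read_table_1d(motion_path)
  ideal_path <- file.path(bundle_dir, "ideal.1D")
  ideal <- if (file.exists(ideal_path)) read_table_1d(ideal_path)

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  nt <- n_timepoints(vol)
  mean_epi <- apply(vol$data, 1:3, mean)

  # --- mot: motion, outliers, censoring
  enorm <- if (!is.null(motion)) compute_enorm(motion, vol$run_lengths)
  outfrac <- outlier_fractions(vol, mask)
  censor <- make_censor(enorm, outfrac, enorm_limit = enorm_limit,
                        outlier_limit = outlier_limit,
                        run_lengths = vol$run_lengths)
  write_censor_1d(censor, file.path(outdir, sprintf("censor_%s.1D", subject)))
  mot_summary <- censor_summary(if (is.null(enorm)) outfrac else enorm, censor)
  gp <- grayplot(vol, mask, enorm = enorm, outliers = outfrac)

  # --- regr: TSNR, GCOR, corr_brain, DF ledger
  tsnr <- tsnr_volreg(vol, mask)
  g <- gcor(vol, mask)
  errts <- vol
  y <- masked_matrix(vol, mask)
  res <- detrend_poly(y, order = 2L, run_lengths = vol$run_lengths)
  e <- array(0, dim = dim(vol$data))
  em <- matrix(e, nrow = prod(d3))
  em[attr(y, "voxel_index"), ] <- res
  errts$data <- array(em, dim = dim(vol$data))
  cb <- corr_brain(errts, mask)
  design <- NULL
  if (!is.null(motion) || !is.null(ideal)) {
    drift_cols <- do.call(rbind, lapply(vol$run_lengths, function(rl)
      stats::poly(seq_len(rl), degree = 2)))
    cols <- drift_cols
    # the constant baseline term is accounted in the DF ledger separately
    # and is exempt from the correlation checks
    groups <- rep("baseline", ncol(drift_cols))
    labels <- paste0("drift", seq_len(ncol(drift_cols)))
    if (!is.null(motion)) {
      # constant (e.g. identically zero) parameter columns carry no
      # information and would only trip zero-variance warnings
      keep_mot <- apply(motion, 2L, stats::sd) > 0
      if (any(keep_mot)) {
        cols <- cbind(cols, motion[, keep_mot, drop = FALSE])
        groups <- c(groups, rep("motion", sum(keep_mot)))
        labels <- c(labels, paste0("mot", which(keep_mot)))
      }
    }
    if (!is.null(ideal)) {
      cols <- cbind(cols, ideal)
      groups <- c(groups, rep("interest", ncol(ideal)))
      labels <- c(labels, paste0("stim", seq_len(ncol(ideal))))
    }
    design <- design_matrix(cols, labels = labels, groups = groups)
  }
  ledger <- df_ledger(nt, censor = censor, design = design,
                      intercepts = length(vol$run_lengths))
  coll <- if (!is.null(design))
    tryCatch(collinearity_check(design, censor), error = function(e) NULL)
  stim <- if (!is.null(ideal)) stim_censor_fraction(ideal, censor)

  # --- radcor
  radcor <- radial_correlate(vol, mask)

  # --- vstat: seed correlation at the deepest mask voxel
  dep <- roi_depth(mask)
  peak <- which(dep$depth == dep$max_depth)[1L]
  seed_ijk <- as.integer(ijk_of(peak, d3)[1L, ])
  seedmap <- seed_corr(vol, mask, seed_ijk, seed_radius_mm)

  # --- warns
  rng_chk <- data_range_check(vol)
  presteady <- pre_steady_check(vol, mask)
  vlines <- variance_lines(vol, mask)
  flip <- if (!is.null(anat))
    flip_check(mean_epi, anat, mask, orient = vol$orient)
  cfg <- qc_warn_config()
  warns <- list(rng_chk$warn)
  if (length(presteady) > 0L)
    warns <- c(warns, list(warn_level(cfg$pre_steady_any,
      paste("pre-steady-state volumes:", paste(presteady, collapse = " ")))))
  if (nrow(vlines) > 0L)
    warns <- c(warns, list(warn_level(cfg$variance_lines_any,
      sprintf("%d variance line(s) detected", nrow(vlines)))))
  if (!is.null(flip))
    warns <- c(warns, list(warn_level(cfg$flip[[flip$guess]],
      sprintf("flip check: %s", flip$guess))))
  if (!is.null(coll) && nrow(coll) > 0L)
    warns <- c(warns, lapply(seq_len(nrow(coll)), function(r) warn_level(
      coll$level[r],
      if (coll$type[r] == "zero_var")
        sprintf("regressor %s has no variance over kept time points",
                coll$label1[r])
      else if (coll$type[r] == "pair")
        sprintf("|r|=%.3f between %s and %s", coll$value[r],
                coll$label1[r], coll$label2[r])
      else sprintf("design condition number %.3g", coll$value[r]))))
  warns <- c(warns, list(warn_level(
    grade_level(mot_summary$fraction, cfg$censor_fraction),
    sprintf("censor fraction %.4g", mot_summary$fraction))))
  warn_top <- aggregate_warns(warns)
  if (nrow(vlines) > 0L)
    utils::write.table(vlines, file.path(outdir, "variance_lines.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  # --- review dictionary
  review <- review_merge(
    review_dict("subject ID" = subject),
    review_from_censor(censor),
    review_from_ledger(ledger),
    review_dict(
      "TSNR average" = round(mean(tsnr$data[mask]), 2),
      "global correlation (GCOR)" = signif(g, 6),
      "anat/EPI mask Dice coef" = if (!is.null(anat))
        round(mask_dice(mask, automask(anat)), 6) else NULL,
      "orig voxel counts" = as.numeric(d3),
      "orig voxel resolution" = vol$voxdims,
      "TR" = vol$tr,
      "data min (stored)" = signif(rng_chk$min, 6),
      "data max (stored)" = signif(rng_chk$max, 6),
      "pre-steady-state volumes" = length(presteady),
      "num variance lines" = nrow(vlines),
      "max warning level" = warn_top$level
    ),
    if (!is.null(flip)) review_dict("flip guess" = flip$guess),
    if (!is.null(stim)) review_dict(
      "num regs of interest" = nrow(stim),
      "num TRs per stim (orig)" = stim$n_resp,
      "num TRs censored per stim" = stim$n_censored,
      "fraction TRs censored" = stim$fraction)
  )
  write_review(review, file.path(outdir, sprintf("out.ss_review.%s.txt", subject)),
               "colon")

  # --- report blocks
  blocks <- list(
    qc_block("vorig", "original EPI",
             items = list(
               "mean EPI (axial)" = render_montage(mean_epi, plane = "axial"),
               sprintf("stored range [%s, %s]%s", fmt_num(rng_chk$min),
                       fmt_num(rng_chk$max),
                       if (length(rng_chk$flags)) paste0(" flags: ",
                         paste(rng_chk$flags, collapse = ", ")) else "")),
             warn = rng_chk$warn),
    qc_block("vstat", "seed correlation",
             items = stats::setNames(list(
               render_montage(mean_epi, seedmap, plane = "axial")),
               sprintf("seed (%d,%d,%d) r-map, transparent alpha",
                       seed_ijk[1L], seed_ijk[2L], seed_ijk[3L]))),
    qc_block("mot", "motion and censoring",
             items = list(
               "grayplot (similarity order; enorm/outlier strips on top)" =
                 render_grayplot(gp),
               "censor summary" = tibble::tibble(
                 n_total = mot_summary$n_total,
                 n_censored = mot_summary$n_censored,
                 fraction = round(mot_summary$fraction, 6)),
               "series five-number summaries (BC / AC)" = tibble::tibble(
                 stat = names(mot_summary$bc),
                 BC = as.numeric(mot_summary$bc),
                 AC = as.numeric(mot_summary$ac))),
             warn = warn_level(grade_level(mot_summary$fraction,
                                           cfg$censor_fraction))),
    qc_block("regr", "regression and TSNR",
             items = c(list(
               "TSNR (volreg stage)" = render_montage(mean_epi, tsnr,
                                                      plane = "axial"),
               "corr_brain" = render_montage(mean_epi, cb, plane = "axial",
                                             thr = 0.3, vmax = 0.6),
               "DF ledger" = tibble::tibble(
                 n_total = ledger$n_total, censored = ledger$n_censored,
                 drift = ledger$df_drift, motion = ledger$df_motion,
                 bandpass = ledger$df_bandpass, other = ledger$df_other,
                 left = ledger$df_left,
                 frac_left = round(ledger$frac_left, 6))),
               if (!is.null(stim)) list("per-stimulus censoring" = stim),
               if (!is.null(atlas)) list("ROI TSNR/shape table" =
                 roi_warn(roi_table(tsnr, atlas, affine = vol$affine,
                                    voxdims = vol$voxdims)))),
             warn = ledger$warn),
    qc_block("radcor", "radial correlation",
             items = list("radcor (FWHM 20 mm)" =
               render_montage(mean_epi, radcor, plane = "axial",
                              thr = 0.7, vmax = 1))),
    qc_block("warns", "warnings",
             items = c(
               list("summary" = tibble::tibble(
                 check = c("intensity range", "pre-steady-state",
                           "variance lines", "flip", "censoring"),
                 result = c(
                   if (length(rng_chk$flags)) paste(rng_chk$flags, collapse = ", ")
                   else "ok",
                   if (length(presteady)) paste(presteady, collapse = " ")
                   else "none",
                   sprintf("%d detected", nrow(vlines)),
                   if (is.null(flip)) "not run" else flip$guess,
                   sprintf("fraction %.4g", mot_summary$fraction)))),
               if (nrow(vlines) > 0L) list("variance lines" = vlines),
               if (!is.null(coll) && nrow(coll) > 0L)
                 list("collinearity" = coll)),
             warn = warn_top)
  )
  build_report(blocks, review = review, outdir = outdir, subject = subject)
  invisible(list(review = review, censor = censor, ledger = ledger,
                 warns = warn_top, variance_lines = vlines, flip = flip,
                 gcor = g, tsnr = tsnr, outdir = outdir))
}
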