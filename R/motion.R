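#' Motion Euclidean norm (enorm)
#'
#' Per-volume motion magnitude: the Euclidean norm of the forward differences
#' of the six rigid-body motion parameters (three rotations in degrees, three
#' translations in mm, combined unweighted). The first volume of each run has
#' no predecessor and is assigned 0 — runs are acquired separately, so no
#' cross-run difference is taken.
#'
#' @param mp T x 6 numeric matrix of motion parameters
#'   (roll, pitch, yaw \[deg\], dS, dL, dP \[mm\]).
#' @param run_lengths Per-run volume counts summing to T (default one run).
#' @return Numeric length-T nonnegative vector.
#' @export
compute_enorm <- function(mp, run_lengths = NULL) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6L) stop("motion parameters must have 6 columns, got ", ncol(mp))
  nt <- nrow(mp)
  if (is.null(run_lengths)) run_lengths <- nt
  if (sum(run_lengths) != nt) stop("run_lengths must sum to ", nt)
  en <- numeric(nt)
  off <- 0L
  for (rl in run_lengths) {
    rows <- off + seq_len(rl)
    if (rl > 1L) {
      d <- diff(mp[rows, , drop = FALSE])
      en[rows[-1L]] <- sqrt(rowSums(d^2))
    }
    off <- off + rl
  }
  en
}

#' Per-volume outlier fractions
#'
#' For each in-mask voxel the time series is linearly detrended per run; a
#' time point is an outlier when the absolute residual exceeds
#' `k * 1.4826 * MAD` of that voxel's residuals, with
#' `k = qnorm(1 - alpha/2)`. The per-volume fraction is the share of mask
#' voxels that are outliers at that volume.
#'
#' @param vol A [volume_series()].
#' @param mask 3D binary mask (array or single-volume series).
#' @param alpha Two-sided tail probability defining the outlier threshold.
#' @return Numeric length-T vector of fractions in \[0, 1\].
#' @export
outlier_fractions <- function(vol, mask, alpha = 0.01) {
  nt <- n_timepoints(vol)
  if (nt < 4L) stop("need at least 4 time points, got ", nt)
  y <- masked_matrix(vol, mask)
  res <- detrend_poly(y, order = 1L, run_lengths = vol$run_lengths)
  k <- stats::qnorm(1 - alpha / 2)
  med <- apply(res, 1L, stats::median)
  madv <- apply(abs(res - med), 1L, stats::median)
  thr <- k * 1.4826 * madv
  # numerically-constant series must not register as outliers
  thr <- pmax(thr, 1e-8 * (rowMeans(abs(y)) + 1))
  out <- abs(res) > thr
  colSums(out) / nrow(y)
}

#' Build a censor vector from motion and outlier series
#'
#' A volume is censored when its enorm exceeds `enorm_limit` or its outlier
#' fraction exceeds `outlier_limit`. When `censor_prev` is on, the volume
#' preceding an enorm-censored one (within the same run) is censored too —
#' the enorm difference straddles both acquisitions.
#'
#' @param enorm Length-T enorm series (or NULL to censor on outliers only).
#' @param outliers Length-T outlier-fraction series (or NULL).
#' @param enorm_limit Censor limit for enorm (mm-deg), default 0.3.
#' @param outlier_limit Censor limit for the outlier fraction, default 0.1.
#' @param censor_prev Also censor the previous volume on enorm triggers.
#' @param run_lengths Per-run volume counts (neighbor censoring never crosses
#'   a run break).
#' @return An object of class `censor_vector`: list with `keep` (length-T
#'   0/1 integer vector), `reasons` (named character vector for censored
#'   indices: `"enorm"`, `"outlier"`, `"both"`, `"neighbor"`), and the limits.
#' @export
make_censor <- function(enorm = NULL, outliers = NULL,
                        enorm_limit = 0.3, outlier_limit = 0.1,
                        censor_prev = TRUE, run_lengths = NULL) {
  if (is.null(enorm) && is.null(outliers)) stop("supply enorm and/or outliers")
  if (!is.null(enorm) && !is.null(outliers) && length(enorm) != length(outliers))
    stop("enorm and outlier series must have equal length")
  if (enorm_limit <= 0 || outlier_limit <= 0) stop("censor limits must be positive")
  nt <- length(if (is.null(enorm)) outliers else enorm)
  if (is.null(run_lengths)) run_lengths <- nt
  if (sum(run_lengths) != nt) stop("run_lengths must sum to ", nt)
  e_hit <- if (is.null(enorm)) rep(FALSE, nt) else enorm > enorm_limit
  o_hit <- if (is.null(outliers)) rep(FALSE, nt) else outliers > outlier_limit
  reasons <- character(0L)
  keep <- rep(1L, nt)
  for (t in which(e_hit | o_hit)) {
    keep[t] <- 0L
    reasons[as.character(t)] <-
      if (e_hit[t] && o_hit[t]) "both" else if (e_hit[t]) "enorm" else "outlier"
  }
  if (censor_prev) {
    run_start <- cumsum(c(1L, run_lengths[-length(run_lengths)]))
    for (t in which(e_hit)) {
      p <- t - 1L
      if (p >= 1L && !(t %in% run_start) && keep[p] == 1L) {
        keep[p] <- 0L
        reasons[as.character(p)] <- "neighbor"
      }
    }
  }
  structure(list(keep = keep, reasons = reasons,
                 enorm_limit = enorm_limit, outlier_limit = outlier_limit,
                 run_lengths = as.integer(run_lengths)),
            class = "censor_vector")
}

#' @export
print.censor_vector <- function(x, ...) {
  nc <- sum(x$keep == 0L)
  cat(sprintf("<censor_vector> %d / %d volumes censored (enorm > %g, outlier > %g)\n",
              nc, length(x$keep), x$enorm_limit, x$outlier_limit))
  if (nc > 0L)
    cat("  censored:", paste(censored_indices(x), collapse = " "), "\n")
  invisible(x)
}

#' Indices of censored volumes
#' @param censor A `censor_vector`.
#' @return Sorted integer vector of 1-based censored indices.
#' @export
censored_indices <- function(censor) which(censor$keep == 0L)

#' Write a censor vector as a one-column 1D file (1 keep / 0 censor)
#' @param censor A `censor_vector`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_censor_1d <- function(censor, path) {
  write_table_1d(matrix(censor$keep, ncol = 1L), path,
                 comments = sprintf("censor: enorm_limit %g, outlier_limit %g",
                                    censor$enorm_limit, censor$outlier_limit))
}

#' Summarize a series before and after censoring
#'
#' Five-number summaries (min, q25, median, q75, max) of a per-volume series
#' both before censoring (BC: all volumes) and after censoring (AC: kept
#' volumes only), plus per-run censored fractions.
#'
#' @param series Length-T numeric series (e.g. enorm or outlier fractions).
#' @param censor A `censor_vector` of matching length.
#' @param run_lengths Per-run volume counts; defaults to the censor's.
#' @return A list of class `censor_summary`: `n_total`, `n_censored`,
#'   `fraction`, `per_run_fractions`, `bc` and `ac` named five-number
#'   vectors (`ac` is all-NA, flagged `ac_empty`, when everything is censored).
#' @export
censor_summary <- function(series, censor, run_lengths = NULL) {
  nt <- length(series)
  if (nt != length(censor$keep)) stop("series and censor lengths differ")
  if (is.null(run_lengths)) run_lengths <- censor$run_lengths
  if (sum(run_lengths) != nt) stop("run_lengths must sum to ", nt)
  run_id <- rep(seq_along(run_lengths), run_lengths)
  kept <- censor$keep == 1L
  five <- function(x) {
    if (length(x) == 0L)
      return(c(min = NA_real_, q25 = NA_real_, median = NA_real_,
               q75 = NA_real_, max = NA_real_))
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    c(min = q[1L], q25 = q[2L], median = q[3L], q75 = q[4L], max = q[5L])
  }
  per_run <- vapply(seq_along(run_lengths),
                    function(r) mean(!kept[run_id == r]), numeric(1L))
  structure(list(
    n_total = nt,
    n_censored = sum(!kept),
    fraction = sum(!kept) / nt,
    per_run_fractions = per_run,
    bc = five(series),
    ac = five(series[kept]),
    ac_empty = !any(kept)
  ), class = "censor_summary")
}

#' @export
print.censor_summary <- function(x, ...) {
  cat(sprintf("<censor_summary> %d / %d censored (fraction %.6g)\n",
              x$n_censored, x$n_total, x$fraction))
  cat("  per-run fractions:", paste(fmt_num(x$per_run_fractions), collapse = " "), "\n")
  cat("  BC:", paste(sprintf("%.4g", x$bc), collapse = " "),
      "| AC:", if (x$ac_empty) "(empty)" else paste(sprintf("%.4g", x$ac), collapse = " "), "\n")
  invisible(x)
}

#' Review-dictionary entries for censoring
#'
#' Emits the standard censor-count labels (TR counts, per-run and overall
#' censored fractions). Overall fractions are rounded to 6 decimals and
#' per-run fractions to 6 significant digits, matching the conventional
#' review-file formatting.
#'
#' @param censor A `censor_vector`.
#' @return A [review_dict()].
#' @export
review_from_censor <- function(censor) {
  nt <- length(censor$keep)
  nc <- sum(censor$keep == 0L)
  rl <- censor$run_lengths
  run_id <- rep(seq_along(rl), rl)
  per_run_cens <- vapply(seq_along(rl),
                         function(r) sum(censor$keep[run_id == r] == 0L), numeric(1L))
  review_dict(
    "num runs found" = length(rl),
    "num TRs per run" = as.numeric(rl),
    "num TRs per run (applied)" = as.numeric(rl) - per_run_cens,
    "num TRs per run (censored)" = per_run_cens,
    "fraction censored per run" = signif(per_run_cens / rl, 6),
    "TRs total (uncensored)" = nt,
    "TRs total" = nt - nc,
    "TRs censored" = nc,
    "censor fraction" = round(nc / nt, 6)
  )
}
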